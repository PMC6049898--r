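# The intensity-mixture detector: a nine-parameter two-component model over
# (target, partner) peak-intensity pairs, fitted by expectation maximization.
#
# Model: p(x, y) = w * f_c(x) g_c(y) + (1 - w) * f_n(x) g_n(y), where each
# marginal f/g is log-normal (default), gamma, or Gaussian, and the two
# intensities are assumed independent within each component. The cooperative
# component is, by assumption and by post-fit relabeling, the one whose
# target-axis mean is lower: a cooperatively bound target TF tends to bind
# more weakly than a non-cooperatively bound one.

.families <- c("lognormal", "gamma", "gaussian")

#' Marginal distribution parameters
#'
#' @param family one of `"lognormal"`, `"gamma"`, `"gaussian"`.
#' @param location log-mean for lognormal, mean for gaussian, shape `k` for
#'   gamma.
#' @param scale log-sd for lognormal, sd for gaussian, scale `theta` for
#'   gamma; must be positive.
#' @return a list with class `marginal_params`.
#' @export
marginal_params <- function(family, location, scale) {
  family <- match.arg(family, .families)
  if (!is.finite(location) || !is.finite(scale) || scale <= 0) {
    stop("invalid marginal parameters: scale must be positive and finite")
  }
  if (family == "gamma" && location <= 0) stop("gamma shape must be > 0")
  structure(list(family = family, location = location, scale = scale),
            class = "marginal_params")
}

#' Marginal density of one intensity axis
#'
#' @param params a [marginal_params()].
#' @param x intensity values; must be strictly positive for the lognormal
#'   and gamma families.
#' @param log return log-density?
#' @return density (or log-density) values.
#' @export
marginal_density <- function(params, x, log = FALSE) {
  stopifnot(inherits(params, "marginal_params"))
  if (params$family %in% c("lognormal", "gamma") && any(x <= 0)) {
    stop("intensities must be > 0 for the ", params$family, " family")
  }
  switch(params$family,
    lognormal = stats::dlnorm(x, meanlog = params$location,
                              sdlog = params$scale, log = log),
    gamma = stats::dgamma(x, shape = params$location,
                          scale = params$scale, log = log),
    gaussian = stats::dnorm(x, mean = params$location,
                            sd = params$scale, log = log)
  )
}

# Target-axis mean used to decide which fitted component is "cooperative":
# the log-location for lognormal, the mean for gaussian, k * theta for gamma.
#' @keywords internal
axis_mean <- function(params) {
  switch(params$family,
    lognormal = params$location,
    gaussian = params$location,
    gamma = params$location * params$scale
  )
}

# Weighted maximum-likelihood fit of one marginal. `w` are responsibilities.
#' @keywords internal
fit_marginal_weighted <- function(x, w, family,
                                  scale_floor = 1e-6) {
  sw <- sum(w)
  if (family == "lognormal") {
    lx <- log(x)
    mu <- sum(w * lx) / sw
    sigma <- sqrt(sum(w * (lx - mu)^2) / sw)
    marginal_params("lognormal", mu, max(sigma, scale_floor))
  } else if (family == "gaussian") {
    mu <- sum(w * x) / sw
    sigma <- sqrt(sum(w * (x - mu)^2) / sw)
    marginal_params("gaussian", mu, max(sigma, scale_floor))
  } else {
    # gamma: Newton iterations on the shape via the digamma equation
    #   log k - digamma(k) = log(weighted mean) - weighted mean of log x,
    # weighted method-of-moments fallback on non-convergence.
    mw <- sum(w * x) / sw
    c0 <- log(mw) - sum(w * log(x)) / sw
    vw <- sum(w * (x - mw)^2) / sw
    mom <- function() {
      k <- max(mw^2 / max(vw, 1e-12), 1e-3)
      marginal_params("gamma", min(k, 1e6), max(mw / min(k, 1e6), scale_floor))
    }
    if (!is.finite(c0) || c0 <= 0) return(mom())
    k <- (3 - c0 + sqrt((c0 - 3)^2 + 24 * c0)) / (12 * c0)
    ok <- FALSE
    for (it in 1:50) {
      f <- log(k) - digamma(k) - c0
      fp <- 1 / k - trigamma(k)
      step <- f / fp
      k_new <- k - step
      if (!is.finite(k_new) || k_new <= 0) break
      if (abs(k_new - k) < 1e-10 * max(1, k)) { k <- k_new; ok <- TRUE; break }
      k <- k_new
    }
    if (!ok || !is.finite(k) || k <= 0) return(mom())
    k <- min(k, 1e6)
    marginal_params("gamma", k, max(mw / k, scale_floor))
  }
}

#' @keywords internal
joint_log_density <- function(comp_target, comp_partner, x, y) {
  marginal_density(comp_target, x, log = TRUE) +
    marginal_density(comp_partner, y, log = TRUE)
}

# One EM run from a given parameter state. Log-likelihood is asserted
# non-decreasing at every iteration (a defining property of EM).
#' @keywords internal
run_em <- function(x, y, family, init, tol, max_iter,
                   resp_clamp = 1e-12, weight_clamp = 1e-6) {
  n <- length(x)
  par <- init
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    lc <- log(par$weight) +
      joint_log_density(par$coop_target, par$coop_partner, x, y)
    ln <- log(1 - par$weight) +
      joint_log_density(par$noncoop_target, par$noncoop_partner, x, y)
    lse <- logsumexp2(lc, ln)
    ll <- sum(lse)
    if (!is.finite(ll)) stop("degenerate fit: non-finite log-likelihood")
    if (ll < ll_old - 1e-8 * max(1, abs(ll_old))) {
      stop("EM log-likelihood decreased; this indicates a numerical fault")
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * max(1, abs(ll_old))) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll
    r <- exp(lc - lse)
    r <- pmin(pmax(r, resp_clamp), 1 - resp_clamp)
    par$weight <- min(max(mean(r), weight_clamp), 1 - weight_clamp)
    par$coop_target <- fit_marginal_weighted(x, r, family)
    par$coop_partner <- fit_marginal_weighted(y, r, family)
    par$noncoop_target <- fit_marginal_weighted(x, 1 - r, family)
    par$noncoop_partner <- fit_marginal_weighted(y, 1 - r, family)
  }
  list(par = par, log_likelihood = ll, n_iterations = iter,
       converged = converged, ll_trace = ll_trace)
}

# Deterministic initialization: split at the median target intensity; the
# low half seeds the cooperative component (which the model assumes binds
# the target more weakly); initial weight 0.5. Restarts beyond the first
# perturb this state multiplicatively.
#' @keywords internal
init_from_median_split <- function(x, y, family, perturb = 0) {
  low <- x <= stats::median(x)
  if (all(low) || !any(low)) low <- seq_along(x) <= length(x) / 2
  r <- as.numeric(low)
  r <- pmin(pmax(r, 0.05), 0.95)  # keep both components informed by all data
  init <- list(
    weight = 0.5,
    coop_target = fit_marginal_weighted(x, r, family),
    coop_partner = fit_marginal_weighted(y, r, family),
    noncoop_target = fit_marginal_weighted(x, 1 - r, family),
    noncoop_partner = fit_marginal_weighted(y, 1 - r, family)
  )
  if (perturb > 0) {
    jitter <- function(p) {
      loc <- p$location * exp(stats::rnorm(1, 0, perturb))
      if (p$family != "gamma" && stats::runif(1) < 0.5) {
        loc <- p$location + stats::rnorm(1, 0, perturb * max(1, abs(p$location)))
      }
      sc <- p$scale * exp(stats::rnorm(1, 0, perturb))
      if (p$family == "gamma") loc <- max(loc, 1e-3)
      marginal_params(p$family, loc, max(sc, 1e-6))
    }
    init$coop_target <- jitter(init$coop_target)
    init$coop_partner <- jitter(init$coop_partner)
    init$noncoop_target <- jitter(init$noncoop_target)
    init$noncoop_partner <- jitter(init$noncoop_partner)
    init$weight <- min(max(stats::runif(1, 0.2, 0.8), 1e-6), 1 - 1e-6)
  }
  init
}

#' Fit the two-component intensity mixture by expectation maximization
#'
#' Fits `p(x, y) = w f_c(x) g_c(y) + (1 - w) f_n(x) g_n(y)` to the intensity
#' pairs of overlapping peaks. The nine free parameters are the location and
#' scale of the four marginals plus the cooperative weight `w`. After
#' fitting, the component with the lower target-axis mean is labeled
#' cooperative (ties broken by the lower partner-axis mean).
#'
#' @param pairs a [find_overlapping_pairs()] result, or any data frame with
#'   numeric columns `x` (target intensity) and `y` (partner intensity).
#' @param family marginal family: `"lognormal"` (default), `"gamma"`, or
#'   `"gaussian"`.
#' @param n_restarts number of EM runs; the first uses a deterministic
#'   median-split initialization, the rest perturb it randomly. The run with
#'   the highest final log-likelihood is returned.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per run.
#' @param seed integer seed for the restart perturbations (ignored when
#'   `n_restarts == 1`).
#' @return an object of class `cpiem_model`: the four fitted
#'   [marginal_params()], `weight` (cooperative fraction), `log_likelihood`,
#'   `n_iterations`, `converged`, and the per-iteration `ll_trace` of the
#'   winning run.
#' @export
fit_cpiem <- function(pairs, family = "lognormal", n_restarts = 1L,
                      tol = 1e-6, max_iter = 1000L, seed = 1L) {
  family <- match.arg(family, .families)
  x <- pairs$x
  y <- pairs$y
  if (length(x) < 20L) {
    stop("need at least 20 intensity pairs to fit the mixture")
  }
  if (family %in% c("lognormal", "gamma") && any(x <= 0 | y <= 0)) {
    stop("intensities must be > 0 for the ", family, " family")
  }
  if (length(unique(x)) == 1L && length(unique(y)) == 1L) {
    stop("degenerate fit: all intensity pairs are identical")
  }
  runs <- with_seed(if (n_restarts > 1L) seed else NULL, {
    lapply(seq_len(n_restarts), function(k) {
      init <- init_from_median_split(x, y, family,
                                     perturb = if (k == 1L) 0 else 0.3)
      tryCatch(run_em(x, y, family, init, tol, max_iter),
               error = function(e) NULL)
    })
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L) stop("degenerate fit: no EM run completed")
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "log_likelihood"))]]
  par <- best$par
  # fix component identity: cooperative = lower target-axis mean
  mt_c <- axis_mean(par$coop_target)
  mt_n <- axis_mean(par$noncoop_target)
  swap <- mt_c > mt_n ||
    (mt_c == mt_n && axis_mean(par$coop_partner) > axis_mean(par$noncoop_partner))
  if (swap) {
    par <- list(weight = 1 - par$weight,
                coop_target = par$noncoop_target,
                coop_partner = par$noncoop_partner,
                noncoop_target = par$coop_target,
                noncoop_partner = par$coop_partner)
  }
  structure(list(
    family = family,
    coop_target = par$coop_target, coop_partner = par$coop_partner,
    noncoop_target = par$noncoop_target, noncoop_partner = par$noncoop_partner,
    weight = par$weight,
    log_likelihood = best$log_likelihood,
    n_iterations = best$n_iterations,
    converged = best$converged,
    ll_trace = best$ll_trace,
    n_pairs = length(x)
  ), class = "cpiem_model")
}

#' @export
print.cpiem_model <- function(x, ...) {
  cat("Two-component", x$family, "intensity mixture\n")
  cat(sprintf("  cooperative fraction w = %.4f\n", x$weight))
  fmt <- function(p, lab) {
    cat(sprintf("  %-16s location = %8.4f  scale = %8.4f\n",
                lab, p$location, p$scale))
  }
  fmt(x$coop_target, "coop target")
  fmt(x$coop_partner, "coop partner")
  fmt(x$noncoop_target, "noncoop target")
  fmt(x$noncoop_partner, "noncoop partner")
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s)\n",
              x$log_likelihood, x$n_iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Posterior probability of cooperative binding
#'
#' Bayes' formula under the fitted mixture:
#' `P(coop | x, y) = w f_c(x) g_c(y) / [w f_c(x) g_c(y) + (1-w) f_n(x) g_n(y)]`,
#' evaluated in log space to remain accurate at extreme intensities.
#'
#' @param model a fitted [fit_cpiem()] model.
#' @param pairs a data frame with columns `x` and `y`, or a numeric vector of
#'   target intensities (then `y` must be supplied).
#' @param y partner intensities when `pairs` is a numeric vector.
#' @return posterior probabilities in `[0, 1]`, one per pair.
#' @export
posterior_coop <- function(model, pairs, y = NULL) {
  stopifnot(inherits(model, "cpiem_model"))
  if (is.numeric(pairs) && !is.null(y)) {
    x <- pairs
  } else {
    x <- pairs$x
    y <- pairs$y
  }
  lc <- log(model$weight) +
    joint_log_density(model$coop_target, model$coop_partner, x, y)
  ln <- log(1 - model$weight) +
    joint_log_density(model$noncoop_target, model$noncoop_partner, x, y)
  p <- 1 / (1 + exp(ln - lc))
  # resolve 0/0 when both components vanish: fall back to the prior weight
  p[is.infinite(lc) & is.infinite(ln)] <- model$weight
  p
}

#' Threshold posteriors into cooperative / non-cooperative calls
#'
#' A pair is called cooperative iff its posterior exceeds `alpha` strictly.
#'
#' @param posteriors posterior probabilities from [posterior_coop()].
#' @param alpha decision threshold in `[0, 1]`.
#' @return logical vector, `TRUE` for cooperative calls.
#' @export
classify_pairs <- function(posteriors, alpha) {
  stopifnot(length(alpha) == 1L, alpha >= 0, alpha <= 1)
  posteriors > alpha
}

#' Serialize a fitted model to a plain-text key-value file
#'
#' @param model a `cpiem_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpiem_model <- function(model, path) {
  stopifnot(inherits(model, "cpiem_model"))
  kv <- c(
    family = model$family,
    coop_target_location = model$coop_target$location,
    coop_target_scale = model$coop_target$scale,
    coop_partner_location = model$coop_partner$location,
    coop_partner_scale = model$coop_partner$scale,
    noncoop_target_location = model$noncoop_target$location,
    noncoop_target_scale = model$noncoop_target$scale,
    noncoop_partner_location = model$noncoop_partner$location,
    noncoop_partner_scale = model$noncoop_partner$scale,
    weight = model$weight,
    log_likelihood = model$log_likelihood,
    n_iterations = model$n_iterations,
    converged = tolower(as.character(model$converged)),
    n_pairs = model$n_pairs
  )
  writeLines(sprintf("%s\t%s", names(kv),
                     vapply(kv, function(v) {
                       if (suppressWarnings(!is.na(as.numeric(v)))) {
                         format(as.numeric(v), digits = 17)
                       } else v
                     }, character(1))), path)
  invisible(path)
}

#' Read a model written by [write_cpiem_model()]
#'
#' @param path path to the key-value model file.
#' @return a `cpiem_model` (without the iteration trace).
#' @export
read_cpiem_model <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(parts, `[`, character(1), 2L),
                        vapply(parts, `[`, character(1), 1L))
  fam <- kv[["family"]]
  mp <- function(loc, sc) {
    marginal_params(fam, as.numeric(kv[[loc]]), as.numeric(kv[[sc]]))
  }
  structure(list(
    family = fam,
    coop_target = mp("coop_target_location", "coop_target_scale"),
    coop_partner = mp("coop_partner_location", "coop_partner_scale"),
    noncoop_target = mp("noncoop_target_location", "noncoop_target_scale"),
    noncoop_partner = mp("noncoop_partner_location", "noncoop_partner_scale"),
    weight = as.numeric(kv[["weight"]]),
    log_likelihood = as.numeric(kv[["log_likelihood"]]),
    n_iterations = as.integer(as.numeric(kv[["n_iterations"]])),
    converged = identical(kv[["converged"]], "true"),
    ll_trace = numeric(0),
    n_pairs = as.integer(as.numeric(kv[["n_pairs"]]))
  ), class = "cpiem_model")
}
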