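test_that("marginal densities match closed forms for all three families", {
  ln <- marginal_params("lognormal", 0, 1)
  # ln(1) = 0: density 1/sqrt(2*pi)
  expect_equal(marginal_density(ln, 1), 1 / sqrt(2 * pi), tolerance = 1e-12)
  # direct evaluation of (1/(x sigma sqrt(2 pi))) exp(-(ln x - mu)^2 / (2 sigma^2))
  # = exp(-1/2) / (e * sqrt(2 pi)) = 0.0890164
  expect_equal(marginal_density(ln, exp(1)),
               exp(-0.5) / (exp(1) * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(marginal_density(ln, exp(1)), 0.0890161, tolerance = 1e-6)
  # gamma with shape 1 is the exponential: 0.5 exp(-x/2)
  ga <- marginal_params("gamma", 1, 2)
  expect_equal(marginal_density(ga, 2), 0.18394, tolerance = 1e-4)
  expect_equal(marginal_density(ga, 1e-9), 0.5, tolerance = 1e-6)
  gs <- marginal_params("gaussian", 3, 0.5)
  expect_equal(marginal_density(gs, 3), 1 / (0.5 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_error(marginal_density(ln, 0), "> 0")
  expect_error(marginal_density(ga, -1), "> 0")
  expect_error(marginal_params("lognormal", 0, -1))
  expect_error(marginal_params("gamma", -2, 1))
})

test_that("fitted marginals integrate to one", {
  fits <- list(
    marginal_params("lognormal", 1.3, 0.6),
    marginal_params("gamma", 2.5, 1.7),
    marginal_params("gaussian", 4, 2)
  )
  lowers <- c(1e-12, 1e-12, -Inf)
  for (i in seq_along(fits)) {
    total <- integrate(function(z) marginal_density(fits[[i]], z),
                       lowers[i], Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("EM recovers the generating parameters of the lognormal mixture", {
  cfg <- sim_config(n_pairs = 4000, seed = 100)
  sim <- simulate_intensity_pairs(cfg)
  model <- fit_cpiem(sim$pairs, family = "lognormal", seed = 1)
  expect_true(model$converged)
  expect_lt(abs(model$weight - 0.4), 0.05)
  expect_lt(abs(model$coop_target$location - 1.0), 0.1)
  expect_lt(abs(model$coop_partner$location - 2.0), 0.1)
  expect_lt(abs(model$noncoop_target$location - 2.5), 0.1)
  expect_lt(abs(model$noncoop_partner$location - 2.1), 0.1)
  # component identity: cooperative component has the lower target location
  expect_lt(model$coop_target$location, model$noncoop_target$location)
  # stored log-likelihood equals the sum of log densities under the fit
  ll <- sum(log(
    model$weight *
      marginal_density(model$coop_target, sim$pairs$x) *
      marginal_density(model$coop_partner, sim$pairs$y) +
    (1 - model$weight) *
      marginal_density(model$noncoop_target, sim$pairs$x) *
      marginal_density(model$noncoop_partner, sim$pairs$y)))
  expect_equal(model$log_likelihood, ll, tolerance = 1e-8)
})

test_that("a generic numerical maximizer cannot improve on the EM solution", {
  cfg <- sim_config(n_pairs = 1000, seed = 17)
  sim <- simulate_intensity_pairs(cfg)
  model <- fit_cpiem(sim$pairs, seed = 1)
  negll <- function(theta) {
    w <- 1 / (1 + exp(-theta[9]))
    -sum(logsumexp2_oracle(
      log(w) + dlnorm(sim$pairs$x, theta[1], exp(theta[2]), log = TRUE) +
        dlnorm(sim$pairs$y, theta[3], exp(theta[4]), log = TRUE),
      log(1 - w) + dlnorm(sim$pairs$x, theta[5], exp(theta[6]), log = TRUE) +
        dlnorm(sim$pairs$y, theta[7], exp(theta[8]), log = TRUE)))
  }
  logsumexp2_oracle <- function(a, b) {
    m <- pmax(a, b); m + log(exp(a - m) + exp(b - m))
  }
  start <- c(model$coop_target$location, log(model$coop_target$scale),
             model$coop_partner$location, log(model$coop_partner$scale),
             model$noncoop_target$location, log(model$noncoop_target$scale),
             model$noncoop_partner$location, log(model$noncoop_partner$scale),
             log(model$weight / (1 - model$weight)))
  opt <- optim(start, negll, method = "BFGS", control = list(maxit = 200))
  expect_lt(-opt$value - model$log_likelihood,
            1e-4 * abs(model$log_likelihood))
})

test_that("gamma and gaussian mixtures also recover their generating parameters", {
  set.seed(5)
  n <- 3000
  coop <- runif(n) < 0.35
  x <- ifelse(coop, rgamma(n, shape = 2, scale = 1.5),
              rgamma(n, shape = 8, scale = 1.5))
  y <- ifelse(coop, rgamma(n, shape = 5, scale = 1),
              rgamma(n, shape = 5.5, scale = 1))
  mg <- fit_cpiem(data.frame(x = x, y = y), family = "gamma", seed = 1)
  expect_lt(abs(mg$weight - 0.35), 0.07)
  # component means (k * theta) on the target axis: 3 vs 12
  expect_lt(abs(mg$coop_target$location * mg$coop_target$scale - 3), 0.6)
  expect_lt(abs(mg$noncoop_target$location * mg$noncoop_target$scale - 12), 0.8)
  xg <- ifelse(coop, rnorm(n, 2, 0.7), rnorm(n, 6, 1))
  yg <- ifelse(coop, rnorm(n, 4, 1), rnorm(n, 4.2, 1))
  mn <- fit_cpiem(data.frame(x = xg, y = yg), family = "gaussian", seed = 1)
  expect_lt(abs(mn$weight - 0.35), 0.05)
  expect_lt(abs(mn$coop_target$location - 2), 0.15)
  expect_lt(abs(mn$noncoop_target$location - 6), 0.15)
})

test_that("EM input validation and degenerate data are rejected", {
  expect_error(fit_cpiem(data.frame(x = rlnorm(5), y = rlnorm(5))),
               "at least 20")
  same <- data.frame(x = rep(3, 50), y = rep(4, 50))
  expect_error(fit_cpiem(same), "degenerate")
  neg <- data.frame(x = c(rlnorm(30), -1), y = rlnorm(31))
  expect_error(fit_cpiem(neg), "> 0")
})

test_that("posterior is the Bayes ratio, equal-component mixtures return the weight", {
  cfg <- sim_config(n_pairs = 500, seed = 23)
  sim <- simulate_intensity_pairs(cfg)
  model <- fit_cpiem(sim$pairs, seed = 1)
  post <- posterior_coop(model, sim$pairs)
  expect_true(all(post >= 0 & post <= 1))
  # brute-force direct evaluation of the density ratio
  num <- model$weight *
    marginal_density(model$coop_target, sim$pairs$x) *
    marginal_density(model$coop_partner, sim$pairs$y)
  den <- num + (1 - model$weight) *
    marginal_density(model$noncoop_target, sim$pairs$x) *
    marginal_density(model$noncoop_partner, sim$pairs$y)
  expect_lt(max(abs(post - num / den)), 1e-12)
  # identical components: posterior equals the prior weight for every pair
  flat <- model
  flat$coop_target <- flat$noncoop_target
  flat$coop_partner <- flat$noncoop_partner
  flat$weight <- 0.3
  expect_equal(posterior_coop(flat, sim$pairs), rep(0.3, nrow(sim$pairs)),
               tolerance = 1e-12)
})

test_that("posterior matches a hand-evaluated two-density case and tail limits", {
  m <- structure(list(
    family = "lognormal",
    coop_target = marginal_params("lognormal", 0, 1),
    coop_partner = marginal_params("lognormal", 0, 1),
    noncoop_target = marginal_params("lognormal", 1, 1),
    noncoop_partner = marginal_params("lognormal", 0, 1),
    weight = 0.5), class = "cpiem_model")
  # partner terms cancel; 0.39894 / (0.39894 + 0.24197)
  expect_equal(posterior_coop(m, data.frame(x = 1, y = 1)), 0.622459,
               tolerance = 1e-5)
  # x -> 0+ with the cooperative log-mean lower: posterior -> 1
  expect_gt(posterior_coop(m, data.frame(x = 1e-12, y = 1)), 0.999)
})

test_that("classification threshold is strict", {
  expect_true(classify_pairs(0.6, 0.5))
  expect_false(classify_pairs(0.5, 0.5))
  expect_equal(classify_pairs(c(0, 1e-9, 0.3), 0), c(FALSE, TRUE, TRUE))
})

test_that("model serialization round-trips through the key-value file", {
  cfg <- sim_config(n_pairs = 200, seed = 3)
  sim <- simulate_intensity_pairs(cfg)
  model <- fit_cpiem(sim$pairs, seed = 1)
  path <- tempfile(fileext = ".txt")
  write_cpiem_model(model, path)
  back <- read_cpiem_model(path)
  for (f in c("family", "weight", "log_likelihood", "n_iterations",
              "converged")) {
    expect_equal(back[[f]], model[[f]], tolerance = 1e-12)
  }
  expect_equal(back$coop_target, model$coop_target, tolerance = 1e-12)
  expect_equal(back$noncoop_partner, model$noncoop_partner, tolerance = 1e-12)
  # posteriors from the restored model agree
  expect_equal(posterior_coop(back, sim$pairs), posterior_coop(model, sim$pairs),
               tolerance = 1e-10)
})

test_that("the lognormal fit is cross-checked by an independent single-sample fit", {
  # one-component sanity: with weight pinned by identical components, the
  # marginal fit of all x equals fitdistrplus's MLE on the same data
  set.seed(31)
  x <- rlnorm(2000, 1.4, 0.7)
  fd <- suppressWarnings(fitdistrplus::fitdist(x, "lnorm"))
  ours <- cpiem:::fit_marginal_weighted(x, rep(1, length(x)), "lognormal")
  expect_equal(ours$location, unname(fd$estimate["meanlog"]), tolerance = 1e-3)
  expect_equal(ours$scale, unname(fd$estimate["sdlog"]), tolerance = 1e-3)
})
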