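#' Run code with a temporary RNG seed
#'
#' Sets the random seed, evaluates `expr`, and restores the caller's RNG
#' state afterwards so that seeded helpers do not perturb outer simulations.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Numerically stable log(exp(a) + exp(b))
#' @keywords internal
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf: log(0 + 0)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Nearest-rank percentile (ceiling convention)
#'
#' The p-th percentile of `x` is the value at sorted position
#' `ceiling(p/100 * length(x))`. This convention is stated explicitly because
#' call/flag boundaries in the indirect-binding filter depend on it bit for
#' bit.
#'
#' @param x numeric vector, non-empty.
#' @param p percentile level in (0, 100].
#' @return a single value of `x`.
#' @export
nearest_rank_percentile <- function(x, p) {
  if (length(x) == 0L) stop("empty vector: cannot take a percentile")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 100) {
    stop("percentile level must be a single number in (0, 100]")
  }
  sort(x)[ceiling(p / 100 * length(x))]
}
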