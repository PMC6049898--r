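# Detection-performance metrics: ROC / precision-recall against knockout
# labels, plus the diagnostic statistics used to check model assumptions
# (rank-sum intensity comparison, mutual information between the two
# intensity axes, motif-score/intensity correlation).

#' @keywords internal
as_coop_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    return(labels %in% c("cooperative", "coop", "C", "TRUE", "1"))
  }
  as.logical(labels)
}

#' ROC curve and auROC
#'
#' Computes `FPR(alpha) = N_FP / N_nc` and `TPR(alpha) = N_TP / N_c` as the
#' decision threshold sweeps over the unique score values (descending; a
#' region is called cooperative when its score strictly exceeds the
#' threshold, so all observations sharing a score enter at one threshold).
#' The area is computed by the trapezoidal rule, which under this tie
#' convention equals the Mann-Whitney U statistic normalized by
#' `N_c * N_nc`.
#'
#' @param labels cooperative / non-cooperative truth: logical, or characters
#'   where `"cooperative"` marks positives.
#' @param scores detector scores (higher = more cooperative), same length.
#' @return object of class `roc_curve`: `thresholds` (descending), `fpr`,
#'   `tpr` (each starting at 0, ending at 1), and `auroc`.
#' @export
roc_curve <- function(labels, scores) {
  pos <- as_coop_logical(labels)
  if (length(pos) != length(scores)) stop("labels and scores lengths differ")
  n_c <- sum(pos)
  n_nc <- sum(!pos)
  if (n_c == 0L || n_nc == 0L) {
    stop("both cooperative and non-cooperative labels must be present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(pos & scores == t), numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(!pos & scores == t), numeric(1)))
  tpr <- c(0, tp / n_c)
  fpr <- c(0, fp / n_nc)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr,
                 auroc = auroc, n_c = n_c, n_nc = n_nc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d cooperative vs %d non-cooperative, auROC = %.4f\n",
              x$n_c, x$n_nc, x$auroc))
  invisible(x)
}

#' Precision-recall curve and area
#'
#' Precision and recall at each unique score threshold (calls are
#' score >= threshold, descending), with area by step-wise integration
#' (precision at each threshold times the recall increment it contributes).
#'
#' @inheritParams roc_curve
#' @return object of class `pr_curve`: `thresholds`, `precision`, `recall`,
#'   `area`.
#' @export
precision_recall_curve <- function(labels, scores) {
  pos <- as_coop_logical(labels)
  if (length(pos) != length(scores)) stop("labels and scores lengths differ")
  n_c <- sum(pos)
  if (n_c == 0L || sum(!pos) == 0L) {
    stop("both cooperative and non-cooperative labels must be present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(pos & scores == t), numeric(1)))
  called <- cumsum(vapply(thr, function(t) sum(scores == t), numeric(1)))
  precision <- tp / called
  recall <- tp / n_c
  area <- sum(diff(c(0, recall)) * precision)
  structure(list(thresholds = thr, precision = precision, recall = recall,
                 area = area),
            class = "pr_curve")
}

#' Write a ROC or PR curve as a tab-separated table
#'
#' @param curve a `roc_curve` or `pr_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- if (inherits(curve, "roc_curve")) {
    data.frame(threshold = curve$thresholds, fpr = curve$fpr, tpr = curve$tpr)
  } else {
    data.frame(threshold = curve$thresholds,
               precision = curve$precision, recall = curve$recall)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by full enumeration of all `choose(n + m, n)` rank
#' assignments when `min(n, m) <= 8` (ties handled by average ranks);
#' normal approximation with tie correction otherwise. Used to compare
#' cooperative vs non-cooperative peak-intensity distributions.
#'
#' @param sample_a,sample_b numeric samples, both non-empty.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b) {
  n <- length(sample_a)
  m <- length(sample_b)
  if (n == 0L || m == 0L) stop("both samples must be non-empty")
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled, ties.method = "average")
  w_obs <- sum(r[seq_len(n)])
  if (min(n, m) <= 8L) {
    idx <- utils::combn(n + m, n)
    w_all <- colSums(matrix(r[idx], nrow = n))
    eps <- 1e-9
    p <- 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps))
    return(min(1, p))
  }
  mu <- n * (n + m + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
  sigma2 <- n * m / 12 * (n + m + 1 - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (w_obs - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Mutual information between two intensity vectors
#'
#' Plug-in estimate on equal-frequency (quantile) bins with a base-2
#' logarithm. Quantile bins are used because ChIP-seq intensities are
#' heavy-tailed. Used to check the within-component independence assumption
#' of the intensity mixture.
#'
#' @param x,y numeric vectors of equal length, at least `n_bins^2` long.
#' @param n_bins number of quantile bins per axis (default 4).
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y, n_bins = 4L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < n_bins^2) {
    stop("need at least n_bins^2 observations for the plug-in estimate")
  }
  qbin <- function(v) {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2L) return(rep(1L, length(v)))  # constant input: one bin
    as.integer(cut(v, breaks = br, include.lowest = TRUE))
  }
  bx <- qbin(x)
  by <- qbin(y)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  terms <- joint * log2(joint / outer(px, py))
  sum(terms[joint > 0])
}

#' Squared Pearson correlation
#'
#' @param x,y numeric vectors, equal length >= 3, neither constant.
#' @return R-squared in `[0, 1]`.
#' @export
pearson_r_squared <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  stats::cor(x, y)^2
}
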