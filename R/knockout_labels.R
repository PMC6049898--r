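# Ground-truth labels from a genetic knockout of the partner TF.
#
# A doubly bound region is labeled cooperative when the target TF's peak
# disappears after the partner knockout (peak loss), or when its rank among
# all target peaks moves significantly closer to the weak end (rank_up:
# rank 1 is the strongest peak, so a larger normalized rank means weaker
# binding). A significant move toward rank 1 is competitive; no significant
# change is independent. Competitive and independent together constitute
# non-cooperative binding.

#' Rank peaks by intensity, strongest first
#'
#' Rank 1 is the highest intensity; ties receive the average of the tied
#' rank positions.
#'
#' @param intensities numeric vector.
#' @return numeric vector of ranks (possibly half-integer under ties).
#' @export
rank_peaks <- function(intensities) {
  if (length(intensities) == 0L) return(numeric(0))
  rank(-intensities, ties.method = "average")
}

# Match each query peak to the peak in `subject` with the largest overlap
# (>= 1 bp); returns NA where there is no overlap.
#' @keywords internal
match_peaks_by_overlap <- function(query, subject) {
  if (nrow(query) == 0L) return(integer(0))
  if (nrow(subject) == 0L) return(rep(NA_integer_, nrow(query)))
  hits <- find_overlapping_pairs(query, subject)
  out <- rep(NA_integer_, nrow(query))
  if (nrow(hits) == 0L) return(out)
  best <- vapply(split(seq_len(nrow(hits)), hits$target_idx), function(i) {
    i[order(-hits$overlap_length[i], hits$summit_distance[i])][1L]
  }, integer(1))
  out[hits$target_idx[best]] <- hits$partner_idx[best]
  out
}

# Normalized (fractional) rank of each query target peak within one sample:
# the matched peak's rank divided by the number of peaks in that sample, so
# samples with different peak counts are comparable. NA when unmatched.
#' @keywords internal
normalized_rank_in_sample <- function(query, sample_peaks) {
  idx <- match_peaks_by_overlap(query, sample_peaks)
  nr <- rank_peaks(sample_peaks$signal) / nrow(sample_peaks)
  ifelse(is.na(idx), NA_real_, nr[idx])
}

#' Label peak pairs as cooperative / competitive / independent from knockout data
#'
#' Compares the target TF's peaks before and after partner knockout. A pair
#' whose target peak overlaps no knockout peak (in any replicate) is labeled
#' cooperative with evidence `peak_loss`. For surviving peaks:
#'
#' * in `loss_only` mode (used when replicate peak calls are unavailable),
#'   all survivors are labeled independent (non-cooperative);
#' * in `rank_change` mode, each surviving peak's normalized rank
#'   (rank / peak count, rank 1 = strongest) is averaged over wild-type and
#'   over knockout replicates; the shift `delta = mean KO - mean WT`,
#'   median-centered over surviving peaks to remove the compositional offset
#'   that peak losses impose on every survivor's normalized rank, is
#'   compared with an empirical null of wild-type-vs-wild-type shifts pooled
#'   over all peaks and replicate pairs. Shifts above the upper
#'   `significance` percentile of the null (peak became weaker-ranked) are
#'   cooperative (`rank_up`); below the lower `(100 - significance)`
#'   percentile, competitive (`rank_down`); otherwise independent
#'   (`rank_same`).
#'
#' @param pairs a [find_overlapping_pairs()] result.
#' @param target_peaks the wild-type target [peak_table()] the pairs were
#'   built from (rows indexed by `pairs$target_idx`).
#' @param ko_peaksets a [peak_table()] or list of them: target-TF peak calls
#'   after partner knockout (replicates).
#' @param wt_peaksets a [peak_table()] or list of them: wild-type target-TF
#'   replicate peak calls; at least 2 required in `rank_change` mode.
#' @param mode `"loss_only"` or `"rank_change"`.
#' @param significance percentile level for the rank-shift null (default 95).
#' @return `pairs` with added columns `label` (factor: cooperative,
#'   competitive, independent) and `evidence` (peak_loss, rank_up, rank_down,
#'   rank_same).
#' @export
label_from_knockout <- function(pairs, target_peaks, ko_peaksets,
                                wt_peaksets = NULL,
                                mode = c("loss_only", "rank_change"),
                                significance = 95) {
  mode <- match.arg(mode)
  if (inherits(ko_peaksets, "peak_table")) ko_peaksets <- list(ko_peaksets)
  if (inherits(wt_peaksets, "peak_table")) wt_peaksets <- list(wt_peaksets)
  if (mode == "rank_change" && (is.null(wt_peaksets) || length(wt_peaksets) < 2L)) {
    stop("rank_change labeling requires at least 2 wild-type replicates")
  }
  tp <- target_peaks[pairs$target_idx, , drop = FALSE]
  class(tp) <- c("peak_table", "data.frame")
  # peak loss: the target peak overlaps no knockout peak in any replicate
  matched <- vapply(ko_peaksets, function(ko) {
    !is.na(match_peaks_by_overlap(tp, ko))
  }, logical(nrow(tp)))
  if (is.null(dim(matched))) matched <- matrix(matched, nrow = nrow(tp))
  survived <- rowSums(matched) > 0L
  evidence <- rep("peak_loss", nrow(tp))
  if (mode == "loss_only") {
    evidence[survived] <- "rank_same"
  } else {
    wt_nr <- vapply(wt_peaksets, function(s) normalized_rank_in_sample(tp, s),
                    numeric(nrow(tp)))
    ko_nr <- vapply(ko_peaksets, function(s) normalized_rank_in_sample(tp, s),
                    numeric(nrow(tp)))
    if (is.null(dim(wt_nr))) wt_nr <- matrix(wt_nr, nrow = nrow(tp))
    if (is.null(dim(ko_nr))) ko_nr <- matrix(ko_nr, nrow = nrow(tp))
    delta <- rowMeans(ko_nr, na.rm = TRUE) - rowMeans(wt_nr, na.rm = TRUE)
    # Losing peaks from the knockout sample shrinks its peak count, which
    # shifts every survivor's normalized rank upward regardless of its own
    # behaviour. Median-centering the observed shifts over surviving peaks
    # removes this compositional offset before comparison with the null.
    delta <- delta - stats::median(delta[survived], na.rm = TRUE)
    # null distribution of rank shifts between wild-type replicates
    null_shifts <- unlist(lapply(seq_along(wt_peaksets), function(i) {
      unlist(lapply(seq_along(wt_peaksets), function(j) {
        if (i >= j) return(numeric(0))
        d <- wt_nr[, j] - wt_nr[, i]
        c(d[!is.na(d)], -d[!is.na(d)])  # symmetrize: replicate order is arbitrary
      }))
    }))
    if (length(null_shifts) == 0L) {
      stop("no wild-type replicate overlap to build the rank-shift null")
    }
    upper <- nearest_rank_percentile(null_shifts, significance)
    lower <- nearest_rank_percentile(null_shifts, 100 - significance)
    ev <- ifelse(is.na(delta), "rank_same",
          ifelse(delta > upper, "rank_up",
          ifelse(delta < lower, "rank_down", "rank_same")))
    evidence[survived] <- ev[survived]
  }
  label <- c(peak_loss = "cooperative", rank_up = "cooperative",
             rank_down = "competitive", rank_same = "independent")[evidence]
  out <- pairs
  out$label <- factor(label,
                      levels = c("cooperative", "competitive", "independent"))
  out$evidence <- evidence
  out
}
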