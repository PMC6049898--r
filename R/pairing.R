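# Doubly bound regions: overlapping (target, partner) peak pairs.
#
# Two peaks form a pair when their half-open intervals share at least one
# base on the same chromosome. All overlapping combinations are emitted by
# default (an intersect-style join); `collapse = TRUE` keeps one partner per
# target peak (largest overlap, ties to the smaller summit distance).

#' @keywords internal
peaks_to_granges <- function(peaks, seqlevels = unique(peaks$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(peaks$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  )
}

#' Find overlapping target/partner peak pairs
#'
#' Identifies every (target, partner) pair of peaks on the same chromosome
#' whose intervals overlap by at least one base pair, and records the
#' intensity pair (x, y), the overlap length, and the distance between the
#' two peak summits. These intensity pairs are the input to [fit_cpiem()].
#'
#' @param target_peaks,partner_peaks [peak_table()]s for the target TF (the
#'   one assayed after partner knockout) and the partner TF.
#' @param collapse if `TRUE`, keep a single partner per target peak: the one
#'   with the largest overlap, ties broken by smaller summit distance.
#' @return a `data.frame` with class `peak_pairs`: columns `target_idx`,
#'   `partner_idx` (row indices into the inputs), `chrom`, `x` (target
#'   intensity), `y` (partner intensity), `overlap_length`,
#'   `summit_distance`, ordered by target then partner file order.
#' @export
find_overlapping_pairs <- function(target_peaks, partner_peaks,
                                   collapse = FALSE) {
  validate_peak_table(target_peaks)
  validate_peak_table(partner_peaks)
  empty <- data.frame(target_idx = integer(), partner_idx = integer(),
                      chrom = character(), x = numeric(), y = numeric(),
                      overlap_length = integer(),
                      summit_distance = integer(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("peak_pairs", "data.frame")
  if (nrow(target_peaks) == 0L || nrow(partner_peaks) == 0L) return(empty)
  lv <- unique(c(target_peaks$chrom, partner_peaks$chrom))
  gt <- peaks_to_granges(target_peaks, lv)
  gp <- peaks_to_granges(partner_peaks, lv)
  hits <- GenomicRanges::findOverlaps(gt, gp, minoverlap = 1L)
  ti <- S4Vectors::queryHits(hits)
  pi_ <- S4Vectors::subjectHits(hits)
  if (length(ti) == 0L) return(empty)
  ord <- order(ti, pi_)
  ti <- ti[ord]; pi_ <- pi_[ord]
  ov <- pmin(target_peaks$end[ti], partner_peaks$end[pi_]) -
    pmax(target_peaks$start[ti], partner_peaks$start[pi_])
  sd_ <- abs(peak_summit(target_peaks)[ti] - peak_summit(partner_peaks)[pi_])
  out <- data.frame(
    target_idx = ti, partner_idx = pi_,
    chrom = target_peaks$chrom[ti],
    x = target_peaks$signal[ti], y = partner_peaks$signal[pi_],
    overlap_length = as.integer(ov),
    summit_distance = as.integer(sd_),
    stringsAsFactors = FALSE
  )
  if (collapse && nrow(out) > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$target_idx),
                          function(i) {
      i[order(-out$overlap_length[i], out$summit_distance[i])][1L]
    }), use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("peak_pairs", "data.frame")
  out
}

#' Distance between two peak summits
#'
#' Absolute distance in bp between the summits of two peaks on the same
#' chromosome; peaks without summit annotation use their interval midpoint.
#'
#' @param a,b single-row [peak_table()]s (or rows of one).
#' @return non-negative integer distance in bp.
#' @export
summit_distance <- function(a, b) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (a$chrom != b$chrom) {
    stop("summit distance undefined across chromosomes (",
         a$chrom, " vs ", b$chrom, ")")
  }
  abs(peak_summit(a) - peak_summit(b))
}
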