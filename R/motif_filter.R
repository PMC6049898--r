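# PWM best-hit scanning and removal of indirectly bound (tethered) peaks.
#
# A ChIP-seq peak can arise without direct DNA contact, via tethering to a
# DNA-bound partner. Such peaks are detected by scoring the best motif match
# in each peak sequence and comparing it with a negative control: the best
# scores of unbound genomic windows. Peaks scoring below the control
# distribution's 90th percentile (threshold T) are flagged indirect.

.dna_alphabet <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param scores 4 x width numeric matrix of per-position log-odds scores,
#'   rows in A, C, G, T order (row names set accordingly).
#' @param background zeroth-order letter frequencies (A, C, G, T), strictly
#'   positive, summing to 1.
#' @return object of class `pwm`.
#' @export
pwm <- function(scores, background = rep(0.25, 4)) {
  scores <- as.matrix(scores)
  if (nrow(scores) != 4L) stop("PWM score matrix must have 4 rows (A, C, G, T)")
  if (ncol(scores) < 1L || any(!is.finite(scores))) {
    stop("PWM must have width >= 1 with finite scores at every position")
  }
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 strictly positive frequencies")
  }
  background <- background / sum(background)
  rownames(scores) <- .dna_alphabet
  names(background) <- .dna_alphabet
  structure(list(width = ncol(scores), scores = scores,
                 background = background), class = "pwm")
}

#' Build a log-odds PWM from a count matrix
#'
#' Per-cell pseudocount `pseudocount * background[letter]` is added before
#' normalizing each column, and scores are `log2(p / background)` against a
#' zeroth-order background model.
#'
#' @param counts 4 x width matrix of non-negative base counts (A, C, G, T
#'   rows).
#' @param background zeroth-order letter frequencies.
#' @param pseudocount pseudocount weight (default 0.01).
#' @return a [pwm()].
#' @export
pwm_from_counts <- function(counts, background = rep(0.25, 4),
                            pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("count matrix must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  background <- background / sum(background)
  adj <- counts + pseudocount * background
  probs <- sweep(adj, 2, colSums(adj), "/")
  pwm(log2(probs / background), background)
}

#' Read a PWM from a whitespace-delimited text file
#'
#' Expects one header line followed by one row per motif position with four
#' columns (A C G T). Non-negative matrices are treated as counts and
#' converted with [pwm_from_counts()]; matrices with negative entries are
#' taken as ready-made log-odds scores.
#'
#' @param path path to the matrix file.
#' @param background zeroth-order letter frequencies.
#' @param type `"auto"` (default), `"counts"`, or `"logodds"`.
#' @return a [pwm()].
#' @export
read_pwm <- function(path, background = rep(0.25, 4),
                     type = c("auto", "counts", "logodds")) {
  type <- match.arg(type)
  mat <- as.matrix(utils::read.table(path, header = FALSE, skip = 1L))
  if (ncol(mat) != 4L) stop("PWM file must have 4 columns (A C G T)")
  mat <- t(mat)  # rows = letters, columns = positions
  if (type == "auto") type <- if (all(mat >= 0)) "counts" else "logodds"
  if (type == "counts") pwm_from_counts(mat, background) else pwm(mat, background)
}

#' Write a PWM in the 4-column text format read by [read_pwm()]
#'
#' @param x a [pwm()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  header <- paste(">logodds", paste(sprintf("%.6f", x$background), collapse = " "))
  body <- apply(t(x$scores), 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @keywords internal
seq_to_index <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1L]]
  idx <- match(chars, c(.dna_alphabet, "N"))
  if (anyNA(idx)) {
    stop("sequence contains letters outside {A, C, G, T, N}: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  }
  idx
}

# Scores of every window of width `w` along an index vector; windows
# containing N score -Inf.
#' @keywords internal
window_scores <- function(idx, scores) {
  w <- ncol(scores)
  n_off <- length(idx) - w + 1L
  padded <- rbind(scores, rep(-Inf, w))  # 5th row: N
  acc <- numeric(n_off)
  for (j in seq_len(w)) {
    acc <- acc + padded[cbind(idx[j:(j + n_off - 1L)], j)]
  }
  acc
}

#' Best motif hit in a sequence
#'
#' Scans every offset on both strands (the reverse strand is scored on the
#' reverse complement) and returns the maximal total log-odds score. Ties
#' are broken by the smaller offset, then by the + strand. Windows
#' containing N are skipped; if no window is scannable the hit score is
#' `-Inf`.
#'
#' @param sequence a DNA string (character or `Biostrings::DNAString`), at
#'   least as long as the motif.
#' @param pwm a [pwm()].
#' @return list with class `scan_hit`: `score`, `position` (0-based offset),
#'   `strand` (`"+"` or `"-"`).
#' @export
best_hit_score <- function(sequence, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  sequence <- as.character(sequence)
  if (nchar(sequence) < pwm$width) {
    stop("sequence (length ", nchar(sequence),
         ") shorter than motif width ", pwm$width)
  }
  idx <- seq_to_index(sequence)
  fwd <- window_scores(idx, pwm$scores)
  # reverse strand: score the reverse complement of each window; equivalent
  # to scanning the full reverse complement and mapping offsets back
  rc_idx <- rev(c(4L, 3L, 2L, 1L, 5L)[idx])
  rev_rc <- window_scores(rc_idx, pwm$scores)
  rev_ <- rev(rev_rc)  # rev_[o] = score of the window starting at offset o
  n_off <- length(fwd)
  scores <- c(fwd, rev_)
  best <- max(scores)
  # tie-break: smaller position first, '+' strand before '-'
  cand <- which(scores == best)
  pos <- (cand - 1L) %% n_off
  strand <- ifelse(cand > n_off, "-", "+")
  pick <- order(pos, strand)[1L]
  structure(list(score = best, position = as.integer(pos[pick]),
                 strand = strand[pick]),
            class = "scan_hit")
}

#' Extract the sequences under peaks from a genome
#'
#' @param peaks a [peak_table()].
#' @param genome a named `Biostrings::DNAStringSet` (or object coercible to
#'   one) whose names match `peaks$chrom`.
#' @return character vector of peak sequences.
#' @export
peak_sequences <- function(peaks, genome) {
  genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing)) {
    stop("peaks reference contigs absent from the genome: ",
         paste(missing, collapse = ", "))
  }
  vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start = peaks$start[i] + 1L,
                                    end = peaks$end[i]))
  }, character(1))
}

#' Sample unbound genomic windows (negative controls)
#'
#' Draws `n_windows` windows of length `window_length`, uniformly over the
#' genome, rejecting windows that overlap any peak or contain N. Their best
#' motif-hit scores form the negative-control distribution whose 90th
#' percentile is the indirect-binding threshold T.
#'
#' @param genome a named `Biostrings::DNAStringSet` (or coercible).
#' @param peaks a [peak_table()] of bound regions to avoid.
#' @param n_windows number of windows N (the number of peaks in the dataset,
#'   or 10000 for small datasets).
#' @param window_length window length l in bp (the mean peak length).
#' @param seed integer seed; the same seed yields the same windows.
#' @param max_tries rejection-sampling cap before declaring the genome too
#'   crowded.
#' @return character vector of `n_windows` sequences, each `window_length`
#'   long.
#' @export
sample_unbound_windows <- function(genome, peaks, n_windows, window_length,
                                   seed = 1L, max_tries = 200L) {
  genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome))) stop("genome sequences must be named")
  lens <- Biostrings::width(genome)
  if (all(lens < window_length)) stop("no contig is as long as window_length")
  lv <- unique(c(names(genome), peaks$chrom))
  peak_gr <- if (nrow(peaks) > 0L) peaks_to_granges(peaks, lv) else NULL
  out <- character(0)
  tries <- 0L
  with_seed(seed, {
    while (length(out) < n_windows) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("insufficient unbound genome space to place ", n_windows,
             " windows of length ", window_length)
      }
      need <- n_windows - length(out)
      contig <- sample.int(length(genome), need * 2L, replace = TRUE,
                           prob = pmax(lens - window_length + 1L, 0))
      start0 <- vapply(contig, function(ci) {
        sample.int(lens[ci] - window_length + 1L, 1L) - 1L
      }, integer(1))
      cand <- GenomicRanges::GRanges(
        seqnames = factor(names(genome)[contig], levels = lv),
        ranges = IRanges::IRanges(start = start0 + 1L,
                                  width = window_length))
      if (!is.null(peak_gr)) {
        hit <- GenomicRanges::countOverlaps(cand, peak_gr) > 0L
        cand <- cand[!hit]
      }
      if (length(cand) == 0L) next
      seqs <- vapply(seq_along(cand), function(i) {
        as.character(Biostrings::subseq(
          genome[[as.character(GenomicRanges::seqnames(cand)[i])]],
          start = GenomicRanges::start(cand)[i],
          end = GenomicRanges::end(cand)[i]))
      }, character(1))
      seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
      out <- c(out, utils::head(seqs, need))
    }
  })
  out
}

#' Flag and remove indirectly bound peaks
#'
#' Computes the nearest-rank `percentile` of the negative-control best-hit
#' scores (threshold T) and flags every peak whose own best motif-hit score
#' is strictly below T as indirectly bound. Peaks whose sequence has no
#' scannable window (N runs leaving no N-free offset) are excluded from both
#' sets with a warning.
#'
#' @param peaks a [peak_table()].
#' @param genome named `Biostrings::DNAStringSet` (or coercible).
#' @param pwm a [pwm()] for the peak's own TF.
#' @param control_scores best-hit scores of unbound control windows, e.g.
#'   from [sample_unbound_windows()] + [best_hit_score()].
#' @param percentile control percentile defining T (default 90).
#' @return list with `retained` and `flagged` [peak_table()]s, `threshold`
#'   (T), `scores` (per input peak, NA if unscannable), and `unscannable`
#'   (row indices excluded).
#' @export
indirect_binding_filter <- function(peaks, genome, pwm, control_scores,
                                    percentile = 90) {
  if (length(control_scores) == 0L) stop("control score set is empty")
  threshold <- nearest_rank_percentile(control_scores, percentile)
  seqs <- peak_sequences(peaks, genome)
  scores <- vapply(seqs, function(s) best_hit_score(s, pwm)$score, numeric(1),
                   USE.NAMES = FALSE)
  unscannable <- which(!is.finite(scores))
  if (length(unscannable)) {
    warning(length(unscannable),
            " peak(s) had no N-free window of motif width and were excluded")
    scores[unscannable] <- NA_real_
  }
  flag <- !is.na(scores) & scores < threshold
  keep <- !is.na(scores) & scores >= threshold
  retained <- peaks[keep, , drop = FALSE]
  flagged <- peaks[flag, , drop = FALSE]
  class(retained) <- class(flagged) <- c("peak_table", "data.frame")
  list(retained = retained, flagged = flagged, threshold = threshold,
       scores = scores, unscannable = unscannable)
}
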