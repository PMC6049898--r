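# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive enumeration / string operations so they share no code with the
# implementation they check.

make_peaks <- function(starts, ends, signal = NULL, chrom = "chr1",
                       summit = NA_integer_) {
  if (is.null(signal)) signal <- seq_along(starts)
  peak_table(chrom = chrom, start = starts, end = ends, signal = signal,
             summit_offset = summit)
}

write_peak_lines <- function(lines, path = tempfile(fileext = ".narrowPeak")) {
  writeLines(lines, path)
  path
}

# all-against-all interval intersection, half-open coordinates
brute_force_pairs <- function(target, partner) {
  out <- list()
  for (i in seq_len(nrow(target))) {
    for (j in seq_len(nrow(partner))) {
      if (target$chrom[i] == partner$chrom[j] &&
          target$start[i] < partner$end[j] &&
          partner$start[j] < target$end[i]) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# auROC as the normalized count of correctly ordered (pos, neg) pairs,
# ties counting 1/2
brute_force_auroc <- function(pos_scores, neg_scores) {
  total <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos_scores) * length(neg_scores))
}

# best PWM hit by explicit enumeration over offsets and strands using
# string operations only
revcomp_str <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

brute_force_best_hit <- function(sequence, score_matrix) {
  w <- ncol(score_matrix)
  best <- -Inf
  score_one <- function(window) {
    chars <- strsplit(window, "")[[1]]
    if (any(!chars %in% c("A", "C", "G", "T"))) return(-Inf)
    sum(vapply(seq_len(w), function(j) score_matrix[chars[j], j], numeric(1)))
  }
  for (o in seq_len(nchar(sequence) - w + 1L)) {
    window <- substr(sequence, o, o + w - 1L)
    best <- max(best, score_one(window), score_one(revcomp_str(window)))
  }
  best
}

# a small informative PWM over a non-uniform background
test_pwm <- function() {
  counts <- matrix(c(90, 4, 3, 3,
                     3, 3, 4, 90,
                     4, 90, 3, 3,
                     90, 4, 3, 3,
                     3, 3, 90, 4,
                     4, 3, 3, 90), nrow = 4)
  pwm_from_counts(counts, background = c(0.3, 0.2, 0.2, 0.3))
}

# a softer, wider motif whose best-hit score distribution is effectively
# continuous: needed when a test relies on percentile calibration, since a
# sharp motif quantizes best-hit scores into large ties
soft_pwm <- function() {
  counts <- matrix(c(45, 27, 17, 11,
                     11, 45, 27, 17,
                     17, 11, 45, 27,
                     27, 17, 11, 45,
                     45, 17, 27, 11,
                     11, 27, 17, 45,
                     17, 45, 11, 27,
                     27, 11, 45, 17,
                     45, 11, 17, 27,
                     17, 27, 45, 11), nrow = 4)
  pwm_from_counts(counts, background = c(0.3, 0.2, 0.2, 0.3))
}

random_dna <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
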