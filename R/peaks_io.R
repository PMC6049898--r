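# Reading, validating and writing ENCODE narrowPeak / BED6 peak calls.
#
# Coordinates are BED-convention 0-based half-open throughout the package.
# A peak's "intensity" is its signalValue (narrowPeak column 7, i.e. the
# 0-indexed 6th column) by default; the column is configurable because some
# pipelines store the usable intensity in the BED score column instead.

.peak_columns <- c("chrom", "start", "end", "name", "score", "strand",
                   "signal", "p_log10", "q_log10", "summit_offset")

#' Construct a peak table
#'
#' Builds the canonical data frame of ChIP-seq peak calls used throughout the
#' package and checks its invariants. Missing optional fields are filled with
#' defaults (`name = "."`, `score = 0`, `strand = "."`, p/q = `NA`,
#' `summit_offset = NA` meaning unknown).
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open coordinates, `start < end`.
#' @param signal non-negative peak intensities.
#' @param name,score,strand,p_log10,q_log10,summit_offset optional narrowPeak
#'   fields; `summit_offset` is the summit position relative to `start`, with
#'   `NA` meaning unknown (the narrowPeak `-1` sentinel).
#' @return a `data.frame` with class `peak_table`, one row per peak.
#' @export
peak_table <- function(chrom, start, end, signal,
                       name = ".", score = 0L, strand = ".",
                       p_log10 = NA_real_, q_log10 = NA_real_,
                       summit_offset = NA_integer_) {
  n <- length(start)
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.integer(score), n),
    strand = rep_len(as.character(strand), n),
    signal = as.numeric(signal),
    p_log10 = rep_len(as.numeric(p_log10), n),
    q_log10 = rep_len(as.numeric(q_log10), n),
    summit_offset = rep_len(as.integer(summit_offset), n),
    stringsAsFactors = FALSE
  )
  validate_peak_table(df)
  class(df) <- c("peak_table", "data.frame")
  df
}

#' @keywords internal
validate_peak_table <- function(df) {
  stopifnot(all(.peak_columns %in% names(df)))
  if (any(df$start < 0L)) stop("negative start coordinate")
  if (any(df$start >= df$end)) stop("start must be < end for every peak")
  if (any(df$signal < 0)) stop("peak intensities (signal) must be >= 0")
  bad <- !is.na(df$summit_offset) &
    (df$summit_offset < 0L | df$summit_offset >= df$end - df$start)
  if (any(bad)) stop("summit_offset must lie within [0, end - start)")
  invisible(df)
}

#' Read a narrowPeak or BED peak-call file
#'
#' Parses ENCODE narrowPeak (BED6+4) or plain BED files with at least six
#' tab-separated fields. The peak intensity is taken from the narrowPeak
#' signalValue field (the 7th field, 0-indexed column 6) by default;
#' `intensity_column` can redirect it, e.g. to the BED score field for
#' pipelines that store intensity there.
#'
#' @param path path to the peak file.
#' @param intensity_column which field carries the peak intensity: either a
#'   field name (`"signalValue"` or `"score"`) or a 1-based column number.
#' @return a [peak_table()] with one row per data line, in file order.
#' @export
read_narrowpeak <- function(path, intensity_column = "signalValue") {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(peak_table(character(), integer(), integer(), numeric()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("parse error at line ", lineno[which(nf < 6L)[1L]],
         ": fewer than 6 tab-separated fields")
  }
  get_col <- function(i, default = NA_character_) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           character(1))
  }
  num_col <- function(i, what) {
    raw <- get_col(i)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad)) {
      stop("parse error at line ", lineno[bad[1L]], ": non-numeric ", what,
           " ('", raw[bad[1L]], "')")
    }
    val
  }
  start <- num_col(2L, "start")
  end <- num_col(3L, "end")
  if (any(start != floor(start)) || any(end != floor(end))) {
    bad <- which(start != floor(start) | end != floor(end))[1L]
    stop("parse error at line ", lineno[bad], ": non-integer coordinate")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("parse error at line ", lineno[bad[1L]],
         ": start >= end (", start[bad[1L]], " >= ", end[bad[1L]], ")")
  }
  score <- suppressWarnings(as.numeric(get_col(5L)))
  score[is.na(score)] <- 0
  signal_col <- if (identical(intensity_column, "signalValue")) {
    7L
  } else if (identical(intensity_column, "score")) {
    5L
  } else if (is.numeric(intensity_column) && length(intensity_column) == 1L) {
    as.integer(intensity_column)
  } else {
    stop("intensity_column must be 'signalValue', 'score' or a column number")
  }
  if (signal_col <= 6L || all(nf >= signal_col)) {
    signal <- num_col(signal_col, "intensity")
  } else {
    signal <- suppressWarnings(as.numeric(get_col(signal_col)))
  }
  if (anyNA(signal)) {
    stop("parse error at line ", lineno[which(is.na(signal))[1L]],
         ": missing intensity in column ", signal_col)
  }
  p_log10 <- suppressWarnings(as.numeric(get_col(8L)))
  q_log10 <- suppressWarnings(as.numeric(get_col(9L)))
  summit <- suppressWarnings(as.numeric(get_col(10L)))
  summit[!is.na(summit) & summit < 0] <- NA  # narrowPeak -1 sentinel
  peak_table(
    chrom = get_col(1L), start = as.integer(start), end = as.integer(end),
    name = get_col(4L), score = as.integer(round(score)),
    strand = get_col(6L), signal = signal,
    p_log10 = p_log10, q_log10 = q_log10,
    summit_offset = as.integer(summit)
  )
}

#' Write a peak table as narrowPeak
#'
#' Emits ENCODE narrowPeak (BED6+4). Unknown summits are written as `-1` and
#' missing p/q values as `-1`, per the format's sentinels. An optional
#' `extra` data frame (e.g. posterior probabilities) is appended as
#' additional tab-separated columns.
#'
#' @param peaks a [peak_table()].
#' @param path output file path.
#' @param extra optional data frame of extra columns, `nrow(peaks)` rows.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path, extra = NULL) {
  validate_peak_table(peaks)
  df <- data.frame(
    peaks$chrom, peaks$start, peaks$end, peaks$name, peaks$score,
    peaks$strand, peaks$signal,
    ifelse(is.na(peaks$p_log10), -1, peaks$p_log10),
    ifelse(is.na(peaks$q_log10), -1, peaks$q_log10),
    ifelse(is.na(peaks$summit_offset), -1L, peaks$summit_offset),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == nrow(df))
    df <- cbind(df, extra)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summit position of each peak
#'
#' Absolute genomic coordinate of the peak summit. Peaks without a summit
#' annotation use the interval midpoint (`floor((start + end) / 2)`).
#'
#' @param peaks a [peak_table()].
#' @return integer vector of summit coordinates.
#' @export
peak_summit <- function(peaks) {
  s <- peaks$start + peaks$summit_offset
  mid <- (peaks$start + peaks$end) %/% 2L
  ifelse(is.na(s), mid, as.integer(s))
}

#' Trim peaks to a fixed window around their summits
#'
#' Replaces each peak interval by `[summit - flank, summit + flank)`, clamped
#' at coordinate 0. This is the control transform used to check that wide
#' peak regions, rather than binding-site-proximal signal, do not drive the
#' intensity comparisons: intensities are unchanged, only intervals shrink.
#' Peaks without summit annotation are trimmed around their midpoint.
#'
#' @param peaks a [peak_table()].
#' @param flank positive flank size in bp (default 50).
#' @return a [peak_table()] of trimmed peaks, same order and intensities.
#' @export
trim_to_summit <- function(peaks, flank = 50L) {
  stopifnot(flank > 0)
  validate_peak_table(peaks)
  summit <- peak_summit(peaks)
  new_start <- pmax(0L, as.integer(summit - flank))
  new_end <- as.integer(summit + flank)
  out <- peaks
  out$start <- new_start
  out$end <- new_end
  out$summit_offset <- as.integer(summit - new_start)
  validate_peak_table(out)
  out
}
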