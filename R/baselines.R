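# Comparison detectors: summit-distance thresholding and the cooperative
# index computed from an external occupancy model's predicted intensities.

#' Peak summit-distance detector
#'
#' Declares a doubly bound region cooperatively bound when the distance
#' between the two peaks' summits is strictly less than a threshold `d`.
#' Sweeping `d` over all observed distances yields this detector's ROC; use
#' [roc_curve()] with `-summit_distance` as the score.
#'
#' @param pairs a [find_overlapping_pairs()] result (or any data frame with
#'   a `summit_distance` column).
#' @param d non-negative distance threshold in bp.
#' @return logical vector, `TRUE` for cooperative calls.
#' @export
peak_distance_detect <- function(pairs, d) {
  stopifnot(length(d) == 1L, d >= 0)
  pairs$summit_distance < d
}

#' Cooperative index from paired occupancy-model predictions
#'
#' For each region, the relative change in the predicted target intensity
#' when a cooperative interaction term is enabled in an external occupancy
#' model: `delta = (I_coop - I_ind) / I_ind`. Regions with `delta` above a
#' threshold (which may be negative) are considered cooperatively bound; the
#' index itself is the detector's ranking score.
#'
#' @param independent_prediction predicted intensities `I` without the
#'   interaction term; must be strictly positive.
#' @param cooperative_prediction predicted intensities `I'` with the
#'   interaction term; same length.
#' @return numeric vector of cooperative indices.
#' @export
cooperative_index <- function(independent_prediction, cooperative_prediction) {
  if (length(independent_prediction) != length(cooperative_prediction)) {
    stop("prediction vectors must have equal length")
  }
  if (any(independent_prediction <= 0)) {
    stop("independent predictions must be > 0")
  }
  (cooperative_prediction - independent_prediction) / independent_prediction
}

#' Read a two-column (region id, predicted intensity) prediction file
#'
#' Accepts the tab- or whitespace-separated output of any external occupancy
#' model, so its predictions can be scored with [cooperative_index()].
#'
#' @param path path to the prediction file.
#' @return data frame with columns `id` and `intensity`.
#' @export
read_predictions <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "intensity"))
  df$intensity <- as.numeric(df$intensity)
  df
}
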