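# PPV-semantics risk index. On the calibrating cohort, for each distinct raw
# score s the fraction of patients with score >= s that are cases is the
# empirical PPV-above-threshold; a running maximum from the lowest score up
# makes the curve monotone, and linear interpolation between the resulting
# knots maps any raw score to a 0-100 index. The defining property: patients
# with index >= L have (approximately) an L% probability of the outcome.

#' Fit the PPV calibration map
#'
#' @param scores Raw model scores on the calibrating cohort.
#' @param labels Binary outcomes on the same cohort.
#' @param min_cell Minimum number of patients at or above a knot for its PPV to
#'   be estimated directly; sparser high-score tails inherit the nearest valid
#'   knot's index (variance control). Use `min_cell = 1` to disable.
#' @param t_medium,t_high Risk-group thresholds on the 0-100 index scale.
#' @return An object of class `calibration_map` with `knots`
#'   (`raw_score`, `index`), thresholds `t_medium` / `t_high`, and
#'   `n_calibration`.
#' @export
#' @examples
#' fit_calibration(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1), min_cell = 1)$knots
fit_calibration <- function(scores, labels, min_cell = 50L,
                            t_medium = 30, t_high = 70) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("calibration requires both cases and controls (PPV gradient undefined)",
         call. = FALSE)
  if (t_medium >= t_high)
    stop("t_medium must be below t_high", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  y_sorted <- labels[ord]
  n_above <- seq_along(s_sorted)
  pos_above <- cumsum(y_sorted)
  ## distinct scores: take the last occurrence in the sorted-down order so the
  ## cumulative counts include every patient with score >= s
  last <- which(!duplicated(s_sorted, fromLast = TRUE))
  knot_score <- s_sorted[last]
  knot_n <- n_above[last]
  knot_ppv <- 100 * pos_above[last] / n_above[last]
  valid <- knot_n >= min_cell
  if (!any(valid)) valid[which.max(knot_n)] <- TRUE
  ## sparser tails inherit the nearest valid knot (knots ordered by descending
  ## score, so the nearest valid knot for an invalid one is the next valid
  ## knot downward in score)
  idx_valid <- which(valid)
  nearest <- findInterval(seq_along(knot_score), idx_valid) # 0 before first valid
  nearest[nearest == 0L] <- 1L
  raw_index <- knot_ppv[idx_valid][nearest]
  ## monotone correction: running maximum from lowest score to highest
  o <- order(knot_score)
  idx_mono <- cummax(raw_index[o])
  knots <- data.frame(raw_score = knot_score[o], index = idx_mono)
  structure(list(knots = knots,
                 t_medium = t_medium, t_high = t_high,
                 n_calibration = length(scores)),
            class = "calibration_map")
}

#' Map raw scores to the 0-100 risk index
#'
#' Linear interpolation between calibration knots; scores beyond the knot range
#' clamp to the nearest knot's index.
#'
#' @param map A `calibration_map`.
#' @param raw_score Numeric vector of raw model scores.
#' @return Numeric vector of indices in `[0, 100]`, non-decreasing in the raw
#'   score.
#' @export
risk_index <- function(map, raw_score) {
  stopifnot(inherits(map, "calibration_map"))
  k <- map$knots
  if (nrow(k) == 1L) return(rep(k$index, length(raw_score)))
  approx(k$raw_score, k$index, xout = raw_score, rule = 2, ties = "ordered")$y
}

#' Assign low / medium / high risk groups
#'
#' @param index Risk indices in `[0, 100]`.
#' @param t_medium,t_high Group thresholds: low below `t_medium`, medium from
#'   `t_medium` up to (not including) `t_high`, high at or above `t_high`.
#' @return Character vector of `"low"`, `"medium"`, `"high"`.
#' @export
#' @examples
#' assign_risk_group(c(29.99, 30, 69.99, 70))
assign_risk_group <- function(index, t_medium = 30, t_high = 70) {
  if (anyNA(index) || any(index < 0 | index > 100))
    stop("index must lie in [0, 100]", call. = FALSE)
  ifelse(index >= t_high, "high",
         ifelse(index >= t_medium, "medium", "low"))
}

#' Per-patient risk assessment table
#'
#' @param patient_id Patient identifiers.
#' @param raw_score Raw model scores.
#' @param map A `calibration_map`.
#' @return A data.frame `patient_id`, `raw_score`, `risk_index`, `risk_group`.
#' @export
risk_assessment <- function(patient_id, raw_score, map) {
  idx <- risk_index(map, raw_score)
  data.frame(patient_id = patient_id,
             raw_score = raw_score,
             risk_index = idx,
             risk_group = assign_risk_group(idx, map$t_medium, map$t_high),
             stringsAsFactors = FALSE)
}

#' @export
print.calibration_map <- function(x, ...) {
  cat("PPV calibration map:", nrow(x$knots), "knots fitted on",
      x$n_calibration, "patients\n")
  cat(sprintf("  thresholds: medium >= %g, high >= %g (index scale 0-100)\n",
              x$t_medium, x$t_high))
  invisible(x)
}
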