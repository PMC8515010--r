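#' Relative Z-score of a predicted log IC50 within a cohort
#'
#' Standardizes a predicted log IC50 against the cohort of the same cancer
#' type (population SD) — the quantity the recommendation rule thresholds.
#'
#' @param value predicted log IC50.
#' @param cohort numeric vector of the cohort's log IC50 values (length >= 2).
#' @return The relative Z-score.
#' @export
relativeZ <- function(value, cohort) {
  if (length(cohort) < 2) stop("cohort must contain at least 2 values")
  sdp <- sqrt(mean((cohort - mean(cohort))^2))
  if (sdp == 0) stop("cohort SD is zero; relative Z undefined")
  (value - mean(cohort)) / sdp
}

#' Zone assignment from an ineffectiveness probability
#'
#' Splits the probability axis into effective / intermediate / ineffective
#' zones (default cuts at thirds; strict inequalities, so a probability
#' exactly on a cut falls in the intermediate zone).
#'
#' @param p ineffectiveness probability in [0, 1].
#' @param cuts increasing pair (low, high) strictly inside (0, 1).
#' @return One of \code{"effective"}, \code{"intermediate"},
#'   \code{"ineffective"}.
#' @export
zoneOf <- function(p, cuts = c(1 / 3, 2 / 3)) {
  if (length(cuts) != 2 || cuts[1] <= 0 || cuts[2] >= 1 || cuts[1] >= cuts[2])
    stop("cuts must satisfy 0 < low < high < 1")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p < cuts[1]) "effective" else if (p > cuts[2]) "ineffective" else "intermediate"
}

#' Per-drug recommendation from predicted log IC50 values
#'
#' Computes each drug's relative Z-score against its cancer-type cohort and
#' issues the three-way call: relative Z strictly below -1 is "sensitive"
#' (green), strictly above +1 "non-sensitive" (red), anything else —
#' including exactly +/-1 — "neutral" (black).
#'
#' @param predictions named numeric vector: predicted log IC50 per drug.
#' @param cohorts named list of numeric vectors: the cohort log IC50 values
#'   per drug (same names).
#' @return \code{data.frame}: drug, predicted_log_ic50, relative_z, call,
#'   display_color.
#' @export
recommend <- function(predictions, cohorts) {
  drugs <- names(predictions)
  if (is.null(drugs) || !all(drugs %in% names(cohorts)))
    stop("predictions and cohorts must be named per drug, with matching names")
  rz <- vapply(drugs, function(d) relativeZ(predictions[[d]], cohorts[[d]]),
               numeric(1))
  call <- ifelse(rz < -1, "sensitive", ifelse(rz > 1, "non-sensitive", "neutral"))
  col <- c(sensitive = "green", neutral = "black", `non-sensitive` = "red")[call]
  data.frame(drug = drugs, predicted_log_ic50 = unname(predictions[drugs]),
             relative_z = unname(rz), call = unname(call),
             display_color = unname(col), stringsAsFactors = FALSE)
}
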