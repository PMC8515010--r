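#' Fit the linear delta-Cq to TPM calibration
#'
#' Ordinary least squares of log10(TPM + 1) on dCq (target Cq minus
#' reference-gene Cq). The +1 pseudo-count avoids the undefined log at
#' TPM = 0. Typical calibrations on housekeeping-referenced qPCR panels give
#' a slope near -0.4: one extra cycle corresponds to roughly 2.5-fold less
#' transcript.
#'
#' @param dcq numeric delta-Cq values.
#' @param tpmValues matching non-negative TPM values.
#' @param referenceGene annotation stored on the model.
#' @return A [ConversionModel-class] with slope, intercept and R-squared.
#' @export
fitConversion <- function(dcq, tpmValues, referenceGene = "GAPDH") {
  if (length(dcq) != length(tpmValues)) stop("length mismatch")
  if (length(dcq) < 2) stop("need at least 2 (dCq, TPM) pairs")
  if (any(tpmValues < 0)) stop("TPM must be >= 0")
  if (stats::sd(dcq) == 0) stop("constant dCq: degenerate fit")
  y <- log10(tpmValues + 1)
  fit <- stats::lm(y ~ dcq)
  co <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  ConversionModel(slope = unname(co[2]), intercept = unname(co[1]),
                  referenceGene = referenceGene, fitR2 = r2)
}

#' Convert delta-Cq values to TPM
#'
#' TPM = 10^(slope * dCq + intercept) - 1, floored at 0 (negative
#' back-transformed abundances are unphysical). Strictly decreasing in dCq
#' for the (negative-slope) models the class admits.
#'
#' @param dcq finite delta-Cq values.
#' @param model a [ConversionModel-class] (defaults to the published
#'   calibration coefficients).
#' @return Non-negative TPM values.
#' @export
dcqToTpm <- function(dcq, model = ConversionModel()) {
  if (any(!is.finite(dcq))) stop("dCq must be finite")
  pmax(10^(model@slope * dcq + model@intercept) - 1, 0)
}

#' Convert TPM values to delta-Cq (inverse calibration)
#'
#' dCq = (log10(TPM + 1) - intercept) / slope; the exact inverse of
#' [dcqToTpm()] wherever the floor at 0 is not active.
#'
#' @param tpmValues non-negative TPM values.
#' @param model a [ConversionModel-class].
#' @return delta-Cq values.
#' @export
tpmToDcq <- function(tpmValues, model = ConversionModel()) {
  if (any(tpmValues < 0)) stop("TPM must be >= 0")
  if (model@slope == 0) stop("slope must be non-zero")
  (log10(tpmValues + 1) - model@intercept) / model@slope
}

#' Predict drug sensitivity from a qRT-PCR Cq table
#'
#' Computes dCq = Cq_gene - Cq_reference per sample, converts to TPM with
#' the calibration model, and runs the marker's KNN predictor — the
#' "extremely rapid" path that needs only a small qPCR panel instead of
#' RNA-seq. When the Cq values are generated noiselessly from TPM via
#' [tpmToDcq()], this path reproduces the direct TPM-path prediction
#' exactly (identical neighbours).
#'
#' @param cq a [CqTable-class] covering all marker genes plus the reference.
#' @param marker a [DigitalMarker-class].
#' @param model a [ConversionModel-class].
#' @param zoneCuts probability cuts for [zoneOf()] (classification tasks).
#' @return \code{data.frame}: sample, predicted value (\code{z} or
#'   \code{p_ineffective}), and zone/label for classification tasks.
#' @export
predictFromQpcr <- function(cq, marker, model = ConversionModel(),
                            zoneCuts = c(1 / 3, 2 / 3)) {
  missing <- setdiff(marker@genes, cq@genes)
  if (length(missing))
    stop("Cq table is missing marker gene(s): ", paste(missing, collapse = ", "))
  refIdx <- match(cq@referenceGene, cq@genes)
  dcq <- cq@cq[, match(marker@genes, cq@genes), drop = FALSE] - cq@cq[, refIdx]
  tpmMat <- matrix(dcqToTpm(as.vector(dcq), model), nrow = nrow(dcq),
                   dimnames = list(cq@samples, marker@genes))
  predictFromTpm(tpmMat, marker, zoneCuts = zoneCuts)
}

#' Predict drug sensitivity from a TPM table
#'
#' @param query sample-by-gene TPM matrix or [TpmExperiment-class].
#' @param marker a [DigitalMarker-class].
#' @param zoneCuts probability cuts for [zoneOf()].
#' @return \code{data.frame}: sample plus \code{z} (regression) or
#'   \code{p_ineffective}, \code{label}, \code{zone} (classification).
#' @export
predictFromTpm <- function(query, marker, zoneCuts = c(1 / 3, 2 / 3)) {
  if (marker@task == "regression") {
    z <- knnRegress(marker, query)
    data.frame(sample = names(z) %||% seq_along(z), z = unname(z),
               stringsAsFactors = FALSE)
  } else {
    knnClassify(marker, query, zoneCuts = zoneCuts)
  }
}
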