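#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors metadata SimpleList
NULL

#' TpmExperiment: a TPM expression matrix for one cohort
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single gene-by-sample assay named \code{"tpm"} (non-negative, unitless
#' normalized abundances) plus the cohort annotations the screening pipeline
#' keys on: the cancer type and a dataset tag (e.g. the cohort name).
#'
#' @slot cancerType single string, cancer-type tag of the cohort.
#' @slot datasetTag single string identifying the dataset/cohort.
#' @export
setClass("TpmExperiment",
  contains = "SummarizedExperiment",
  representation(cancerType = "character", datasetTag = "character")
)

setValidity("TpmExperiment", function(object) {
  msg <- NULL
  if (!"tpm" %in% names(assays(object)))
    msg <- c(msg, "assay 'tpm' is required")
  else {
    v <- assay(object, "tpm")
    if (!is.numeric(v)) msg <- c(msg, "'tpm' assay must be numeric")
    else if (any(v[is.finite(v)] < 0)) msg <- c(msg, "TPM values must be >= 0")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  if (length(object@cancerType) != 1L || length(object@datasetTag) != 1L)
    msg <- c(msg, "cancerType and datasetTag must be single strings")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TpmExperiment
#'
#' @param tpm numeric gene-by-sample matrix with unique row (gene) and column
#'   (sample) names; values are TPM, hence non-negative.
#' @param cancerType,datasetTag single-string cohort annotations.
#' @return A [TpmExperiment-class] object.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' TpmExperiment(m, "CRC", "cohortA")
#' @export
TpmExperiment <- function(tpm, cancerType = "unspecified", datasetTag = "unspecified") {
  tpm <- as.matrix(tpm)
  se <- SummarizedExperiment(assays = SimpleList(tpm = tpm))
  new("TpmExperiment", se, cancerType = as.character(cancerType),
      datasetTag = as.character(datasetTag))
}

#' DrugResponse: per-sample response to one drug
#'
#' Continuous mode carries IC50 concentrations (uM) together with cohort
#' Z-scores of log IC50 (standardized with the population SD, so they average
#' to 0 with SD 1 over the cohort they were computed on). Binary mode carries
#' effective/ineffective labels, as used for patient and organoid cohorts
#' (effective meaning IC50 below the assay cut, 100 uM in the source data).
#'
#' @slot drug single string.
#' @slot samples character vector of sample identifiers.
#' @slot mode \code{"continuous"} or \code{"binary"}.
#' @slot ic50 numeric, positive, same length as samples (continuous mode).
#' @slot z numeric Z-scores of log IC50 (continuous mode).
#' @slot label character in \code{c("effective","ineffective")} (binary mode).
#' @export
setClass("DrugResponse", representation(
  drug = "character", samples = "character", mode = "character",
  ic50 = "numeric", z = "numeric", label = "character"
))

setValidity("DrugResponse", function(object) {
  msg <- NULL
  n <- length(object@samples)
  if (anyDuplicated(object@samples)) msg <- c(msg, "duplicate sample identifiers")
  if (!object@mode %in% c("continuous", "binary"))
    msg <- c(msg, "mode must be 'continuous' or 'binary'")
  if (object@mode == "continuous") {
    if (length(object@ic50) != n || length(object@z) != n)
      msg <- c(msg, "ic50 and z must match samples in length")
    if (length(object@label)) msg <- c(msg, "binary labels must be empty in continuous mode")
    if (any(object@ic50 <= 0)) msg <- c(msg, "ic50 must be > 0")
    if (n >= 2) {
      sdp <- sqrt(mean((object@z - mean(object@z))^2))
      if (abs(mean(object@z)) > 1e-6 || abs(sdp - 1) > 1e-6)
        msg <- c(msg, "z must be cohort-standardized (mean 0, population SD 1)")
    }
  } else if (object@mode == "binary") {
    if (length(object@label) != n) msg <- c(msg, "label must match samples in length")
    if (length(object@ic50) || length(object@z))
      msg <- c(msg, "ic50/z must be empty in binary mode")
    if (!all(object@label %in% c("effective", "ineffective")))
      msg <- c(msg, "labels must be 'effective' or 'ineffective'")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a DrugResponse
#'
#' In continuous mode, if \code{z} is omitted it is computed by standardizing
#' log-transformed IC50 over the supplied samples (population SD; natural log
#' by default, configurable because IC50 spans orders of magnitude and the
#' training databases store log-scale potencies).
#'
#' @param drug drug name.
#' @param samples sample identifiers.
#' @param ic50 positive IC50 values in uM (continuous mode).
#' @param z optional precomputed Z-scores of log IC50.
#' @param label character labels (binary mode).
#' @param logFun log used before standardization: "ln", "log10", or "none".
#' @return A [DrugResponse-class] object.
#' @examples
#' DrugResponse("5-FU", c("a", "b", "c"), ic50 = c(1, exp(2), exp(4)))
#' @export
DrugResponse <- function(drug, samples, ic50 = NULL, z = NULL, label = NULL,
                         logFun = c("ln", "log10", "none")) {
  logFun <- match.arg(logFun)
  samples <- as.character(samples)
  if (!is.null(label)) {
    return(new("DrugResponse", drug = drug, samples = samples, mode = "binary",
               ic50 = numeric(0), z = numeric(0), label = as.character(label)))
  }
  if (is.null(ic50)) stop("either ic50 or label must be supplied")
  if (any(ic50 <= 0)) stop("ic50 must be > 0")
  if (is.null(z)) {
    if (length(ic50) < 2)
      stop("cannot standardize IC50 with fewer than 2 samples")
    lx <- switch(logFun, ln = log(ic50), log10 = log10(ic50), none = ic50)
    sdp <- sqrt(mean((lx - mean(lx))^2))
    if (sdp == 0) stop("IC50 values are constant; Z-scores undefined")
    z <- (lx - mean(lx)) / sdp
  }
  new("DrugResponse", drug = drug, samples = samples, mode = "continuous",
      ic50 = as.numeric(ic50), z = as.numeric(z), label = character(0))
}

#' CqTable: qRT-PCR quantification cycles for a set of samples and genes
#'
#' @slot samples,genes identifiers; \code{cq} is samples x genes.
#' @slot cq numeric matrix of quantification cycles (replicates already
#'   collapsed to their mean).
#' @slot referenceGene identifier of the housekeeping reference (e.g. GAPDH),
#'   present in \code{genes} and measured for every sample.
#' @export
setClass("CqTable", representation(
  samples = "character", genes = "character", cq = "matrix",
  referenceGene = "character"
))

setValidity("CqTable", function(object) {
  msg <- NULL
  if (!identical(dim(object@cq), c(length(object@samples), length(object@genes))))
    msg <- c(msg, "cq matrix shape must be samples x genes")
  if (!object@referenceGene %in% object@genes)
    msg <- c(msg, sprintf("reference gene '%s' not measured", object@referenceGene))
  else if (any(!is.finite(object@cq[, match(object@referenceGene, object@genes)])))
    msg <- c(msg, "reference gene must be measured (finite Cq) for every sample")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(object@samples)) msg <- c(msg, "duplicate sample identifiers")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CqTable
#' @param cq numeric samples-by-genes matrix of quantification cycles, with
#'   sample row names and gene column names.
#' @param referenceGene reference (housekeeping) gene identifier.
#' @return A [CqTable-class] object.
#' @export
CqTable <- function(cq, referenceGene) {
  cq <- as.matrix(cq)
  new("CqTable", samples = rownames(cq), genes = colnames(cq),
      cq = cq, referenceGene = referenceGene)
}

#' CohortPair: two cohorts profiled for the same cancer type and drug
#'
#' Holds the paired training data for cross-dataset screening: two
#' expression/response cohorts (e.g. two pharmacogenomic databases) plus the
#' exact intersection of their gene universes.
#'
#' @slot exprA,exprB [TpmExperiment-class] cohorts.
#' @slot respA,respB matching [DrugResponse-class] objects (same drug).
#' @slot sharedGenes character, genes present in both cohorts.
#' @export
setClass("CohortPair", representation(
  exprA = "TpmExperiment", respA = "DrugResponse",
  exprB = "TpmExperiment", respB = "DrugResponse",
  sharedGenes = "character"
))

setValidity("CohortPair", function(object) {
  msg <- NULL
  if (!identical(object@respA@drug, object@respB@drug))
    msg <- c(msg, "both responses must refer to the same drug")
  if (!identical(object@exprA@cancerType, object@exprB@cancerType))
    msg <- c(msg, "both cohorts must share the cancer type")
  expect <- intersect(rownames(object@exprA), rownames(object@exprB))
  if (!identical(sort(object@sharedGenes), sort(expect)))
    msg <- c(msg, "sharedGenes must equal the exact gene intersection")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CohortPair
#' @param exprA,respA,exprB,respB the two cohorts' expression and response.
#' @return A [CohortPair-class] object.
#' @export
CohortPair <- function(exprA, respA, exprB, respB) {
  new("CohortPair", exprA = exprA, respA = respA, exprB = exprB, respB = respB,
      sharedGenes = intersect(rownames(exprA), rownames(exprB)))
}

#' DigitalMarker: a frozen KNN predictor over a compact gene list
#'
#' The finalized predictor for one cancer type-drug pair: the ordered marker
#' gene list (at most 30 genes), the neighbour count chosen by cross-validated
#' enumeration, the standardized training feature matrix (log10(1+TPM),
#' per-gene centred/scaled with the stored statistics), the training targets,
#' and the achieved mean cross-validation AUC.
#'
#' @slot cancerType,drug cohort annotations.
#' @slot genes ordered marker genes (prefix of the screened ranking).
#' @slot k0 neighbour count.
#' @slot task \code{"regression"} (predict IC50 Z-score) or
#'   \code{"classification"} (predict ineffectiveness probability).
#' @slot trainX standardized training matrix, samples x genes.
#' @slot trainY numeric Z-scores (regression) or 0/1 ineffectiveness
#'   indicators (classification).
#' @slot geneCenter,geneScale per-gene standardization statistics on the
#'   log10(1+TPM) scale; scales are strictly positive.
#' @slot cvAuc achieved mean cross-validation AUC.
#' @slot zThreshold sensitivity cut on the true Z-score (-1 by default).
#' @export
setClass("DigitalMarker", representation(
  cancerType = "character", drug = "character", genes = "character",
  k0 = "integer", task = "character", trainX = "matrix", trainY = "numeric",
  geneCenter = "numeric", geneScale = "numeric", cvAuc = "numeric",
  zThreshold = "numeric"
))

setValidity("DigitalMarker", function(object) {
  msg <- NULL
  m <- length(object@genes)
  if (m < 1 || m > 30) msg <- c(msg, "marker must contain between 1 and 30 genes")
  if (object@k0 < 1L || object@k0 > nrow(object@trainX))
    msg <- c(msg, "k0 must lie in [1, n_train]")
  if (!object@task %in% c("regression", "classification"))
    msg <- c(msg, "task must be 'regression' or 'classification'")
  if (ncol(object@trainX) != m || length(object@geneCenter) != m ||
      length(object@geneScale) != m)
    msg <- c(msg, "trainX/standardization must match the marker genes")
  if (length(object@trainY) != nrow(object@trainX))
    msg <- c(msg, "trainY must match trainX rows")
  if (any(object@geneScale <= 0)) msg <- c(msg, "standardization SDs must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' ConversionModel: the linear delta-Cq to TPM calibration
#'
#' Models log10(TPM + 1) = slope * dCq + intercept, where dCq is the target
#' gene's Cq minus the reference gene's Cq. More cycles mean rarer transcript,
#' so any physically meaningful fit has a negative slope. Defaults are the
#' coefficients fitted on the SW620 colorectal line calibration.
#'
#' @slot slope,intercept linear coefficients (log10(TPM+1) per cycle; log10 units).
#' @slot referenceGene housekeeping gene the dCq values are relative to.
#' @slot fitR2 coefficient of determination when fitted (NA when defaulted).
#' @export
setClass("ConversionModel", representation(
  slope = "numeric", intercept = "numeric", referenceGene = "character",
  fitR2 = "numeric"
))

setValidity("ConversionModel", function(object) {
  if (length(object@slope) != 1L || length(object@intercept) != 1L)
    return("slope and intercept must be single numbers")
  if (!is.finite(object@slope) || object@slope >= 0)
    return("slope must be finite and negative")
  TRUE
})

#' Construct a ConversionModel
#' @param slope,intercept coefficients of log10(TPM+1) = slope * dCq + intercept.
#'   Defaults are the published SW620 calibration (-0.3995, 5.6974).
#' @param referenceGene housekeeping gene (default GAPDH).
#' @param fitR2 R-squared of the fit, NA if not fitted.
#' @return A [ConversionModel-class] object.
#' @export
ConversionModel <- function(slope = -0.3995, intercept = 5.6974,
                            referenceGene = "GAPDH", fitR2 = NA_real_) {
  new("ConversionModel", slope = slope, intercept = intercept,
      referenceGene = referenceGene, fitR2 = fitR2)
}
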