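## K-nearest-neighbour prediction in marker-gene space. Features are
## log10(1+TPM), per-gene standardized with training statistics; distances
## are Euclidean; distance ties are broken deterministically by training
## sample index order.

.markerFeatures <- function(marker, query) {
  q <- as.matrix(query)
  missing <- setdiff(marker@genes, colnames(q))
  if (length(missing))
    stop("query is missing marker gene(s): ", paste(missing, collapse = ", "))
  ql <- log10(1 + q[, marker@genes, drop = FALSE])
  sweep(sweep(ql, 2, marker@geneCenter), 2, marker@geneScale, "/")
}

## neighbor index matrix: one row per query, k columns, ties by index order
.knnIndices <- function(trainX, queryX, k) {
  n <- nrow(trainX)
  t(apply(queryX, 1, function(q) {
    d <- sqrt(colSums((t(trainX) - q)^2))
    order(d, seq_len(n))[seq_len(k)]
  }))
}

#' Predict IC50 Z-scores by KNN regression
#'
#' The prediction for each query sample is the unweighted mean of its k0
#' nearest training samples' Z-scores in standardized marker-gene space.
#'
#' @param marker a regression-task [DigitalMarker-class].
#' @param query sample-by-gene TPM matrix (column names must cover the
#'   marker genes) or a [TpmExperiment-class] (transposed internally).
#' @return Named numeric vector of predicted Z-scores.
#' @export
knnRegress <- function(marker, query) {
  if (marker@task != "regression") stop("marker task is not regression")
  if (is(query, "TpmExperiment")) query <- t(tpm(query))
  qx <- .markerFeatures(marker, query)
  idx <- .knnIndices(marker@trainX, qx, marker@k0)
  setNames(rowMeans(matrix(marker@trainY[idx], nrow = nrow(qx))), rownames(qx))
}

#' Predict drug ineffectiveness by KNN classification
#'
#' Returns the fraction of ineffective samples among the k0 nearest training
#' neighbours, the hard label (ineffective when p >= 0.5, the conservative
#' tie resolution), and the zone per [zoneOf()].
#'
#' @param marker a classification-task [DigitalMarker-class] (trainY holds
#'   0/1 ineffectiveness indicators).
#' @param query as in [knnRegress()].
#' @param zoneCuts probability cuts passed to [zoneOf()].
#' @return \code{data.frame} (sample, p_ineffective, label, zone).
#' @export
knnClassify <- function(marker, query, zoneCuts = c(1 / 3, 2 / 3)) {
  if (marker@task != "classification") stop("marker task is not classification")
  if (is(query, "TpmExperiment")) query <- t(tpm(query))
  qx <- .markerFeatures(marker, query)
  idx <- .knnIndices(marker@trainX, qx, marker@k0)
  p <- rowMeans(matrix(marker@trainY[idx], nrow = nrow(qx)))
  data.frame(sample = rownames(qx) %||% seq_len(nrow(qx)),
             p_ineffective = unname(p),
             label = ifelse(p >= 0.5, "ineffective", "effective"),
             zone = vapply(p, zoneOf, character(1), cuts = zoneCuts),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
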