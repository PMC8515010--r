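#' Cross-prediction harness over a paired cohort
#'
#' Compares the three evaluation designs used for paired pharmacogenomic
#' cohorts:
#' \describe{
#'   \item{method 1}{filter and score genes on both datasets, synthesize the
#'     ranking, then 5-fold cross-validate within each dataset separately;}
#'   \item{method 2}{filter/score and cross-validate within the same dataset;}
#'   \item{method 3}{"cross-prediction" — rank genes on one dataset and
#'     cross-validate on the other.}
#' }
#'
#' Two evaluation designs are offered. \code{evaluation = "cv"} follows the
#' original protocol: the (m, k) maximizing the 5-fold CV AUC is selected
#' and the out-of-fold predictions at that choice are reported — note the
#' selection and the report share folds, so null data scores optimistically
#' (winner's curse). \code{evaluation = "nested"} decouples them: outer
#' folds are scored by markers whose ranking and (m, k) come only from the
#' outer training portion, which calibrates to AUC 0.5 on signal-free data.
#'
#' @param pair a [CohortPair-class].
#' @param method 1, 2 or 3.
#' @param config a [filterConfig()].
#' @param zThreshold sensitivity cut on the true Z-score.
#' @param kGrid,seed,mMax passed to [selectDigitalMarker()].
#' @param evaluation \code{"cv"} (protocol-faithful) or \code{"nested"}
#'   (leakage-free outer evaluation).
#' @return Named list of \code{"EvalReport"}s, one per evaluated dataset
#'   (tagged by that dataset's tag); under \code{"cv"} the selected marker
#'   is attached as attribute \code{"marker"}.
#' @export
runCrossPrediction <- function(pair, method = 1, config = filterConfig(),
                               zThreshold = -1.0, kGrid = 1:30, seed = 1L,
                               mMax = 30L, evaluation = c("cv", "nested")) {
  stopifnot(method %in% 1:3)
  evaluation <- match.arg(evaluation)
  shared <- pair@sharedGenes
  xa <- pair@exprA[shared, , drop = FALSE]
  xb <- pair@exprB[shared, , drop = FALSE]
  screenRank <- function(x, r) {
    names(sort(screenCellLineCohort(x, r, config)$scores, decreasing = TRUE))
  }
  ## per-method ranking rules; for nested evaluation these are functions of
  ## the evaluated dataset's *training* portion (the other dataset is
  ## external and may be used in full)
  rankFunFor <- function(which) {
    other <- if (which == "a") list(x = xb, r = pair@respB)
             else list(x = xa, r = pair@respA)
    switch(as.character(method),
      "1" = {
        otherScores <- screenCellLineCohort(other$x, other$r, config)$scores
        function(xx, rr) {
          own <- screenCellLineCohort(xx, rr, config)$scores
          tryCatch(synthesizeScores(own, otherScores)$gene,
                   error = function(e) character(0))
        }
      },
      "2" = function(xx, rr) screenRank(xx, rr),
      "3" = {
        fixed <- screenRank(other$x, other$r)
        function(xx, rr) fixed
      })
  }
  evalOne <- function(which, x, r) {
    rankFun <- rankFunFor(which)
    if (evaluation == "cv") {
      ranked <- rankFun(x, r)
      marker <- selectDigitalMarker(ranked, x, r, zThreshold = zThreshold,
                                    kGrid = kGrid, seed = seed, mMax = mMax)
      rep <- .cvEvalReport(marker, x, r, zThreshold, seed)
      attr(rep, "marker") <- marker
      rep
    } else {
      nest <- nestedCvAuc(x, r, zThreshold = zThreshold, kGrid = kGrid,
                          seed = seed, mMax = mMax, rankFun = rankFun,
                          config = config)
      ok <- !is.na(nest$score)
      pred <- if (nest$task == "regression") (-nest$score[ok]) <= zThreshold
              else nest$score[ok] >= 0.5
      rep <- classificationMetrics(pred, nest$truth[ok],
                                   scores = nest$score[ok])
      attr(rep, "outerAuc") <- nest$outerAuc
      rep
    }
  }
  out <- list(evalOne("a", xa, pair@respA), evalOne("b", xb, pair@respB))
  names(out) <- c(datasetTag(pair@exprA), datasetTag(pair@exprB))
  out
}

## out-of-fold predictions at the selected (m0, k0), summarized as an
## EvalReport with ROC from the continuous ranking scores
.cvEvalReport <- function(marker, x, r, zThreshold, seed, nFolds = 5L) {
  common <- intersect(colnames(x), r@samples)
  task <- marker@task
  if (task == "regression") {
    y <- zScores(r)[common]
    truth <- y <= zThreshold
  } else {
    truth <- responseLabels(r)[common] == "effective"
  }
  fold <- .stratifiedFolds(unname(truth), nFolds, seed)
  score <- rep(NA_real_, length(common))
  for (f in seq_len(nFolds)) {
    tr <- common[fold != f]; te <- common[fold == f]
    sub <- .refitMarker(marker, x, r, tr)
    q <- t(tpm(x)[, te, drop = FALSE])
    score[fold == f] <- if (task == "regression") -unname(knnRegress(sub, q))
                        else 1 - knnClassify(sub, q)$p_ineffective
  }
  ## hard labels: regression calls sensitive when predicted z <= threshold
  pred <- if (task == "regression") (-score) <= zThreshold else score >= 0.5
  classificationMetrics(pred, unname(truth), scores = score)
}

## refit the marker's reference data on a training subset (genes fixed)
.refitMarker <- function(marker, x, r, trainSamples) {
  Xm <- log10(1 + t(tpm(x)[marker@genes, trainSamples, drop = FALSE]))
  ctr <- colMeans(Xm)
  csd <- apply(Xm, 2, stats::sd)
  csd[csd == 0 | !is.finite(csd)] <- 1
  y <- if (marker@task == "regression") unname(zScores(r)[trainSamples])
       else as.numeric(responseLabels(r)[trainSamples] == "ineffective")
  k0 <- min(marker@k0, length(trainSamples))
  new("DigitalMarker", cancerType = marker@cancerType, drug = marker@drug,
      genes = marker@genes, k0 = as.integer(k0), task = marker@task,
      trainX = sweep(sweep(Xm, 2, ctr), 2, csd, "/"), trainY = y,
      geneCenter = ctr, geneScale = csd, cvAuc = marker@cvAuc,
      zThreshold = marker@zThreshold)
}

#' Project a marker's training space to 2D with a KNN probability field
#'
#' PCA (top two components of the standardized training matrix) coordinates
#' for the training samples and optional extra points, plus a grid of KNN
#' class probabilities computed in the 2D space — the decision map used to
#' visualize how a marker separates sensitive from non-sensitive samples.
#'
#' @param marker a [DigitalMarker-class] with at least 2 genes.
#' @param extraPoints optional sample-by-gene TPM matrix to co-project.
#' @param k neighbour count for the probability field (defaults to the
#'   marker's k0).
#' @param gridSize grid resolution per axis.
#' @return List with \code{train} (PC coordinates + target), \code{extra}
#'   (or NULL), and \code{field} (x, y, p) where p is the probability of the
#'   positive/ineffective class among the k nearest training samples in 2D.
#' @export
project2dMap <- function(marker, extraPoints = NULL, k = NULL, gridSize = 25L) {
  if (length(marker@genes) < 2) stop("need a marker with at least 2 genes")
  k <- as.integer(k %||% marker@k0)
  pca <- stats::prcomp(marker@trainX, center = TRUE, scale. = FALSE)
  tr2 <- pca$x[, 1:2, drop = FALSE]
  ex2 <- NULL
  if (!is.null(extraPoints)) {
    qx <- .markerFeatures(marker, extraPoints)
    ex2 <- scale(qx, center = pca$center, scale = FALSE) %*% pca$rotation[, 1:2]
  }
  all2 <- rbind(tr2, ex2)
  gx <- seq(min(all2[, 1]), max(all2[, 1]), length.out = gridSize)
  gy <- seq(min(all2[, 2]), max(all2[, 2]), length.out = gridSize)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  yb <- if (marker@task == "classification") marker@trainY
        else as.numeric(marker@trainY <= marker@zThreshold)
  idx <- .knnIndices(tr2, grid, min(k, nrow(tr2)))
  p <- rowMeans(matrix(yb[idx], nrow = nrow(grid)))
  list(train = data.frame(pc1 = tr2[, 1], pc2 = tr2[, 2], y = marker@trainY),
       extra = if (is.null(ex2)) NULL else data.frame(pc1 = ex2[, 1], pc2 = ex2[, 2]),
       field = data.frame(x = grid[, 1], y = grid[, 2], p = p))
}
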