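## Cross-validated enumeration of (m, k): marker size and neighbour count.
## The gene list is enumerated in rank order (m = 1..30); for each m, every
## k in the grid is tried; performance is the mean held-out AUC over
## stratified 5-fold CV.

## stratified fold assignment: within each class, shuffled then dealt
## round-robin so fold sizes differ by at most one per class
.stratifiedFolds <- function(labels, nFolds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  }
  fold
}

## Per-fold CV AUC surface over (m, k). Xl: samples x genes log10(1+TPM),
## columns in rank order (prefixes define markers). y: numeric target (z or
## 0/1 ineffectiveness). labels: logical positives for AUC. rankFun: when
## non-NULL, re-ranks genes on each training fold (leakage-free screening).
.cvAucGrid <- function(Xl, y, labels, task, kGrid, nFolds, seed, mMax,
                       rankFun = NULL) {
  n <- nrow(Xl)
  fold <- .stratifiedFolds(labels, nFolds, seed)
  kMaxAll <- max(kGrid)
  auc <- array(NA_real_, c(mMax, kMaxAll, nFolds))
  for (f in seq_len(nFolds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(labels[te])) < 2 || length(tr) < 2) next
    cols <- if (is.null(rankFun)) colnames(Xl) else rankFun(tr)
    mEff <- min(mMax, length(cols))
    if (mEff < 1) next
    Xf <- Xl[, cols[seq_len(mEff)], drop = FALSE]
    ctr <- colMeans(Xf[tr, , drop = FALSE])
    csd <- apply(Xf[tr, , drop = FALSE], 2, stats::sd)
    csd[csd == 0 | !is.finite(csd)] <- 1
    Ztr <- sweep(sweep(Xf[tr, , drop = FALSE], 2, ctr), 2, csd, "/")
    Zte <- sweep(sweep(Xf[te, , drop = FALSE], 2, ctr), 2, csd, "/")
    kMax <- min(kMaxAll, length(tr))
    ks <- kGrid[kGrid <= kMax]
    ## cumulative squared distances over the gene prefix
    d2 <- matrix(0, length(te), length(tr))
    for (m in seq_len(mEff)) {
      d2 <- d2 + outer(Zte[, m], Ztr[, m], "-")^2
      ## neighbour targets in distance order, ties by training index
      scoreK <- matrix(NA_real_, length(te), kMax)
      for (i in seq_along(te)) {
        nb <- y[tr][order(d2[i, ], seq_along(tr))[seq_len(kMax)]]
        scoreK[i, ] <- cumsum(nb) / seq_len(kMax)
      }
      ## ranking score toward the positive (sensitive/effective) class:
      ## regression: -predicted z; classification: 1 - p_ineffective
      for (k in ks) {
        s <- if (task == "regression") -scoreK[, k] else 1 - scoreK[, k]
        auc[m, k, f] <- rocAuc(s, labels[te])
      }
    }
  }
  auc
}

#' Select a digital marker by cross-validated (m, k) enumeration
#'
#' Enumerates marker sizes m = 1..min(30, number of ranked genes) in rank
#' order and, for each m, every neighbour count k in \code{kGrid}; each
#' (m, k) is scored by the mean AUC over stratified 5-fold cross-validation
#' (regression tasks rank held-out samples by -predicted Z and define the
#' positive class by \code{z <= zThreshold}; classification tasks rank by
#' the predicted probability of effectiveness). The marker maximizing mean
#' CV AUC is returned, ties broken by smaller m then smaller k, with
#' standardization statistics refit on the full data.
#'
#' With \code{nested = TRUE} the gene ranking is recomputed inside each
#' training fold via \code{rankFun}, so held-out folds never influence the
#' screening — the leakage-free variant. The default (\code{nested = FALSE})
#' follows the original protocol of ranking once on the full cohort.
#'
#' @param rankedGenes screened genes in rank order (ignored when nested).
#' @param x a [TpmExperiment-class] of training samples.
#' @param r the matching [DrugResponse-class]; continuous mode implies a
#'   regression task, binary mode a classification task (overridable).
#' @param task \code{"regression"} or \code{"classification"}.
#' @param zThreshold sensitivity cut on the true Z-score (default -1).
#' @param kGrid neighbour counts to enumerate (default 1..30).
#' @param nFolds number of CV folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param mMax largest marker size (default 30).
#' @param nested recompute the ranking within each training fold.
#' @param rankFun function(x, r) -> ranked gene vector, used when nested;
#'   defaults to the cell-line screen for continuous responses and the
#'   patient screen for binary ones.
#' @param config [filterConfig()] for the default rankFun.
#' @return A [DigitalMarker-class]; attribute \code{"aucGrid"} holds the
#'   full mean-CV-AUC matrix (m x k) for inspection.
#' @export
selectDigitalMarker <- function(rankedGenes, x, r, task = NULL,
                                zThreshold = -1.0, kGrid = 1:30, nFolds = 5L,
                                seed = 1L, mMax = 30L, nested = FALSE,
                                rankFun = NULL, config = filterConfig()) {
  common <- intersect(colnames(x), r@samples)
  if (length(common) < 10) stop("need at least 10 samples")
  if (is.null(task))
    task <- if (responseMode(r) == "continuous") "regression" else "classification"
  if (task == "regression") {
    yAll <- zScores(r)[common]
    labels <- yAll <= zThreshold          # positive class: sensitive
  } else {
    lab <- responseLabels(r)[common]
    yAll <- as.numeric(lab == "ineffective")
    labels <- lab == "effective"
  }
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop("need at least 2 samples per class after thresholding")
  if (nested && is.null(rankFun)) {
    rankFun <- if (responseMode(r) == "continuous") {
      function(xx, rr) names(sort(screenCellLineCohort(xx, rr, config)$scores,
                                  decreasing = TRUE))
    } else {
      function(xx, rr) screenPatientCohort(xx, rr, config)$rankedGenes
    }
  }
  geneUniverse <- if (nested) rownames(x) else {
    if (is.null(rankedGenes) || length(rankedGenes) < 1)
      stop("rankedGenes must be non-empty")
    rankedGenes
  }
  Xl <- log10(1 + t(tpm(x)[geneUniverse, common, drop = FALSE]))
  foldRankFun <- if (nested) {
    function(tr) {
      xs <- x[, common[tr], drop = FALSE]
      rs <- .subsetResponse(r, common[tr])
      rankFun(xs, rs)
    }
  } else NULL
  mCap <- if (nested) mMax else min(mMax, length(geneUniverse))
  auc <- .cvAucGrid(Xl, unname(yAll), unname(labels), task, kGrid, nFolds,
                    seed, mCap, foldRankFun)
  meanAuc <- apply(auc, c(1, 2), mean, na.rm = TRUE)
  meanAuc[!is.finite(meanAuc)] <- NA_real_
  if (all(is.na(meanAuc))) stop("cross-validation produced no valid AUC")
  best <- which(meanAuc == max(meanAuc, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]  # smaller m, then k
  m0 <- best[1]; k0 <- best[2]
  finalGenes <- if (nested) {
    rk <- rankFun(x[, common, drop = FALSE], .subsetResponse(r, common))
    rk[seq_len(min(m0, length(rk)))]
  } else rankedGenes[seq_len(m0)]
  Xm <- log10(1 + t(tpm(x)[finalGenes, common, drop = FALSE]))
  ctr <- colMeans(Xm)
  csd <- apply(Xm, 2, stats::sd)
  csd[csd == 0 | !is.finite(csd)] <- 1
  marker <- new("DigitalMarker", cancerType = cancerType(x), drug = r@drug,
                genes = finalGenes, k0 = as.integer(k0), task = task,
                trainX = sweep(sweep(Xm, 2, ctr), 2, csd, "/"),
                trainY = unname(yAll), geneCenter = ctr, geneScale = csd,
                cvAuc = meanAuc[m0, k0], zThreshold = zThreshold)
  attr(marker, "aucGrid") <- meanAuc
  marker
}

.subsetResponse <- function(r, samples) {
  idx <- match(samples, r@samples)
  if (r@mode == "continuous") {
    ## z is re-standardized within the subset so it stays a valid cohort
    ## Z-score for the training portion
    obj <- r
    obj@samples <- r@samples[idx]
    obj@ic50 <- r@ic50[idx]
    zi <- r@z[idx]
    sdp <- sqrt(mean((zi - mean(zi))^2))
    obj@z <- if (sdp > 0) (zi - mean(zi)) / sdp else zi
    obj
  } else {
    new("DrugResponse", drug = r@drug, samples = r@samples[idx],
        mode = "binary", ic50 = numeric(0), z = numeric(0),
        label = r@label[idx])
  }
}

#' Nested cross-validation estimate of pipeline performance
#'
#' Outer stratified k-fold evaluation of the \emph{whole} pipeline: within
#' each outer training set the genes are screened and ranked and (m, k) is
#' chosen by inner cross-validation; the frozen marker then scores the
#' untouched outer test fold. The mean outer AUC is an unbiased estimate of
#' generalization — on null data it calibrates to 0.5, unlike the maximum of
#' the selection grid, which retains winner's-curse optimism even without
#' information leakage.
#'
#' @inheritParams selectDigitalMarker
#' @param nOuter outer fold count (default 5).
#' @return List with \code{outerAuc} (per-fold vector) and \code{meanAuc}.
#' @export
nestedCvAuc <- function(x, r, task = NULL, zThreshold = -1.0, kGrid = 1:30,
                        nFolds = 5L, nOuter = 5L, seed = 1L, mMax = 30L,
                        rankFun = NULL, config = filterConfig()) {
  common <- intersect(colnames(x), r@samples)
  if (is.null(task))
    task <- if (responseMode(r) == "continuous") "regression" else "classification"
  labels <- if (task == "regression") zScores(r)[common] <= zThreshold
            else responseLabels(r)[common] == "effective"
  fold <- .stratifiedFolds(unname(labels), nOuter, seed)
  if (is.null(rankFun)) {
    rankFun <- if (responseMode(r) == "continuous") {
      function(xx, rr) names(sort(screenCellLineCohort(xx, rr, config)$scores,
                                  decreasing = TRUE))
    } else {
      function(xx, rr) screenPatientCohort(xx, rr, config)$rankedGenes
    }
  }
  outer <- rep(NA_real_, nOuter)
  oofScore <- rep(NA_real_, length(common))
  for (f in seq_len(nOuter)) {
    tr <- common[fold != f]; te <- common[fold == f]
    xtr <- x[, tr, drop = FALSE]
    rtr <- .subsetResponse(r, tr)
    ranked <- rankFun(xtr, rtr)
    if (length(ranked) < 1) next
    marker <- selectDigitalMarker(ranked, xtr, rtr, task = task,
                                  zThreshold = zThreshold, kGrid = kGrid,
                                  nFolds = nFolds, seed = seed + f, mMax = mMax)
    q <- t(tpm(x)[, te, drop = FALSE])
    score <- if (task == "regression") -knnRegress(marker, q)
             else 1 - knnClassify(marker, q)$p_ineffective
    oofScore[fold == f] <- unname(score)
    if (length(unique(labels[te])) >= 2)
      outer[f] <- rocAuc(unname(score), unname(labels[te]))
  }
  list(outerAuc = outer, meanAuc = mean(outer, na.rm = TRUE),
       score = setNames(oofScore, common),
       truth = setNames(unname(labels), common), task = task,
       zThreshold = zThreshold)
}
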