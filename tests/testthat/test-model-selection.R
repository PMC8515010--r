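test_that("marker selection recovers a perfectly predictive planted signal", {
  pc <- plantedCohort()
  mk <- selectDigitalMarker(pc$ranked, pc$x, pc$r, seed = 3)
  expect_equal(cvAuc(mk), 1.0)
  expect_lte(length(markerGenes(mk)), 10)
  expect_true(all(startsWith(markerGenes(mk), "sig")))
  ## tie-break: many (m, k) reach AUC 1; the smallest m must win
  grid <- attr(mk, "aucGrid")
  mStar <- min(which(apply(grid, 1, max, na.rm = TRUE) == 1))
  expect_equal(length(markerGenes(mk)), mStar)
  kStar <- min(which(grid[mStar, ] == 1))
  expect_equal(neighborCount(mk), kStar)
})

test_that("the CV grid at m = 1, k = 1 equals a brute-force 1-NN baseline", {
  pc <- plantedCohort(nDecoys = 10, n = 30, seed = 8, noise = 0.5)
  seed <- 13
  mk <- selectDigitalMarker(pc$ranked[1], pc$x, pc$r, kGrid = 1, mMax = 1,
                            seed = seed)
  ## independent oracle: same dealing scheme, naive 1-NN per fold
  common <- colnames(pc$x)
  y <- zScores(pc$r)[common]
  labels <- y <= -1
  fold <- oracleFolds(unname(labels), 5, seed)
  Xl <- log10(1 + t(tpm(pc$x)[pc$ranked[1], , drop = FALSE]))
  aucs <- sapply(1:5, function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(labels[te])) < 2) return(NA_real_)
    mu <- mean(Xl[tr, ]); sdv <- sd(Xl[tr, ])
    ztr <- (Xl[tr, ] - mu) / sdv; zte <- (Xl[te, ] - mu) / sdv
    pred <- sapply(zte, function(q) {
      d <- abs(ztr - q)
      y[tr][order(d, seq_along(d))[1]]
    })
    oracleAuc(-pred, labels[te])
  })
  expect_equal(cvAuc(mk), mean(aucs, na.rm = TRUE), tolerance = 1e-12)
})

test_that("selection is deterministic under a fixed seed", {
  pc <- plantedCohort(nDecoys = 20, n = 30, seed = 4, noise = 0.4)
  mk1 <- selectDigitalMarker(pc$ranked, pc$x, pc$r, seed = 11)
  mk2 <- selectDigitalMarker(pc$ranked, pc$x, pc$r, seed = 11)
  expect_identical(markerGenes(mk1), markerGenes(mk2))
  expect_identical(neighborCount(mk1), neighborCount(mk2))
  expect_identical(cvAuc(mk1), cvAuc(mk2))
  expect_identical(attr(mk1, "aucGrid"), attr(mk2, "aucGrid"))
})

test_that("identical paired datasets make methods 2 and 3 coincide", {
  sim <- generateCellLinePair(generatorConfig(nGenes = 300, nSamplesA = 30,
                                              nSamplesB = 30, seed = 17))
  p <- sim$pair
  same <- CohortPair(p@exprA, p@respA,
                     TpmExperiment(tpm(p@exprA), cancerType(p@exprA), "copy"),
                     p@respA)
  m2 <- runCrossPrediction(same, method = 2, seed = 2)
  m3 <- runCrossPrediction(same, method = 3, seed = 2)
  for (f in c("accuracy", "precision", "recall", "specificity",
              "f1_weighted", "auc")) {
    expect_equal(m2[[1]][[f]], m3[[1]][[f]], tolerance = 1e-12)
    expect_equal(m2[[2]][[f]], m3[[2]][[f]], tolerance = 1e-12)
  }
})

test_that("EvalReports carry consistent confusion counts", {
  sim <- generateCellLinePair(generatorConfig(nGenes = 300, nSamplesA = 30,
                                              nSamplesB = 30, seed = 23))
  rep1 <- runCrossPrediction(sim$pair, method = 1, seed = 5)[[1]]
  with(rep1, {
    expect_equal(accuracy, (tp + tn) / (tp + tn + fp + fn))
    expect_equal(recall, tp / (tp + fn))
    expect_equal(specificity, tn / (tn + fp))
  })
  expect_true(rep1$auc >= 0 && rep1$auc <= 1)
  expect_s4_class(attr(rep1, "marker"), "DigitalMarker")
})

test_that("2D projection preserves a centred 2D space and quantizes the field", {
  set.seed(31)
  feat <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("gA", "gB")))
  feat <- scale(feat, scale = FALSE)
  mk <- makeMarker(feat, rnorm(20), k = 5)
  proj <- project2dMap(mk, gridSize = 8)
  ## PCA of an already-2D centred cloud is a rotation: distances preserved
  d0 <- dist(feat); d1 <- dist(as.matrix(proj$train[, c("pc1", "pc2")]))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-9)
  expect_true(all(abs(proj$field$p * 5 - round(proj$field$p * 5)) < 1e-12))
  mk1 <- makeMarker(feat[, 1, drop = FALSE], rnorm(20), k = 3)
  expect_error(project2dMap(mk1), "at least 2")
})

test_that("marker JSON serialization round-trips predictions exactly", {
  pc <- plantedCohort(nDecoys = 10, n = 30, seed = 19, noise = 0.4)
  mk <- selectDigitalMarker(pc$ranked, pc$x, pc$r, seed = 7)
  p <- withr::local_tempfile(fileext = ".json")
  writeMarker(mk, p)
  mk2 <- readMarker(p)
  q <- t(tpm(pc$x))[1:5, ]
  expect_equal(knnRegress(mk, q), knnRegress(mk2, q), tolerance = 1e-12)
  expect_identical(markerGenes(mk), markerGenes(mk2))
  expect_identical(neighborCount(mk), neighborCount(mk2))
})
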