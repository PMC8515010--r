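test_that("the calibration fit recovers exactly linear data to machine precision", {
  slope <- -0.3995; intercept <- 5.6974
  dcq <- seq(-2, 14, by = 0.5)   # stays below the TPM = 0 root
  tpmv <- 10^(slope * dcq + intercept) - 1
  m <- fitConversion(dcq, tpmv)
  expect_equal(m@slope, slope, tolerance = 1e-9)
  expect_equal(m@intercept, intercept, tolerance = 1e-9)
  expect_equal(m@fitR2, 1, tolerance = 1e-12)
  ## two distinct points interpolate with R2 = 1
  m2 <- fitConversion(c(0, 10), 10^c(5, 1) - 1)
  expect_equal(m2@slope, -0.4, tolerance = 1e-12)
  expect_equal(m2@intercept, 5, tolerance = 1e-12)
  expect_error(fitConversion(rep(3, 5), 1:5), "constant")
})

test_that("noisy calibration recovers the generating slope within 3 SE", {
  set.seed(101)
  n <- 1000
  dcq <- runif(n, 0, 14)
  y <- -0.3995 * dcq + 5.6974 + rnorm(n, sd = 0.3)
  tpmv <- pmax(10^y - 1, 0)
  m <- fitConversion(dcq, tpmv)
  se <- summary(lm(log10(tpmv + 1) ~ dcq))$coefficients["dcq", "Std. Error"]
  expect_lt(abs(m@slope + 0.3995), 3 * se)
})

test_that("dCq/TPM conversion evaluates the line and inverts to 1e-9", {
  m <- ConversionModel()
  expect_equal(dcqToTpm(0, m), 10^5.6974 - 1, tolerance = 1e-12)
  root <- 5.6974 / 0.3995
  expect_equal(dcqToTpm(root, m), 0, tolerance = 1e-9)
  expect_equal(tpmToDcq(0, m), root, tolerance = 1e-12)
  expect_equal(tpmToDcq(10^5.6974 - 1, m), 0, tolerance = 1e-9)
  grid <- seq(-5, 13, by = 0.25)   # below the TPM = 0 root, floor inactive
  expect_lt(max(abs(tpmToDcq(dcqToTpm(grid, m), m) - grid)), 1e-9)
  ## strictly decreasing in dCq
  expect_true(all(diff(dcqToTpm(grid, m)) < 0))
  expect_error(ConversionModel(slope = 0.1), "negative")
})

test_that("relative Z standardizes against the cohort with population SD", {
  expect_equal(relativeZ(5, c(4, 5, 6)), 0)
  expect_equal(relativeZ(3, c(0, 2)), 2.0)
  vals <- seq(-2, 4, by = 0.5)
  rz <- sapply(vals, relativeZ, cohort = c(0, 1, 3))
  expect_true(all(diff(rz) > 0))
  expect_error(relativeZ(1, c(2, 2, 2)), "SD is zero")
  expect_error(relativeZ(1, 3), "at least 2")
})

test_that("zones split the probability axis with strict cuts", {
  expect_identical(zoneOf(0), "effective")
  expect_identical(zoneOf(0.5), "intermediate")
  expect_identical(zoneOf(1), "ineffective")
  expect_identical(zoneOf(1 / 3), "intermediate")  # boundary -> middle zone
  expect_error(zoneOf(0.5, cuts = c(0.7, 0.3)), "cuts")
})

test_that("recommendations use strict +/-1 relative-Z rules with colors", {
  cohort <- c(-1, 0, 1)   # mean 0, population SD ~0.816
  sdp <- sqrt(mean(cohort^2))
  preds <- setNames(c(-1.5, -1, 0, 1, 2.3) * sdp, paste0("drug", 1:5))
  rec <- recommend(preds, setNames(rep(list(cohort), 5), names(preds)))
  expect_equal(rec$relative_z, c(-1.5, -1, 0, 1, 2.3), tolerance = 1e-12)
  expect_identical(rec$call,
                   c("sensitive", "neutral", "neutral", "neutral", "non-sensitive"))
  expect_identical(rec$display_color, c("green", "black", "black", "black", "red"))
  ## affine invariance: shifting/scaling cohort and value together
  rec2 <- recommend(setNames(preds * 3 + 7, names(preds)),
                    setNames(rep(list(cohort * 3 + 7), 5), names(preds)))
  expect_equal(rec2$relative_z, rec$relative_z, tolerance = 1e-12)
})

test_that("the qPCR path reproduces the TPM path exactly on noiseless Cq", {
  pc <- plantedCohort(nDecoys = 10, n = 30, seed = 19, noise = 0.3)
  mk <- selectDigitalMarker(pc$ranked, pc$x, pc$r, seed = 3)
  sub <- pc$x[markerGenes(mk), 1:6]
  cq <- generateQpcrReadout(sub, cqNoiseSd = 0)
  fromCq <- predictFromQpcr(cq, mk)
  fromTpm <- predictFromTpm(t(tpm(sub)), mk)
  expect_equal(fromCq$z, fromTpm$z, tolerance = 1e-12)
  ## k0 = 1 query built from a training sample returns its response
  mk1 <- makeMarker(mk@trainX, mk@trainY, k = 1, genes = markerGenes(mk))
  tr1 <- t(tpm(pc$x)[markerGenes(mk), 4, drop = FALSE])
  ## features must go through the same standardization as training
  mk1@geneCenter <- mk@geneCenter; mk1@geneScale <- mk@geneScale
  expect_equal(unname(knnRegress(mk1, tr1)), mk@trainY[4], tolerance = 1e-12)
  ## missing marker gene in the Cq table
  cqBad <- CqTable(matrix(c(24, 20), 1, 2,
                          dimnames = list("s1", c("other", "GAPDH"))), "GAPDH")
  expect_error(predictFromQpcr(cqBad, mk), "missing marker gene")
})

test_that("Cq generation inverts the calibration and shifts by log2 per doubling", {
  x <- randomTpmCohort(8, 4, seed = 55)
  cq <- generateQpcrReadout(x, cqNoiseSd = 0)
  dcq <- cq@cq[, rownames(x)] - cq@cq[, "GAPDH"]
  back <- matrix(dcqToTpm(as.vector(dcq)), nrow(dcq))
  expect_lt(max(abs(back - t(tpm(x))) / (1 + t(tpm(x)))), 1e-6)
  ## doubling TPM+1 changes dCq by log10(2)/|slope| cycles
  d1 <- tpmToDcq(9); d2 <- tpmToDcq(19)
  expect_equal(d1 - d2, log10(2) / 0.3995, tolerance = 1e-9)
})
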