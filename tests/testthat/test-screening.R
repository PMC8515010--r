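test_that("expression filter uses a strict cut on mean log expression", {
  x <- makeTpm(rbind(c(99, 99, 99),   # mean log10(100) = 2 > 1
               c(9, 9, 9),            # mean log10(10) = 1, boundary: rejected
               c(999, 999, 999)))
  kept <- filterByExpression(x, threshold = 1, pseudo = 1)
  expect_identical(kept, c("g1", "g3"))
  ## patient path: a single zero TPM fails the gene (log10(0) = -Inf)
  xp <- makeTpm(rbind(c(0, 100), c(10, 10)))
  expect_identical(filterByExpression(xp, threshold = 0, pseudo = 0), "g2")
})

test_that("raising the expression threshold never enlarges the gene set", {
  x <- randomTpmCohort(300, 12, seed = 11)
  thresholds <- seq(-0.5, 2.5, by = 0.25)
  for (pseudo in c(1, 0)) {
    sets <- lapply(thresholds, function(t) filterByExpression(x, t, pseudo))
    for (i in seq_along(sets)[-1])
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("correlation filter handles sign policy, exact boundaries, and degeneracy", {
  z <- c(-1.5, -0.5, 0.5, 1.5)
  zc <- z / sqrt(mean(z^2))
  x <- makeTpm(rbind(c(1, 2, 3, 4),      # r = +1
               c(4, 3, 2, 1),            # r = -1
               c(5, 5, 5, 5)),           # zero variance: undefined, dropped
               samples = c("a", "b", "c", "d"))
  r <- makeContinuousResponse(zc, c("a", "b", "c", "d"))
  expect_setequal(filterByCorrelation(x, r, 0.25, useAbs = TRUE), c("g1", "g2"))
  expect_identical(filterByCorrelation(x, r, 0.25, useAbs = FALSE), "g1")
  ## strictness: a gene whose |r| equals the threshold exactly is rejected
  set.seed(3)
  xr <- makeTpm(matrix(runif(8, 1, 9), 2), samples = c("a", "b", "c", "d"))
  robs <- abs(cor(tpm(xr)[1, ], zScores(r)))
  expect_false("g1" %in% filterByCorrelation(xr, r, threshold = robs))
  expect_error(filterByCorrelation(x[, 1:2], r, 0.25), "at least 3")
})

test_that("Fisher discriminant scores match hand-derived extremes", {
  ## six samples; extreme fraction 0.5 puts three in each IC50 tail;
  ## expression built so log10(1+TPM) is exactly [1,2,3] vs [7,8,9]
  z <- c(-3, -2, -1, 1, 2, 3)
  samples <- sprintf("s%d", 1:6)
  lowLog <- c(1, 2, 3); highLog <- c(7, 8, 9)
  x <- makeTpm(matrix(10^c(lowLog, highLog) - 1, 1), samples = samples)
  r <- makeContinuousResponse(z, samples)
  s <- scoreFisherLD(x, r, extremeFraction = 0.5)
  expect_equal(unname(s), 6 / sqrt(2), tolerance = 1e-12)  # |6|/sqrt(1+1)
  ## degenerate groups
  x2 <- makeTpm(rbind(rep(10^5 - 1, 4), 10^c(1, 1, 2, 2) - 1),
                samples = sprintf("s%d", 1:4))
  r2 <- makeContinuousResponse(c(-1, -2, 1, 2), sprintf("s%d", 1:4))
  s2 <- scoreFisherLD(x2, r2, extremeFraction = 0.5)
  expect_identical(unname(s2["g1"]), 0)        # equal means, zero variances
  expect_identical(unname(s2["g2"]), Inf)      # unequal means, zero variances
  expect_error(scoreFisherLD(x2[, 1:3], r2), "at least 4")
})

test_that("Fisher scores agree with a brute-force oracle on random instances", {
  worst <- 0
  for (trial in 1:250) {
    set.seed(trial)
    n <- sample(4:12, 1)
    g <- sample(1:5, 1)
    x <- randomTpmCohort(g, n, seed = trial + 1000)
    z <- rnorm(n)
    r <- makeContinuousResponse(z, colnames(x))
    got <- scoreFisherLD(x, r, extremeFraction = 0.15)
    want <- oracleFisher(tpm(x), zScores(r), f = 0.15)
    worst <- max(worst, max(abs(got - want[names(got)]), na.rm = TRUE))
  }
  expect_lt(worst, 1e-12)
})

test_that("Mann-Whitney scores reproduce exact enumeration", {
  x <- makeTpm(matrix(c(1, 2, 3, 4), 1), samples = c("a", "b", "c", "d"))
  r <- DrugResponse("d", c("a", "b", "c", "d"),
                    label = c("effective", "effective", "ineffective", "ineffective"))
  expect_equal(unname(scoreMannWhitney(x, r)), -log10(1 / 3), tolerance = 1e-12)
  ## identical groups with ties -> p = 1, score 0
  xt <- makeTpm(matrix(c(1, 2, 1, 2), 1), samples = c("a", "b", "c", "d"))
  expect_equal(unname(scoreMannWhitney(xt, r)), 0, tolerance = 1e-12)
  ## perfect separation of 8 vs 8
  s16 <- sprintf("s%d", 1:16)
  xs <- makeTpm(matrix(1:16, 1), samples = s16)
  rs <- DrugResponse("d", s16, label = rep(c("effective", "ineffective"), each = 8))
  expect_equal(unname(scoreMannWhitney(xs, rs)), -log10(2 / choose(16, 8)),
               tolerance = 1e-12)
  expect_error(scoreMannWhitney(xs, DrugResponse("d", s16, label = rep("effective", 16))),
               "non-empty")
})

test_that("exact-branch Mann-Whitney agrees with full enumeration on random data", {
  worst <- 0
  for (trial in 1:200) {
    set.seed(trial + 5000)
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- sample(1000, n1 + n2)  # no ties
    samples <- sprintf("s%d", seq_len(n1 + n2))
    x <- makeTpm(matrix(vals, 1), samples = samples)
    r <- DrugResponse("d", samples,
                      label = rep(c("effective", "ineffective"), c(n1, n2)))
    got <- 10^(-scoreMannWhitney(x, r))
    want <- oracleMannWhitneyP(vals[1:n1], vals[(n1 + 1):(n1 + n2)])
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-9)
})

test_that("score synthesis sums, ranks, and tie-breaks deterministically", {
  tab <- synthesizeScores(c(g1 = 2, g2 = 1), c(g1 = 0.5, g2 = 3))
  expect_equal(tab$score_combined, c(4, 2.5))
  expect_identical(tab$gene, c("g2", "g1"))
  expect_identical(tab$rank, 1:2)
  expect_error(synthesizeScores(c(g1 = 1), c(g2 = 1)), "relax")
  tie <- synthesizeScores(c(g1 = 1, g2 = 1), c(g2 = 1, g1 = 1))
  expect_identical(tie$gene, c("g1", "g2"))   # lexicographic tie-break
  ## symmetry under mode = sum
  set.seed(9)
  a <- setNames(runif(30), sprintf("g%02d", 1:30))
  b <- setNames(runif(30), sprintf("g%02d", 1:30))
  ab <- synthesizeScores(a, b); ba <- synthesizeScores(b, a)
  expect_equal(ab[c("gene", "score_combined", "rank")],
               ba[c("gene", "score_combined", "rank")])
  ## percentile mode maps into (0, 1] before summing
  pct <- synthesizeScores(c(g1 = 100, g2 = 1), c(g1 = 0.1, g2 = 0.2),
                          mode = "rank_percentile_sum")
  expect_equal(sort(pct$score_combined), c(1.5, 1.5))
})

test_that("stable-gene counting requires strict counts in both datasets", {
  mk <- function(gene, k, total = 30)
    c(lapply(seq_len(k), function(i) c(gene, sprintf("pad%d_%d", i, k))),
      lapply(seq_len(total - k), function(i) sprintf("pad%d_%d", i, k)))
  la <- mk("gA", 21); lb <- mk("gA", 21)
  tab <- countStableGenes(la, lb, 20)
  expect_identical(tab$gene, "gA")
  expect_identical(tab$count_a, 21L)
  ## boundary: count exactly 20 in one dataset fails (strict >)
  expect_equal(nrow(countStableGenes(mk("gB", 25), mk("gB", 20), 20)), 0)
  ## present in one dataset only fails
  expect_equal(nrow(countStableGenes(mk("gC", 30), mk("other", 30), 20)), 0)
})

test_that("null correlation-filter pass rate matches the t-tail mass", {
  ## decoy-only cohort: expression independent of z, so the Pearson null is
  ## exact (z is iid normal); aggregate over seeds and compare binomially
  passes <- 0; total <- 0
  for (seed in 1:5) {
    sim <- generateCellLinePair(generatorConfig(nGenes = 1000, effectSize = 0,
                                                seed = seed))
    x <- sim$pair@exprA; r <- sim$pair@respA
    v <- tpm(x)
    nonConst <- rownames(v)[apply(v, 1, sd) > 0]
    kept <- filterByCorrelation(x[nonConst, ], r, 0.25, useAbs = TRUE)
    passes <- passes + length(kept); total <- total + length(nonConst)
  }
  n <- ncol(sim$pair@exprA)
  t0 <- 0.25 * sqrt((n - 2) / (1 - 0.25^2))
  p0 <- 2 * pt(-t0, df = n - 2)
  expect_lt(abs(passes - total * p0), 5 * sqrt(total * p0 * (1 - p0)))
})

test_that("patient screening ranks planted genes first under strong effect", {
  sim <- generatePatientCohort(generatorConfig(nSignalGenes = 6, effectSize = 0.9,
                                               nGenes = 400, seed = 21))
  scr <- screenPatientCohort(sim$x, sim$r)
  ## down-shifted signal genes can hit the zero-TPM rule of the patient
  ## expression filter; every signal gene that survives it must outrank
  ## every decoy
  surviving <- intersect(sim$truth$gene, scr$rankedGenes)
  expect_gte(length(surviving), 4)
  expect_true(all(match(surviving, scr$rankedGenes) <= length(surviving)))
  expect_identical(scr$table$rank, seq_len(nrow(scr$table)))
})
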