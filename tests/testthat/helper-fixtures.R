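## In-code fixtures: tiny cohorts and temp-file writers.

makeTpm <- function(values, genes = NULL, samples = NULL, ...) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  TpmExperiment(m, ...)
}

## continuous response whose standardized ln IC50 equals a chosen z vector
makeContinuousResponse <- function(z, samples, drug = "drugX") {
  zc <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  DrugResponse(drug, samples, ic50 = exp(zc))
}

writeTsv <- function(lines, path = withr::local_tempfile(fileext = ".tsv",
                                                         .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

randomTpmCohort <- function(nGenes, nSamples, seed) {
  set.seed(seed)
  v <- matrix(10^rnorm(nGenes * nSamples, 1, 0.5) - 1, nGenes)
  v[v < 0] <- 0
  makeTpm(v)
}

## small planted cohort: 5 perfectly predictive genes among decoys
plantedCohort <- function(nDecoys = 50, n = 40, seed = 5, noise = 0) {
  set.seed(seed)
  z <- rnorm(n)
  samples <- sprintf("s%02d", 1:n)
  genes <- c(sprintf("sig%d", 1:5), sprintf("dec%02d", seq_len(nDecoys)))
  feat <- rbind(t(sapply(1:5, function(i) 1.5 + z + rnorm(n, sd = noise))),
                matrix(rnorm(nDecoys * n, 1.5, 1), nDecoys))
  x <- makeTpm(pmax(10^feat - 1, 0), genes = genes, samples = samples)
  r <- makeContinuousResponse(z, samples)
  list(x = x, r = r, ranked = genes)
}

## hand-built marker over an already-standardized identity feature space
makeMarker <- function(trainX, trainY, k, task = "regression",
                       genes = colnames(trainX)) {
  if (is.null(rownames(trainX))) rownames(trainX) <- sprintf("t%d", seq_len(nrow(trainX)))
  new("DigitalMarker", cancerType = "t", drug = "d", genes = genes,
      k0 = as.integer(k), task = task, trainX = trainX,
      trainY = trainY, geneCenter = setNames(rep(0, ncol(trainX)), genes),
      geneScale = setNames(rep(1, ncol(trainX)), genes),
      cvAuc = NA_real_, zThreshold = -1)
}

## TPM whose log10(1+TPM) equals the wanted feature value
asTpm <- function(feat) 10^feat - 1

`%||%` <- function(a, b) if (is.null(a)) b else a
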