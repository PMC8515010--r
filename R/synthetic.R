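#' Generator configuration for synthetic cohorts
#'
#' Defines the study conditions the simulators emulate: a paired pair of
#' cell-line cohorts with planted sensitivity-associated genes, a labelled
#' patient cohort, and qPCR readouts consistent with the linear dCq/TPM
#' calibration.
#'
#' Background log10(1+TPM) baselines are drawn per gene from
#' N(baseMean, baseSd); with the defaults (0.8, 0.6) roughly one third of
#' decoy genes pass the cell-line expression filter, mirroring the behaviour
#' of real transcriptomes under that cut. Signal genes get well-expressed
#' baselines (signalBaseMean) so the planted markers survive the expression
#' filter, and their effects alternate in sign to exercise both directions
#' of the correlation filter.
#'
#' @param nGenes total gene count (default 2000).
#' @param nSignalGenes planted sensitivity-associated genes (default 10).
#' @param nSamplesA,nSamplesB cohort sizes of the paired datasets (60/60).
#' @param nPatients patient cohort size (default 60).
#' @param effectSize log10-expression shift per unit latent z, or between
#'   outcome classes (default 1.5 * noiseSd).
#' @param noiseSd per-measurement log10-scale noise SD (default 0.3).
#' @param baseMean,baseSd background baseline distribution on log10(1+TPM).
#' @param signalBaseMean baseline mean for signal genes (default 2).
#' @param batchShift additive log10-scale offset applied to dataset B (0.2).
#' @param ic50CutUm effective/ineffective cut on IC50 in uM (default 100).
#' @param ic50MedianUm median IC50 of the simulated drug in uM (default 10).
#' @param ic50LogSd SD of ln IC50 around its median (default 1).
#' @param seed RNG seed; every generator is deterministic given it.
#' @return A list with class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(nGenes = 2000L, nSignalGenes = 10L,
                            nSamplesA = 60L, nSamplesB = 60L, nPatients = 60L,
                            noiseSd = 0.3, effectSize = 1.5 * noiseSd,
                            baseMean = 0.8, baseSd = 0.6, signalBaseMean = 2.0,
                            batchShift = 0.2, ic50CutUm = 100,
                            ic50MedianUm = 10, ic50LogSd = 1, seed = 1L) {
  stopifnot(nSignalGenes <= nGenes, noiseSd >= 0, nGenes >= 1,
            ic50CutUm > 0, ic50MedianUm > 0, ic50LogSd > 0)
  structure(as.list(environment()), class = "GeneratorConfig")
}

.geneNames <- function(cfg) sprintf("gene%04d", seq_len(cfg$nGenes))

## one cohort: latent z drives signal genes (alternating directions) and
## ln IC50, so standardized log IC50 recovers z exactly
.simCohort <- function(cfg, n, tag, shift, baselines, directions, cancerType) {
  z <- stats::rnorm(n)
  genes <- .geneNames(cfg)
  logExpr <- matrix(baselines, cfg$nGenes, n) +
    matrix(stats::rnorm(cfg$nGenes * n, sd = cfg$noiseSd), cfg$nGenes, n) + shift
  sig <- seq_len(cfg$nSignalGenes)
  logExpr[sig, ] <- logExpr[sig, ] +
    cfg$effectSize * outer(directions, z)
  v <- pmax(10^logExpr - 1, 0)
  dimnames(v) <- list(genes, sprintf("%s_s%03d", tag, seq_len(n)))
  x <- TpmExperiment(v, cancerType, tag)
  ic50 <- exp(cfg$ic50LogSd * z + log(cfg$ic50MedianUm))
  r <- DrugResponse("simdrug", colnames(v), ic50 = ic50)
  list(x = x, r = r, z = z)
}

#' Generate a paired cell-line cohort with planted signal
#'
#' Each sample carries a latent sensitivity z ~ N(0, 1); signal genes'
#' log10(1+TPM) shift by effectSize * z with alternating sign, decoys are
#' pure noise, and IC50 = exp(sd * z + ln median) so the standardized log
#' IC50 recovers z. Dataset B shares the signal genes and directions but
#' draws fresh samples and applies an additive log-scale batch shift.
#'
#' @param cfg a [generatorConfig()].
#' @return List: \code{pair} (a [CohortPair-class]) and \code{truth}
#'   (signal genes with their effect directions).
#' @export
generateCellLinePair <- function(cfg = generatorConfig()) {
  set.seed(cfg$seed)
  genes <- .geneNames(cfg)
  baselines <- stats::rnorm(cfg$nGenes, cfg$baseMean, cfg$baseSd)
  sig <- seq_len(cfg$nSignalGenes)
  baselines[sig] <- stats::rnorm(cfg$nSignalGenes, cfg$signalBaseMean,
                                 cfg$baseSd / 2)
  directions <- rep_len(c(1, -1), cfg$nSignalGenes)
  a <- .simCohort(cfg, cfg$nSamplesA, "cohortA", 0, baselines, directions, "simcancer")
  b <- .simCohort(cfg, cfg$nSamplesB, "cohortB", cfg$batchShift, baselines,
                  directions, "simcancer")
  list(pair = CohortPair(a$x, a$r, b$x, b$r),
       truth = data.frame(gene = genes[sig], direction = directions,
                          stringsAsFactors = FALSE))
}

#' Generate a labelled patient cohort with planted signal
#'
#' Outcomes are assigned first (balanced effective/ineffective by default);
#' signal genes shift between the classes by effectSize on the log10 scale
#' (alternating direction), decoys are noise around their baselines.
#'
#' @param cfg a [generatorConfig()].
#' @param balanced balance the two outcome classes (default TRUE).
#' @return List: \code{x} ([TpmExperiment-class]), \code{r} (binary
#'   [DrugResponse-class]) and \code{truth}.
#' @export
generatePatientCohort <- function(cfg = generatorConfig(), balanced = TRUE) {
  set.seed(cfg$seed + 1L)
  n <- cfg$nPatients
  nEff <- if (balanced) n %/% 2 else stats::rbinom(1, n, 0.5)
  if (nEff < 2 || n - nEff < 2) stop("each outcome class needs at least 2 patients")
  label <- sample(rep(c("effective", "ineffective"), c(nEff, n - nEff)))
  genes <- .geneNames(cfg)
  baselines <- stats::rnorm(cfg$nGenes, cfg$baseMean, cfg$baseSd)
  sig <- seq_len(cfg$nSignalGenes)
  baselines[sig] <- stats::rnorm(cfg$nSignalGenes, cfg$signalBaseMean,
                                 cfg$baseSd / 2)
  directions <- rep_len(c(1, -1), cfg$nSignalGenes)
  logExpr <- matrix(baselines, cfg$nGenes, n) +
    matrix(stats::rnorm(cfg$nGenes * n, sd = cfg$noiseSd), cfg$nGenes, n)
  eff <- label == "effective"
  logExpr[sig, eff] <- logExpr[sig, eff] + cfg$effectSize * directions
  v <- pmax(10^logExpr - 1, 0)
  dimnames(v) <- list(genes, sprintf("patient_%03d", seq_len(n)))
  list(x = TpmExperiment(v, "simcancer", "patients"),
       r = DrugResponse("simdrug", colnames(v), label = label),
       truth = data.frame(gene = genes[sig], direction = directions,
                          stringsAsFactors = FALSE))
}

#' Generate a qPCR Cq table consistent with a conversion model
#'
#' Inverts the dCq/TPM calibration: Cq_gene = Cq_reference + tpmToDcq(TPM)
#' + Gaussian noise, with the reference gene fixed at a constant cycle
#' count. With zero noise, converting the dCq values back reproduces the
#' input TPM (up to the floor at 0).
#'
#' @param x a [TpmExperiment-class] providing the TPM values.
#' @param model a [ConversionModel-class] (slope < 0).
#' @param cqNoiseSd per-measurement Cq noise SD (cycles; default 0).
#' @param referenceCq constant reference-gene cycle count (default 20).
#' @param seed RNG seed used when cqNoiseSd > 0.
#' @return A [CqTable-class] over x's genes plus the reference gene.
#' @export
generateQpcrReadout <- function(x, model = ConversionModel(), cqNoiseSd = 0,
                                referenceCq = 20, seed = 1L) {
  v <- tpm(x)
  dcq <- matrix(tpmToDcq(as.vector(v), model), nrow = nrow(v))
  cq <- t(referenceCq + dcq)           # samples x genes
  if (cqNoiseSd > 0) {
    set.seed(seed)
    cq <- cq + matrix(stats::rnorm(length(cq), sd = cqNoiseSd), nrow(cq))
  }
  dimnames(cq) <- list(colnames(v), rownames(v))
  cq <- cbind(cq, matrix(referenceCq, nrow(cq), 1,
                         dimnames = list(NULL, model@referenceGene)))
  CqTable(cq, model@referenceGene)
}
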