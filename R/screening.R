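#' Filter configuration for gene screening
#'
#' Bundles the screening thresholds: mean log-expression cuts for the
#' cell-line and patient paths, the Pearson correlation cut against IC50
#' Z-scores, the IC50 extreme-tail fraction used by the Fisher discriminant
#' score, and the occurrence cut for stable-gene selection. Defaults are the
#' published values; all comparisons are strict.
#'
#' @param exprThresholdCell mean log10(1+TPM) cut, cell-line path (default 1).
#' @param exprThresholdPatient mean log10(TPM) cut, patient path (default 0).
#' @param corrThreshold Pearson correlation cut (default 0.25).
#' @param extremeFraction fraction of samples in each IC50 tail (default 0.15).
#' @param useAbsCorrelation use |r| (default TRUE) or signed r.
#' @param occurrenceThreshold stable-gene occurrence cut (default 20, strict >).
#' @return A list with class \code{"FilterConfig"}.
#' @export
filterConfig <- function(exprThresholdCell = 1.0, exprThresholdPatient = 0.0,
                         corrThreshold = 0.25, extremeFraction = 0.15,
                         useAbsCorrelation = TRUE, occurrenceThreshold = 20L) {
  stopifnot(is.finite(exprThresholdCell), is.finite(exprThresholdPatient),
            is.finite(corrThreshold),
            extremeFraction > 0, extremeFraction <= 0.5)
  structure(list(exprThresholdCell = exprThresholdCell,
                 exprThresholdPatient = exprThresholdPatient,
                 corrThreshold = corrThreshold,
                 extremeFraction = extremeFraction,
                 useAbsCorrelation = useAbsCorrelation,
                 occurrenceThreshold = occurrenceThreshold),
            class = "FilterConfig")
}

#' Expression-level gene filter
#'
#' Retains genes whose mean transformed expression across all samples
#' strictly exceeds the threshold. Cell lines use log10(1+TPM)
#' (\code{pseudo = 1}); patient cohorts use log10(TPM) (\code{pseudo = 0}),
#' where any zero TPM makes the gene fail the filter (its mean log would be
#' -Inf).
#'
#' @param x a [TpmExperiment-class].
#' @param threshold strict lower cut on the mean transformed expression.
#' @param pseudo pseudo-count inside the log: 1 (cell lines) or 0 (patients).
#' @return Character vector of retained gene identifiers.
#' @export
filterByExpression <- function(x, threshold = 1.0, pseudo = 1) {
  stopifnot(pseudo %in% c(0, 1))
  v <- tpm(x)
  m <- rowMeans(log10(v + pseudo))
  rownames(v)[is.finite(m) & m > threshold]
}

#' Correlation gene filter
#'
#' Retains genes whose Pearson correlation between TPM and the cohort's IC50
#' Z-scores strictly exceeds the threshold (|r| by default; signed r
#' optionally). Samples are inner-joined between expression and response;
#' zero-variance genes are excluded (their correlation is undefined).
#'
#' @param x a [TpmExperiment-class].
#' @param r a continuous-mode [DrugResponse-class].
#' @param threshold strict correlation cut (default 0.25).
#' @param useAbs compare |r| (default) or signed r against the threshold.
#' @return Character vector of retained gene identifiers.
#' @export
filterByCorrelation <- function(x, r, threshold = 0.25, useAbs = TRUE) {
  if (responseMode(r) != "continuous")
    stop("correlation filter requires a continuous-mode response")
  common <- intersect(colnames(x), r@samples)
  if (length(common) < 3) stop("need at least 3 overlapping samples")
  v <- tpm(x)[, common, drop = FALSE]
  z <- zScores(r)[common]
  cors <- suppressWarnings(as.vector(stats::cor(t(v), z)))  # NA for zero-variance genes
  stat <- if (useAbs) abs(cors) else cors
  rownames(v)[!is.na(stat) & stat > threshold]
}

#' Fisher linear discriminant score between IC50 extremes
#'
#' For each gene, compares log10(1+TPM) between the cell lines with the
#' lowest and highest fraction of IC50 Z-scores (tails of size
#' \code{max(2, floor(fraction * n))}; ties at the quantile boundary broken
#' by sample-ID order). The score is the univariate two-group Fisher
#' criterion |mu_high - mu_low| / sqrt(s2_high + s2_low) with unbiased group
#' variances. When both variances are zero the score is 0 for equal means
#' and +Inf (ranked first) otherwise.
#'
#' @param x a [TpmExperiment-class].
#' @param r a continuous-mode [DrugResponse-class].
#' @param extremeFraction tail fraction of the cohort (default 0.15).
#' @param genes optional gene subset to score (defaults to all).
#' @return Named numeric vector of scores (larger = more discriminative).
#' @export
scoreFisherLD <- function(x, r, extremeFraction = 0.15, genes = NULL) {
  if (responseMode(r) != "continuous")
    stop("Fisher LD scoring requires a continuous-mode response")
  common <- intersect(colnames(x), r@samples)
  n <- length(common)
  if (n < 4) stop("need at least 4 overlapping samples")
  z <- zScores(r)[common]
  ord <- common[order(z, common)]
  nTail <- max(2L, floor(extremeFraction * n))
  low <- ord[seq_len(nTail)]                  # most sensitive (lowest IC50 z)
  high <- ord[seq.int(n - nTail + 1L, n)]
  v <- tpm(x)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  lo <- log10(1 + v[, low, drop = FALSE])
  hi <- log10(1 + v[, high, drop = FALSE])
  muL <- rowMeans(lo); muH <- rowMeans(hi)
  vL <- rowSums((lo - muL)^2) / (nTail - 1)
  vH <- rowSums((hi - muH)^2) / (nTail - 1)
  denom <- sqrt(vL + vH)
  score <- abs(muH - muL) / denom
  zero <- denom == 0
  score[zero & abs(muH - muL) == 0] <- 0
  score[zero & abs(muH - muL) > 0] <- Inf
  score
}

#' Mann-Whitney U score for labelled cohorts
#'
#' Scores each gene by -log10 of the two-sided Mann-Whitney U p-value
#' comparing TPM between the effective and ineffective groups. The exact
#' null distribution is used when the smaller group has at most 8 samples
#' and there are no ties; otherwise the normal approximation with tie
#' correction. Ranking by descending score equals ranking by ascending p.
#'
#' @param x a [TpmExperiment-class].
#' @param r a binary-mode [DrugResponse-class].
#' @param genes optional gene subset.
#' @return Named numeric vector of -log10(p) scores.
#' @export
scoreMannWhitney <- function(x, r, genes = NULL) {
  if (responseMode(r) != "binary")
    stop("Mann-Whitney scoring requires a binary-mode response")
  common <- intersect(colnames(x), r@samples)
  lab <- responseLabels(r)[common]
  g1 <- common[lab == "effective"]
  g2 <- common[lab == "ineffective"]
  if (length(g1) == 0 || length(g2) == 0)
    stop("both outcome classes must be non-empty")
  v <- tpm(x)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  p <- apply(v, 1, function(row) {
    a <- row[g1]; b <- row[g2]
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && min(length(a), length(b)) <= 8
    stats::wilcox.test(a, b, exact = exact, correct = !exact)$p.value
  })
  -log10(pmin(p, 1))
}

#' Combine per-dataset gene scores into a final ranking
#'
#' The gene universe is the intersection of the two filtered/scored sets.
#' With \code{mode = "sum"} raw scores are added; with
#' \code{mode = "rank_percentile_sum"} each dataset's scores are first mapped
#' to percentile ranks in (0, 1] (so cohorts with incommensurable score
#' scales contribute equally). The final rank is by descending combined
#' score, ties broken lexicographically by gene ID. A single-dataset table
#' can be passed as \code{b = NULL}, in which case the combined score equals
#' \code{a}.
#'
#' @param a,b named numeric score vectors restricted to filter-passing genes.
#' @param mode \code{"sum"} (default) or \code{"rank_percentile_sum"}.
#' @return A \code{data.frame} (gene, score_a, score_b, score_combined, rank)
#'   ordered by rank; ranks are a permutation of 1..N.
#' @export
synthesizeScores <- function(a, b = NULL, mode = c("sum", "rank_percentile_sum")) {
  mode <- match.arg(mode)
  if (is.null(b)) {
    genes <- names(a)
    sa <- a[genes]; sb <- rep(NA_real_, length(genes))
    combined <- unname(sa)
  } else {
    genes <- intersect(names(a), names(b))
    if (length(genes) == 0)
      stop("no genes pass the filters in both datasets; relax the thresholds")
    sa <- a[genes]; sb <- b[genes]
    if (mode == "rank_percentile_sum") {
      pct <- function(s) rank(s, ties.method = "average") / length(s)
      combined <- unname(pct(sa) + pct(sb))
    } else combined <- unname(sa + sb)
  }
  ord <- order(-combined, genes)
  out <- data.frame(gene = genes[ord], score_a = unname(sa)[ord],
                    score_b = if (is.null(b)) NA_real_ else unname(sb)[ord],
                    score_combined = combined[ord],
                    rank = seq_along(genes), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count gene occurrences across per-drug marker lists from two datasets
#'
#' Emulates the stable-gene selection used for wet-lab validation: genes
#' screened repeatedly across many drugs within a tissue are considered to
#' have stable predictive ability. A gene qualifies when its occurrence count
#' is strictly greater than the threshold in \emph{both} datasets.
#'
#' @param listsA,listsB named lists (drug -> character vector of screened
#'   genes) for the two datasets.
#' @param occurrenceThreshold strict lower cut on the per-dataset count
#'   (default 20).
#' @return \code{data.frame} (gene, count_a, count_b) of qualifying genes,
#'   ordered by decreasing total count then gene ID.
#' @export
countStableGenes <- function(listsA, listsB, occurrenceThreshold = 20L) {
  cnt <- function(lists) {
    tab <- table(unlist(lapply(lists, unique), use.names = FALSE))
    setNames(as.integer(tab), names(tab))
  }
  ca <- cnt(listsA); cb <- cnt(listsB)
  qa <- names(ca)[ca > occurrenceThreshold]
  qb <- names(cb)[cb > occurrenceThreshold]
  genes <- intersect(qa, qb)
  out <- data.frame(gene = genes, count_a = unname(ca[genes]),
                    count_b = unname(cb[genes]), stringsAsFactors = FALSE)
  out <- out[order(-(out$count_a + out$count_b), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen one continuous-response (cell-line) cohort
#'
#' Applies the expression filter (mean log10(1+TPM) > threshold), then the
#' correlation filter against IC50 Z-scores, then scores survivors with the
#' Fisher discriminant between IC50 extremes.
#'
#' @param x a [TpmExperiment-class].
#' @param r a continuous-mode [DrugResponse-class].
#' @param config a [filterConfig()].
#' @return List with \code{scores} (named vector over passing genes) and the
#'   per-stage gene sets \code{passedExpression}, \code{passedCorrelation}.
#' @export
screenCellLineCohort <- function(x, r, config = filterConfig()) {
  gExpr <- filterByExpression(x, config$exprThresholdCell, pseudo = 1)
  sub <- x[gExpr, , drop = FALSE]
  gCorr <- filterByCorrelation(sub, r, config$corrThreshold,
                               config$useAbsCorrelation)
  scores <- scoreFisherLD(x, r, config$extremeFraction, genes = gCorr)
  list(scores = scores, passedExpression = gExpr, passedCorrelation = gCorr)
}

#' Screen a paired two-dataset cell-line cohort
#'
#' Runs [screenCellLineCohort()] on each dataset separately (restricted to
#' the shared gene universe), then combines the two score tables with
#' [synthesizeScores()].
#'
#' @param pair a [CohortPair-class].
#' @param config a [filterConfig()].
#' @param mode synthesis mode, see [synthesizeScores()].
#' @return List with the combined \code{table} (GeneScoreTable data.frame
#'   with per-dataset filter flags), the \code{rankedGenes} character vector,
#'   and the two per-dataset screen results \code{a}, \code{b}.
#' @export
screenCellLinePair <- function(pair, config = filterConfig(), mode = "sum") {
  shared <- pair@sharedGenes
  xa <- pair@exprA[shared, , drop = FALSE]
  xb <- pair@exprB[shared, , drop = FALSE]
  sa <- screenCellLineCohort(xa, pair@respA, config)
  sb <- screenCellLineCohort(xb, pair@respB, config)
  tab <- synthesizeScores(sa$scores, sb$scores, mode = mode)
  tab$passed_expr_a <- tab$gene %in% sa$passedExpression
  tab$passed_expr_b <- tab$gene %in% sb$passedExpression
  tab$passed_corr_a <- tab$gene %in% sa$passedCorrelation
  tab$passed_corr_b <- tab$gene %in% sb$passedCorrelation
  list(table = tab, rankedGenes = tab$gene, a = sa, b = sb)
}

#' Screen a labelled patient cohort
#'
#' Applies the patient-path expression filter (mean log10(TPM) > threshold,
#' no pseudo-count) and scores survivors by -log10 Mann-Whitney p. Equal
#' p-values are broken by descending absolute difference of group medians,
#' then gene ID.
#'
#' @param x a [TpmExperiment-class].
#' @param r a binary-mode [DrugResponse-class].
#' @param config a [filterConfig()].
#' @return List with \code{table} (gene, score_a, score_combined, rank),
#'   \code{rankedGenes}, and \code{passedExpression}.
#' @export
screenPatientCohort <- function(x, r, config = filterConfig()) {
  gExpr <- filterByExpression(x, config$exprThresholdPatient, pseudo = 0)
  scores <- scoreMannWhitney(x, r, genes = gExpr)
  common <- intersect(colnames(x), r@samples)
  lab <- responseLabels(r)[common]
  v <- tpm(x)[gExpr, common, drop = FALSE]
  medDiff <- abs(apply(v[, lab == "effective", drop = FALSE], 1, stats::median) -
                 apply(v[, lab == "ineffective", drop = FALSE], 1, stats::median))
  ord <- order(-scores, -medDiff, gExpr)
  tab <- data.frame(gene = gExpr[ord], score_a = unname(scores)[ord],
                    score_b = NA_real_, score_combined = unname(scores)[ord],
                    rank = seq_along(gExpr), stringsAsFactors = FALSE)
  list(table = tab, rankedGenes = tab$gene, passedExpression = gExpr)
}
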