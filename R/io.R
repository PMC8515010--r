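## Delimited-text readers/writers. TSV is the default; the delimiter is
## auto-detected between tab and comma from the header line. IDs are opaque
## strings (no case folding); decimal separator is ".".

.naTokens <- c("NA", "NaN", "na", "")

.detectSep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read a gene-by-sample TPM matrix from delimited text
#'
#' Expects a header row of sample identifiers and a leading gene-identifier
#' column. Duplicate gene rows are collapsed by their mean (with a warning);
#' genes with any missing value are dropped (count reported via message).
#'
#' @param path file path (TSV or CSV; auto-detected unless \code{sep} given).
#' @param cancerType,datasetTag cohort annotations stored on the result.
#' @param sep optional field separator override.
#' @return A [TpmExperiment-class].
#' @export
loadExpression <- function(path, cancerType = "unspecified",
                           datasetTag = "unspecified", sep = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- .detectSep(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected a gene-ID column plus sample columns")
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  isNa <- is.na(body) | body %in% .naTokens
  num <- suppressWarnings(as.numeric(body))
  bad <- which(is.na(num) & !isNa)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(body)) + 1
    j <- ((bad[1] - 1) %/% nrow(body)) + 1
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 body[i, j], genes[i], samples[j]))
  }
  values <- matrix(num, nrow = nrow(body), dimnames = list(NULL, samples))
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning(sprintf("%d duplicated gene identifier(s) collapsed by mean: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    values <- rowsum(values, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
  }
  rownames(values) <- genes
  keep <- rowSums(is.na(values)) == 0
  if (any(!keep))
    message(sprintf("dropped %d gene(s) with missing values", sum(!keep)))
  TpmExperiment(values[keep, , drop = FALSE], cancerType, datasetTag)
}

#' Write a TpmExperiment back to delimited text
#'
#' Values are written with full (round-trippable) precision so that
#' \code{loadExpression(writeExpression(x))} reproduces the matrix exactly.
#'
#' @param x a [TpmExperiment-class].
#' @param path output path.
#' @param sep field separator (tab default).
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, sep = "\t") {
  v <- tpm(x)
  header <- paste(c("gene", colnames(v)), collapse = sep)
  rows <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a per-sample drug-response table
#'
#' Continuous mode expects columns \code{sample, ic50[, z]}; when \code{z} is
#' absent it is computed as the standardized log IC50 over the loaded samples
#' (population SD). Binary mode expects \code{sample, label} with label
#' strings mapped onto effective/ineffective.
#'
#' @param path file path.
#' @param drug drug name stored on the result.
#' @param mode \code{"continuous"} or \code{"binary"}.
#' @param labelMap named character vector mapping file label strings to
#'   \code{"effective"}/\code{"ineffective"}.
#' @param logFun log scale for Z standardization ("ln" default, "log10", "none").
#' @param sep optional separator override.
#' @return A [DrugResponse-class].
#' @export
loadResponse <- function(path, drug, mode = c("continuous", "binary"),
                         labelMap = c(effective = "effective",
                                      ineffective = "ineffective"),
                         logFun = "ln", sep = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("response file not found: ", path)
  sep <- .detectSep(path, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(tab[[1]])
  if (mode == "binary") {
    lab <- as.character(tab[[2]])
    unknown <- setdiff(unique(lab), names(labelMap))
    if (length(unknown))
      stop("unknown label value(s): ", paste(unknown, collapse = ", "),
           "; accepted: ", paste(names(labelMap), collapse = ", "))
    return(DrugResponse(drug, samples, label = unname(labelMap[lab])))
  }
  ic <- as.numeric(tab[[2]])
  if (any(!is.finite(ic)) || any(ic <= 0)) stop("ic50 must be finite and > 0")
  z <- if (ncol(tab) >= 3) as.numeric(tab[[3]]) else NULL
  DrugResponse(drug, samples, ic50 = ic, z = z, logFun = logFun)
}

#' Read a sample-by-gene qRT-PCR Cq table
#'
#' Technical-replicate columns named \code{<gene><suffix>} (default suffix
#' pattern \code{"_<digits>"}) are averaged into one column per gene before
#' any delta-Cq computation.
#'
#' @param path file path; first column sample IDs, remaining columns Cq values.
#' @param referenceGene housekeeping gene that must be present.
#' @param replicateSuffix regular expression stripped from column names to
#'   group technical replicates; NULL disables collapsing.
#' @param sep optional separator override.
#' @return A [CqTable-class].
#' @export
loadCq <- function(path, referenceGene = "GAPDH",
                   replicateSuffix = "_[0-9]+$", sep = NULL) {
  if (!file.exists(path)) stop("Cq file not found: ", path)
  sep <- .detectSep(path, sep)
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(tab[[1]])
  cq <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(cq) <- "double"
  genes <- colnames(cq)
  if (!is.null(replicateSuffix)) {
    base <- sub(replicateSuffix, "", genes)
    if (anyDuplicated(base) || !identical(base, genes)) {
      cq <- t(rowsum(t(cq), group = base, reorder = FALSE)) /
        rep(as.vector(table(factor(base, levels = unique(base)))),
            each = nrow(cq))
      colnames(cq) <- unique(base)
    }
  }
  if (!referenceGene %in% colnames(cq))
    stop(sprintf("reference gene '%s' missing from Cq table", referenceGene))
  rownames(cq) <- samples
  CqTable(cq, referenceGene)
}

#' Write a gene score table as TSV
#' @param scores data.frame as returned by [synthesizeScores()] or the
#'   screening drivers.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneScores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
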