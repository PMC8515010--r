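#' Accessors for the core classes
#'
#' \code{tpm} returns the TPM assay matrix; \code{cancerType} and
#' \code{datasetTag} the cohort annotations; \code{responseMode},
#' \code{zScores}, \code{ic50} and \code{responseLabels} the drug-response
#' content; \code{markerGenes}, \code{neighborCount} and \code{cvAuc} the
#' frozen predictor's components.
#'
#' @param x an object of the documented class.
#' @return The slot content (see Description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))
#' @rdname accessors
#' @export
setMethod("tpm", "TpmExperiment", function(x) assay(x, "tpm"))

#' @rdname accessors
#' @export
setGeneric("cancerType", function(x) standardGeneric("cancerType"))
#' @rdname accessors
#' @export
setMethod("cancerType", "TpmExperiment", function(x) x@cancerType)

#' @rdname accessors
#' @export
setGeneric("datasetTag", function(x) standardGeneric("datasetTag"))
#' @rdname accessors
#' @export
setMethod("datasetTag", "TpmExperiment", function(x) x@datasetTag)

#' @rdname accessors
#' @export
setGeneric("responseMode", function(x) standardGeneric("responseMode"))
#' @rdname accessors
#' @export
setMethod("responseMode", "DrugResponse", function(x) x@mode)

#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setMethod("zScores", "DrugResponse", function(x) {
  if (length(x@z) == 0) return(numeric(0))
  setNames(x@z, x@samples)
})

#' @rdname accessors
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))
#' @rdname accessors
#' @export
setMethod("ic50", "DrugResponse", function(x) {
  if (length(x@ic50) == 0) return(numeric(0))
  setNames(x@ic50, x@samples)
})

#' @rdname accessors
#' @export
setGeneric("responseLabels", function(x) standardGeneric("responseLabels"))
#' @rdname accessors
#' @export
setMethod("responseLabels", "DrugResponse", function(x) setNames(x@label, x@samples))

#' @rdname accessors
#' @export
setGeneric("drugName", function(x) standardGeneric("drugName"))
#' @rdname accessors
#' @export
setMethod("drugName", "DrugResponse", function(x) x@drug)
#' @rdname accessors
#' @export
setMethod("drugName", "DigitalMarker", function(x) x@drug)

#' @rdname accessors
#' @export
setGeneric("markerGenes", function(x) standardGeneric("markerGenes"))
#' @rdname accessors
#' @export
setMethod("markerGenes", "DigitalMarker", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("neighborCount", function(x) standardGeneric("neighborCount"))
#' @rdname accessors
#' @export
setMethod("neighborCount", "DigitalMarker", function(x) x@k0)

#' @rdname accessors
#' @export
setGeneric("cvAuc", function(x) standardGeneric("cvAuc"))
#' @rdname accessors
#' @export
setMethod("cvAuc", "DigitalMarker", function(x) x@cvAuc)

setMethod("show", "TpmExperiment", function(object) {
  cat(sprintf("TpmExperiment: %d genes x %d samples (%s, %s)\n",
              nrow(object), ncol(object), object@cancerType, object@datasetTag))
})

setMethod("show", "DrugResponse", function(object) {
  cat(sprintf("DrugResponse: drug '%s', %d samples, mode %s\n",
              object@drug, length(object@samples), object@mode))
  if (object@mode == "binary") {
    tab <- table(factor(object@label, c("effective", "ineffective")))
    cat(sprintf("  effective: %d, ineffective: %d\n", tab[1], tab[2]))
  }
})

setMethod("show", "CqTable", function(object) {
  cat(sprintf("CqTable: %d samples x %d genes, reference gene '%s'\n",
              length(object@samples), length(object@genes), object@referenceGene))
})

setMethod("show", "CohortPair", function(object) {
  cat(sprintf("CohortPair for drug '%s' (%s):\n", object@respA@drug,
              object@exprA@cancerType))
  cat(sprintf("  A: %s (%d samples)  B: %s (%d samples)  shared genes: %d\n",
              object@exprA@datasetTag, ncol(object@exprA),
              object@exprB@datasetTag, ncol(object@exprB),
              length(object@sharedGenes)))
})

setMethod("show", "DigitalMarker", function(object) {
  cat(sprintf("DigitalMarker (%s, %s): m0 = %d genes, k0 = %d, task = %s\n",
              object@cancerType, object@drug, length(object@genes),
              object@k0, object@task))
  cat(sprintf("  CV AUC = %.3f; genes: %s%s\n", object@cvAuc,
              paste(head(object@genes, 6), collapse = ", "),
              if (length(object@genes) > 6) ", ..." else ""))
})

setMethod("show", "ConversionModel", function(object) {
  cat(sprintf("ConversionModel: log10(TPM+1) = %.4f * dCq + %.4f (ref %s%s)\n",
              object@slope, object@intercept, object@referenceGene,
              if (is.finite(object@fitR2)) sprintf(", R2 = %.4f", object@fitR2) else ""))
})
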