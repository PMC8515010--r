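#' Serialize a DigitalMarker to JSON
#'
#' Writes every component needed to reproduce predictions exactly: the
#' ordered gene list, k0, task, per-gene standardization statistics, the
#' standardized training matrix and targets, the achieved CV AUC and the
#' Z threshold. [readMarker()] restores an equivalent object.
#'
#' @param marker a [DigitalMarker-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMarker <- function(marker, path) {
  obj <- list(
    cancer_type = marker@cancerType, drug = marker@drug,
    genes = marker@genes, k0 = marker@k0, task = marker@task,
    gene_center = marker@geneCenter, gene_scale = marker@geneScale,
    train_x = marker@trainX, train_samples = rownames(marker@trainX),
    train_y = marker@trainY, cv_auc = marker@cvAuc,
    z_threshold = marker@zThreshold)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a DigitalMarker from JSON
#' @param path path written by [writeMarker()].
#' @return A [DigitalMarker-class].
#' @export
readMarker <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  trainX <- as.matrix(o$train_x)
  dimnames(trainX) <- list(o$train_samples, o$genes)
  new("DigitalMarker", cancerType = o$cancer_type, drug = o$drug,
      genes = o$genes, k0 = as.integer(o$k0), task = o$task,
      trainX = trainX, trainY = as.numeric(o$train_y),
      geneCenter = setNames(as.numeric(o$gene_center), o$genes),
      geneScale = setNames(as.numeric(o$gene_scale), o$genes),
      cvAuc = as.numeric(o$cv_auc), zThreshold = as.numeric(o$z_threshold))
}

#' Serialize an EvalReport to JSON (ROC points inline)
#' @param report an \code{"EvalReport"} from [classificationMetrics()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
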