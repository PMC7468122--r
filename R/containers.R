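#' Focal gene panel
#'
#' The eight genes at the centre of the pipeline: the GLI transcription
#' factors, the three TGF-beta ligand genes and the three Hedgehog ligand
#' genes.
#'
#' @return Character vector of the eight gene symbols.
#' @export
focal_genes <- function() {
  c("GLI1", "GLI2", "TGFB1", "TGFB2", "TGFB3", "SHH", "IHH", "DHH")
}

#' Construct an expression dataset
#'
#' One study's genes x samples expression matrix, labelled with a dataset id,
#' a cancer-type label and a platform class. Platform `"counts"` means raw
#' non-negative integer counts (RNA-seq-like); `"array_log2"` means values
#' already on a log2 scale (microarray-like); `"log2_ready"` marks data that
#' have been through the log2 step and are ready for z-scoring and modelling.
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param dataset_id Character scalar.
#' @param cancer_type Character scalar.
#' @param platform One of `"array_log2"`, `"counts"`, `"log2_ready"`.
#' @return An `ExpressionDataset` object.
#' @export
expression_dataset <- function(values, dataset_id, cancer_type,
                               platform = c("array_log2", "counts", "log2_ready")) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in dataset ", dataset_id)
  if (platform == "counts") {
    if (any(values < 0) || any(values != round(values)))
      stop("platform 'counts' requires non-negative integer values")
  }
  structure(
    list(values = values,
         dataset_id = as.character(dataset_id),
         cancer_type = as.character(cancer_type),
         platform = platform),
    class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset '%s' (%s, %s): %d genes x %d samples\n",
              x$dataset_id, x$cancer_type, x$platform,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Construct a clinical (overall survival) table
#'
#' @param sample_id Character vector of sample ids.
#' @param os_time Positive overall-survival times (study time units).
#' @param os_event Event indicator: 1 = death observed, 0 = censored.
#' @return A data.frame of class `ClinicalTable` with columns
#'   `sample_id`, `os_time`, `os_event`.
#' @export
clinical_table <- function(sample_id, os_time, os_event) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in clinical table")
  if (any(!is.finite(os_time)) || any(os_time <= 0))
    stop("os_time must be positive and finite")
  if (!all(os_event %in% c(0, 1))) stop("os_event must be 0 or 1")
  df <- data.frame(sample_id = sample_id,
                   os_time = as.numeric(os_time),
                   os_event = as.integer(os_event),
                   stringsAsFactors = FALSE)
  class(df) <- c("ClinicalTable", "data.frame")
  df
}
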