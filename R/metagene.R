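#' Metagene score: mean zero-centred expression of signature genes
#'
#' Each signature gene measured in the dataset is centred to zero mean across
#' samples (no variance scaling); the score is the per-sample mean over those
#' genes. Signature genes absent from the dataset are excluded with a logged
#' count. By construction the scores have zero mean across samples.
#'
#' @param dataset A log2-ready [expression_dataset()] (centring makes the
#'   result invariant to per-gene offsets, so z-scored input works too).
#' @param genes Character vector of signature gene symbols (no duplicates).
#' @param name Signature name carried into the result.
#' @param scale_genes Also divide each centred gene by its SD before
#'   averaging (off by default: the standard score is centring only).
#' @return `list(dataset_id, signature, scores (named per sample),
#'   n_genes_used, genes_used)`.
#' @export
compute_metagene <- function(dataset, genes, name = "metagene",
                             scale_genes = FALSE) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (anyDuplicated(genes)) stop("duplicate symbols in signature '", name, "'")
  measured <- intersect(genes, rownames(dataset$values))
  if (length(measured) == 0L)
    stop("no gene of signature '", name, "' is measured in dataset ",
         dataset$dataset_id)
  n_absent <- length(genes) - length(measured)
  if (n_absent > 0L)
    message(n_absent, " signature gene(s) of '", name,
            "' not measured in dataset ", dataset$dataset_id)
  v <- dataset$values[measured, , drop = FALSE]
  centred <- v - rowMeans(v)
  if (scale_genes) {
    sdv <- apply(v, 1, stats::sd)
    centred <- centred[sdv > 0, , drop = FALSE] / sdv[sdv > 0]
  }
  scores <- colMeans(centred)
  list(dataset_id = dataset$dataset_id, signature = name,
       scores = scores, n_genes_used = nrow(centred), genes_used = measured)
}

#' Metagene scores for several signatures at once
#'
#' @inheritParams compute_metagene
#' @param signatures Named list of gene vectors.
#' @return Named list of [compute_metagene()] results.
#' @export
compute_metagenes <- function(dataset, signatures, scale_genes = FALSE) {
  out <- lapply(names(signatures), function(nm)
    compute_metagene(dataset, signatures[[nm]], nm, scale_genes))
  stats::setNames(out, names(signatures))
}
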