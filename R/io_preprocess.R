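#' Upper-quartile normalization of a count dataset
#'
#' Per-sample scaling by the 75th percentile of that sample's counts,
#' restricted to genes with nonzero counts in the sample (robust to zero
#' inflation). Scaled values are multiplied by the mean scale factor across
#' samples so the overall magnitude of the matrix is preserved.
#'
#' @param dataset An [expression_dataset()] with platform `"counts"`.
#' @param quantile_type Quantile convention passed to [stats::quantile()];
#'   7 (linear interpolation, the usual numerical-stack default) or 1
#'   (nearest rank / inverse ECDF).
#' @return The dataset with normalized (no longer integer) values; platform
#'   stays `"counts"` with an attribute `normalized = TRUE`.
#' @export
upper_quartile_normalize <- function(dataset, quantile_type = 7) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (dataset$platform != "counts")
    stop("upper_quartile_normalize expects platform 'counts'")
  v <- dataset$values
  factors <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    nz <- x[x > 0]
    if (length(nz) == 0L)
      stop("sample '", colnames(v)[j], "' has all-zero counts")
    stats::quantile(nz, probs = 0.75, type = quantile_type, names = FALSE)
  }, numeric(1))
  scaled <- sweep(v, 2, factors, "/") * mean(factors)
  out <- dataset
  out$values <- scaled
  attr(out, "normalized") <- TRUE
  out
}

#' Log2 transformation
#'
#' Elementwise `log2(value + offset)` for count data; array data already on a
#' log2 scale pass through unchanged. Either way the platform is relabelled
#' `"log2_ready"`.
#'
#' @param dataset An [expression_dataset()].
#' @param offset Pseudocount added before the log; default 1 for counts,
#'   ignored for array data.
#' @return The dataset on log2 scale, platform `"log2_ready"`.
#' @export
log2_transform <- function(dataset, offset = 1) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  out <- dataset
  if (dataset$platform %in% c("array_log2", "log2_ready")) {
    out$platform <- "log2_ready"
    return(out)
  }
  if (any(dataset$values + offset <= 0))
    stop("non-positive values after offset; cannot log2-transform")
  out$values <- log2(dataset$values + offset)
  out$platform <- "log2_ready"
  out
}

#' Aggregate probe-level rows to gene symbols
#'
#' Rows sharing a symbol are collapsed to their per-sample arithmetic mean
#' (default) or the single probe of maximal variance. Probes without a
#' mapping are dropped, with the count reported via message.
#'
#' @param dataset An [expression_dataset()].
#' @param probe_map Named character vector: names are probe ids (matching the
#'   dataset rownames), values are gene symbols.
#' @param method `"mean"` (default) or `"max_variance"`.
#' @return The dataset with unique symbol rownames.
#' @export
aggregate_by_symbol <- function(dataset, probe_map, method = c("mean", "max_variance")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  method <- match.arg(method)
  probes <- rownames(dataset$values)
  mapped <- intersect(probes, names(probe_map))
  if (length(mapped) == 0L)
    stop("no probe in the dataset is present in the probe map")
  n_dropped <- length(probes) - length(mapped)
  if (n_dropped > 0L)
    message(n_dropped, " unmapped probe(s) dropped from dataset ", dataset$dataset_id)
  v <- dataset$values[mapped, , drop = FALSE]
  sym <- unname(probe_map[mapped])
  if (method == "mean") {
    agg <- rowsum(v, group = sym, reorder = TRUE)
    counts <- as.vector(table(sym)[rownames(agg)])
    agg <- agg / counts
  } else {
    vars <- apply(v, 1, stats::var)
    keep <- vapply(split(seq_along(sym), sym), function(idx) {
      idx[which.max(vars[idx])]
    }, integer(1))
    agg <- v[keep, , drop = FALSE]
    rownames(agg) <- names(keep)
  }
  out <- dataset
  out$values <- agg
  out
}

#' Z-score each gene across samples within a dataset
#'
#' Per gene: subtract the mean and divide by the sample standard deviation
#' (n - 1 denominator). Genes with zero variance have an undefined z-score;
#' they are removed from the returned matrix and reported in the mask so
#' downstream models never see them.
#'
#' @param dataset An [expression_dataset()] with platform `"log2_ready"`.
#' @return A list with elements `dataset` (z-scored, platform `"log2_ready"`)
#'   and `dropped` (character vector of zero-variance gene symbols).
#' @export
zscore_within_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (dataset$platform != "log2_ready")
    stop("zscore_within_dataset expects platform 'log2_ready' (run log2_transform first)")
  if (ncol(dataset$values) < 3L)
    stop("need at least 3 samples to z-score dataset ", dataset$dataset_id)
  v <- dataset$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  dropped <- rownames(v)[sdv == 0 | !is.finite(sdv)]
  keep <- setdiff(rownames(v), dropped)
  z <- (v[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  out <- dataset
  out$values <- z
  attr(out, "zscored") <- TRUE
  list(dataset = out, dropped = dropped)
}

#' Standard pre-treatment for one dataset
#'
#' Applies the fixed pipeline order: for counts, upper-quartile -> log2 ->
#' (aggregate) -> z-score; for array data, (aggregate) -> z-score.
#'
#' @inheritParams zscore_within_dataset
#' @param probe_map Optional probe -> symbol map; skipped when `NULL`
#'   (rownames already symbols).
#' @param offset log2 pseudocount for counts.
#' @return As [zscore_within_dataset()].
#' @export
preprocess_dataset <- function(dataset, probe_map = NULL, offset = 1) {
  if (dataset$platform == "counts")
    dataset <- upper_quartile_normalize(dataset)
  dataset <- log2_transform(dataset, offset = offset)
  if (!is.null(probe_map))
    dataset <- aggregate_by_symbol(dataset, probe_map)
  zscore_within_dataset(dataset)
}

## ---- readers / writers ----------------------------------------------------

#' Read / write an expression matrix as TSV
#'
#' Layout: first column `gene`, remaining columns one per sample. Missing
#' values are encoded as `NA`.
#'
#' @param path File path.
#' @param dataset_id,cancer_type,platform Metadata for the returned object.
#' @return An [expression_dataset()].
#' @export
read_expression_tsv <- function(path, dataset_id, cancer_type, platform) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  expression_dataset(m, dataset_id, cancer_type, platform)
}

#' @rdname read_expression_tsv
#' @param dataset The dataset to write.
#' @export
write_expression_tsv <- function(dataset, path) {
  df <- data.frame(gene = rownames(dataset$values),
                   dataset$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table as TSV
#'
#' Columns: `sample_id`, `os_time`, `os_event`.
#'
#' @param path File path.
#' @return A [clinical_table()].
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  clinical_table(df$sample_id, df$os_time, df$os_event)
}

#' @rdname read_clinical_tsv
#' @param clinical The table to write.
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(as.data.frame(clinical), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene signature
#'
#' Accepts either GMT (tab-separated: name, description, genes...) or plain
#' one-symbol-per-line text (signature name taken from the file name).
#'
#' @param path File path.
#' @return A named list of character vectors (signature name -> genes).
#' @export
read_signatures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (any(grepl("\t", lines))) {
    sigs <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
    names(sigs) <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1L)
    sigs
  } else {
    sig <- list(unique(trimws(lines)))
    names(sig) <- sub("\\.[^.]*$", "", basename(path))
    sig
  }
}
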