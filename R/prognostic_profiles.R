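#' Thresholded prognostic score
#'
#' `log2(pooled HR)` when the meta-analytic p-value is below `alpha`
#' (strict), 0 otherwise. Zeros mean "no significant prognostic association",
#' a real value on the score scale — not missing data.
#'
#' @param meta A `MetaResult` from [meta_aggregate()].
#' @param alpha Significance threshold.
#' @return Numeric scalar.
#' @export
prognostic_score <- function(meta, alpha = 0.05) {
  if (!is.finite(meta$pooled_hr) || meta$pooled_hr <= 0)
    stop("pooled hazard ratio must be positive")
  if (meta$p < alpha) log2(meta$pooled_hr) else 0
}

#' Variables x cancer-types prognostic score matrix
#'
#' @param metas List of `MetaResult`s (any order); each must carry
#'   `cancer_type` and `variable` labels.
#' @param alpha Significance threshold for [prognostic_score()].
#' @return A list with `scores` (variables x cancer types numeric matrix,
#'   NA where no meta-result exists for the cell) and `alpha`.
#' @export
prognostic_score_matrix <- function(metas, alpha = 0.05) {
  vars <- unique(vapply(metas, `[[`, character(1), "variable"))
  types <- unique(vapply(metas, `[[`, character(1), "cancer_type"))
  m <- matrix(NA_real_, length(vars), length(types),
              dimnames = list(vars, types))
  for (r in metas)
    m[r$variable, r$cancer_type] <- prognostic_score(r, alpha)
  list(scores = m, alpha = alpha)
}

#' Correlation between prognostic profiles across cancer types
#'
#' Pearson (or Spearman) correlation between each pair of variables' score
#' vectors over cancer types. Zero scores participate as real values; a
#' variable whose vector has zero variance (e.g. all zeros) has an undefined
#' correlation and its entries are reported as `NA`, never as 0.
#'
#' @param score_matrix Result of [prognostic_score_matrix()], or a bare
#'   variables x cancer-types matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return `list(correlations, n_types)`: a symmetric variables x variables
#'   matrix with unit diagonal where defined, and the number of cancer types
#'   jointly observed per pair.
#' @export
profile_correlations <- function(score_matrix, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- if (is.list(score_matrix)) score_matrix$scores else score_matrix
  if (ncol(m) < 3L) stop("need at least 3 cancer types")
  vars <- rownames(m)
  p <- length(vars)
  corr <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  n_types <- matrix(0L, p, p, dimnames = list(vars, vars))
  for (i in seq_len(p)) for (j in i:p) {
    ok <- is.finite(m[i, ]) & is.finite(m[j, ])
    n_types[i, j] <- n_types[j, i] <- sum(ok)
    if (sum(ok) < 3L) next
    xi <- m[i, ok]; xj <- m[j, ok]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    corr[i, j] <- corr[j, i] <- stats::cor(xi, xj, method = method)
  }
  list(correlations = corr, n_types = n_types)
}
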