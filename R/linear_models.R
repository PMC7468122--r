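zscore_vec <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant variable")
  (x - mean(x)) / s
}

# Minimum-norm least squares via SVD pseudo-inverse; returns coefficients and
# whether the design was rank-deficient. Deterministic and order-independent,
# unlike predictor dropping.
min_norm_ls <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  pos <- sv$d > tol * sv$d[1]
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  list(beta = as.vector(beta), rank_deficient = any(!pos))
}

ols_standardized <- function(Z, y, kind, dataset_id, metagene_name) {
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, Z)
  fit <- min_norm_ls(X, y)
  if (fit$rank_deficient)
    warning("collinear predictors in dataset ", dataset_id,
            " (", kind, ", ", metagene_name, "); minimum-norm solution used")
  beta <- stats::setNames(fit$beta, colnames(X))
  fitted <- as.vector(X %*% fit$beta)
  fc <- if (stats::sd(fitted) > 0) stats::cor(fitted, y) else NA_real_
  list(dataset_id = dataset_id, metagene = metagene_name, kind = kind,
       coefficients = beta[-1], intercept = unname(beta[1]),
       fit_correlation = fc, n_samples = n)
}

#' Full eight-gene linear model of a metagene
#'
#' Ordinary least squares of the z-scored metagene on the z-scored focal
#' genes (intercept included; it is 0 by construction). Coefficients are in
#' SD units; the goodness of fit is recorded as the Pearson correlation
#' between in-sample fitted values and the observed z-scored metagene
#' (its square equals the model R^2).
#'
#' Collinear designs are fitted by minimum-norm least squares with a warning
#' rather than dropping predictors.
#'
#' @param dataset A z-scored [expression_dataset()].
#' @param metagene A [compute_metagene()] result (scores aligned to the
#'   dataset's samples).
#' @param predictors Predictor gene symbols; default the eight focal genes.
#'   All must be present and non-constant, otherwise `NULL` is returned with
#'   a warning (dataset skipped for this model).
#' @return A `LinearModelResult` list (`coefficients`, `fit_correlation`,
#'   `n_samples`, ...), or `NULL` when skipped.
#' @export
fit_full_model <- function(dataset, metagene, predictors = focal_genes()) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  v <- dataset$values
  if (ncol(v) <= 10L) stop("need more than 10 samples to fit")
  if (!all(predictors %in% rownames(v)) ||
      any(apply(v[predictors, , drop = FALSE], 1, stats::sd) == 0)) {
    warning("missing or constant predictor gene(s) in dataset ",
            dataset$dataset_id, "; model skipped")
    return(NULL)
  }
  scores <- metagene$scores[colnames(v)]
  Z <- t(apply(v[predictors, , drop = FALSE], 1, zscore_vec))
  res <- ols_standardized(t(Z), zscore_vec(scores), "full_8gene",
                          dataset$dataset_id, metagene$signature)
  res$cancer_type <- dataset$cancer_type
  res
}

#' Grouped (compound-variable) linear model of a metagene
#'
#' Each group's compound variable is the mean of its member genes' z-scores,
#' re-standardized to unit SD; the z-scored metagene is regressed on the
#' compounds by OLS. Default groups: GLI = \{GLI1, GLI2\},
#' HH = \{SHH, IHH, DHH\}, TGFB = \{TGFB1, TGFB2, TGFB3\}.
#'
#' @inheritParams fit_full_model
#' @param groups Named list of gene vectors.
#' @return A `LinearModelResult` list with one coefficient per group.
#' @export
fit_group_model <- function(dataset, metagene,
                            groups = list(GLI = c("GLI1", "GLI2"),
                                          HH = c("SHH", "IHH", "DHH"),
                                          TGFB = c("TGFB1", "TGFB2", "TGFB3"))) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  v <- dataset$values
  if (ncol(v) <= 10L) stop("need more than 10 samples to fit")
  comp <- vapply(names(groups), function(g) {
    members <- intersect(groups[[g]], rownames(v))
    if (length(members))
      members <- members[apply(v[members, , drop = FALSE], 1, stats::sd) > 0]
    if (length(members) == 0L)
      stop("group '", g, "' has no measured non-constant gene in dataset ",
           dataset$dataset_id)
    zs <- t(apply(v[members, , drop = FALSE], 1, zscore_vec))
    if (length(members) == 1L) zs <- matrix(zs, nrow = 1)
    zscore_vec(colMeans(zs))
  }, numeric(ncol(v)))
  scores <- metagene$scores[colnames(v)]
  res <- ols_standardized(comp, zscore_vec(scores), "grouped_3var",
                          dataset$dataset_id, metagene$signature)
  res$cancer_type <- dataset$cancer_type
  res
}

#' Aggregate linear-model results by cancer type
#'
#' Unweighted arithmetic mean of coefficients and of fit correlations across
#' the datasets of each (cancer type, metagene, model kind) group.
#'
#' @param results List of `LinearModelResult`s (NULLs from skipped fits are
#'   tolerated and removed).
#' @return A long-format data.frame, one row per
#'   (cancer_type, metagene, kind, predictor), with the unweighted
#'   `mean_coefficient`, the group's `mean_fit_correlation` and `n_datasets`.
#' @export
aggregate_models <- function(results) {
  results <- Filter(Negate(is.null), results)
  if (length(results) == 0L) stop("no model results to aggregate")
  key <- vapply(results, function(r)
    paste(r$cancer_type, r$metagene, r$kind, sep = "\r"), character(1))
  rows <- lapply(split(results, key), function(rs) {
    co <- do.call(rbind, lapply(rs, `[[`, "coefficients"))
    data.frame(cancer_type = rs[[1]]$cancer_type,
               metagene = rs[[1]]$metagene,
               kind = rs[[1]]$kind,
               predictor = colnames(co),
               mean_coefficient = unname(colMeans(co)),
               mean_fit_correlation =
                 mean(vapply(rs, `[[`, numeric(1), "fit_correlation")),
               n_datasets = length(rs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
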