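#' Per-dataset correlation of every gene with target genes
#'
#' Pearson correlation of each measured gene with each target gene across the
#' samples of one dataset. Genes absent from the dataset are simply absent
#' from the profile (missing, not zero). If a target is absent or constant
#' the dataset is skipped for that target with a warning.
#'
#' @param dataset A (typically z-scored) [expression_dataset()] with
#'   platform `"log2_ready"`.
#' @param targets Character vector of target gene symbols (e.g. GLI1, GLI2).
#' @return Named list (one per usable target) of `CorrelationProfile` lists:
#'   `target`, `level = "dataset"`, `dataset_id`, `cancer_type`, `entries`
#'   (named numeric of correlations), `n_contributing` (all 1 at this level).
#' @export
dataset_correlations <- function(dataset, targets = c("GLI1", "GLI2")) {
  stopifnot(inherits(dataset, "ExpressionDataset"))
  if (ncol(dataset$values) < 3L)
    stop("need at least 3 samples for correlations")
  v <- dataset$values
  sds <- apply(v, 1, stats::sd)
  out <- list()
  for (tg in targets) {
    if (!tg %in% rownames(v) || sds[tg] == 0 || !is.finite(sds[tg])) {
      warning("target '", tg, "' absent or constant in dataset ",
              dataset$dataset_id, "; skipped")
      next
    }
    measurable <- rownames(v)[sds > 0 & is.finite(sds)]
    r <- as.vector(stats::cor(t(v[measurable, , drop = FALSE]), v[tg, ]))
    names(r) <- measurable
    r[tg] <- 1
    out[[tg]] <- list(target = tg, level = "dataset",
                      dataset_id = dataset$dataset_id,
                      cancer_type = dataset$cancer_type,
                      entries = r,
                      n_contributing = stats::setNames(rep(1L, length(r)),
                                                       measurable))
  }
  out
}

#' Coverage filter: genes measured in enough cancer types
#'
#' @param presence Named list: gene symbol -> character vector of cancer
#'   types in which the gene is measured.
#' @param min_types Minimum number of cancer types (inclusive).
#' @return Character vector of retained gene symbols.
#' @export
filter_genes_by_coverage <- function(presence, min_types = 30) {
  stopifnot(length(presence) > 0)
  n <- vapply(presence, function(x) length(unique(x)), integer(1))
  names(n)[n >= min_types]
}

#' Gene-type presence map from a study collection
#'
#' @param datasets List of `list(expr, ...)` pairs.
#' @return Named list gene -> cancer types measured, for
#'   [filter_genes_by_coverage()].
#' @export
gene_presence <- function(datasets) {
  acc <- list()
  for (pair in datasets) {
    ct <- pair$expr$cancer_type
    for (g in rownames(pair$expr$values)) acc[[g]] <- c(acc[[g]], ct)
  }
  lapply(acc, unique)
}

#' Average correlation profiles across datasets
#'
#' Unweighted arithmetic mean of raw correlations per gene, ignoring missing
#' entries; the number of contributing datasets is recorded per gene. With
#' `grouping = "cancer_type"` one averaged profile per type is returned; for
#' the pan-cancer level, `two_stage = TRUE` averages the per-type means
#' instead of pooling all datasets directly.
#'
#' @param profiles List of dataset-level profiles sharing one target.
#' @param grouping `"none"` (pan-cancer) or `"cancer_type"`.
#' @param two_stage Pan-cancer only: mean of per-type means.
#' @return One averaged `CorrelationProfile`, or a named list of them when
#'   grouped by cancer type.
#' @export
average_profiles <- function(profiles, grouping = c("none", "cancer_type"),
                             two_stage = FALSE) {
  grouping <- match.arg(grouping)
  if (length(profiles) == 0L) stop("empty profile list")
  tg <- unique(vapply(profiles, `[[`, character(1), "target"))
  if (length(tg) != 1L) stop("profiles mix targets: ", paste(tg, collapse = ", "))

  pool <- function(ps, level) {
    genes <- unique(unlist(lapply(ps, function(p) names(p$entries))))
    sums <- stats::setNames(numeric(length(genes)), genes)
    ns <- stats::setNames(integer(length(genes)), genes)
    for (p in ps) {
      e <- p$entries[!is.na(p$entries)]
      sums[names(e)] <- sums[names(e)] + e
      ns[names(e)] <- ns[names(e)] + 1L
    }
    keep <- ns > 0L
    list(target = tg, level = level,
         entries = sums[keep] / ns[keep], n_contributing = ns[keep])
  }

  if (grouping == "cancer_type") {
    by_type <- split(profiles, vapply(profiles, `[[`, character(1), "cancer_type"))
    out <- lapply(by_type, pool, level = "cancer_type")
    for (nm in names(out)) out[[nm]]$cancer_type <- nm
    return(out)
  }
  if (two_stage) {
    per_type <- average_profiles(profiles, "cancer_type")
    return(pool(unname(per_type), level = "pan_cancer"))
  }
  pool(profiles, level = "pan_cancer")
}

#' Rank genes by correlation with a target
#'
#' Percentile of each query gene when all profiled genes are sorted by
#' decreasing correlation (ties get their mean rank); percentile =
#' 100 * rank / n_ranked, so smaller means more correlated.
#'
#' @param profile A pan-cancer `CorrelationProfile`.
#' @param query_genes Genes to report (must be present in the profile).
#' @return Named numeric of percentiles.
#' @export
rank_genes <- function(profile, query_genes) {
  r <- profile$entries
  missing <- setdiff(query_genes, names(r))
  if (length(missing))
    stop("query gene(s) absent from profile: ", paste(missing, collapse = ", "))
  rk <- rank(-r, ties.method = "average")
  100 * rk[query_genes] / length(r)
}

#' Focal 8x8 correlation matrix for one cancer type
#'
#' Pairwise Pearson correlations among the eight focal genes, computed per
#' dataset and averaged (unweighted) across the datasets of one cancer type.
#' Datasets lacking a focal gene contribute to the remaining pairs only.
#' Also returns the boolean positive-correlation call per pair under the
#' strict threshold r > `threshold`.
#'
#' @param datasets List of `list(expr, ...)` pairs of one cancer type, with
#'   `expr` z-scored / log2-ready.
#' @param threshold Positive-call threshold (strict inequality).
#' @return `list(cancer_type, values, n_contributing, positive)`: `values`
#'   an 8x8 symmetric unit-diagonal matrix (NA where no dataset measures a
#'   pair), `positive` the logical call matrix.
#' @export
focal_matrix <- function(datasets, threshold = 0.25) {
  if (length(datasets) == 0L) stop("no datasets supplied")
  cts <- unique(vapply(datasets, function(p) p$expr$cancer_type, character(1)))
  if (length(cts) != 1L) stop("datasets mix cancer types")
  fg <- focal_genes()
  sums <- matrix(0, 8, 8, dimnames = list(fg, fg))
  ns <- matrix(0L, 8, 8, dimnames = list(fg, fg))
  for (pair in datasets) {
    v <- pair$expr$values
    have <- intersect(fg, rownames(v))
    have <- have[apply(v[have, , drop = FALSE], 1, stats::sd) > 0]
    if (length(have) < 2L) next
    cc <- stats::cor(t(v[have, , drop = FALSE]))
    sums[have, have] <- sums[have, have] + cc
    ns[have, have] <- ns[have, have] + 1L
  }
  if (all(ns[upper.tri(ns)] == 0L))
    stop("no dataset measures any focal gene pair")
  avg <- ifelse(ns > 0L, sums / pmax(ns, 1L), NA_real_)
  diag(avg) <- 1
  list(cancer_type = cts, values = avg, n_contributing = ns,
       positive = !is.na(avg) & avg > threshold)
}
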