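#' Run the full meta-analysis pipeline on a study collection
#'
#' Executes, in order: per-dataset pre-treatment (upper-quartile for counts,
#' log2, z-score), metagene scoring on the log2-scale data, per-dataset
#' correlation profiling with cross-dataset averaging and the focal 8x8
#' matrices, the two linear models per (dataset, metagene), univariate Cox
#' fits per (eligible dataset, variable) with per-cancer-type
#' inverse-variance meta-analysis, and the thresholded prognostic-score
#' matrix with its profile correlations.
#'
#' @param collection `list(datasets, manifest, ...)` from
#'   [generate_study_collection()] or [read_study_collection()].
#' @param signatures Named list of signature gene vectors (may be empty).
#' @param targets Correlation target genes.
#' @param min_types Coverage filter: genes must be measured in at least this
#'   many cancer types to enter the averaged profiles.
#' @param alpha Significance threshold for prognostic scores.
#' @param meta_model `"random"` or `"fixed"` pooling for the headline
#'   meta-analytic numbers.
#' @param survival_variables Variables to model for survival; default the
#'   eight focal genes plus every signature name.
#' @param ties Tie handling for the Cox fits.
#' @param compute_correlations,compute_linear_models Switch stages off to
#'   save time when only the survival arm is needed.
#' @param min_patients,min_events Cohort eligibility bounds.
#' @return A list with elements `zscored`, `dropped_genes`, `metagenes`,
#'   `profiles` (averaged correlation profiles per target: `pan_cancer`,
#'   `per_type`), `retained_genes`, `focal_matrices`, `models`,
#'   `model_summary`, `cox`, `meta`, `score_matrix`,
#'   `profile_correlation`, `n_eligible_cohorts`.
#' @export
run_pipeline <- function(collection, signatures = list(),
                         targets = c("GLI1", "GLI2"),
                         min_types = 1, alpha = 0.05,
                         meta_model = c("random", "fixed"),
                         survival_variables = NULL,
                         ties = "efron",
                         compute_correlations = TRUE,
                         compute_linear_models = TRUE,
                         min_patients = 50, min_events = 10) {
  meta_model <- match.arg(meta_model)
  datasets <- collection$datasets
  if (is.null(survival_variables))
    survival_variables <- c(focal_genes(), names(signatures))

  zscored <- list(); dropped <- list(); metagenes <- list()
  for (id in names(datasets)) {
    d <- datasets[[id]]$expr
    if (d$platform == "counts") d <- upper_quartile_normalize(d)
    d <- log2_transform(d)
    if (length(signatures))
      metagenes[[id]] <- compute_metagenes(d, signatures)
    zres <- zscore_within_dataset(d)
    zscored[[id]] <- zres$dataset
    dropped[[id]] <- zres$dropped
  }

  profiles <- NULL; retained <- NULL; focal <- NULL
  if (compute_correlations) {
    presence <- gene_presence(datasets)
    retained <- filter_genes_by_coverage(presence, min_types)
    per_ds <- lapply(zscored, dataset_correlations, targets = targets)
    profiles <- list()
    for (tg in targets) {
      ps <- Filter(Negate(is.null), lapply(per_ds, `[[`, tg))
      if (length(ps) == 0L) next
      ps <- lapply(ps, function(p) {
        keep <- intersect(names(p$entries), retained)
        p$entries <- p$entries[keep]
        p$n_contributing <- p$n_contributing[keep]
        p
      })
      profiles[[tg]] <- list(pan_cancer = average_profiles(ps, "none"),
                             per_type = average_profiles(ps, "cancer_type"))
    }
    by_type <- split(names(zscored),
                     vapply(zscored, `[[`, character(1), "cancer_type"))
    focal <- lapply(by_type, function(ids)
      focal_matrix(lapply(ids, function(i) list(expr = zscored[[i]]))))
  }

  models <- list(); model_summary <- NULL
  if (compute_linear_models && length(signatures)) {
    for (id in names(zscored)) {
      for (s in names(signatures)) {
        mg <- metagenes[[id]][[s]]
        models[[length(models) + 1L]] <-
          tryCatch(fit_full_model(zscored[[id]], mg), error = function(e) NULL)
        models[[length(models) + 1L]] <-
          tryCatch(fit_group_model(zscored[[id]], mg), error = function(e) NULL)
      }
    }
    models <- Filter(Negate(is.null), models)
    if (length(models)) model_summary <- aggregate_models(models)
  }

  cox <- list(); n_eligible <- 0L
  for (id in names(zscored)) {
    clin <- datasets[[id]]$clinical
    if (!cohort_eligible(clin, min_patients, min_events)) next
    n_eligible <- n_eligible + 1L
    z <- zscored[[id]]
    idx <- match(clin$sample_id, colnames(z$values))
    for (v in survival_variables) {
      xv <- if (v %in% rownames(z$values)) {
        z$values[v, idx]
      } else if (!is.null(metagenes[[id]][[v]])) {
        sc <- metagenes[[id]][[v]]$scores[idx]
        if (stats::sd(sc) == 0) next
        zscore_vec(sc)
      } else next
      fit <- tryCatch(
        fit_univariate_cox(clin$os_time, clin$os_event, xv, ties = ties,
                           dataset_id = id, variable = v),
        error = function(e) NULL)
      if (is.null(fit)) next
      fit$cancer_type <- z$cancer_type
      cox[[length(cox) + 1L]] <- fit
    }
  }

  meta <- list()
  if (length(cox)) {
    key <- vapply(cox, function(r) paste(r$cancer_type, r$variable, sep = "\r"),
                  character(1))
    for (grp in split(cox, key)) {
      m <- tryCatch(
        meta_aggregate(grp, model = meta_model,
                       cancer_type = grp[[1]]$cancer_type,
                       variable = grp[[1]]$variable),
        error = function(e) NULL)
      if (!is.null(m)) meta[[length(meta) + 1L]] <- m
    }
  }

  score_matrix <- NULL; prof_corr <- NULL
  if (length(meta)) {
    score_matrix <- prognostic_score_matrix(meta, alpha)
    if (ncol(score_matrix$scores) >= 3L)
      prof_corr <- profile_correlations(score_matrix)
  }

  list(zscored = zscored, dropped_genes = dropped, metagenes = metagenes,
       profiles = profiles, retained_genes = retained,
       focal_matrices = focal,
       models = models, model_summary = model_summary,
       cox = cox, meta = meta,
       score_matrix = score_matrix, profile_correlation = prof_corr,
       n_eligible_cohorts = n_eligible)
}

#' Tabulate Cox results
#'
#' @param cox List of `CoxResult`s.
#' @return A data.frame, one row per fit.
#' @export
cox_results_table <- function(cox) {
  do.call(rbind, lapply(cox, function(r)
    data.frame(dataset_id = r$dataset_id, cancer_type = r$cancer_type %||% NA,
               variable = r$variable, beta = r$beta, se = r$se, hr = r$hr,
               ci_low = r$ci95[["low"]], ci_high = r$ci95[["high"]],
               p = r$p, n = r$n, n_events = r$n_events,
               monotone = r$monotone, stringsAsFactors = FALSE)))
}

#' Tabulate meta-analysis results
#'
#' Includes the p-value bin used in forest-style displays:
#' `<0.001`, `<0.05`, or `ns`.
#'
#' @param meta List of `MetaResult`s.
#' @return A data.frame, one row per (cancer type, variable).
#' @export
meta_results_table <- function(meta) {
  do.call(rbind, lapply(meta, function(r)
    data.frame(cancer_type = r$cancer_type, variable = r$variable,
               pooled_hr = r$pooled_hr, pooled_beta = r$pooled_beta,
               pooled_se = r$pooled_se,
               ci_low = r$ci95[["low"]], ci_high = r$ci95[["high"]],
               p = r$p, tau2 = r$tau2, Q = r$Q, k = r$k, model = r$model,
               p_bin = if (r$p < 0.001) "<0.001" else if (r$p < 0.05) "<0.05" else "ns",
               stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
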