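#' Simulation configuration for a synthetic multi-study cohort
#'
#' Describes a collection of studies across cancer types with planted
#' structure: a latent correlation matrix over the eight focal genes,
#' single-factor gene signatures driven by weighted combinations of the focal
#' genes, dataset-specific platform effects (already-log2 array values or
#' negative-binomial counts), and survival times with proportional-hazards
#' dependence on chosen variables.
#'
#' @param cancer_types List of `list(name, n_datasets, samples_per_dataset)`;
#'   `samples_per_dataset` is a single integer or a `c(min, max)` range
#'   sampled per dataset.
#' @param latent_correlation Symmetric unit-diagonal matrix over the eight
#'   focal genes (see [focal_genes()]), or a named list of such matrices, one
#'   per cancer type. Repaired by eigenvalue clipping (with a warning) if not
#'   positive semi-definite.
#' @param signatures Named list; each element
#'   `list(genes, factor_loading, driver_weights)` where `factor_loading` is a
#'   scalar or per-gene vector in \[0, 1) and `driver_weights` is a named
#'   numeric over focal genes. Signature genes are generated as
#'   `loading * standardized(driver combination) + independent noise`, scaled
#'   to unit latent variance.
#' @param n_background_genes Number of independent standard-normal background
#'   genes. Keep this at 100 or more when count-like platforms are in play:
#'   the upper-quartile normalization factor is estimated per sample from the
#'   gene panel, and with too few genes it is dominated by the focal genes
#'   themselves, which perturbs their correlations.
#' @param platform_mix Fraction of datasets that are count-like (negative
#'   binomial); the rest are array-like (already-log2).
#' @param hazard_spec Named list: cancer type -> named numeric of log hazard
#'   ratios per 1 SD of the named variable (focal gene, background gene, or
#'   signature name). Types absent from the list have all-null hazards.
#' @param baseline_hazard Exponential baseline event rate per time unit.
#' @param censoring `list(horizon_quantile =, dropout =)`: administrative
#'   horizon at that quantile of the drawn event times plus a uniform-dropout
#'   fraction; or `"none"` for fully observed events.
#' @param nb_dispersion Negative-binomial dispersion for count platforms.
#' @param array_noise_sd Measurement noise SD added to the unit-variance
#'   latent on array platforms.
#' @param seed Master integer seed; per-dataset seeds are derived by a stable
#'   hash of (seed, cancer type, dataset index).
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(cancer_types,
                       latent_correlation = diag(8),
                       signatures = list(),
                       n_background_genes = 200,
                       platform_mix = 0.25,
                       hazard_spec = list(),
                       baseline_hazard = 0.1,
                       censoring = list(horizon_quantile = 0.7, dropout = 0.35),
                       nb_dispersion = 0.2,
                       array_noise_sd = 0.1,
                       seed = 1L) {
  fg <- focal_genes()
  fix_corr <- function(R) {
    R <- as.matrix(R)
    if (is.null(rownames(R))) dimnames(R) <- list(fg, fg)
    stopifnot(nrow(R) == 8, ncol(R) == 8)
    if (max(abs(R - t(R))) > 1e-8) stop("latent_correlation must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-8) stop("latent_correlation must have unit diagonal")
    repair_psd(R)
  }
  if (is.list(latent_correlation)) {
    latent_correlation <- lapply(latent_correlation, fix_corr)
  } else {
    latent_correlation <- fix_corr(latent_correlation)
  }
  for (s in names(signatures)) {
    sig <- signatures[[s]]
    stopifnot(is.character(sig$genes), length(sig$genes) > 0)
    if (is.null(sig$factor_loading)) signatures[[s]]$factor_loading <- 0.7
    w <- sig$driver_weights
    if (is.null(names(w)) || !all(names(w) %in% fg))
      stop("driver_weights of signature '", s, "' must be named over focal genes")
  }
  valid_vars <- c(fg, names(signatures),
                  sprintf("BG%04d", seq_len(n_background_genes)))
  for (ct in names(hazard_spec)) {
    bad <- setdiff(names(hazard_spec[[ct]]), valid_vars)
    if (length(bad))
      stop("hazard_spec for '", ct, "' names unknown variable(s): ",
           paste(bad, collapse = ", "))
  }
  structure(
    list(cancer_types = cancer_types,
         gene_panel = fg,
         latent_correlation = latent_correlation,
         signatures = signatures,
         n_background_genes = n_background_genes,
         platform_mix = platform_mix,
         hazard_spec = hazard_spec,
         baseline_hazard = baseline_hazard,
         censoring = censoring,
         nb_dispersion = nb_dispersion,
         array_noise_sd = array_noise_sd,
         seed = as.integer(seed)),
    class = "SimulationConfig")
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Eigenvalues below zero are clipped to a small positive floor and the
#' matrix is rescaled back to unit diagonal. A warning is emitted when a
#' repair actually changes the matrix; an error if the repair moves any
#' entry by more than `tol`.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param tol Maximum admissible entrywise change during repair.
#' @return A positive semi-definite correlation matrix.
#' @export
repair_psd <- function(R, tol = 0.1) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -1e-10) return(R)
  vals <- pmax(e$values, 1e-8)
  R2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(R2))
  R2 <- R2 / outer(d, d)
  dimnames(R2) <- dimnames(R)
  delta <- max(abs(R2 - R))
  if (delta > tol)
    stop("latent correlation is too far from positive semi-definite (max change ",
         signif(delta, 3), ")")
  warning("latent correlation repaired to PSD by eigenvalue clipping (max change ",
          signif(delta, 3), ")")
  R2
}

# Deterministic 31-bit seed from the master seed and dataset coordinates,
# independent of generation order and platform.
dataset_seed <- function(seed, cancer_type, dataset_index) {
  key <- paste(seed, cancer_type, dataset_index, sep = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

type_spec <- function(config, cancer_type) {
  for (ct in config$cancer_types)
    if (ct$name == cancer_type) return(ct)
  stop("unknown cancer type '", cancer_type, "'")
}

type_correlation <- function(config, cancer_type) {
  R <- config$latent_correlation
  if (is.list(R)) {
    if (!cancer_type %in% names(R))
      stop("no latent correlation configured for type '", cancer_type, "'")
    R[[cancer_type]]
  } else R
}

#' Generate one synthetic dataset (expression + clinical)
#'
#' Draws per-sample latent focal-gene values from a zero-mean multivariate
#' normal with the configured correlation; signature genes from a
#' single-factor model on the weighted focal-gene combination; background
#' genes independent. Array-like datasets deliver
#' `offset + scale * latent + noise` as already-log2 values; count-like
#' datasets deliver raw negative-binomial counts with log-mean linear in the
#' latent. Survival times are exponential under a proportional-hazards model
#' on the planted (unit-variance) variables, then censored.
#'
#' Deterministic given (config seed, cancer type, dataset index).
#'
#' @param config A [sim_config()].
#' @param cancer_type Cancer-type name present in the config.
#' @param dataset_index 1-based index below that type's `n_datasets`.
#' @return `list(expr = ExpressionDataset, clinical = ClinicalTable)`.
#' @export
generate_dataset <- function(config, cancer_type, dataset_index) {
  stopifnot(inherits(config, "SimulationConfig"))
  ct <- type_spec(config, cancer_type)
  if (dataset_index < 1 || dataset_index > ct$n_datasets)
    stop("dataset_index out of range for type '", cancer_type, "'")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(dataset_seed(config$seed, cancer_type, dataset_index))

  spd <- ct$samples_per_dataset
  n <- if (length(spd) == 2L) sample(spd[1]:spd[2], 1L) else as.integer(spd)
  fg <- focal_genes()
  R <- type_correlation(config, cancer_type)
  L <- chol(R + diag(1e-10, 8))
  Fmat <- matrix(stats::rnorm(n * 8), n, 8) %*% L     # n x 8 latent focal (unit var)
  colnames(Fmat) <- fg

  lat <- list(t(Fmat))
  drivers <- list()
  for (s in names(config$signatures)) {
    sig <- config$signatures[[s]]
    w <- sig$driver_weights
    d <- as.vector(Fmat[, names(w), drop = FALSE] %*% w)
    vd <- as.numeric(t(w) %*% R[names(w), names(w)] %*% w)
    d <- d / sqrt(vd)
    drivers[[s]] <- d
    lam <- rep_len(sig$factor_loading, length(sig$genes))
    G <- vapply(seq_along(sig$genes), function(k) {
      lam[k] * d + sqrt(1 - lam[k]^2) * stats::rnorm(n)
    }, numeric(n))
    G <- t(G)
    rownames(G) <- sig$genes
    lat <- c(lat, list(G))
  }
  if (config$n_background_genes > 0) {
    B <- matrix(stats::rnorm(config$n_background_genes * n),
                config$n_background_genes, n,
                dimnames = list(sprintf("BG%04d", seq_len(config$n_background_genes)), NULL))
    lat <- c(lat, list(B))
  }
  latent <- do.call(rbind, lat)                    # genes x samples, unit variance
  sample_ids <- sprintf("%s_D%02d_S%04d", cancer_type, dataset_index, seq_len(n))
  colnames(latent) <- sample_ids
  dataset_id <- sprintf("%s_D%02d", cancer_type, dataset_index)

  count_like <- stats::runif(1) < config$platform_mix
  if (count_like) {
    log_base <- stats::runif(nrow(latent), log(50), log(500))
    mu <- exp(log_base + log(2) * latent)
    cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                  nrow(mu), ncol(mu), dimnames = dimnames(latent))
    expr <- expression_dataset(cnt, dataset_id, cancer_type, "counts")
  } else {
    gene_offset <- stats::runif(nrow(latent), 4, 10)
    scale <- stats::runif(1, 0.8, 1.5)
    vals <- gene_offset + scale * latent +
      matrix(stats::rnorm(length(latent), sd = config$array_noise_sd),
             nrow(latent), ncol(latent))
    dimnames(vals) <- dimnames(latent)
    expr <- expression_dataset(vals, dataset_id, cancer_type, "array_log2")
  }

  hs <- config$hazard_spec[[cancer_type]]
  lp <- numeric(n)
  if (!is.null(hs) && length(hs)) {
    for (v in names(hs)) {
      z <- if (v %in% rownames(latent)) latent[v, ] else drivers[[v]]
      lp <- lp + hs[[v]] * z
    }
  }
  haz <- config$baseline_hazard * exp(lp)
  T <- stats::rexp(n, rate = haz)
  if (identical(config$censoring, "none")) {
    time <- T; event <- rep(1L, n)
  } else {
    H <- stats::quantile(T, probs = config$censoring$horizon_quantile,
                         names = FALSE)
    C <- ifelse(stats::runif(n) < config$censoring$dropout,
                stats::runif(n, 0, H), Inf)
    lim <- pmin(C, H)
    time <- pmin(T, lim)
    event <- as.integer(T <= lim)
  }
  clinical <- clinical_table(sample_ids, time, event)
  list(expr = expr, clinical = clinical)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate the whole study collection
#'
#' One dataset per (cancer type, dataset index), a manifest, and the ground
#' truth (planted correlations and log hazard ratios) for recovery tests.
#'
#' @param config A [sim_config()].
#' @return `list(datasets, manifest, ground_truth)`: `datasets` is a list of
#'   `list(expr, clinical)`; `manifest` a data.frame with columns
#'   `dataset_id`, `cancer_type`, `platform`, `n_samples`; `ground_truth`
#'   holds `planted_correlations` (per cancer type), `planted_log_hrs` and
#'   the seed.
#' @export
generate_study_collection <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  datasets <- list()
  rows <- list()
  for (ct in config$cancer_types) {
    for (i in seq_len(ct$n_datasets)) {
      pair <- generate_dataset(config, ct$name, i)
      datasets[[pair$expr$dataset_id]] <- pair
      rows[[length(rows) + 1L]] <- data.frame(
        dataset_id = pair$expr$dataset_id,
        cancer_type = ct$name,
        platform = pair$expr$platform,
        n_samples = ncol(pair$expr$values),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  planted_corr <- lapply(stats::setNames(nm = vapply(config$cancer_types, `[[`,
                                                    character(1), "name")),
                         function(nm) type_correlation(config, nm))
  gt <- list(planted_correlations = planted_corr,
             planted_log_hrs = config$hazard_spec,
             seed = config$seed)
  list(datasets = datasets, manifest = manifest, ground_truth = gt)
}

#' Write a study collection to disk
#'
#' Expression and clinical tables as TSV, manifest as JSON — the on-disk
#' interchange format the readers in this package consume.
#'
#' @param collection Result of [generate_study_collection()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- collection$manifest
  man$expr_path <- file.path(dir, paste0(man$dataset_id, "_expr.tsv"))
  man$clinical_path <- file.path(dir, paste0(man$dataset_id, "_clinical.tsv"))
  for (i in seq_len(nrow(man))) {
    pair <- collection$datasets[[man$dataset_id[i]]]
    write_expression_tsv(pair$expr, man$expr_path[i])
    write_clinical_tsv(pair$clinical, man$clinical_path[i])
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, manifest_path, dataframe = "rows", pretty = TRUE)
  invisible(manifest_path)
}

#' Read a study collection back from a manifest
#'
#' @param manifest_path Path to the JSON manifest written by
#'   [write_study_collection()].
#' @return `list(datasets, manifest)` as in [generate_study_collection()].
#' @export
read_study_collection <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  datasets <- list()
  for (i in seq_len(nrow(man))) {
    expr <- read_expression_tsv(man$expr_path[i], man$dataset_id[i],
                                man$cancer_type[i], man$platform[i])
    clinical <- read_clinical_tsv(man$clinical_path[i])
    datasets[[man$dataset_id[i]]] <- list(expr = expr, clinical = clinical)
  }
  list(datasets = datasets, manifest = man)
}
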