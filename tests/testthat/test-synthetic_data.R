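simple_config <- function(...) {
  sim_config(
    cancer_types = list(list(name = "alpha", n_datasets = 3, samples_per_dataset = 40),
                        list(name = "beta", n_datasets = 2, samples_per_dataset = c(30, 60)),
                        list(name = "gamma", n_datasets = 2, samples_per_dataset = 40)),
    n_background_genes = 5, seed = 11, ...)
}

test_that("generation is deterministic given (seed, type, index) and order-independent", {
  cfg <- simple_config()
  a <- generate_dataset(cfg, "beta", 2)
  set.seed(999)  # generator must not depend on ambient RNG state
  b <- generate_dataset(cfg, "beta", 2)
  expect_identical(a, b)

  # file serializations byte-identical too
  f1 <- tempfile(); f2 <- tempfile()
  write_expression_tsv(a$expr, f1); write_expression_tsv(b$expr, f2)
  expect_identical(readLines(f1), readLines(f2))

  # different index/seed changes the draw
  expect_false(identical(generate_dataset(cfg, "beta", 1)$expr$values,
                         a$expr$values))
  cfg2 <- simple_config(); cfg2$seed <- 12L
  expect_false(identical(generate_dataset(cfg2, "beta", 2)$expr$values,
                         a$expr$values))
})

test_that("a collection has one pair per (type, index) and a matching manifest", {
  cfg <- simple_config()
  coll <- generate_study_collection(cfg)
  expect_length(coll$datasets, 7)
  expect_equal(nrow(coll$manifest), 7)
  expect_setequal(coll$manifest$cancer_type, c("alpha", "beta", "gamma"))
  expect_true(all(coll$manifest$n_samples >= 30 & coll$manifest$n_samples <= 60))
  expect_equal(coll$ground_truth$seed, 11L)
  expect_named(coll$ground_truth$planted_correlations, c("alpha", "beta", "gamma"))
})

test_that("identity latent correlation yields near-zero empirical correlation (n = 2000)", {
  cfg <- sim_config(
    cancer_types = list(list(name = "t", n_datasets = 1, samples_per_dataset = 2000)),
    latent_correlation = diag(8), platform_mix = 0, n_background_genes = 0,
    seed = 5)
  d <- generate_dataset(cfg, "t", 1)$expr
  r <- cor(d$values["GLI1", ], d$values["TGFB1", ])
  expect_lt(abs(r), 0.08)  # 3 / sqrt(n) null bound, with headroom for noise
})

test_that("a planted r(GLI2, TGFB1) = 0.6 is recovered within the Fisher-z band at n = 2000", {
  R <- diag(8); dimnames(R) <- list(focal_genes(), focal_genes())
  R["GLI2", "TGFB1"] <- R["TGFB1", "GLI2"] <- 0.6
  cfg <- sim_config(
    cancer_types = list(list(name = "t", n_datasets = 1, samples_per_dataset = 2000)),
    latent_correlation = R, platform_mix = 0, n_background_genes = 0, seed = 21)
  d <- generate_dataset(cfg, "t", 1)$expr
  r <- cor(d$values["GLI2", ], d$values["TGFB1", ])
  expect_equal(r, 0.6, tolerance = 0.05 / 0.6)
})

test_that("count-like platforms deliver raw integer counts, array-like log2 values", {
  cfg <- sim_config(
    cancer_types = list(list(name = "t", n_datasets = 4, samples_per_dataset = 30)),
    platform_mix = 1, n_background_genes = 2, seed = 3)
  d <- generate_dataset(cfg, "t", 1)$expr
  expect_equal(d$platform, "counts")
  expect_true(all(d$values == round(d$values) & d$values >= 0))
  cfg$platform_mix <- 0
  d2 <- generate_dataset(cfg, "t", 1)$expr
  expect_equal(d2$platform, "array_log2")
})

test_that("signature genes track their driver combination", {
  sig <- list(EMT = list(genes = paste0("E", 1:6), factor_loading = 0.8,
                         driver_weights = c(TGFB1 = 1)))
  cfg <- sim_config(
    cancer_types = list(list(name = "t", n_datasets = 1, samples_per_dataset = 3000)),
    signatures = sig, platform_mix = 0, n_background_genes = 0,
    array_noise_sd = 0, seed = 9)
  d <- generate_dataset(cfg, "t", 1)$expr
  # each signature gene: loading 0.8 on the (unit-variance) driver TGFB1
  r <- cor(d$values["E1", ], d$values["TGFB1", ])
  expect_equal(r, 0.8, tolerance = 0.05)
  # unit latent variance after the factor construction (scale is dataset-wide)
  expect_equal(sd(d$values["E1", ]) / sd(d$values["TGFB1", ]), 1, tolerance = 0.06)
})

test_that("with null hazards and no censoring the survival median matches ln(2)/rate", {
  cfg <- sim_config(
    cancer_types = list(list(name = "t", n_datasets = 1, samples_per_dataset = 2000)),
    baseline_hazard = 0.1, censoring = "none", n_background_genes = 0, seed = 13)
  cl <- generate_dataset(cfg, "t", 1)$clinical
  expect_true(all(cl$os_event == 1))
  expect_equal(median(cl$os_time), log(2) / 0.1, tolerance = 0.1)
})

test_that("default censoring yields a clinically plausible event fraction", {
  cfg <- simple_config()
  coll <- generate_study_collection(cfg)
  frac <- vapply(coll$datasets, function(p) mean(p$clinical$os_event), numeric(1))
  expect_true(all(frac > 0.3 & frac < 0.75))
})

test_that("non-PSD latent correlations are repaired with a warning, far ones rejected", {
  R <- diag(8)
  R[1, 2] <- R[2, 1] <- 0.8
  R[2, 3] <- R[3, 2] <- 0.8
  R[1, 3] <- R[3, 1] <- 0.2  # slightly infeasible triangle (min eig ~ -0.036)
  expect_warning(cfg <- sim_config(
    cancer_types = list(list(name = "t", n_datasets = 1, samples_per_dataset = 10)),
    latent_correlation = R, seed = 1), "repaired")
  ev <- eigen(cfg$latent_correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(diag(cfg$latent_correlation), rep(1, 8), tolerance = 1e-12,
               ignore_attr = TRUE)

  R2 <- diag(8); R2[1, 2] <- R2[2, 1] <- 0.99
  R2[2, 3] <- R2[3, 2] <- 0.99
  R2[1, 3] <- R2[3, 1] <- -0.99  # grossly infeasible
  expect_error(suppressWarnings(repair_psd(R2)), "too far")
})

test_that("config validation rejects unknown types and hazard variables", {
  cfg <- simple_config()
  expect_error(generate_dataset(cfg, "nope", 1), "unknown cancer type")
  expect_error(generate_dataset(cfg, "alpha", 4), "out of range")
  expect_error(
    sim_config(cancer_types = list(list(name = "t", n_datasets = 1,
                                        samples_per_dataset = 10)),
               hazard_spec = list(t = list(NOSUCHGENE = 1)), seed = 1),
    "unknown variable")
})

test_that("planted hazards shift survival in the planted direction", {
  cfg <- sim_config(
    cancer_types = list(list(name = "t", n_datasets = 1, samples_per_dataset = 4000)),
    hazard_spec = list(t = list(TGFB1 = log(2))),
    censoring = "none", platform_mix = 0, n_background_genes = 0,
    array_noise_sd = 0, seed = 17)
  pair <- generate_dataset(cfg, "t", 1)
  hi <- pair$expr$values["TGFB1", ] > median(pair$expr$values["TGFB1", ])
  expect_lt(median(pair$clinical$os_time[hi]),
            median(pair$clinical$os_time[!hi]))
})

test_that("a study collection round-trips through disk", {
  cfg <- sim_config(
    cancer_types = list(list(name = "t", n_datasets = 2, samples_per_dataset = 12)),
    n_background_genes = 3, platform_mix = 0, seed = 8)
  coll <- generate_study_collection(cfg)
  dir <- tempfile()
  manifest_path <- write_study_collection(coll, dir)
  back <- read_study_collection(manifest_path)
  expect_equal(names(back$datasets), names(coll$datasets))
  expect_equal(back$datasets$t_D01$expr$values, coll$datasets$t_D01$expr$values,
               tolerance = 1e-8)
  expect_equal(back$datasets$t_D02$clinical$os_event,
               coll$datasets$t_D02$clinical$os_event)
  unlink(dir, recursive = TRUE)
})
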