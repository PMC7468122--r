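# Shared simulated-world configuration for the analysis scripts.
#
# The world mirrors the structure the pipeline is built to detect: GLI2 and
# TGFB1 co-expressed and sharing a pejorative survival hazard whose strength
# varies across cancer types, Hedgehog ligands protective with an inversely
# tracking hazard, and an EMT-like signature driven by TGFB1/GLI2. Ten cancer
# types, three datasets each, mixed array/count platforms.

library(pancanGLI)

SEED <- as.integer(Sys.getenv("ANALYSIS_SEED", "1"))

EMT_GENES <- paste0("EMT", sprintf("%02d", 1:20))
SIGNATURES <- list(emt = EMT_GENES)

analysis_config <- function(seed = SEED) {
  fg <- focal_genes()
  R <- diag(8); dimnames(R) <- list(fg, fg)
  R["GLI1", "GLI2"] <- R["GLI2", "GLI1"] <- 0.5
  R["GLI2", "TGFB1"] <- R["TGFB1", "GLI2"] <- 0.6
  R["SHH", "IHH"] <- R["IHH", "SHH"] <- 0.3

  types <- paste0("ct", sprintf("%02d", 1:10))
  b <- seq(0.4, 0.9, length.out = 8)
  hz <- lapply(1:10, function(i) {
    if (i <= 8) list(GLI2 = b[i], TGFB1 = b[i], SHH = -(0.2 + 0.6 * b[i]),
                     emt = 0.3)
    else list(SHH = -0.2)
  })
  names(hz) <- types

  sim_config(
    cancer_types = lapply(types, function(t)
      list(name = t, n_datasets = 3, samples_per_dataset = c(100, 250))),
    latent_correlation = R,
    signatures = list(emt = list(genes = EMT_GENES, factor_loading = 0.7,
                                 driver_weights = c(TGFB1 = 1, GLI2 = 0.5))),
    hazard_spec = hz,
    platform_mix = 0.25,
    n_background_genes = 200,
    seed = seed)
}

results_dir <- function() {
  dir.create("results", showWarnings = FALSE)
  "results"
}
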