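# Small in-code fixtures and independent oracles shared across test files.

# A log2-ready dataset from a plain matrix.
make_dataset <- function(values, id = "D1", type = "testtype",
                         platform = "log2_ready") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("G", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  expression_dataset(values, id, type, platform)
}

# Dataset whose rows are the eight focal genes drawn from a given latent
# correlation, plus optional extra rows.
make_focal_dataset <- function(n, R = diag(8), id = "D1", type = "testtype",
                               extra = NULL) {
  L <- chol(R + diag(1e-10, 8))
  m <- t(matrix(rnorm(n * 8), n, 8) %*% L)
  rownames(m) <- focal_genes()
  colnames(m) <- paste0("S", seq_len(n))
  if (!is.null(extra)) {
    colnames(extra) <- colnames(m)
    m <- rbind(m, extra)
  }
  expression_dataset(m, id, type, "log2_ready")
}

# Independent brute-force Cox oracle: the partial likelihood is summed
# explicitly by looping over risk sets (no cumulative-sum tricks shared with
# the implementation) and maximized in 1-D by stats::optimize.
oracle_cox_loglik <- function(beta, time, event, x, ties = "efron") {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    risk <- which(time >= t)
    deaths <- which(time == t & event == 1)
    d <- length(deaths)
    ll <- ll + beta * sum(x[deaths])
    if (ties == "breslow" || d == 1) {
      ll <- ll - d * log(sum(exp(beta * x[risk])))
    } else {
      for (l in 0:(d - 1)) {
        ll <- ll - log(sum(exp(beta * x[risk])) -
                         (l / d) * sum(exp(beta * x[deaths])))
      }
    }
  }
  ll
}

oracle_cox_beta <- function(time, event, x, ties = "efron", interval = c(-8, 8)) {
  stats::optimize(oracle_cox_loglik, interval, time = time, event = event,
                  x = x, ties = ties, maximum = TRUE, tol = 1e-10)$maximum
}

# Exponential proportional-hazards cohort with a single standard-normal
# covariate; returns a data.frame ready for fit_univariate_cox.
sim_cox_cohort <- function(n, beta = 0, censor_q = 0.7) {
  x <- rnorm(n)
  T <- rexp(n, rate = 0.1 * exp(beta * x))
  H <- quantile(T, censor_q, names = FALSE)
  data.frame(time = pmin(T, H), event = as.integer(T <= H), x = x)
}
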