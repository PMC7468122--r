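#' Cohort eligibility for survival modelling
#'
#' A cohort enters the meta-analysis when it has more than 50 patients
#' (strict) and at least 10 observed death events (inclusive).
#'
#' @param clinical A [clinical_table()].
#' @param min_patients Patients must exceed this number.
#' @param min_events Minimum number of death events.
#' @return Logical scalar.
#' @export
cohort_eligible <- function(clinical, min_patients = 50, min_events = 10) {
  nrow(clinical) > min_patients && sum(clinical$os_event) >= min_events
}

# Risk-set bookkeeping for a cohort pre-sorted by increasing time: for each
# distinct event time, the first index of its risk set, the indices of the
# tied deaths, and which groups actually have ties.
cox_risk_groups <- function(time, event) {
  ev <- which(event == 1L)
  ut <- unique(time[ev])
  first_idx <- which(!duplicated(time))
  f <- first_idx[match(ut, time[first_idx])]
  D <- split(ev, match(time[ev], ut))
  d <- lengths(D)
  list(f = f, D = D, d = as.numeric(d), tied = which(d > 1L))
}

# Efron/Breslow partial-likelihood value, score and information for a scalar
# covariate at the supplied beta. Untied (and all Breslow) groups are handled
# vectorised; Efron's within-group downweighting only needs a loop over the
# tied groups.
cox_quantities <- function(beta, x, rg, ties) {
  e <- exp(beta * x)
  cs0 <- rev(cumsum(rev(e)))
  cs1 <- rev(cumsum(rev(x * e)))
  cs2 <- rev(cumsum(rev(x * x * e)))
  S0 <- cs0[rg$f]; S1 <- cs1[rg$f]; S2 <- cs2[rg$f]
  xD <- vapply(rg$D, function(idx) sum(x[idx]), numeric(1))
  ll <- beta * sum(xD) - sum(rg$d * log(S0))
  U <- sum(xD) - sum(rg$d * S1 / S0)
  I <- sum(rg$d * (S2 / S0 - (S1 / S0)^2))
  if (ties == "efron" && length(rg$tied)) {
    for (j in rg$tied) {
      idx <- rg$D[[j]]; d <- rg$d[j]
      s0 <- sum(e[idx]); s1 <- sum(x[idx] * e[idx]); s2 <- sum(x[idx]^2 * e[idx])
      frac <- (seq_len(d) - 1) / d
      S0v <- S0[j] - frac * s0
      S1v <- S1[j] - frac * s1
      S2v <- S2[j] - frac * s2
      ll <- ll + d * log(S0[j]) - sum(log(S0v))
      U <- U + d * S1[j] / S0[j] - sum(S1v / S0v)
      I <- I - d * (S2[j] / S0[j] - (S1[j] / S0[j])^2) +
        sum(S2v / S0v - (S1v / S0v)^2)
    }
  }
  list(loglik = ll, score = U, information = I)
}

#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood for a single (z-scored) covariate by
#' Newton-Raphson with step-halving; the Efron correction for tied event
#' times is the default, Breslow selectable. Convergence when the score is
#' below 1e-9 in absolute value or the step below 1e-10; at most `max_iter`
#' iterations. The standard error comes from the inverse observed
#' information, the p-value from the two-sided Wald normal approximation.
#'
#' Monotone likelihoods (the covariate perfectly separates the event order)
#' drift to unbounded beta; such fits are flagged `monotone = TRUE` and should
#' be excluded from meta-analysis.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = death, 0 = censored).
#' @param x Covariate values (conventionally z-scored, so beta is the log
#'   hazard ratio per 1 SD).
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter Newton-Raphson iteration cap.
#' @param dataset_id,variable Labels carried into the result.
#' @return A `CoxResult` list: `beta`, `se`, `hr`, `ci95`, `p`, `loglik`,
#'   `n`, `n_events`, `iterations`, `monotone`, plus the labels.
#' @export
fit_univariate_cox <- function(time, event, x, ties = c("efron", "breslow"),
                               max_iter = 50L, dataset_id = NA_character_,
                               variable = NA_character_) {
  ties <- match.arg(ties)
  stopifnot(length(time) == length(event), length(time) == length(x))
  if (any(time <= 0)) stop("all times must be positive")
  if (sum(event) == 0) stop("no events; Cox model undefined")
  if (stats::sd(x) == 0) stop("constant covariate")
  ord <- order(time)
  time <- time[ord]; event <- as.integer(event[ord]); x <- x[ord]
  rg <- cox_risk_groups(time, event)

  beta <- 0
  q <- cox_quantities(beta, x, rg, ties)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (abs(q$score) < 1e-9) break
    if (q$information <= 0) break
    step <- q$score / q$information
    # step-halving: insist on a non-decreasing partial likelihood
    h <- 0L
    repeat {
      cand <- beta + step
      qc <- cox_quantities(cand, x, rg, ties)
      if (qc$loglik >= q$loglik - 1e-12 || h >= 20L) break
      step <- step / 2; h <- h + 1L
    }
    converged_step <- abs(step) < 1e-10
    beta <- cand; q <- qc
    if (converged_step) break
    if (iter >= max_iter) {
      if (abs(q$score) > 1e-4)
        stop("Cox Newton-Raphson failed to converge (|score| = ",
             signif(abs(q$score), 3), ", beta = ", signif(beta, 4), ")")
      break
    }
  }
  monotone <- abs(beta) > 15 || q$information < 1e-10
  se <- if (q$information > 0) 1 / sqrt(q$information) else Inf
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  list(dataset_id = dataset_id, variable = variable,
       beta = beta, se = se, hr = exp(beta),
       ci95 = c(low = exp(beta - 1.96 * se), high = exp(beta + 1.96 * se)),
       p = p, loglik = q$loglik, n = length(x), n_events = sum(event),
       iterations = iter, ties = ties, monotone = monotone)
}

#' Inverse-variance meta-analysis of log hazard ratios
#'
#' Fixed effect: weights `1/se^2`, pooled beta the weighted mean, pooled se
#' `1/sqrt(sum w)`. Random effects: DerSimonian-Laird between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))` with `Q` the
#' fixed-effect heterogeneity statistic, then inverse-variance pooling with
#' weights `1/(se^2 + tau2)`. A single study pools to itself with `tau2 = 0`.
#' P-values are two-sided normal.
#'
#' @param results List of `CoxResult`s for one (cancer type, variable);
#'   monotone fits are dropped with a warning.
#' @param model `"random"` (headline) or `"fixed"`; both sets of numbers are
#'   returned regardless.
#' @param cancer_type,variable Labels carried into the result.
#' @return A `MetaResult` list: `pooled_beta`, `pooled_se`, `pooled_hr`,
#'   `ci95`, `p`, `tau2`, `Q`, `k`, `model`, plus the fixed-effect
#'   counterparts `fixed_beta`, `fixed_se`, `fixed_p`.
#' @export
meta_aggregate <- function(results, model = c("random", "fixed"),
                           cancer_type = NA_character_,
                           variable = NA_character_) {
  model <- match.arg(model)
  usable <- Filter(function(r) !isTRUE(r$monotone), results)
  if (length(usable) < length(results))
    warning(length(results) - length(usable),
            " monotone Cox fit(s) excluded from meta-analysis")
  k <- length(usable)
  if (k == 0L) stop("no usable Cox results to pool")
  b <- vapply(usable, `[[`, numeric(1), "beta")
  se <- vapply(usable, `[[`, numeric(1), "se")
  w <- 1 / se^2
  fixed_beta <- sum(w * b) / sum(w)
  fixed_se <- 1 / sqrt(sum(w))
  Q <- sum(w * (b - fixed_beta)^2)
  tau2 <- if (k > 1L) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  if (model == "random") {
    wr <- 1 / (se^2 + tau2)
    pooled_beta <- sum(wr * b) / sum(wr)
    pooled_se <- 1 / sqrt(sum(wr))
  } else {
    pooled_beta <- fixed_beta
    pooled_se <- fixed_se
  }
  pval <- function(est, s) 2 * stats::pnorm(-abs(est / s))
  list(cancer_type = cancer_type, variable = variable,
       pooled_beta = pooled_beta, pooled_se = pooled_se,
       pooled_hr = exp(pooled_beta),
       ci95 = c(low = exp(pooled_beta - 1.96 * pooled_se),
                high = exp(pooled_beta + 1.96 * pooled_se)),
       p = pval(pooled_beta, pooled_se),
       tau2 = tau2, Q = Q, k = k, model = model,
       fixed_beta = fixed_beta, fixed_se = fixed_se,
       fixed_p = pval(fixed_beta, fixed_se))
}
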