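# Shared fixtures and independent oracles, built in code at test time.

# --- planted-effect simulation scenarios -----------------------------------

# three genes outside the correlated block carry all the signal; clinical
# effects and the LRBA residual effect are switched off so the fitted model
# is the data-generating model
planted_beta <- c(RABEP1 = -0.2, FUT8 = -0.2, SCUBE2 = 0.2)

planted_config <- function(n = 225, seed = 1, beta = planted_beta, ...) {
  sim_config(n_patients = n, seed = seed,
             true_beta_os = beta, true_beta_dfs = beta,
             lrba_residual_beta = 0,
             stage_beta_os = rep(0, 4), stage_beta_dfs = rep(0, 4),
             er_pr_beta_os = rep(0, 4), er_pr_beta_dfs = rep(0, 4), ...)
}

# fuller follow-up for coefficient-recovery checks (more events, so the
# sampling error is small relative to the planted effects)
recovery_config <- function(n = 2000, seed = 1,
                            beta = c(RABEP1 = -0.3, FUT8 = -0.3, SCUBE2 = 0.3)) {
  planted_config(n = n, seed = seed, beta = beta,
                 baseline_hazard_os = 0.004, censor_rate = 0.002,
                 admin_horizon = 600)
}

# fully null cohort: no gene, residual or clinical effects
null_config <- function(n = 225, seed = 1, ...) {
  planted_config(n = n, seed = seed, beta = c(PGR = 0), ...)
}

# --- small hand-built survival data ----------------------------------------

toy_cohort <- function(n = 12, seed = 42) {
  generate_cohort(sim_config(n_patients = n, seed = seed))
}

# --- independent oracles ----------------------------------------------------

# exhaustive pair enumeration for Harrell's C (plain double loop, written
# directly from the pair rules; independent of the package implementation)
bf_harrell_c <- function(times, events, scores) {
  n <- length(times)
  num <- 0
  den <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      # identify the definitely-earlier failure, if any
      if (times[i] == times[j]) {
        if (events[i] + events[j] != 1) next  # 0 or 2 events at a tie: unordered
        first <- if (events[i] == 1) i else j
        second <- if (events[i] == 1) j else i
      } else {
        first <- if (times[i] < times[j]) i else j
        second <- if (times[i] < times[j]) j else i
        if (events[first] != 1) next  # earlier subject censored: unordered
      }
      den <- den + 1
      if (scores[first] > scores[second]) num <- num + 1
      else if (scores[first] == scores[second]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# split-variable convex reformulation of the L1-penalized partial likelihood,
# solved by a generic box-constrained quasi-Newton optimizer
oracle_cox_lasso <- function(X, times, events, lambda) {
  p <- ncol(X)
  obj <- function(bpm) {
    b <- bpm[1:p] - bpm[(p + 1):(2 * p)]
    -(cox_partial_loglik(b, X, times, events, ties = "breslow") -
        lambda * sum(bpm))
  }
  o <- stats::optim(rep(0, 2 * p), obj, method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 5000, factr = 1e3))
  list(beta = o$par[1:p] - o$par[(p + 1):(2 * p)], objective = -o$value)
}
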