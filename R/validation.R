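# Simulation studies validating the summary-level estimators against the
# generating truth and against individual-level reference fits.

#' Parameter-recovery study for the Wald-ratio estimator
#'
#' Repeatedly simulates cohorts with a known causal effect of the
#' exposure on fasting glucose, reduces each to per-SNP summary
#' statistics, runs the summary-level pipeline (score combination +
#' Wald ratio), and records the causal estimate, its delta-method SE and
#' whether the 95\% CI covers the truth. Optionally also fits two-stage
#' least squares on the individual-level data as an independent
#' cross-check of the summary-level estimate.
#'
#' The design is two-sample by default, mirroring the consortium setting
#' it emulates: the score-exposure effect comes from one cohort and the
#' score-outcome effect from an independent cohort, so the two sampling
#' errors are uncorrelated as the delta-method SE assumes. With
#' `two_sample = FALSE` both summaries come from the outcome cohort
#' (one-sample MR), where shared sampling error makes the delta-method CI
#' conservative for nonzero effects.
#'
#' @param theta true causal effect (per SD of exposure, linear scale).
#' @param n cohort size per replicate (each of the two cohorts).
#' @param reps number of replicates.
#' @param seed base seed; replicate r derives its cohort seeds from
#'   `seed + r`.
#' @param tsls also run the individual-level two-stage least-squares fit
#'   on the outcome cohort, together with the one-sample Wald ratio from
#'   that same cohort's summaries, for a like-for-like comparison.
#' @param two_sample draw exposure summaries from an independent cohort.
#' @param confounder_effect,reverse_effect passed to
#'   [simulation_config()].
#' @return data frame with one row per replicate: `beta_iv`, `se_iv`,
#'   `covered`, observational `beta_obs`, `se_obs`, `p_obs` (from the
#'   outcome cohort), and when requested `beta_iv_1s`, `se_iv_1s`,
#'   `beta_tsls`, `se_tsls`.
#' @export
recovery_study <- function(theta, n = 5000, reps = 500, seed = 1,
                           tsls = FALSE, two_sample = TRUE,
                           confounder_effect = c(0, 0),
                           reverse_effect = 0) {
  res <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg_out <- simulation_config(n = n,
                                 causal_effect = c(glucose = theta),
                                 confounder_effect = confounder_effect,
                                 reverse_effect = reverse_effect,
                                 seed = seed + 2L * r)
    coh_out <- simulate_cohort(cfg_out)
    out_sum <- gwas_summarize(coh_out, "glucose")
    if (two_sample) {
      cfg_exp <- simulation_config(n = n,
                                   causal_effect = c(glucose = theta),
                                   confounder_effect = confounder_effect,
                                   reverse_effect = reverse_effect,
                                   seed = seed + 2L * r + 1L)
      exp_sum <- gwas_summarize(simulate_cohort(cfg_exp), "exposure")
    } else {
      exp_sum <- gwas_summarize(coh_out, "exposure")
    }
    est <- wald_ratio(combine_score(exp_sum), combine_score(out_sum))
    obs <- observational_estimates(coh_out, "glucose")
    row <- data.frame(beta_iv = est$beta_iv, se_iv = est$se_iv,
                      covered = est$ci_low <= theta & theta <= est$ci_high,
                      beta_obs = obs$estimate, se_obs = obs$se,
                      p_obs = obs$p)
    if (tsls) {
      est1s <- wald_ratio(combine_score(gwas_summarize(coh_out, "exposure")),
                          combine_score(out_sum))
      iv_fit <- tsls_fit(coh_out$outcomes$glucose, coh_out$exposure,
                         rowSums(coh_out$genotypes))
      row$beta_iv_1s <- est1s$beta_iv
      row$se_iv_1s <- est1s$se_iv
      row$beta_tsls <- iv_fit$beta
      row$se_tsls <- iv_fit$se
    }
    res[[r]] <- row
  }
  do.call(rbind, res)
}

#' Monte-Carlo check of the delta-method ratio SE
#'
#' Draws the two score-level effects from normal distributions centered
#' at their point estimates with the stated SEs, forms the ratio in each
#' draw, and compares the empirical SD of the simulated ratio with the
#' first-order delta-method SE. The approximation is expected to hold
#' well for a strong instrument (|beta_exp/se_exp| large).
#'
#' @param beta_exp,se_exp,beta_out,se_out the two effects and SEs.
#' @param nsim number of Monte-Carlo draws.
#' @param seed RNG seed.
#' @return list with `mc_sd`, `delta` ([delta_se()] value) and `ratio`
#'   (`mc_sd / delta`).
#' @export
delta_se_mc <- function(beta_exp, se_exp, beta_out, se_out,
                        nsim = 200000, seed = 1) {
  set.seed(seed)
  bx <- stats::rnorm(nsim, beta_exp, se_exp)
  by <- stats::rnorm(nsim, beta_out, se_out)
  mc_sd <- stats::sd(by / bx)
  d <- delta_se(beta_exp, se_exp, beta_out, se_out)
  list(mc_sd = mc_sd, delta = d, ratio = mc_sd / d)
}
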