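test_that("cohort generation is deterministic given the config", {
  cfg <- simulation_config(n = 500, causal_effect = c(glucose = 0.2),
                           confounder_effect = c(0.3, 0.3), seed = 13)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
})

test_that("configuration errors are caught with informative messages", {
  expect_error(simulation_config(eafs = c(0.2, 0.5),
                                 snp_effects = c(0.1, 0.1, 0.1)),
               "length")
  expect_error(simulation_config(eafs = c(0.2, 1.5),
                                 snp_effects = c(0.1, 0.1)), "\\(0, 1\\)")
  expect_error(simulation_config(confounder_effect = c(1.2, 0)),
               "variance budget")
  expect_error(simulation_config(n = 0), "n must be")
})

test_that("genotypes are in Hardy-Weinberg equilibrium at the panel EAFs", {
  cfg <- simulation_config(n = 10000, seed = 21)
  coh <- simulate_cohort(cfg)
  for (j in seq_len(ncol(coh$genotypes))) {
    g <- coh$genotypes[, j]
    counts <- tabulate(g + 1L, nbins = 3L)
    phat <- mean(g) / 2
    expected <- cfg$n * c((1 - phat)^2, 2 * phat * (1 - phat), phat^2)
    chi2 <- sum((counts - expected)^2 / expected)
    expect_gt(pchisq(chi2, df = 1, lower.tail = FALSE), 0.001)
    # marginal frequency within binomial sampling error of the target
    expect_lt(abs(phat - cfg$eafs[j]),
              4 * sqrt(cfg$eafs[j] * (1 - cfg$eafs[j]) / (2 * cfg$n)))
  }
})

test_that("the exposure is SD-standardized within-sample", {
  coh <- simulate_cohort(simulation_config(n = 2000, seed = 3))
  expect_equal(sd(coh$exposure), 1, tolerance = 1e-12)
  expect_equal(mean(coh$exposure), 0, tolerance = 1e-12)
})

test_that("per-SNP exposure summaries recover the generating effects", {
  cfg <- simulation_config(n = 100000, seed = 17)
  coh <- simulate_cohort(cfg)
  summ <- gwas_summarize(coh, "exposure")
  expect_equal(summ$rsid, cfg$rsids)
  for (j in seq_len(5)) {
    expect_lt(abs(summ$beta[j] - cfg$snp_effects[j]), 3 * summ$se[j])
  }
  expect_lt(max(abs(summ$eaf - cfg$eafs)), 0.01)
})

test_that("a null instrument yields mostly non-significant score effects", {
  hits <- 0L
  n_seeds <- 60
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(n = 1016, snp_effects = rep(0, 5), seed = 300 + s)
    sc <- combine_score(gwas_summarize(simulate_cohort(cfg), "exposure"))
    if (sc$p < 0.05) hits <- hits + 1L
  }
  expect_lte(hits / n_seeds, 0.10)
})

test_that("the binary outcome hits its baseline prevalence and guards small counts", {
  coh <- simulate_cohort(simulation_config(n = 20000, seed = 8))
  expect_lt(abs(mean(coh$outcomes$t2d) - 0.12), 0.01)
  expect_equal(sort(unique(coh$outcomes$t2d)), c(0L, 1L))

  tiny <- simulate_cohort(simulation_config(n = 300, t2d_baseline_prev = 0.005,
                                            seed = 9))
  expect_error(gwas_summarize(tiny, "t2d"), "cases")
})

test_that("binary-trait summaries are lnOR from logistic fits", {
  cfg <- simulation_config(n = 30000, causal_effect = c(t2d = 0.6), seed = 31)
  coh <- simulate_cohort(cfg)
  summ <- gwas_summarize(coh, "t2d")
  expect_identical(attr(summ, "scale"), "lnor")
  # spot-check one SNP against a direct logistic fit
  fit <- glm(coh$outcomes$t2d ~ coh$genotypes[, 2], family = binomial())
  expect_equal(summ$beta[2], unname(coef(fit)[2]))
})

test_that("a monomorphic SNP is flagged and excluded from summaries", {
  cfg <- simulation_config(n = 400, eafs = c(0.3, 1 - 1e-9, 0.5),
                           snp_effects = c(0.1, 0.1, 0.1),
                           seed = 5)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$genotypes[, 2] == 2L))
  expect_warning(summ <- gwas_summarize(coh, "exposure"), "monomorphic")
  expect_equal(nrow(summ), 2)
  expect_equal(attr(summ, "excluded")$rsid, "snp2")
  expect_false("snp2" %in% summ$rsid)
})

test_that("observational regression is consistent absent confounding", {
  cfg <- simulation_config(n = 20000, causal_effect = c(glucose = 0.2),
                           seed = 41)
  obs <- observational_estimates(simulate_cohort(cfg), "glucose")
  expect_lt(abs(obs$estimate - 0.2), 3 * obs$se)
  expect_identical(obs$scale, "linear")
})

test_that("confounding and reverse causation bias the observational estimate only", {
  # pure confounding, no causal effect
  cfg <- simulation_config(n = 50000, confounder_effect = c(0.5, 0.5),
                           seed = 43)
  coh <- simulate_cohort(cfg)
  obs <- observational_estimates(coh, "glucose")
  expect_gt(obs$estimate / obs$se, 5)
  iv <- wald_ratio(combine_score(gwas_summarize(coh, "exposure")),
                   combine_score(gwas_summarize(coh, "glucose")))
  expect_true(iv$ci_low <= 0 && 0 <= iv$ci_high)

  # reverse causation, no causal effect
  cfg_r <- simulation_config(n = 50000, reverse_effect = 0.3, seed = 47)
  coh_r <- simulate_cohort(cfg_r)
  obs_r <- observational_estimates(coh_r, "glucose")
  expect_gt(obs_r$estimate / obs_r$se, 5)
  iv_r <- wald_ratio(combine_score(gwas_summarize(coh_r, "exposure")),
                     combine_score(gwas_summarize(coh_r, "glucose")))
  expect_true(iv_r$ci_low <= 0 && 0 <= iv_r$ci_high)

  # t2d observational OR is likewise confounded upward
  obs_t2d <- observational_estimates(coh, "t2d")
  expect_identical(obs_t2d$scale, "lnor")
  expect_gt(obs_t2d$estimate, 1)
})

test_that("configs round-trip through YAML and cohorts through TSV", {
  cfg <- simulation_config(n = 123, causal_effect = c(glucose = 0.25,
                                                      t2d = 0.1),
                           confounder_effect = c(0.2, 0.3),
                           reverse_effect = 0.05, seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n, cfg$n)
  expect_equal(back$eafs, cfg$eafs)
  expect_equal(back$causal_effect, cfg$causal_effect)
  expect_equal(back$confounder_effect, cfg$confounder_effect)
  expect_equal(back$seed, cfg$seed)
  expect_identical(simulate_cohort(back)$exposure,
                   simulate_cohort(cfg)$exposure)

  coh <- simulate_cohort(cfg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, tsv)
  df <- read.delim(tsv)
  expect_equal(nrow(df), 123)
  expect_equal(df$exposure, coh$exposure, tolerance = 1e-6)
  expect_true(all(cfg$rsids %in% names(df)))
})
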