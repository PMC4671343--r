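#!/usr/bin/env Rscript

# Recompute the summary-statistics MR analysis of homocysteine on T2D,
# fasting glucose and ln fasting insulin from the packaged five-SNP panel.
#
# What this run finds: the five-SNP score is a strong instrument for
# lnHcy (F ~ 390 from the printed 2-decimal per-SNP inputs; the source
# analysis reports F = 650 from unrounded data), and none of the three
# outcomes shows evidence of a causal effect: causal OR for T2D ~ 1.09
# (95% CI 0.92, 1.29), causal effects near zero for fasting glucose and
# ln fasting insulin. Score-level and causal estimates are written to
# results/, together with a cell-by-cell comparison against the published
# values flagging which cells are recoverable from printed inputs.

library(hcymr)
dir.create("results", showWarnings = FALSE)

report <- run_mr(panel_fixture("hcy"),
                 outcomes = list(t2d = panel_fixture("t2d"),
                                 glucose = panel_fixture("glucose"),
                                 insulin = panel_fixture("insulin")),
                 outcome_scales = c(t2d = "lnor", glucose = "linear",
                                    insulin = "linear"))
print(report)
write_mr_report(report, "results/panel_mr_report.json")

rows <- do.call(rbind, lapply(names(report$traits), function(nm) {
  blk <- report$traits[[nm]]
  data.frame(trait = nm, scale = blk$score$scale,
             score_beta = blk$score$beta, score_se = blk$score$se,
             score_p = blk$score$p,
             causal_beta = blk$causal$beta_iv, causal_se = blk$causal$se_iv,
             causal_ci_low = blk$causal$ci_low,
             causal_ci_high = blk$causal$ci_high, causal_p = blk$causal$p)
}))
write.table(rows, "results/panel_estimates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rp <- reproduce_published()
print(rp)
write.table(rp$comparison, "results/published_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("\nWrote results/panel_mr_report.json, results/panel_estimates.tsv,",
    "results/published_comparison.tsv\n")
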