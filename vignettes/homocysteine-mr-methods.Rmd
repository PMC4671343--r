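---
title: "Methods: summary-statistics Mendelian randomization of homocysteine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistics Mendelian randomization of homocysteine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the design

Observational studies have repeatedly associated elevated circulating
homocysteine (Hcy) with type 2 diabetes (T2D) and insulin resistance, but
such associations can arise from confounding (shared causes of Hcy and
glycemic state) or reverse causation (disease physiology altering Hcy).
Mendelian randomization (MR) sidesteps both by using genetic variants as
instrumental variables: alleles are allocated at conception, independent
of later confounders, so if variants that raise Hcy also raise T2D risk —
and affect T2D *only* through Hcy — the variant-outcome association
carries causal information about Hcy.

`hcymr` implements the two-sample, summary-statistics version of this
design for a panel of five SNPs from three Hcy-metabolism loci (*MTHFR*
×2, *MTR*, *CBS* ×2). "Two-sample" means the instrument-exposure effects
and the instrument-outcome effects come from different study populations,
as when one consortium's GWAS of Hcy supplies the exposure effects and
T2D/glycemic consortia supply the outcome effects. Restricting the panel
to pathway genes is the design's defense of the exclusion restriction:
variants in Hcy-metabolism enzymes are the least likely to carry
pleiotropic paths to diabetes.

The exposure is analyzed throughout in SD units of natural-log Hcy; T2D
effects are natural-log odds ratios (lnOR); fasting glucose is in mmol/L
and fasting insulin in ln units.

## Estimators

**Harmonization.** All estimation uses the Hcy-increasing allele as the
effect allele. Any exposure record with a negative beta is flipped (beta
negated, EAF complemented); an outcome record is flipped whenever its
stated effect allele disagrees with the harmonized exposure allele. The
summary tables this package consumes carry only the effect allele (the
source tables print no other allele), so a flipped record's new allele is
labelled `"other"`, and a disagreement is interpreted on the assumption
that both tables are forward-strand reports of the same biallelic SNP. A
complementary-base disagreement (A/T or C/G pair), which could equally be
a strand artifact, is flipped with a warning. A genuinely unresolvable
allele pair cannot arise under single-allele records; with two-allele
records it would be an error, and extending the reader is the natural
upgrade path if richer tables appear.

**Score combination.** The per-allele effect of the unweighted genetic
score on a trait is the inverse-variance-weighted mean of the per-SNP
effects,

$$\beta_{score} = \frac{\sum_i \beta_i s_i^{-2}}{\sum_i s_i^{-2}},
\qquad SE = \Big(\sum_i s_i^{-2}\Big)^{-1/2},$$

assuming the SNPs are independent (the two same-locus pairs in the panel
are independent association signals). This is the fixed-weight
approximation to regressing the trait on the allele-count score, and on
synthetic cohorts it agrees with that regression within sampling error.
Instrument strength is summarized as $F = z^2 = (\beta_{score}/SE)^2$.
The exact F definition used by summary-score software varies; $z^2$ is
the definition this package commits to, and it is asserted in tests as a
formula property rather than against any published F value.

**Wald ratio.** The causal effect of 1 SD of lnHcy on an outcome is

$$\beta_{IV} = \frac{\beta_{score,outcome}}{\beta_{score,Hcy}},$$

with the first-order delta-method standard error

$$SE_{IV} = |\beta_{IV}|\sqrt{\Big(\frac{s_{exp}}{\beta_{exp}}\Big)^2 +
\Big(\frac{s_{out}}{\beta_{out}}\Big)^2}.$$

The textbook form above is singular at $\beta_{out}=0$ although the
quantity it computes is not: the $1/\beta_{out}^2$ inside the root
cancels against $|\beta_{IV}|$. The implementation therefore evaluates
the algebraically identical
$\sqrt{\beta_{out}^2 s_{exp}^2/\beta_{exp}^4 + s_{out}^2/\beta_{exp}^2}$,
which is finite everywhere with $\beta_{exp}\neq 0$ and reduces to
$s_{out}/|\beta_{exp}|$ at a null outcome effect. Confidence intervals
are $\beta_{IV} \pm 1.96\,SE_{IV}$ (the 1.96 is used verbatim, matching
the reporting precision of the source analyses, not a higher-precision
quantile), and p-values come from the normal approximation. No
weak-instrument correction (e.g. Fieller intervals) is applied: the
panel's score-exposure association has $z \approx 20$–23, far from the
regime where the delta method misbehaves, and the Monte-Carlo check below
confirms it at this strength. lnOR-scale results are additionally
reported as odds ratios by exponentiating the estimate and CI.

**P-values at extreme z.** The score-exposure association has
$|z| > 19$; two-sided normal p-values are computed in log space
(`pnorm(log.p = TRUE)`) so they survive $|z| > 25$ without underflowing,
and are reported as exactly 0 only below $10^{-300}$.

## What is recoverable from printed inputs

The packaged panel transcribes the published per-SNP table, whose
exposure betas carry two decimals. From those inputs the score-exposure
effect is 0.088 (SE 0.0045) and $F \approx 387$; the published text
reports 0.092 and $F = 650$, computed from unrounded source data that was
never printed. The reproduction report therefore flags such cells as
"rounding-limited" rather than asserting equality; cells that are
recoverable at printed precision (the T2D score OR of 1.01, the causal OR
of 1.09 with lower bound 0.92, the insulin score effect printing as
−0.002, the glucose causal effect printing as 0.002) are flagged
"match". The same applies to the glucose score row (printed 0.0002,
recomputed −0.00008) and the insulin causal estimate (−0.019 published
from unrounded scores; −0.022 from printed ones). Causal estimates in
the reproduction are formed from the published score-level pairs, since
that is how the published ratios were produced; the package also reports
the fully recomputed chain from the per-SNP table.

## The synthetic cohort generator

No individual-level data ships with the package; a generator produces
cohorts with known causal structure so every stage — per-SNP regressions,
score combination, Wald ratios, and the observational comparison
regressions — can be validated against the truth.

Defaults emulate the population-based cohort the design contrasts
against: n = 1,016 individuals aged ~70 (half women), five biallelic
SNPs drawn as Binomial(2, EAF) at the panel frequencies (0.20, 0.34,
0.79, 0.55, 0.47) — Hardy-Weinberg equilibrium, no linkage
disequilibrium — and per-allele exposure effects (0.10, 0.16, 0.05,
0.07, 0.06 SD) from the panel. The exposure is built as genotypic score
+ confounder path + optional reverse-causation path + Gaussian noise,
with the noise variance chosen so the total variance is 1, then
standardized within-sample (empirical SD), matching the convention of
ln-transforming and SD-transforming measured Hcy. The implied variance
explained by the five SNPs is $\sum_i \beta_i^2\,2p_i(1-p_i) \approx
0.02$; this follows from the panel's published betas and EAFs and is a
derived default, not a quantity calibrated to any cohort (none was
published). Continuous outcomes are $\theta\,x + \gamma_y C + \epsilon$
with unit residual SD; the binary outcome is Bernoulli under
$\text{logit}(p) = \text{logit}(0.12) + \theta_{lnOR}\,x + \gamma_y C$,
the 12% intercept matching a baseline prevalence of about 119/1,016.
The marginal simulated prevalence sits within a percentage point of the
intercept value at these effect sizes.

Two misspecification pathways are built in. A standard-normal confounder
$C$ feeds both exposure (path $\gamma_x$) and outcomes (path
$\gamma_y$). A reverse-causation path feeds the *non-causal liability*
of one designated outcome (default fasting glucose) back into the
exposure: the outcome's noise realization is drawn first and enters both
the exposure and that outcome, which yields exposure-outcome association
without any exposure-to-outcome effect and without a circular structural
system. Draws occur in a fixed order (genotypes SNP by SNP, confounder,
reverse-liability noise, exposure noise, remaining outcome noise,
binary-outcome uniforms, age jitter, sex), so changing one effect size
does not reshuffle unrelated components, and identical configs are
bit-reproducible.

What the generator does **not** emulate: linkage disequilibrium between
the two same-locus SNP pairs (the design treats them as independent
signals; correlated instruments would require an LD-aware score
variance), population stratification, genotyping error or missingness,
assay noise in the exposure, non-Gaussian trait distributions, vitamin
B12/folate intake, and time-to-event outcomes. Passing the simulation
suite therefore shows the estimators are correct under the design's own
assumptions, not that those assumptions hold in any real cohort.

## Validation studies and their problem sizes

The calibration studies (run by `analysis/02`, `analysis/03` and the
acceptance suite) use 500 replicates per setting at n = 5,000 per
cohort — sizes chosen so Monte-Carlo error on a mean causal estimate is
~0.005, small enough to detect meaningful bias while keeping a full
calibration run in the order of a minute.

* **Parameter recovery.** At true effects $\theta \in \{0, 0.1, 0.3\}$
  on fasting glucose, the two-sample Wald ratio (exposure summaries from
  one cohort, outcome summaries from an independent one, as in the
  consortium setting) is unbiased within 3 Monte-Carlo SEs with 95% CI
  coverage close to nominal (0.946–0.964 in the shipped runs; the
  acceptance band is 0.92–0.975). The two-sample structure matters: with
  both summaries from one cohort their sampling errors correlate, and
  the delta-method CI — which assumes independence — becomes
  conservative for nonzero effects.
* **Confounding and reverse causation.** With $\gamma_x = \gamma_y =
  0.5$ and $\theta = 0$, the age/sex-adjusted observational regression
  reports a strong association (mean beta ~0.25, significant in
  essentially every replicate) while the IV estimate stays at zero; a
  reverse path of 0.3 produces the same signature. This is the
  qualitative pattern that lets a null causal estimate coexist with a
  robust observational association, as for insulin.
* **Delta-method adequacy.** At the published instrument strength
  (exposure effect 0.092, SE 0.004, z = 23), the delta-method SE of the
  T2D ratio matches the Monte-Carlo SD over 200,000 simulated effect
  pairs to within ~0.1% (tolerance 10%).
* **2SLS agreement.** On the same cohort, the summary-level Wald ratio
  and an individual-level two-stage least-squares fit (written in-package
  with the standard IV variance estimator, residuals from the observed
  exposure) differ by well under 2 combined SEs in every replicate.

## Scope and limitations

The package implements exactly the single-instrument (score-level) Wald
ratio: no per-SNP IVW meta-analysis, no pleiotropy-robust estimators
(MR-Egger, weighted median), no heterogeneity statistics, and no
weighted score — the design under study uses the unweighted score only.
Survival (incident-disease) outcomes and their proportional-hazards
analyses are out of scope, as are LD-proxy lookup, liftover and VCF
parsing; rsid matching is exact. EAF is carried through for the
simulator's benefit but no estimator uses it, so it may be absent.
Observational estimates on synthetic cohorts validate a *pattern*
(confounded association vs null IV), not any published cohort's numbers,
which would require individual-level data that was never deposited.
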