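# End-to-end orchestration: read -> harmonize -> combine -> Wald ratio,
# collected into a report mirroring the side-by-side layout of the source
# study's results table, plus a comparison against its printed values.

#' Run the full summary-statistics MR pipeline
#'
#' Reads (or accepts pre-loaded) exposure and outcome summary tables,
#' harmonizes them to the exposure-increasing allele, combines the
#' per-SNP effects into score-level effects, and forms a Wald-ratio
#' causal estimate per outcome. All values are stored unrounded; printing
#' applies display rounding only (2 significant figures for odds ratios,
#' 3 decimals for linear effects).
#'
#' @param exposure a file path or a [snp_assoc] table for the exposure.
#' @param outcomes named list of file paths or [snp_assoc] tables; may be
#'   empty, in which case only the score-on-exposure block is produced.
#' @param outcome_scales named character vector giving `"linear"` or
#'   `"lnor"` per outcome, used when `outcomes` entries are file paths.
#' @param or_input named logical vector: which outcome files report odds
#'   ratios needing log conversion at load time.
#' @return an `mr_report`: list with `exposure_score`, per-outcome blocks
#'   (`score` and `causal`), `provenance` (inputs, harmonization flips,
#'   dropped SNPs), and `weak_instrument` flag (score z < 3).
#' @export
run_mr <- function(exposure, outcomes = list(),
                   outcome_scales = NULL, or_input = NULL) {
  input_names <- list()
  if (is.character(exposure)) {
    input_names$exposure <- exposure
    exposure <- read_summary_table(exposure, scale = "linear",
                                   trait = "exposure")
  }
  stopifnot(inherits(exposure, "snp_assoc"))
  loaded <- list()
  for (nm in names(outcomes)) {
    o <- outcomes[[nm]]
    if (is.character(o)) {
      input_names[[nm]] <- o
      scl <- if (!is.null(outcome_scales) && nm %in% names(outcome_scales)) {
        outcome_scales[[nm]]
      } else {
        "linear"
      }
      o <- read_summary_table(
        o, scale = scl, trait = nm,
        or_input = !is.null(or_input) && isTRUE(or_input[[nm]]))
    }
    stopifnot(inherits(o, "snp_assoc"))
    loaded[[nm]] <- o
  }

  iset <- harmonize(exposure, loaded)
  exposure_score <- combine_score(iset$exposure)
  weak <- abs(exposure_score$z) < 3
  if (weak) {
    warning("weak instrument: score-exposure |z| = ",
            sprintf("%.2f", abs(exposure_score$z)), " < 3; ",
            "Wald-ratio estimates will be unreliable", call. = FALSE)
  }

  trait_blocks <- list()
  for (nm in names(iset$outcomes)) {
    sc <- combine_score(iset$outcomes[[nm]])
    trait_blocks[[nm]] <- list(score = sc,
                               causal = wald_ratio(exposure_score, sc))
  }

  structure(list(exposure_score = exposure_score,
                 traits = trait_blocks,
                 provenance = list(inputs = input_names,
                                   n_snps = length(iset$snps),
                                   snps = iset$snps,
                                   flips = iset$flips),
                 weak_instrument = weak),
            class = "mr_report")
}

#' @export
print.mr_report <- function(x, ...) {
  cat("=== Summary-statistics MR report ===\n")
  cat(sprintf("Instrument: %d SNPs; score effect on exposure: %.4g (se %.4g), F = %.4g\n",
              x$provenance$n_snps, x$exposure_score$beta,
              x$exposure_score$se, x$exposure_score$f_stat))
  if (x$weak_instrument) cat("!! WEAK INSTRUMENT (score z < 3)\n")
  for (nm in names(x$traits)) {
    blk <- x$traits[[nm]]
    cat("\n--", nm, "--\n")
    if (identical(blk$score$scale, "lnor")) {
      sv <- score_odds_ratio(blk$score)
      cat(sprintf("  score (per allele): OR %.2f (95%% CI %.2f, %.2f), p = %.2g\n",
                  sv$or, sv$ci_low, sv$ci_high, blk$score$p))
      ov <- blk$causal$or_view
      cat(sprintf("  causal (per SD exposure): OR %.2f (95%% CI %.2f, %.2f), p = %.2g\n",
                  ov$or, ov$ci_low, ov$ci_high, blk$causal$p))
    } else {
      cat(sprintf("  score (per allele): beta %.3f (95%% CI %.3f, %.3f), p = %.2g\n",
                  blk$score$beta, blk$score$beta - 1.96 * blk$score$se,
                  blk$score$beta + 1.96 * blk$score$se, blk$score$p))
      cat(sprintf("  causal (per SD exposure): beta %.3f (95%% CI %.3f, %.3f), p = %.2g\n",
                  blk$causal$beta_iv, blk$causal$ci_low, blk$causal$ci_high,
                  blk$causal$p))
    }
  }
  if (nrow(x$provenance$flips) > 0) {
    cat("\nHarmonization actions:\n")
    print(x$provenance$flips, row.names = FALSE)
  }
  invisible(x)
}

report_to_list <- function(x) {
  strip <- function(se) se[c("beta", "se", "z", "p", "f_stat", "n_snps",
                             "trait", "scale")]
  out <- list(exposure_score = strip(x$exposure_score),
              traits = lapply(x$traits, function(blk) {
                cb <- blk$causal
                list(score = strip(blk$score),
                     causal = cb[c("beta_iv", "se_iv", "ci_low", "ci_high",
                                   "p", "scale", "or_view")])
              }),
              provenance = x$provenance,
              weak_instrument = x$weak_instrument)
  out
}

#' Serialize an MR report to JSON
#'
#' Unrounded values only; display rounding never enters the JSON stream,
#' so the machine-readable and human-readable outputs agree on every
#' stored quantity. Byte-identical across re-runs with identical inputs.
#'
#' @param x an `mr_report`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
write_mr_report <- function(x, path = NULL) {
  js <- jsonlite::toJSON(report_to_list(x), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

# printed reference values from the published analysis this package
# re-derives, each with the number of printed decimals so agreement can be
# judged at printed precision
published_reference <- function() {
  ref <- function(value, decimals) list(value = value, decimals = decimals)
  list(
    hcy_score_beta     = ref(0.092, 3),
    hcy_score_se       = ref(0.004, 3),
    hcy_score_f        = ref(650, 0),
    t2d_score_or       = ref(1.01, 2),
    glucose_score_beta = ref(0.0002, 4),
    insulin_score_beta = ref(-0.002, 3),
    t2d_causal_or      = ref(1.09, 2),
    t2d_causal_or_low  = ref(0.92, 2),
    t2d_causal_or_high = ref(1.30, 2),
    glucose_causal_beta = ref(0.002, 3),
    insulin_causal_beta = ref(-0.019, 3)
  )
}

# score-level effects exactly as printed in the published results, used for
# the causal-estimate reproduction (the published Wald ratios were formed
# from these unrounded-source score effects, not from the rounded per-SNP
# table this package recomputes from)
published_score_effects <- function() {
  se_of <- function(beta, se, trait, scale) {
    z <- beta / se
    structure(list(beta = beta, se = se, z = z, p = norm_p2(z),
                   f_stat = z^2, n_snps = 5L, trait = trait, scale = scale),
              class = "score_effect")
  }
  list(exposure = se_of(0.092, 0.004, "exposure", "linear"),
       t2d = se_of(0.008, 0.008, "t2d", "lnor"),
       glucose = se_of(0.0002, 0.002, "glucose", "linear"),
       insulin = se_of(-0.002, 0.002, "insulin", "linear"))
}

#' Reproduce the published analysis from the packaged panel
#'
#' Runs [run_mr()] on the packaged five-SNP summary tables and sets the
#' recomputed quantities side by side with the published values, flagging
#' each cell `"match"` when the recomputation agrees at the published
#' printed precision and `"rounding-limited"` when it cannot (the
#' published score-exposure effect 0.092 and F = 650 derive from
#' unrounded source data, while the packaged tables carry the printed
#' 2-decimal effects, which yield 0.088 and F near 390). Causal estimates
#' are additionally formed from the published score-level pairs, since
#' that is how the published Wald ratios were produced.
#'
#' @return list with `report` (the [run_mr()] result from the packaged
#'   tables), `published_pair_causal` (Wald ratios from the published
#'   score-level effects), and `comparison` (data frame: quantity,
#'   recomputed, published, flag).
#' @export
reproduce_published <- function() {
  report <- run_mr(
    panel_fixture("hcy"),
    outcomes = list(t2d = panel_fixture("t2d"),
                    glucose = panel_fixture("glucose"),
                    insulin = panel_fixture("insulin")),
    outcome_scales = c(t2d = "lnor", glucose = "linear", insulin = "linear"))

  pub_scores <- published_score_effects()
  pair_causal <- list(
    t2d = wald_ratio(pub_scores$exposure, pub_scores$t2d),
    glucose = wald_ratio(pub_scores$exposure, pub_scores$glucose),
    insulin = wald_ratio(pub_scores$exposure, pub_scores$insulin))

  ref <- published_reference()
  recomputed <- list(
    hcy_score_beta = report$exposure_score$beta,
    hcy_score_se = report$exposure_score$se,
    hcy_score_f = report$exposure_score$f_stat,
    t2d_score_or = score_odds_ratio(report$traits$t2d$score)$or,
    glucose_score_beta = report$traits$glucose$score$beta,
    insulin_score_beta = report$traits$insulin$score$beta,
    t2d_causal_or = pair_causal$t2d$or_view$or,
    t2d_causal_or_low = pair_causal$t2d$or_view$ci_low,
    t2d_causal_or_high = pair_causal$t2d$or_view$ci_high,
    glucose_causal_beta = pair_causal$glucose$beta_iv,
    insulin_causal_beta = pair_causal$insulin$beta_iv)

  rows <- lapply(names(ref), function(q) {
    pub <- ref[[q]]
    rec <- recomputed[[q]]
    tol <- 0.5 * 10^(-pub$decimals)
    data.frame(quantity = q, recomputed = rec, published = pub$value,
               flag = if (abs(rec - pub$value) <= tol) "match" else
                 "rounding-limited",
               stringsAsFactors = FALSE)
  })
  comparison <- do.call(rbind, rows)
  structure(list(report = report, published_pair_causal = pair_causal,
                 comparison = comparison),
            class = "mr_reproduction")
}

#' @export
print.mr_reproduction <- function(x, ...) {
  cat("Reproduction of the published summary-statistics MR analysis\n")
  cat("(recomputed from the packaged per-SNP panel; causal rows from the\n")
  cat(" published score-level pairs)\n\n")
  df <- x$comparison
  df$recomputed <- signif(df$recomputed, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
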