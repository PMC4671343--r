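# Summary-level association of the unweighted allele-count score with a
# trait, combined from per-SNP associations by inverse-variance weighting.

#' Two-sided normal p-value, safe for very large |z|
#'
#' Computed in log space so score-exposure associations with |z| > 25 keep
#' a representable p-value instead of underflowing; values below 1e-300
#' are reported as 0.
#' @param z z-statistic.
#' @return two-sided p-value.
#' @keywords internal
norm_p2 <- function(z) {
  logp <- stats::pnorm(-abs(z), log.p = TRUE) + log(2)
  p <- exp(logp)
  p[logp < -300 * log(10)] <- 0
  p
}

#' Combine per-SNP associations into the score's per-allele effect
#'
#' The per-allele effect of the unweighted genetic score on a trait is the
#' inverse-variance-weighted mean of the per-SNP effects,
#' \deqn{\beta_{score} = \sum_i \beta_i s_i^{-2} / \sum_i s_i^{-2},}
#' with standard error \eqn{(\sum_i s_i^{-2})^{-1/2}}, assuming the SNPs
#' are mutually independent. This is the fixed-weight summary-level
#' approximation to regressing the trait on the allele-count score.
#' The instrument-strength F-statistic is taken as \eqn{z^2}.
#'
#' @param assocs a [snp_assoc] table (harmonized to the
#'   exposure-increasing allele for MR use).
#' @return a `score_effect`: list with `beta`, `se`, `z`, `p`, `f_stat`,
#'   `n_snps`, plus the trait name and scale.
#' @export
combine_score <- function(assocs) {
  df <- as.data.frame(assocs)
  if (nrow(df) == 0) stop("cannot combine an empty association table",
                          call. = FALSE)
  if (any(!is.finite(df$se) | df$se <= 0)) {
    stop("standard errors must be > 0; offending rsid(s): ",
         paste(df$rsid[!is.finite(df$se) | df$se <= 0], collapse = ", "),
         call. = FALSE)
  }
  w <- 1 / df$se^2
  beta <- sum(df$beta * w) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- beta / se
  structure(list(beta = beta, se = se, z = z, p = norm_p2(z),
                 f_stat = z^2, n_snps = nrow(df),
                 trait = attr(assocs, "trait") %||% "trait",
                 scale = attr(assocs, "scale") %||% "linear"),
            class = "score_effect")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Odds-ratio view of a score effect
#'
#' Exponentiates an lnOR-scale score effect into a per-allele odds ratio
#' with a 95\% Wald confidence interval (1.96 normal quantile, matching
#' the reporting convention of the source meta-analyses).
#'
#' @param effect a `score_effect` on the lnOR scale.
#' @return list with `or`, `ci_low`, `ci_high`.
#' @export
score_odds_ratio <- function(effect) {
  stopifnot(inherits(effect, "score_effect"))
  if (!identical(effect$scale, "lnor")) {
    stop("trait '", effect$trait,
         "' is on a linear scale; an odds-ratio view is undefined",
         call. = FALSE)
  }
  list(or = exp(effect$beta),
       ci_low = exp(effect$beta - 1.96 * effect$se),
       ci_high = exp(effect$beta + 1.96 * effect$se))
}

#' @export
print.score_effect <- function(x, ...) {
  cat(sprintf("Score effect on %s (%s scale, %d SNPs)\n",
              x$trait, x$scale, x$n_snps))
  cat(sprintf("  beta = %.4g  se = %.4g  z = %.3g  p = %.3g  F = %.4g\n",
              x$beta, x$se, x$z, x$p, x$f_stat))
  if (identical(x$scale, "lnor")) {
    orv <- score_odds_ratio(x)
    cat(sprintf("  per-allele OR = %.3g (95%% CI %.3g, %.3g)\n",
                orv$or, orv$ci_low, orv$ci_high))
  }
  invisible(x)
}
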