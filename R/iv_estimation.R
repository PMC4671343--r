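# Wald-ratio instrumental-variable estimation from two score-level effects.

#' Delta-method standard error of a Wald ratio
#'
#' First-order Taylor (delta-method) standard error of the ratio
#' \eqn{\beta_{IV} = \beta_{out}/\beta_{exp}}:
#' \deqn{SE_{IV} = |\beta_{IV}| \sqrt{(s_{exp}/\beta_{exp})^2 +
#'   (s_{out}/\beta_{out})^2}.}
#' The textbook form is singular at \eqn{\beta_{out} = 0}, where the
#' division inside the square root cancels against \eqn{|\beta_{IV}|}; the
#' implementation uses the algebraically equivalent
#' \deqn{\sqrt{\beta_{out}^2 s_{exp}^2/\beta_{exp}^4 +
#'   s_{out}^2/\beta_{exp}^2},}
#' finite everywhere with \eqn{\beta_{exp} \neq 0} and identical to the
#' textbook form when \eqn{\beta_{out} \neq 0} (limit
#' \eqn{s_{out}/|\beta_{exp}|} at a null outcome effect).
#'
#' @param beta_exp,se_exp instrument-exposure effect and its SE.
#' @param beta_out,se_out instrument-outcome effect and its SE.
#' @return the delta-method SE of the ratio.
#' @export
delta_se <- function(beta_exp, se_exp, beta_out, se_out) {
  if (se_exp < 0 || se_out < 0) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  if (beta_exp == 0) {
    stop("instrument-exposure effect is zero; the ratio SE is undefined",
         call. = FALSE)
  }
  sqrt(beta_out^2 * se_exp^2 / beta_exp^4 + se_out^2 / beta_exp^2)
}

#' Wald-ratio causal estimate
#'
#' Forms the instrumental-variable estimate of the causal effect of one
#' SD of the (log-transformed, standardized) exposure on the outcome as
#' the ratio of the two score-level effects,
#' \eqn{\beta_{IV} = \beta_{score,out} / \beta_{score,exp}}, with a
#' delta-method standard error ([delta_se()]), a 95\% Wald confidence
#' interval and a normal-approximation p-value. For an lnOR-scale outcome
#' an odds-ratio view (exp-transformed estimate and CI) is attached.
#'
#' @param exposure_effect,outcome_effect `score_effect` objects from
#'   [combine_score()] (or lists with `beta`, `se`, and for the outcome a
#'   `scale` of `"linear"` or `"lnor"`).
#' @return a `causal_estimate`: list with `beta_iv`, `se_iv`, `ci_low`,
#'   `ci_high`, `p`, `or_view` (present iff the outcome is lnOR-scale),
#'   and the two inputs.
#' @export
wald_ratio <- function(exposure_effect, outcome_effect) {
  bx <- exposure_effect$beta
  sx <- exposure_effect$se
  by <- outcome_effect$beta
  sy <- outcome_effect$se
  if (bx == 0) {
    stop("weak instrument: the score-exposure effect is zero, ",
         "the Wald ratio is undefined", call. = FALSE)
  }
  if (sx < 0 || sy < 0) stop("standard errors must be non-negative",
                             call. = FALSE)
  beta_iv <- by / bx
  se_iv <- delta_se(bx, sx, by, sy)
  z <- if (se_iv > 0) beta_iv / se_iv else sign(beta_iv) * Inf
  scale <- outcome_effect$scale %||% "linear"
  est <- list(beta_iv = beta_iv, se_iv = se_iv,
              ci_low = beta_iv - 1.96 * se_iv,
              ci_high = beta_iv + 1.96 * se_iv,
              p = if (beta_iv == 0 && se_iv == 0) 1 else norm_p2(z),
              outcome = outcome_effect$trait %||% "outcome",
              scale = scale,
              or_view = NULL,
              inputs = list(exposure = exposure_effect,
                            outcome = outcome_effect))
  if (identical(scale, "lnor")) {
    est$or_view <- list(or = exp(beta_iv),
                        ci_low = exp(est$ci_low),
                        ci_high = exp(est$ci_high))
  }
  structure(est, class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("Causal effect of 1 SD exposure on %s (%s scale)\n",
              x$outcome, x$scale))
  cat(sprintf("  beta_iv = %.4g  se = %.4g  95%% CI (%.4g, %.4g)  p = %.3g\n",
              x$beta_iv, x$se_iv, x$ci_low, x$ci_high, x$p))
  if (!is.null(x$or_view)) {
    cat(sprintf("  causal OR = %.3g (95%% CI %.3g, %.3g)\n",
                x$or_view$or, x$or_view$ci_low, x$or_view$ci_high))
  }
  invisible(x)
}

#' Two-stage least squares on individual-level data
#'
#' Reference instrumental-variable fit used to cross-check the
#' summary-level Wald ratio on synthetic cohorts: stage one regresses the
#' exposure on the instrument (the unweighted allele-count score), stage
#' two regresses the outcome on the fitted exposure, with the standard
#' IV variance estimate using residuals formed from the observed exposure.
#'
#' @param y outcome vector (continuous).
#' @param x exposure vector.
#' @param z instrument vector (allele-count score).
#' @return list with `beta`, `se`.
#' @export
tsls_fit <- function(y, x, z) {
  stopifnot(length(y) == length(x), length(x) == length(z))
  n <- length(y)
  if (stats::var(z) == 0) stop("instrument has zero variance", call. = FALSE)
  stage1 <- stats::lm.fit(cbind(1, z), x)
  xhat <- stage1$fitted.values
  stage2 <- stats::lm.fit(cbind(1, xhat), y)
  beta <- stage2$coefficients[2]
  u <- y - cbind(1, x) %*% stage2$coefficients
  sigma2 <- sum(u^2) / (n - 2)
  se <- sqrt(sigma2 / sum((xhat - mean(xhat))^2))
  list(beta = unname(beta), se = unname(se))
}
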