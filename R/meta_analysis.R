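# DerSimonian-Laird random-effects meta-analysis of per-study odds
# ratios supplied as OR + 95% CI. Between-study variance tau^2 is the
# method-of-moments estimate from Cochran's Q, truncated at zero; with
# tau^2 = 0 the pooled estimate reduces to fixed-effect inverse-variance
# weighting.

#' Log odds ratio and standard error from a reported OR and 95% CI
#'
#' Inverts the Wald interval: `theta = ln OR`,
#' `SE = (ln hi - ln lo) / (2 * 1.96)`. The multiplier is fixed at 1.96
#' (the conventional reporting value), matching how published intervals
#' are constructed.
#'
#' @param or odds ratio.
#' @param lo,hi 95% confidence limits.
#' @return list with `theta` and `se`.
#' @export
se_from_ci <- function(or, lo, hi) {
  if (any(c(or, lo, hi) <= 0)) stop_ps("OR and CI limits must be positive")
  if (!(lo <= or && or <= hi)) stop_ps("need lo <= OR <= hi")
  se <- (log(hi) - log(lo)) / (2 * 1.96)
  if (se <= 0) stop_ps("degenerate interval: SE must be positive")
  list(theta = log(or), se = se)
}

#' Build a study-effects table from ORs and confidence intervals
#'
#' @param study study labels.
#' @param or,ci_lo,ci_hi per-study odds ratios and 95% limits.
#' @return data.frame with `study`, `or`, `ci_lo`, `ci_hi`, `theta`,
#'   `se`.
#' @export
study_effects <- function(study, or, ci_lo, ci_hi) {
  stopifnot(length(study) == length(or), length(or) == length(ci_lo),
            length(or) == length(ci_hi))
  conv <- Map(se_from_ci, or, ci_lo, ci_hi)
  data.frame(study = study, or = or, ci_lo = ci_lo, ci_hi = ci_hi,
             theta = vapply(conv, `[[`, numeric(1), "theta"),
             se = vapply(conv, `[[`, numeric(1), "se"),
             stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Fixed weights `w_i = 1/SE_i^2` give Cochran's
#' `Q = sum w_i (theta_i - theta_fixed)^2`;
#' `tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`;
#' random-effects weights `w*_i = 1 / (SE_i^2 + tau^2)` yield the pooled
#' log OR, its standard error `1/sqrt(sum w*)`, a 95% CI (z = 1.96), the
#' z statistic and the two-sided normal p-value. Heterogeneity is
#' reported as Q and `I^2 = max(0, (Q - df)/Q)`.
#'
#' @param effects data.frame from [study_effects()] (needs `theta` and
#'   `se`; `study` labels optional).
#' @return list of class `dl_meta`: `k`, `or`, `ci_lo`, `ci_hi`,
#'   `theta`, `se`, `z`, `p`, `Q`, `df`, `tau2`, `I2`, and `studies`
#'   (the input with fixed/random weights and percent weights).
#' @export
dl_meta <- function(effects) {
  if (nrow(effects) < 2L) stop_ps("meta-analysis needs at least 2 studies")
  if (any(effects$se <= 0)) stop_ps("all standard errors must be positive")
  th <- effects$theta
  w <- 1 / effects$se^2
  k <- length(th)
  theta_fixed <- sum(w * th) / sum(w)
  Q <- sum(w * (th - theta_fixed)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (effects$se^2 + tau2)
  theta <- sum(ws * th) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  z <- theta / se
  studies <- effects
  studies$w_fixed <- w
  studies$w_random <- ws
  studies$weight_pct <- 100 * ws / sum(ws)
  structure(list(
    k = k, or = exp(theta), ci_lo = exp(theta - 1.96 * se),
    ci_hi = exp(theta + 1.96 * se), theta = theta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), Q = Q, df = k - 1L, tau2 = tau2,
    I2 = if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0,
    studies = studies
  ), class = "dl_meta")
}

#' @export
print.dl_meta <- function(x, ...) {
  cat(sprintf("DerSimonian-Laird random-effects meta-analysis (%d studies)\n",
              x$k))
  cat(sprintf("  pooled OR %.3f (95%% CI %.3f-%.3f)\n", x$or, x$ci_lo, x$ci_hi))
  cat(sprintf("  z = %.2f, p = %.3f\n", x$z, x$p))
  cat(sprintf("  Q = %.3f (df %d), tau^2 = %.4f, I^2 = %.1f%%\n",
              x$Q, x$df, x$tau2, 100 * x$I2))
  invisible(x)
}
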