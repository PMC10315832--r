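# Causal estimation: Wald ratio, fixed-effect IVW, odds-ratio reporting.

.usablePairs <- function(pairs) {
  pairs[pairs$status %in% c("ok", "flipped") &
          !is.na(pairs$beta_exp) & !is.na(pairs$beta_out) &
          !is.na(pairs$se_out), , drop = FALSE]
}

#' Wald-ratio causal estimate from a single instrument
#'
#' beta = beta_out / beta_exp, with the first-order delta-method standard
#' error se_out / |beta_exp| and a two-sided normal p-value. The estimate is
#' invariant to recoding the effect allele (negating both betas).
#'
#' @param pair a one-row harmonized data.frame (see [harmonize()]) with
#'   status `ok` or `flipped`.
#' @param exposure_id,outcome_id trait labels for the result.
#' @return An [MRResult-class] with method `wald_ratio`.
#' @export
waldRatio <- function(pair, exposure_id = "exposure", outcome_id = "outcome") {
  pair <- .usablePairs(pair)
  if (nrow(pair) != 1L) .stopf("waldRatio needs exactly one usable pair")
  if (pair$beta_exp == 0) .stopf("exposure effect is zero; Wald ratio undefined")
  beta <- pair$beta_out / pair$beta_exp
  se <- pair$se_out / abs(pair$beta_exp)
  .MRResult(exposure_id, outcome_id, "wald_ratio", beta, se,
            .zToP(beta / se), 1L)
}

#' Fixed-effect inverse-variance-weighted causal estimate
#'
#' Combines per-instrument Wald ratios b_i (first-order standard errors s_i)
#' with weights 1/s_i^2: beta = sum(b_i/s_i^2) / sum(1/s_i^2),
#' se = sqrt(1 / sum(1/s_i^2)). Cochran's Q across the ratios is computed and
#' stored; with `random_effects = TRUE` the standard error is inflated by
#' sqrt(max(1, Q/(k-1))) (multiplicative random effects).
#'
#' @param pairs harmonized data.frame with at least two usable rows.
#' @param exposure_id,outcome_id trait labels.
#' @param random_effects inflate the standard error by the heterogeneity
#'   factor (default `FALSE`, the minimal fixed-effect reading).
#' @return An [MRResult-class] with method `ivw`.
#' @export
mrIVW <- function(pairs, exposure_id = "exposure", outcome_id = "outcome",
                  random_effects = FALSE) {
  pairs <- .usablePairs(pairs)
  if (any(pairs$beta_exp == 0)) {
    warning("dropping instrument(s) with zero exposure effect")
    pairs <- pairs[pairs$beta_exp != 0, , drop = FALSE]
  }
  if (nrow(pairs) < 2L) .stopf("mrIVW needs at least two usable instruments")
  b <- pairs$beta_out / pairs$beta_exp
  s <- pairs$se_out / abs(pairs$beta_exp)
  w <- 1 / s^2
  beta <- sum(w * b) / sum(w)
  se <- sqrt(1 / sum(w))
  k <- length(b)
  q <- sum(w * (b - beta)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  if (random_effects) se <- se * sqrt(max(1, q / (k - 1)))
  .MRResult(exposure_id, outcome_id, "ivw", beta, se, .zToP(beta / se),
            k, q_stat = q, q_pvalue = q_p)
}

#' Dispatch the appropriate MR estimator
#'
#' One usable instrument gives the Wald ratio; two or more give IVW.
#' Instruments with a zero exposure effect are dropped with a warning; an
#' empty usable set is an error (callers that must tolerate it should use
#' [mrNotTestable()]).
#'
#' @param pairs harmonized data.frame (see [harmonize()]).
#' @param exposure_id,outcome_id trait labels.
#' @param random_effects see [mrIVW()].
#' @return An [MRResult-class].
#' @export
mrEstimate <- function(pairs, exposure_id = "exposure", outcome_id = "outcome",
                       random_effects = FALSE) {
  usable <- .usablePairs(pairs)
  if (any(usable$beta_exp == 0) && nrow(usable) > 1L) {
    warning("dropping instrument(s) with zero exposure effect")
    usable <- usable[usable$beta_exp != 0, , drop = FALSE]
  }
  if (nrow(usable) == 0L) .stopf("no usable instrument after harmonization")
  if (nrow(usable) == 1L)
    waldRatio(usable, exposure_id, outcome_id)
  else
    mrIVW(usable, exposure_id, outcome_id, random_effects = random_effects)
}

#' Explicit not-testable MR result
#'
#' Marker returned when an analysis (e.g. bidirectional MR) has no surviving
#' instruments; it is reported, never silently treated as a pass, and counts
#' as non-significant wherever a significance rule is applied.
#'
#' @param exposure_id,outcome_id trait labels.
#' @return An [MRResult-class] with method `not_testable` and `nSnps()` 0.
#' @export
mrNotTestable <- function(exposure_id = "exposure", outcome_id = "outcome") {
  .MRResult(exposure_id, outcome_id, "not_testable",
            NA_real_, NA_real_, NA_real_, 0L)
}

#' Odds ratio with 95\% Wald confidence interval
#'
#' @param beta log odds ratio.
#' @param se its standard error (> 0).
#' @return Named numeric: `or`, `ci_low`, `ci_high`
#'   (exp(beta -/+ 1.959964 se)).
#' @examples
#' toOddsRatio(-0.1278, 0.0232)  # OR ~0.88 (0.84-0.92)
#' @export
toOddsRatio <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) .stopf("se must be > 0")
  c(or = exp(beta), ci_low = exp(beta - .CI_Z * se),
    ci_high = exp(beta + .CI_Z * se))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (>= 1).
#' @return alpha / n_tests.
#' @examples
#' bonferroniThreshold(0.05, 2004)  # 2.495e-05
#' @export
bonferroniThreshold <- function(alpha = 0.05, n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1)
    .stopf("n_tests must be a single integer >= 1")
  alpha / n_tests
}
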