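# Bayesian colocalization under the single-causal-variant model.

#' Wakefield log approximate Bayes factor
#'
#' For a variant with estimate `beta`, standard error `se` (variance
#' V = se^2) and effect-size prior N(0, W = prior_sd^2):
#' log ABF = 0.5 * (log(V / (V + W)) + z^2 * W / (V + W)), z = beta / se.
#' Equivalently 0.5 * (log(1 - r) + z^2 r) with r = W / (V + W).
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), > 0.
#' @param prior_sd prior standard deviation of the true effect
#'   (0.15 is the conventional default for a quantitative trait on the SD
#'   scale, 0.2 for a binary trait on the log-odds scale).
#' @return log ABF, vectorized.
#' @examples
#' wakefieldLABF(0.1, 0.02, 0.2)  # ~10.07
#' @export
wakefieldLABF <- function(beta, se, prior_sd) {
  if (any(is.na(se)) || any(se <= 0)) .stopf("se must be > 0")
  if (any(prior_sd <= 0)) .stopf("prior_sd must be > 0")
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * (log1p(-r) + (beta / se)^2 * r)
}

.asColocRegion <- function(x) {
  df <- .asVariantTable(x)
  if (!all(c("variant_id", "beta", "se") %in% names(df)))
    .stopf("a colocalization region needs variant_id, beta and se")
  df
}

#' Bayesian colocalization of two traits over one region
#'
#' Computes per-variant Wakefield log approximate Bayes factors for each
#' trait and enumerates the five single-causal-variant hypotheses: H0 no
#' association, H1/H2 one trait only, H3 two distinct causal variants, H4 a
#' shared causal variant. With per-variant log ABFs l1, l2 the unnormalized
#' hypothesis masses are 1, p1*S1, p2*S2, p1*p2*(S1*S2 - S12) and p12*S12,
#' where S1 = sum exp(l1), S2 = sum exp(l2), S12 = sum exp(l1 + l2); all sums
#' are taken in log space (log ABFs routinely exceed 700) and the posteriors
#' are the normalized masses.
#'
#' @param region_exp,region_out the two traits' associations over the same
#'   variant set: [SummaryStats-class] objects or data.frames with
#'   `variant_id`, `beta`, `se`. The sets must be equal; `region_out` is
#'   reordered to match.
#' @param p1,p2,p12 per-variant prior probabilities that a variant is causal
#'   for trait 1 only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5).
#'   Requires 0 < p12 <= min(p1, p2) and n * (p1 + p2 + p12) < 1.
#' @param prior_sd_exp,prior_sd_out effect-size prior standard deviations;
#'   when a region is a [SummaryStats-class] the default follows its trait
#'   type (0.15 quantitative, 0.2 binary), otherwise 0.15/0.2.
#' @param pph4_threshold PPH4 cutoff for the colocalization call
#'   (default 0.8, strict inequality).
#' @return A [ColocResult-class].
#' @export
colocABF <- function(region_exp, region_out, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                     prior_sd_exp = NULL, prior_sd_out = NULL,
                     pph4_threshold = 0.8) {
  if (is.null(prior_sd_exp))
    prior_sd_exp <- if (methods::is(region_exp, "SummaryStats") &&
                          traitType(region_exp) == "binary") 0.2 else 0.15
  if (is.null(prior_sd_out))
    prior_sd_out <- if (methods::is(region_out, "SummaryStats") &&
                          traitType(region_out) == "binary") 0.2 else
                      if (methods::is(region_out, "SummaryStats")) 0.15 else 0.2
  e <- .asColocRegion(region_exp)
  o <- .asColocRegion(region_out)
  if (nrow(e) == 0) .stopf("empty colocalization region")
  if (!setequal(e$variant_id, o$variant_id) || nrow(e) != nrow(o))
    .stopf("the two regions must cover the same variant set")
  o <- o[match(e$variant_id, o$variant_id), , drop = FALSE]
  n <- nrow(e)
  if (p12 <= 0 || p12 > min(p1, p2))
    .stopf("priors must satisfy 0 < p12 <= min(p1, p2)")
  if (n * (p1 + p2 + p12) >= 1)
    .stopf("priors too large for the region: n * (p1 + p2 + p12) must be < 1")

  l1 <- wakefieldLABF(e$beta, e$se, prior_sd_exp)
  l2 <- wakefieldLABF(o$beta, o$se, prior_sd_out)
  s1 <- logSumExp(l1)
  s2 <- logSumExp(l2)
  s12 <- logSumExp(l1 + l2)

  lh <- c(h0 = 0,
          h1 = log(p1) + s1,
          h2 = log(p2) + s2,
          h3 = NA_real_,
          h4 = log(p12) + s12)
  # S1*S2 - S12 in log space; the difference is 0 for a 1-variant region
  d <- s12 - (s1 + s2)
  lh["h3"] <- if (d >= 0) -Inf else log(p1) + log(p2) + s1 + s2 + log1p(-exp(d))
  post <- exp(lh - logSumExp(lh))
  post <- pmin(pmax(post, 0), 1)
  post <- post / sum(post)
  names(post) <- paste0("pph", 0:4)
  methods::new("ColocResult", posteriors = post, n_snps = as.integer(n),
               priors = c(p1 = p1, p2 = p2, p12 = p12),
               threshold = pph4_threshold)
}
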