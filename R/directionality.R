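# Reverse-causality testing: MR Steiger filtering and bidirectional MR.

#' MR Steiger directionality test
#'
#' Sums the per-instrument variance explained (PVE = beta^2/(beta^2 + n se^2))
#' in the exposure and in the outcome over the (clumped, hence independent)
#' instruments, converts each to a correlation r = sqrt(PVE), Fisher
#' z-transforms both, and compares them:
#' z = (z_exp - z_out) / sqrt(1/(n_exp - 3) + 1/(n_out - 3)), with a
#' two-sided normal p-value. The verdict is `passed` exactly when the
#' instruments explain more variance in the exposure than in the outcome and
#' p < 0.05. For a binary outcome the same observed-scale PVE formula is used
#' with the total sample size (an approximation; no liability-scale
#' conversion).
#'
#' @param pairs harmonized data.frame (rows with status `ok`/`flipped` are
#'   used) carrying `n_exp` and `n_out`.
#' @param n_exp,n_out override the per-trait sample sizes (defaults: the
#'   median of the respective column).
#' @return A [SteigerResult-class].
#' @export
steigerTest <- function(pairs, n_exp = NULL, n_out = NULL) {
  pairs <- .usablePairs(pairs)
  if (nrow(pairs) == 0L) .stopf("no usable instrument for the Steiger test")
  if (is.null(n_exp)) n_exp <- stats::median(pairs$n_exp)
  if (is.null(n_out)) n_out <- stats::median(pairs$n_out)
  if (is.na(n_exp) || is.na(n_out) || n_exp <= 3 || n_out <= 3)
    .stopf("Steiger test requires sample sizes above 3 for both traits")
  cap <- 1 - 1e-12
  pve_exp <- min(sum(computePVE(pairs$beta_exp, pairs$se_exp, pairs$n_exp)), cap)
  pve_out <- min(sum(computePVE(pairs$beta_out, pairs$se_out, pairs$n_out)), cap)
  z_exp <- atanh(sqrt(pve_exp))
  z_out <- atanh(sqrt(pve_out))
  z <- (z_exp - z_out) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  p <- .zToP(z)
  correct <- pve_exp > pve_out
  methods::new("SteigerResult", pve_exposure = pve_exp, pve_outcome = pve_out,
               correct_direction = correct, zstat = z, pvalue = p,
               verdict = if (correct && p < 0.05) "passed" else "failed")
}

#' Bidirectional (reverse) MR: disease on protein
#'
#' Re-runs MR with the roles swapped: instruments are selected from the
#' disease GWAS with the same strength and independence criteria as for
#' proteins (p < `p_threshold`, F > `f_threshold`, clumping at `clump_r2`) but
#' no cis restriction, harmonized to the protein GWAS, and passed to the
#' usual estimator. By default each candidate disease instrument must also
#' pass a per-variant Steiger direction check (it must explain more variance
#' in the disease than in the protein); without this, in a cis region any
#' true protein-to-disease effect makes every pQTL a significant disease
#' variant and reverse MR would flag every real target. When no instrument
#' survives, an explicit not-testable result is returned.
#'
#' @param outcome_stats the disease [SummaryStats-class] (instrument source).
#' @param protein_stats the protein [SummaryStats-class] (now the outcome).
#' @param ld [LDMatrix-class] covering the disease candidates.
#' @param p_threshold,f_threshold,clump_r2 instrument criteria (defaults
#'   5e-8, 10, 0.001).
#' @param palindrome_eaf_window see [harmonize()].
#' @param steiger_filter_instruments apply the per-variant direction check
#'   (default `TRUE`).
#' @param random_effects see [mrIVW()].
#' @return An [MRResult-class] (possibly `not_testable`).
#' @export
bidirectionalMR <- function(outcome_stats, protein_stats, ld,
                            p_threshold = 5e-8, f_threshold = 10,
                            clump_r2 = 0.001, palindrome_eaf_window = 0.08,
                            steiger_filter_instruments = TRUE,
                            random_effects = FALSE) {
  stopifnot(methods::is(outcome_stats, "SummaryStats"),
            methods::is(protein_stats, "SummaryStats"))
  exp_id <- traitId(outcome_stats)
  out_id <- traitId(protein_stats)
  df <- variants(outcome_stats)
  df <- df[df$pvalue < p_threshold, , drop = FALSE]
  if (nrow(df) > 0) {
    pve <- computePVE(df$beta, df$se, df$n)
    df <- df[computeFStat(pve, df$n) > f_threshold, , drop = FALSE]
  }
  if (nrow(df) == 0) return(mrNotTestable(exp_id, out_id))
  pairs <- harmonize(df, protein_stats,
                     palindrome_eaf_window = palindrome_eaf_window)
  pairs <- .usablePairs(pairs)
  if (steiger_filter_instruments && nrow(pairs) > 0) {
    pve_dis <- computePVE(pairs$beta_exp, pairs$se_exp, pairs$n_exp)
    pve_pro <- computePVE(pairs$beta_out, pairs$se_out, pairs$n_out)
    pairs <- pairs[pve_dis > pve_pro, , drop = FALSE]
  }
  if (nrow(pairs) == 0) return(mrNotTestable(exp_id, out_id))
  keep <- df[df$variant_id %in% pairs$variant_id, , drop = FALSE]
  keep <- clumpVariants(keep, ld, clump_r2)
  pairs <- pairs[match(keep$variant_id, pairs$variant_id), , drop = FALSE]
  mrEstimate(pairs, exposure_id = exp_id, outcome_id = out_id,
             random_effects = random_effects)
}

#' Combined reverse-causality verdict
#'
#' Reverse causation is confirmed when the reverse (disease-on-protein) MR is
#' significant at 0.05 or the forward Steiger filtering failed. A
#' not-testable reverse MR counts as non-significant.
#'
#' @param forward_steiger a [SteigerResult-class] from the forward analysis.
#' @param reverse_mr an [MRResult-class] from [bidirectionalMR()] (may be
#'   not-testable), or `NULL` when the reverse analysis was skipped.
#' @return `"confirmed_reverse"` or `"no_reverse_evidence"`.
#' @export
reverseCausalityVerdict <- function(forward_steiger, reverse_mr = NULL) {
  stopifnot(methods::is(forward_steiger, "SteigerResult"))
  rev_sig <- !is.null(reverse_mr) && isTestable(reverse_mr) &&
    pValue(reverse_mr) < 0.05
  if (rev_sig || steigerVerdict(forward_steiger) == "failed")
    "confirmed_reverse"
  else
    "no_reverse_evidence"
}
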