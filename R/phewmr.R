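# Phenome-wide MR side-effect screening, standardized to a target risk
# reduction in the primary outcome.

#' Protein change producing a target risk reduction
#'
#' The signed protein change (in SD) whose genetically predicted effect on the
#' primary outcome's log-odds equals log(target_rr):
#' factor = log(target_rr) / beta_protein_on_outcome. With the default
#' `target_rr = 0.90` this is the protein shift giving a 10\% risk reduction;
#' the factor is negative for a harmful protein (a reduction is required).
#'
#' @param beta_protein_on_vv the protein's causal log-odds effect on the
#'   primary outcome per SD (non-zero).
#' @param target_rr target relative risk in (0, 1) (default 0.90).
#' @return The scaling factor in SD of protein.
#' @examples
#' scalingToTarget(log(0.88))  # ~0.824 SD increase of a protective protein
#' scalingToTarget(log(1.12))  # ~-0.930 SD (a reduction) of a harmful one
#' @export
scalingToTarget <- function(beta_protein_on_vv, target_rr = 0.90) {
  if (length(beta_protein_on_vv) != 1L || is.na(beta_protein_on_vv) ||
      beta_protein_on_vv == 0)
    .stopf("beta_protein_on_vv must be a single non-zero value")
  if (target_rr <= 0 || target_rr >= 1) .stopf("target_rr must lie in (0, 1)")
  log(target_rr) / beta_protein_on_vv
}

#' Phenome-wide MR screen of one protein across a disease battery
#'
#' Estimates the protein's per-SD causal effect on every disease in the
#' battery with the same instruments as the primary analysis, rescales each
#' estimate by [scalingToTarget()] so effects are per protein change giving a
#' `target_rr` risk change in the primary outcome, and adjusts the raw
#' p-values across the battery (Benjamini-Hochberg by default, Bonferroni as
#' a toggle). CI bounds are rescaled by the same factor, swapping when the
#' factor is negative so `scaled_ci_low < scaled_ci_high` always holds.
#' Diseases with no harmonizable instrument are reported `untested` (with NA
#' estimates) and excluded from the adjustment.
#'
#' @param protein_instruments an [InstrumentSet-class].
#' @param disease_battery named list of [SummaryStats-class] disease GWASs.
#' @param beta_protein_on_vv the protein's primary-analysis effect on the
#'   main outcome (log-odds per SD).
#' @param target_rr see [scalingToTarget()].
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @param palindrome_eaf_window see [harmonize()].
#' @param random_effects see [mrIVW()].
#' @return data.frame, one row per disease: raw per-SD estimate (`beta`,
#'   `se`, `pvalue`, `or`, `ci_low`, `ci_high`, `n_snps`, `method`),
#'   `scaling_factor`, scaled estimate (`scaled_beta`, `scaled_or`,
#'   `scaled_ci_low`, `scaled_ci_high`), `adjusted_q` and `status`
#'   (`tested`/`untested`).
#' @export
phewasScreen <- function(protein_instruments, disease_battery,
                         beta_protein_on_vv, target_rr = 0.90,
                         adjust = c("BH", "bonferroni"),
                         palindrome_eaf_window = 0.08,
                         random_effects = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(methods::is(protein_instruments, "InstrumentSet"))
  if (length(disease_battery) == 0) .stopf("empty disease battery")
  if (is.null(names(disease_battery)))
    names(disease_battery) <- vapply(disease_battery, traitId, character(1))
  inst <- instrumentTable(protein_instruments)
  if (nrow(inst) == 0) .stopf("no instruments for the protein")
  sf <- scalingToTarget(beta_protein_on_vv, target_rr)
  protein_id <- exposureId(protein_instruments)

  one <- function(disease_id) {
    dis <- disease_battery[[disease_id]]
    res <- tryCatch({
      pairs <- harmonize(inst, dis, palindrome_eaf_window = palindrome_eaf_window)
      mrEstimate(pairs, exposure_id = protein_id, outcome_id = disease_id,
                 random_effects = random_effects)
    }, error = function(e) NULL)
    if (is.null(res) || !isTestable(res)) {
      return(data.frame(protein_id = protein_id, disease_id = disease_id,
                        method = NA_character_, n_snps = 0L, beta = NA_real_,
                        se = NA_real_, pvalue = NA_real_, or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        status = "untested", stringsAsFactors = FALSE))
    }
    or <- oddsRatio(res)
    data.frame(protein_id = protein_id, disease_id = disease_id,
               method = mrMethod(res), n_snps = nSnps(res), beta = mrBeta(res),
               se = mrSE(res), pvalue = pValue(res), or = or[["or"]],
               ci_low = or[["ci_low"]], ci_high = or[["ci_high"]],
               status = "tested", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(disease_battery), one))
  if (all(out$status == "untested"))
    .stopf("no disease in the battery could be tested")

  out$scaling_factor <- sf
  out$scaled_beta <- out$beta * sf
  lo <- out$beta - .CI_Z * out$se
  hi <- out$beta + .CI_Z * out$se
  out$scaled_or <- exp(out$scaled_beta)
  out$scaled_ci_low <- exp(pmin(lo * sf, hi * sf))
  out$scaled_ci_high <- exp(pmax(lo * sf, hi * sf))
  out$adjusted_q <- NA_real_
  tested <- out$status == "tested"
  out$adjusted_q[tested] <- stats::p.adjust(
    out$pvalue[tested],
    method = if (adjust == "BH") "BH" else "bonferroni")
  out
}
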