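# S4 containers shared across the package.

.SS_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "eaf", "beta", "se", "pvalue", "n", "n_cases", "n_controls")

# validates a variant table against the per-variant association invariants;
# returns a character vector of problems (empty when valid)
.checkVariantTable <- function(df, trait_type) {
  msg <- character(0)
  missing_cols <- setdiff(.SS_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0) return("no variants")
  if (anyDuplicated(df$variant_id))
    msg <- c(msg, "duplicated variant_id")
  if (any(is.na(df$se)) || any(df$se <= 0))
    msg <- c(msg, "se must be > 0")
  if (any(is.na(df$pos)) || any(df$pos < 1))
    msg <- c(msg, "pos must be >= 1")
  allele_ok <- grepl("^[ACGT]+$", df$effect_allele) & grepl("^[ACGT]+$", df$other_allele)
  if (any(!allele_ok))
    msg <- c(msg, "alleles must be non-empty strings over {A,C,G,T}")
  if (any(df$effect_allele == df$other_allele))
    msg <- c(msg, "effect_allele must differ from other_allele")
  if (any(is.na(df$pvalue)) || any(df$pvalue <= 0 | df$pvalue > 1))
    msg <- c(msg, "pvalue must lie in (0, 1]")
  if (any(is.na(df$beta)))
    msg <- c(msg, "beta must be non-missing")
  if (any(is.na(df$n)) || any(df$n < 1))
    msg <- c(msg, "n must be >= 1")
  eaf <- df$eaf[!is.na(df$eaf)]
  if (any(eaf < 0 | eaf > 1))
    msg <- c(msg, "eaf must lie in [0, 1]")
  if (identical(trait_type, "binary")) {
    has_counts <- !is.na(df$n_cases) & !is.na(df$n_controls)
    if (any(has_counts & df$n_cases + df$n_controls != df$n))
      msg <- c(msg, "n_cases + n_controls must equal n for a binary trait")
  }
  msg
}

#' GWAS summary statistics for one trait
#'
#' An S4 container for one trait's per-variant marginal associations
#' (beta, se, p, alleles, allele frequency, sample size), keyed by variant id.
#' Exposure (protein) effects are interpreted per SD of trait; binary-trait
#' effects are log-odds.
#'
#' @slot trait_id single trait identifier.
#' @slot trait_type `"quantitative"` or `"binary"`.
#' @slot genome_build free-text build label; [harmonize()] refuses to pair
#'   traits whose labels differ.
#' @slot variants `data.frame` with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   `n_cases`, `n_controls` (the last three may be `NA` where not
#'   applicable); extra columns are carried through untouched.
#'
#' @seealso [readSummaryStats()], [writeSummaryStats()], [harmonize()]
#' @export
setClass("SummaryStats",
  representation(trait_id = "character", trait_type = "character",
                 genome_build = "character", variants = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@trait_id) != 1L) msg <- c(msg, "trait_id must be length 1")
    if (!object@trait_type %in% c("quantitative", "binary"))
      msg <- c(msg, "trait_type must be 'quantitative' or 'binary'")
    msg <- c(msg, .checkVariantTable(object@variants, object@trait_type))
    if (length(msg)) msg else TRUE
  })

#' Construct a SummaryStats object
#'
#' @param variants data.frame of per-variant associations (see the class
#'   documentation for the schema; `eaf`, `n_cases`, `n_controls` are filled
#'   with `NA` when absent).
#' @param trait_id trait identifier.
#' @param trait_type `"quantitative"` (e.g. a plasma protein level, per SD)
#'   or `"binary"` (a disease, log-odds).
#' @param genome_build genome build label.
#' @return A validated [SummaryStats-class] object.
#' @examples
#' ss <- SummaryStats(
#'   data.frame(variant_id = "rs1", chrom = "1", pos = 1000L,
#'              effect_allele = "A", other_allele = "G", eaf = 0.3,
#'              beta = 0.5, se = 0.05, pvalue = 1e-20, n = 7213),
#'   trait_id = "LUM", trait_type = "quantitative")
#' nVariants(ss)
#' @export
SummaryStats <- function(variants, trait_id, trait_type = c("quantitative", "binary"),
                         genome_build = "unspecified") {
  trait_type <- match.arg(trait_type)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  for (col in c("eaf", "n_cases", "n_controls")) {
    if (is.null(variants[[col]])) variants[[col]] <- NA_real_
    variants[[col]] <- as.numeric(variants[[col]])
  }
  for (col in c("beta", "se", "pvalue", "n"))
    variants[[col]] <- as.numeric(variants[[col]])
  variants$pos <- as.integer(variants$pos)
  variants <- variants[c(.SS_COLUMNS, setdiff(names(variants), .SS_COLUMNS))]
  rownames(variants) <- NULL
  methods::new("SummaryStats", trait_id = as.character(trait_id),
               trait_type = trait_type, genome_build = as.character(genome_build),
               variants = variants)
}

#' @rdname proteoMR-generics
#' @export
setMethod("traitId", "SummaryStats", function(x) x@trait_id)
#' @rdname proteoMR-generics
#' @export
setMethod("traitType", "SummaryStats", function(x) x@trait_type)
#' @rdname proteoMR-generics
#' @export
setMethod("genomeBuild", "SummaryStats", function(x) x@genome_build)
#' @rdname proteoMR-generics
#' @export
setMethod("variants", "SummaryStats", function(x) x@variants)
#' @rdname proteoMR-generics
#' @export
setMethod("nVariants", "SummaryStats", function(x) nrow(x@variants))
#' @rdname proteoMR-generics
#' @export
setMethod("variantIds", "SummaryStats", function(x) x@variants$variant_id)

#' @rdname proteoMR-generics
#' @export
setMethod("subsetVariants", "SummaryStats", function(x, ids) {
  keep <- x@variants$variant_id %in% ids
  if (!any(keep)) .stopf("no requested variants present in trait '%s'", x@trait_id)
  methods::initialize(x, variants = x@variants[keep, , drop = FALSE])
})

setMethod("show", "SummaryStats", function(object) {
  cat(sprintf("SummaryStats '%s' (%s, build %s): %d variants\n",
              object@trait_id, object@trait_type, object@genome_build,
              nrow(object@variants)))
})

#' Linkage-disequilibrium matrix
#'
#' Square matrix of signed pairwise correlations (r, not r-squared) over an
#' ordered set of variants. Symmetric, unit diagonal, entries in \[-1, 1\].
#'
#' @slot variant_ids ordered variant identifiers.
#' @slot r numeric matrix of signed correlations.
#' @seealso [readLDMatrix()], [clumpVariants()]
#' @export
setClass("LDMatrix",
  representation(variant_ids = "character", r = "matrix"),
  validity = function(object) {
    msg <- character(0)
    r <- object@r
    if (nrow(r) != ncol(r)) msg <- c(msg, "r must be square")
    if (length(object@variant_ids) != nrow(r))
      msg <- c(msg, "variant_ids length must match matrix dimension")
    if (anyDuplicated(object@variant_ids)) msg <- c(msg, "duplicated variant ids")
    if (nrow(r) > 0) {
      if (max(abs(r - t(r))) > 1e-8) msg <- c(msg, "r must be symmetric")
      if (any(abs(r) > 1 + 1e-8)) msg <- c(msg, "|r| must not exceed 1")
      if (any(abs(diag(r) - 1) > 1e-8)) msg <- c(msg, "diagonal must equal 1")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an LDMatrix
#'
#' @param r square numeric matrix of signed correlations; minor asymmetry
#'   (below 1e-8) is removed by averaging with the transpose and entries are
#'   clamped to \[-1, 1\].
#' @param variant_ids variant identifiers in matrix order; defaults to
#'   `rownames(r)`.
#' @return An [LDMatrix-class] object.
#' @export
LDMatrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(variant_ids)) .stopf("variant_ids required (no rownames on r)")
  if (nrow(r) == ncol(r) && max(abs(r - t(r))) <= 1e-8) r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  dimnames(r) <- list(variant_ids, variant_ids)
  methods::new("LDMatrix", variant_ids = as.character(variant_ids), r = r)
}

#' @rdname proteoMR-generics
#' @export
setMethod("variantIds", "LDMatrix", function(x) x@variant_ids)
#' @rdname proteoMR-generics
#' @export
setMethod("nVariants", "LDMatrix", function(x) length(x@variant_ids))

#' @rdname proteoMR-generics
#' @export
setMethod("subsetVariants", "LDMatrix", function(x, ids) {
  miss <- setdiff(ids, x@variant_ids)
  if (length(miss))
    .stopf("variant(s) not present in LD matrix: %s", paste(miss, collapse = ", "))
  idx <- match(ids, x@variant_ids)
  methods::new("LDMatrix", variant_ids = x@variant_ids[idx],
               r = x@r[idx, idx, drop = FALSE])
})

#' Pairwise signed LD correlations
#'
#' @param x an [LDMatrix-class].
#' @param ids optional variant ids selecting a submatrix.
#' @return The signed correlation matrix.
#' @export
ldR <- function(x, ids = NULL) {
  stopifnot(methods::is(x, "LDMatrix"))
  if (is.null(ids)) return(x@r)
  subsetVariants(x, ids)@r
}

setMethod("show", "LDMatrix", function(object) {
  cat(sprintf("LDMatrix: %d variants\n", length(object@variant_ids)))
})

#' Selected genetic instruments for one exposure
#'
#' The cis-pQTL instruments retained for one protein after the full filter
#' cascade (cis window, p-value, F-statistic, LD clumping), with the
#' proportion of variance explained (PVE) and F-statistic attached, the
#' retained pairwise LD, per-stage candidate counts, and pleiotropy flags
#' filled in by [flagPleiotropy()].
#'
#' @slot exposure_id the protein/exposure identifier.
#' @slot table data.frame: the retained variant rows plus `pve`, `f_stat`,
#'   `is_cis` columns.
#' @slot pleiotropy_flags list (one character vector per instrument) of
#'   catalog traits with a genome-wide-significant association.
#' @slot ld_r2 pairwise squared correlations among retained instruments.
#' @slot params thresholds used (`p_threshold`, `f_threshold`, `clump_r2`,
#'   `cis_window_bp`).
#' @slot counts candidates surviving each stage
#'   (`candidates`, `cis`, `significant`, `strong`, `clumped`).
#' @seealso [selectInstruments()]
#' @export
setClass("InstrumentSet",
  representation(exposure_id = "character", table = "data.frame",
                 pleiotropy_flags = "list", ld_r2 = "matrix",
                 params = "list", counts = "integer"),
  validity = function(object) {
    msg <- character(0)
    tab <- object@table
    k <- nrow(tab)
    if (length(object@pleiotropy_flags) != k)
      msg <- c(msg, "pleiotropy_flags must have one entry per instrument")
    p <- object@params
    if (k > 0) {
      if (!all(c("pve", "f_stat", "is_cis") %in% names(tab)))
        msg <- c(msg, "table must carry pve, f_stat, is_cis")
      else {
        if (any(tab$pvalue >= p$p_threshold))
          msg <- c(msg, "instrument p-value at or above p_threshold")
        if (any(tab$f_stat <= p$f_threshold))
          msg <- c(msg, "instrument F at or below f_threshold")
        if (!all(tab$is_cis)) msg <- c(msg, "non-cis instrument retained")
        if (any(tab$pve < 0 | tab$pve >= 1)) msg <- c(msg, "pve outside [0, 1)")
      }
      r2 <- object@ld_r2
      if (nrow(r2) != k || ncol(r2) != k)
        msg <- c(msg, "ld_r2 dimension must match instrument count")
      else if (k > 1 && any(r2[upper.tri(r2)] >= p$clump_r2))
        msg <- c(msg, "retained instruments not pairwise independent at clump_r2")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname proteoMR-generics
#' @export
setMethod("exposureId", "InstrumentSet", function(x) x@exposure_id)
#' @rdname proteoMR-generics
#' @export
setMethod("instrumentTable", "InstrumentSet", function(x) x@table)
#' @rdname proteoMR-generics
#' @export
setMethod("nInstruments", "InstrumentSet", function(x) nrow(x@table))
#' @rdname proteoMR-generics
#' @export
setMethod("stageCounts", "InstrumentSet", function(x) x@counts)
#' @rdname proteoMR-generics
#' @export
setMethod("pleiotropyFlags", "InstrumentSet", function(x) x@pleiotropy_flags)
#' @rdname proteoMR-generics
#' @export
setMethod("isPleiotropic", "InstrumentSet",
          function(x) any(lengths(x@pleiotropy_flags) > 0))

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet '%s': %d instrument(s)\n",
              object@exposure_id, nrow(object@table)))
  if (nrow(object@table) > 0)
    print(object@table[c("variant_id", "beta", "se", "pvalue", "pve", "f_stat")],
          row.names = FALSE)
  cts <- object@counts
  if (length(cts))
    cat("stages: ", paste(sprintf("%s=%d", names(cts), cts), collapse = " -> "), "\n")
})

#' Mendelian-randomization causal estimate
#'
#' One exposure-to-outcome causal estimate: Wald ratio (single instrument),
#' fixed-effect IVW (two or more), or an explicit `not_testable` marker when
#' no instrument survived. Betas are on the outcome scale per SD of exposure
#' (log-odds for a binary outcome). Cochran's Q across per-instrument ratios
#' is stored for multi-instrument fits.
#'
#' @slot exposure_id,outcome_id trait identifiers.
#' @slot method `"wald_ratio"`, `"ivw"` or `"not_testable"`.
#' @slot beta,se,pvalue estimate, standard error, two-sided normal p.
#' @slot n_snps number of instruments used (0 for `not_testable`).
#' @slot q_stat,q_pvalue Cochran heterogeneity Q and its p (`NA` unless
#'   `n_snps >= 2`).
#' @seealso [mrEstimate()], [oddsRatio()]
#' @export
setClass("MRResult",
  representation(exposure_id = "character", outcome_id = "character",
                 method = "character", beta = "numeric", se = "numeric",
                 pvalue = "numeric", n_snps = "integer",
                 q_stat = "numeric", q_pvalue = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (!object@method %in% c("wald_ratio", "ivw", "not_testable"))
      msg <- c(msg, "unknown method")
    if (object@method == "not_testable") {
      if (object@n_snps != 0L) msg <- c(msg, "not_testable implies n_snps = 0")
    } else {
      if (is.na(object@se) || object@se <= 0) msg <- c(msg, "se must be > 0")
      if (is.na(object@pvalue) || object@pvalue <= 0 || object@pvalue > 1)
        msg <- c(msg, "pvalue must lie in (0, 1]")
      if (object@n_snps < 1L) msg <- c(msg, "n_snps must be >= 1")
      if ((object@method == "wald_ratio") != (object@n_snps == 1L))
        msg <- c(msg, "wald_ratio iff n_snps = 1")
    }
    if (length(msg)) msg else TRUE
  })

.MRResult <- function(exposure_id, outcome_id, method, beta, se, pvalue, n_snps,
                      q_stat = NA_real_, q_pvalue = NA_real_) {
  methods::new("MRResult", exposure_id = exposure_id, outcome_id = outcome_id,
               method = method, beta = beta, se = se, pvalue = pvalue,
               n_snps = as.integer(n_snps), q_stat = q_stat, q_pvalue = q_pvalue)
}

#' @rdname proteoMR-generics
#' @export
setMethod("exposureId", "MRResult", function(x) x@exposure_id)
#' @rdname proteoMR-generics
#' @export
setMethod("outcomeId", "MRResult", function(x) x@outcome_id)
#' @rdname proteoMR-generics
#' @export
setMethod("mrMethod", "MRResult", function(x) x@method)
#' @rdname proteoMR-generics
#' @export
setMethod("mrBeta", "MRResult", function(x) x@beta)
#' @rdname proteoMR-generics
#' @export
setMethod("mrSE", "MRResult", function(x) x@se)
#' @rdname proteoMR-generics
#' @export
setMethod("pValue", "MRResult", function(x) x@pvalue)
#' @rdname proteoMR-generics
#' @export
setMethod("nSnps", "MRResult", function(x) x@n_snps)
#' @rdname proteoMR-generics
#' @export
setMethod("isTestable", "MRResult", function(x) x@method != "not_testable")

#' @rdname proteoMR-generics
#' @export
setMethod("oddsRatio", "MRResult", function(x, ...) {
  if (!isTestable(x)) return(c(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  toOddsRatio(x@beta, x@se)
})

#' @rdname proteoMR-generics
#' @export
setMethod("isSignificant", "MRResult", function(x, alpha = 0.05) {
  isTestable(x) && x@pvalue < alpha
})

setMethod("show", "MRResult", function(object) {
  if (!isTestable(object)) {
    cat(sprintf("MRResult %s -> %s: not testable (no instruments)\n",
                object@exposure_id, object@outcome_id))
    return(invisible(NULL))
  }
  or <- oddsRatio(object)
  cat(sprintf("MRResult %s -> %s [%s, %d SNP(s)]\n  OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              object@exposure_id, object@outcome_id, object@method, object@n_snps,
              or["or"], or["ci_low"], or["ci_high"], object@pvalue))
})

#' MR Steiger directionality test result
#'
#' @slot pve_exposure,pve_outcome instrument variance explained in each trait.
#' @slot correct_direction `TRUE` when the instruments explain more variance
#'   in the exposure than in the outcome.
#' @slot zstat,pvalue Fisher-z comparison of the two correlations.
#' @slot verdict `"passed"` iff direction is correct and p < 0.05.
#' @seealso [steigerTest()]
#' @export
setClass("SteigerResult",
  representation(pve_exposure = "numeric", pve_outcome = "numeric",
                 correct_direction = "logical", zstat = "numeric",
                 pvalue = "numeric", verdict = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!object@verdict %in% c("passed", "failed")) msg <- c(msg, "bad verdict")
    want <- if (object@correct_direction && object@pvalue < 0.05) "passed" else "failed"
    if (object@verdict != want)
      msg <- c(msg, "verdict must equal (correct_direction and p < 0.05)")
    if (length(msg)) msg else TRUE
  })

#' @rdname proteoMR-generics
#' @export
setMethod("steigerVerdict", "SteigerResult", function(x) x@verdict)
#' @rdname proteoMR-generics
#' @export
setMethod("correctDirection", "SteigerResult", function(x) x@correct_direction)
#' @rdname proteoMR-generics
#' @export
setMethod("pValue", "SteigerResult", function(x) x@pvalue)

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf("SteigerResult: %s (PVE exposure %.3g vs outcome %.3g, z = %.2f, p = %.3g)\n",
              object@verdict, object@pve_exposure, object@pve_outcome,
              object@zstat, object@pvalue))
})

#' Bayesian colocalization posteriors
#'
#' Posterior probabilities of the five single-causal-variant hypotheses for
#' one region/trait pair: H0 no association, H1/H2 association with one trait
#' only, H3 two distinct causal variants, H4 one shared causal variant.
#'
#' @slot posteriors named numeric of length 5 (`pph0` ... `pph4`), summing to 1.
#' @slot n_snps region size.
#' @slot priors per-variant priors (`p1`, `p2`, `p12`).
#' @slot threshold PPH4 cutoff used for the `colocalized` call.
#' @seealso [colocABF()]
#' @export
setClass("ColocResult",
  representation(posteriors = "numeric", n_snps = "integer",
                 priors = "numeric", threshold = "numeric"),
  validity = function(object) {
    msg <- character(0)
    pp <- object@posteriors
    if (length(pp) != 5L || !identical(names(pp), paste0("pph", 0:4)))
      msg <- c(msg, "posteriors must be named pph0..pph4")
    else {
      if (any(pp < 0 | pp > 1)) msg <- c(msg, "posteriors must lie in [0, 1]")
      if (abs(sum(pp) - 1) > 1e-10) msg <- c(msg, "posteriors must sum to 1")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname proteoMR-generics
#' @export
setMethod("posteriors", "ColocResult", function(x) x@posteriors)
#' @rdname proteoMR-generics
#' @export
setMethod("nSnps", "ColocResult", function(x) x@n_snps)
#' @rdname proteoMR-generics
#' @export
setMethod("isColocalized", "ColocResult",
          function(x) unname(x@posteriors["pph4"] > x@threshold))

setMethod("show", "ColocResult", function(object) {
  pp <- object@posteriors
  cat(sprintf("ColocResult (%d SNPs): PPH0-4 = %s; colocalized: %s\n",
              object@n_snps, paste(sprintf("%.3g", pp), collapse = ", "),
              isColocalized(object)))
})

#' Proteome-screen report
#'
#' Per-protein results of the full screen: instruments, primary MR, pleiotropy
#' verdict, Steiger and bidirectional MR, colocalization, replication, and a
#' final status in `not_instrumentable`, `not_significant`, `prioritized`,
#' `validated_target`.
#'
#' @slot table one row per protein (see [runScreen()]).
#' @slot details per-protein list of the underlying S4 result objects.
#' @slot params the thresholds the screen ran with.
#' @seealso [runScreen()], [writeScreenReport()]
#' @export
setClass("ScreenReport",
  representation(table = "data.frame", details = "list", params = "list"),
  validity = function(object) {
    ok_status <- c("not_instrumentable", "not_significant", "prioritized",
                   "validated_target")
    if (!all(object@table$status %in% ok_status)) "unknown status" else TRUE
  })

#' @rdname proteoMR-generics
#' @export
setMethod("reportTable", "ScreenReport", function(x) x@table)
#' @rdname proteoMR-generics
#' @export
setMethod("screenDetails", "ScreenReport", function(x) x@details)

setMethod("show", "ScreenReport", function(object) {
  cts <- table(factor(object@table$status,
                      levels = c("not_instrumentable", "not_significant",
                                 "prioritized", "validated_target")))
  cat(sprintf("ScreenReport: %d protein(s)\n", nrow(object@table)))
  for (s in names(cts)) cat(sprintf("  %-18s %d\n", s, cts[[s]]))
})
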