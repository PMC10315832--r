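# cis-pQTL instrument selection: strength, independence, cis restriction.

#' Proportion of variance explained by one variant
#'
#' PVE = beta^2 / (beta^2 + n * se^2). For a marginal GWAS effect this is the
#' fraction of trait variance the variant explains; it feeds the F-statistic
#' and the Steiger directionality test.
#'
#' @param beta marginal effect estimate.
#' @param se its standard error (> 0).
#' @param n sample size (>= 1).
#' @return PVE in \[0, 1). Vectorized.
#' @examples
#' computePVE(0.5, 0.05, 1000)  # 0.0909...
#' @export
computePVE <- function(beta, se, n) {
  if (any(is.na(se)) || any(se <= 0)) .stopf("se must be > 0")
  if (any(is.na(n)) || any(n < 1)) .stopf("n must be >= 1")
  beta^2 / (beta^2 + n * se^2)
}

#' Instrument-strength F-statistic
#'
#' Single-instrument approximation F = PVE * (n - k - 1) / (k * (1 - PVE)).
#' The conventional weak-instrument cutoff is F > 10, which at k = 1 is
#' equivalent to PVE > 10 / (n + 8).
#'
#' @param pve proportion of variance explained, in \[0, 1).
#' @param n sample size.
#' @param k number of instruments in the model (default 1, per-variant).
#' @return F >= 0. Vectorized over `pve`.
#' @export
computeFStat <- function(pve, n, k = 1) {
  if (any(is.na(pve)) || any(pve < 0 | pve >= 1)) .stopf("pve must lie in [0, 1)")
  if (any(n <= k + 1)) .stopf("n must exceed k + 1")
  pve * (n - k - 1) / (k * (1 - pve))
}

#' Greedy LD clumping
#'
#' Sorts candidates by ascending p-value (ties broken by chromosome, position,
#' then variant id), repeatedly retains the most significant remaining variant
#' and discards all others with squared correlation at or above
#' `r2_threshold` against it. The retained set is pairwise independent at the
#' threshold and is the unique greedy-by-significance solution.
#'
#' @param candidates variant data.frame (needs `variant_id`, `pvalue`,
#'   `chrom`, `pos`).
#' @param ld an [LDMatrix-class] covering every candidate (missing variants
#'   are an error naming the variant).
#' @param r2_threshold squared-correlation threshold (default 0.001).
#' @return The retained rows of `candidates`, in selection order.
#' @export
clumpVariants <- function(candidates, ld, r2_threshold = 0.001) {
  candidates <- .asVariantTable(candidates)
  if (nrow(candidates) == 0) return(candidates)
  miss <- setdiff(candidates$variant_id, variantIds(ld))
  if (length(miss))
    .stopf("candidate variant(s) absent from LD matrix: %s",
           paste(miss, collapse = ", "))
  ord <- order(candidates$pvalue, candidates$chrom, candidates$pos,
               candidates$variant_id)
  candidates <- candidates[ord, , drop = FALSE]
  r2 <- ldR(ld, candidates$variant_id)^2
  keep <- integer(0)
  remaining <- seq_len(nrow(candidates))
  while (length(remaining)) {
    best <- remaining[1]
    keep <- c(keep, best)
    remaining <- remaining[r2[best, remaining] < r2_threshold]
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select cis-pQTL instruments for one protein
#'
#' Applies the instrument filters in fixed order: cis restriction (same
#' chromosome and within `cis_window_bp` of the gene's TSS), genome-wide
#' significance (`pvalue < p_threshold`), instrument strength
#' (F > `f_threshold`, with PVE and F computed for the significant cis
#' candidates), then greedy LD clumping at `clump_r2`. An empty result is
#' legal: the protein is simply not instrumentable.
#'
#' @param stats the protein's GWAS as a [SummaryStats-class].
#' @param gene list or one-row data.frame with `gene_id`, `chrom`, `tss`.
#' @param ld [LDMatrix-class] covering the candidate variants.
#' @param p_threshold significance cutoff (default 5e-8).
#' @param f_threshold F-statistic cutoff (default 10).
#' @param clump_r2 clumping r-squared threshold (default 0.001).
#' @param cis_window_bp half-width of the cis window around the TSS
#'   (default 1 Mb).
#' @return An [InstrumentSet-class]; `stageCounts()` exposes the number of
#'   candidates surviving each filter.
#' @export
selectInstruments <- function(stats, gene, ld, p_threshold = 5e-8,
                              f_threshold = 10, clump_r2 = 0.001,
                              cis_window_bp = 1e6) {
  stopifnot(methods::is(stats, "SummaryStats"))
  gene <- as.list(gene)
  df <- variants(stats)
  n_candidates <- nrow(df)
  cis <- df$chrom == as.character(gene$chrom) &
    abs(df$pos - as.numeric(gene$tss)) <= cis_window_bp
  df <- df[cis, , drop = FALSE]
  n_cis <- nrow(df)
  df <- df[df$pvalue < p_threshold, , drop = FALSE]
  n_sig <- nrow(df)
  if (nrow(df) > 0) {
    df$pve <- computePVE(df$beta, df$se, df$n)
    df$f_stat <- computeFStat(df$pve, df$n)
    df$is_cis <- TRUE
    df <- df[df$f_stat > f_threshold, , drop = FALSE]
  } else {
    df$pve <- numeric(0); df$f_stat <- numeric(0); df$is_cis <- logical(0)
  }
  n_strong <- nrow(df)
  df <- clumpVariants(df, ld, clump_r2)
  n_clumped <- nrow(df)
  r2 <- if (n_clumped > 0) ldR(ld, df$variant_id)^2 else
    matrix(numeric(0), 0, 0)
  methods::new("InstrumentSet",
    exposure_id = traitId(stats), table = df,
    pleiotropy_flags = rep(list(character(0)), n_clumped),
    ld_r2 = r2,
    params = list(p_threshold = p_threshold, f_threshold = f_threshold,
                  clump_r2 = clump_r2, cis_window_bp = cis_window_bp),
    counts = c(candidates = n_candidates, cis = n_cis, significant = n_sig,
               strong = n_strong, clumped = n_clumped))
}

#' Flag pleiotropic instruments against a local trait catalog
#'
#' Annotates each instrument with the catalog traits showing a
#' genome-wide-significant association for that variant. The scan is
#' advisory at the protein level (see [isPleiotropic()]): flagged proteins
#' are reported, never silently dropped.
#'
#' @param inst an [InstrumentSet-class].
#' @param catalog data.frame with `variant_id`, `trait`, `pvalue` (see
#'   [readTraitCatalog()]).
#' @param gw_threshold significance cutoff for calling an association
#'   pleiotropic (default 5e-8).
#' @return `inst` with `pleiotropyFlags()` filled in.
#' @export
flagPleiotropy <- function(inst, catalog, gw_threshold = 5e-8) {
  stopifnot(methods::is(inst, "InstrumentSet"))
  ids <- inst@table$variant_id
  hits <- catalog[catalog$pvalue < gw_threshold, , drop = FALSE]
  flags <- lapply(ids, function(v) unique(hits$trait[hits$variant_id == v]))
  methods::initialize(inst, pleiotropy_flags = flags)
}
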