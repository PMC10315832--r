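# Reading, writing and harmonizing GWAS summary statistics and LD matrices.

# column-synonym map, matched case-insensitively; first hit wins.
.SS_SYNONYMS <- list(
  variant_id = c("variant_id", "snp", "rsid", "id", "markername", "variant"),
  chrom      = c("chrom", "chr", "chromosome"),
  pos        = c("pos", "position", "bp", "base_pair_location"),
  effect_allele = c("effect_allele", "ea", "a1", "alt", "allele1"),
  other_allele  = c("other_allele", "oa", "a2", "ref", "allele2",
                    "non_effect_allele"),
  eaf        = c("eaf", "effect_allele_frequency", "freq", "af", "maf"),
  beta       = c("beta", "effect", "b", "effect_size"),
  se         = c("se", "standard_error", "stderr", "sebeta"),
  pvalue     = c("pvalue", "p", "pval", "p_value"),
  n          = c("n", "sample_size", "samplesize"),
  n_cases    = c("n_cases", "ncase", "ncases", "cases"),
  n_controls = c("n_controls", "ncontrol", "ncontrols", "controls"))

.MANDATORY <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pvalue", "n")

.resolveColumns <- function(nms) {
  low <- tolower(nms)
  out <- stats::setNames(rep(NA_character_, length(.SS_SYNONYMS)),
                         names(.SS_SYNONYMS))
  for (canon in names(.SS_SYNONYMS)) {
    hit <- which(low %in% .SS_SYNONYMS[[canon]])
    if (length(hit)) out[canon] <- nms[hit[1]]
  }
  out
}

#' Read GWAS summary statistics
#'
#' Reads a tab- or comma-delimited summary-statistics file (gzip-transparent)
#' into a [SummaryStats-class] object. Column names are resolved through a
#' synonym map (e.g. `SE`/`standard_error`, `P`/`pval`); matching is
#' case-insensitive. Allele strings are upper-cased. Rows violating the
#' per-variant invariants (non-positive se, identical alleles, p outside
#' (0,1], missing mandatory fields, malformed alleles) are dropped with a
#' message reporting the count; unknown extra columns are preserved.
#'
#' @param path file path.
#' @param trait_id trait identifier.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param genome_build genome build label (stored; [harmonize()] requires
#'   both traits to declare the same label).
#' @param sep field separator; `NULL` (default) autodetects tab vs comma from
#'   the header line.
#' @return A [SummaryStats-class] object.
#' @seealso [writeSummaryStats()]
#' @export
readSummaryStats <- function(path, trait_id, trait_type = c("quantitative", "binary"),
                             genome_build = "unspecified", sep = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  cols <- .resolveColumns(names(raw))
  missing_mand <- .MANDATORY[is.na(cols[.MANDATORY])]
  if (length(missing_mand))
    .stopf("mandatory column(s) missing from '%s': %s", path,
           paste(missing_mand, collapse = ", "))
  df <- data.frame(stringsAsFactors = FALSE, row.names = NULL,
    variant_id = as.character(raw[[cols["variant_id"]]]),
    chrom = as.character(raw[[cols["chrom"]]]),
    pos = suppressWarnings(as.integer(raw[[cols["pos"]]])),
    effect_allele = toupper(as.character(raw[[cols["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[cols["other_allele"]]])),
    eaf = if (is.na(cols["eaf"])) NA_real_ else suppressWarnings(as.numeric(raw[[cols["eaf"]]])),
    beta = suppressWarnings(as.numeric(raw[[cols["beta"]]])),
    se = suppressWarnings(as.numeric(raw[[cols["se"]]])),
    pvalue = suppressWarnings(as.numeric(raw[[cols["pvalue"]]])),
    n = suppressWarnings(as.numeric(raw[[cols["n"]]])),
    n_cases = if (is.na(cols["n_cases"])) NA_real_ else suppressWarnings(as.numeric(raw[[cols["n_cases"]]])),
    n_controls = if (is.na(cols["n_controls"])) NA_real_ else suppressWarnings(as.numeric(raw[[cols["n_controls"]]])))
  extra <- setdiff(names(raw), stats::na.omit(cols))
  for (col in extra) df[[col]] <- raw[[col]]

  ok <- !is.na(df$variant_id) & !duplicated(df$variant_id) &
    !is.na(df$pos) & df$pos >= 1 &
    grepl("^[ACGT]+$", df$effect_allele) & grepl("^[ACGT]+$", df$other_allele) &
    df$effect_allele != df$other_allele &
    !is.na(df$beta) & !is.na(df$se) & df$se > 0 &
    !is.na(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1 &
    !is.na(df$n) & df$n >= 1 &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1))
  if (trait_type == "binary") {
    counted <- !is.na(df$n_cases) & !is.na(df$n_controls)
    ok <- ok & (!counted | df$n_cases + df$n_controls == df$n)
  }
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("readSummaryStats: dropped %d invalid row(s) from '%s'",
                    n_dropped, path))
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) .stopf("no valid rows in '%s'", path)
  SummaryStats(df, trait_id = trait_id, trait_type = trait_type,
               genome_build = genome_build)
}

#' Write GWAS summary statistics
#'
#' Writes a [SummaryStats-class] object as a tab-delimited file with the
#' canonical header (`SNP CHR POS EA OA EAF BETA SE P N [N_CASES N_CONTROLS]`).
#' `N_CASES`/`N_CONTROLS` are emitted for binary traits only. Reading the file
#' back with [readSummaryStats()] reproduces the object field-for-field.
#'
#' @param stats a [SummaryStats-class] object.
#' @param path output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(stats, path) {
  stopifnot(methods::is(stats, "SummaryStats"))
  df <- variants(stats)
  if (nrow(df) == 0) .stopf("refusing to write a SummaryStats with no records")
  out <- data.frame(SNP = df$variant_id, CHR = df$chrom, POS = df$pos,
                    EA = df$effect_allele, OA = df$other_allele, EAF = df$eaf,
                    BETA = df$beta, SE = df$se, P = df$pvalue, N = df$n,
                    stringsAsFactors = FALSE)
  if (traitType(stats) == "binary") {
    out$N_CASES <- df$n_cases
    out$N_CONTROLS <- df$n_controls
  }
  extra <- setdiff(names(df), .SS_COLUMNS)
  for (col in extra) out[[col]] <- df[[col]]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an LD matrix
#'
#' Reads a delimited square matrix of signed correlations whose first row and
#' first column hold variant ids. The matrix must be square with unit diagonal
#' (within 1e-8) and entries within \[-1, 1\] (within 1e-8); asymmetry below
#' 1e-8 is removed by averaging, anything larger is an error.
#'
#' @param path file path (tab-delimited; gzip-transparent).
#' @return An [LDMatrix-class] object.
#' @export
readLDMatrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, comment.char = "")
  r <- as.matrix(raw)
  if (nrow(r) != ncol(r)) .stopf("LD matrix in '%s' is not square", path)
  if (!identical(rownames(r), colnames(r)))
    .stopf("LD matrix row and column ids disagree in '%s'", path)
  if (!is.numeric(r)) .stopf("LD matrix in '%s' contains non-numeric entries", path)
  if (any(abs(r) > 1 + 1e-8)) .stopf("LD matrix entry with |r| > 1 in '%s'", path)
  if (any(abs(diag(r) - 1) > 1e-8)) .stopf("LD matrix diagonal != 1 in '%s'", path)
  if (max(abs(r - t(r))) >= 1e-8)
    .stopf("LD matrix asymmetry exceeds 1e-8 in '%s'", path)
  LDMatrix((r + t(r)) / 2, variant_ids = rownames(r))
}

#' Write an LD matrix
#'
#' @param ld an [LDMatrix-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLDMatrix <- function(ld, path) {
  stopifnot(methods::is(ld, "LDMatrix"))
  df <- data.frame(ID = variantIds(ld), ldR(ld), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("ID", variantIds(ld))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-delimited with header `GENE CHR TSS` (synonyms `gene_id`, `chrom`,
#' `tss` accepted, case-insensitively).
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `chrom`, `tss`.
#' @export
readGeneAnnotation <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  low <- tolower(names(raw))
  pick <- function(alts) {
    hit <- which(low %in% alts)
    if (!length(hit)) .stopf("gene annotation '%s' lacks column %s", path, alts[1])
    raw[[hit[1]]]
  }
  out <- data.frame(gene_id = as.character(pick(c("gene", "gene_id"))),
                    chrom = as.character(pick(c("chr", "chrom", "chromosome"))),
                    tss = as.integer(pick(c("tss", "position"))),
                    stringsAsFactors = FALSE)
  if (any(out$tss < 1)) .stopf("TSS must be >= 1 in '%s'", path)
  out
}

#' Read a SNP-trait pleiotropy catalog
#'
#' Local stand-in for an online SNP-phenotype lookup: tab-delimited with
#' header `SNP TRAIT P`.
#'
#' @param path file path.
#' @return data.frame with columns `variant_id`, `trait`, `pvalue`.
#' @export
readTraitCatalog <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  low <- tolower(names(raw))
  pick <- function(alts) {
    hit <- which(low %in% alts)
    if (!length(hit)) .stopf("trait catalog '%s' lacks column %s", path, alts[1])
    raw[[hit[1]]]
  }
  out <- data.frame(variant_id = as.character(pick(c("snp", "variant_id", "rsid"))),
                    trait = as.character(pick(c("trait", "trait_name", "phenotype"))),
                    pvalue = as.numeric(pick(c("p", "pvalue", "pval"))),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$pvalue)) || any(out$pvalue <= 0 | out$pvalue > 1))
    .stopf("catalog p-values must lie in (0, 1] in '%s'", path)
  out
}

.asVariantTable <- function(x) {
  if (methods::is(x, "SummaryStats")) return(variants(x))
  if (is.data.frame(x)) return(x)
  .stopf("expected a SummaryStats or a variant data.frame")
}

#' Harmonize exposure and outcome associations to a common effect allele
#'
#' Aligns each shared variant's outcome association to the exposure's effect
#' allele. Same alleles in the same order keep status `ok`; swapped alleles
#' negate the outcome beta and reflect its allele frequency (`flipped`);
#' strand-complement alleles are resolved by complementing before the same
#' logic. Palindromic variants (A/T, C/G) are dropped when either trait's
#' effect-allele frequency is missing or falls inside
#' `0.5 +/- palindrome_eaf_window` (strand cannot be inferred); outside the
#' window strand is inferred from frequency agreement. Any other allele
#' combination is `dropped_mismatch`. Indel alleles are aligned by exact
#' match/swap only and are never treated as palindromic.
#'
#' @param exposure a [SummaryStats-class] or a variant data.frame (e.g. the
#'   rows of an instrument table).
#' @param outcome a [SummaryStats-class] (or variant data.frame).
#' @param variant_ids optional subset of exposure variants to harmonize.
#' @param palindrome_eaf_window half-width of the ambiguous-frequency window
#'   around 0.5 (default 0.08, i.e. drop when EAF is in (0.42, 0.58)).
#' @return data.frame with one row per shared variant: `variant_id`,
#'   `effect_allele`, `other_allele`, exposure fields (`beta_exp`, `se_exp`,
#'   `eaf_exp`, `pvalue_exp`, `n_exp`), aligned outcome fields (`beta_out`,
#'   `se_out`, `eaf_out`, `pvalue_out`, `n_out`) and `status` in
#'   `ok`, `flipped`, `dropped_palindromic`, `dropped_mismatch`. Only
#'   `ok`/`flipped` rows are usable downstream.
#' @export
harmonize <- function(exposure, outcome, variant_ids = NULL,
                      palindrome_eaf_window = 0.08) {
  if (methods::is(exposure, "SummaryStats") && methods::is(outcome, "SummaryStats") &&
      !identical(genomeBuild(exposure), genomeBuild(outcome)))
    .stopf("genome build mismatch: '%s' vs '%s'",
           genomeBuild(exposure), genomeBuild(outcome))
  e <- .asVariantTable(exposure)
  o <- .asVariantTable(outcome)
  if (!is.null(variant_ids)) e <- e[e$variant_id %in% variant_ids, , drop = FALSE]
  shared <- intersect(e$variant_id, o$variant_id)
  if (length(shared) == 0) .stopf("no overlapping variants between the two traits")
  e <- e[match(shared, e$variant_id), , drop = FALSE]
  o <- o[match(shared, o$variant_id), , drop = FALSE]
  w <- palindrome_eaf_window

  eea <- e$effect_allele; eoa <- e$other_allele
  oea <- o$effect_allele; ooa <- o$other_allele
  snp <- nchar(eea) == 1L & nchar(eoa) == 1L & nchar(oea) == 1L & nchar(ooa) == 1L
  pal <- snp & .complementAllele(eea) == eoa

  same <- oea == eea & ooa == eoa
  swap <- oea == eoa & ooa == eea
  csame <- !pal & snp & !same & !swap &
    .complementAllele(oea) == eea & .complementAllele(ooa) == eoa
  cswap <- !pal & snp & !same & !swap &
    .complementAllele(oea) == eoa & .complementAllele(ooa) == eea

  status <- rep("dropped_mismatch", length(shared))
  flip <- rep(FALSE, length(shared))
  status[!pal & (same | csame)] <- "ok"
  status[!pal & (swap | cswap)] <- "flipped"
  flip[!pal & (swap | cswap)] <- TRUE

  # palindromic: allele labels cannot settle strand; use allele frequency
  pal_match <- pal & (same | swap)
  eff_eaf <- ifelse(swap, 1 - o$eaf, o$eaf)
  in_window <- function(f) is.na(f) | (f > 0.5 - w & f < 0.5 + w)
  ambiguous <- in_window(e$eaf) | in_window(eff_eaf)
  status[pal_match & ambiguous] <- "dropped_palindromic"
  keep_pal <- pal_match & !ambiguous
  strand_flip <- keep_pal & ((e$eaf - 0.5) * (eff_eaf - 0.5) < 0)
  flip[keep_pal] <- xor(swap, strand_flip)[keep_pal]
  status[keep_pal] <- ifelse(flip[keep_pal], "flipped", "ok")
  eff_eaf[strand_flip] <- 1 - eff_eaf[strand_flip]

  usable <- status %in% c("ok", "flipped")
  beta_out <- ifelse(usable & flip, -o$beta, o$beta)
  eaf_out <- o$eaf
  eaf_out[usable & pal_match] <- eff_eaf[usable & pal_match]
  plain_flip <- usable & flip & !pal_match
  eaf_out[plain_flip] <- 1 - o$eaf[plain_flip]

  data.frame(variant_id = shared, effect_allele = eea, other_allele = eoa,
             beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf,
             pvalue_exp = e$pvalue, n_exp = e$n,
             beta_out = beta_out, se_out = o$se, eaf_out = eaf_out,
             pvalue_out = o$pvalue, n_out = o$n,
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}
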