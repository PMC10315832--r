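# End-to-end screen orchestration: instruments -> MR -> Bonferroni
# prioritization -> pleiotropy scan -> directionality -> colocalization ->
# replication, with a per-protein report.

# normalizes one protein input (plain list or SimulatedDataset)
.asProteinInput <- function(x, name) {
  if (inherits(x, "SimulatedDataset"))
    return(list(pgwas = x$protein_stats, ld = x$ld, gene = x$gene,
                replication = x$replication_stats))
  need <- c("pgwas", "ld", "gene")
  if (!all(need %in% names(x)))
    .stopf("protein '%s' needs elements: %s", name, paste(need, collapse = ", "))
  if (is.null(x$replication)) x["replication"] <- list(NULL)
  x
}

.emptyReportRow <- function(protein_id) {
  data.frame(protein_id = protein_id, n_candidates = NA_integer_,
             n_cis = NA_integer_, n_significant = NA_integer_,
             n_strong = NA_integer_, n_instruments = 0L,
             method = NA_character_, beta = NA_real_, se = NA_real_,
             pvalue = NA_real_, or = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, significant = NA,
             pleiotropic = NA, pleiotropy_traits = NA_character_,
             steiger_verdict = NA_character_, steiger_pvalue = NA_real_,
             reverse_mr_pvalue = NA_real_, reverse_verdict = NA_character_,
             pph0 = NA_real_, pph1 = NA_real_, pph2 = NA_real_,
             pph3 = NA_real_, pph4 = NA_real_, colocalized = NA,
             replication_beta = NA_real_, replication_pvalue = NA_real_,
             replication_status = NA_character_, status = NA_character_,
             stringsAsFactors = FALSE)
}

.replicateOne <- function(protein, outcome, primary_beta, params) {
  if (is.null(protein$replication))
    return(list(beta = NA_real_, pvalue = NA_real_, status = "not_replicable",
                mr = NULL))
  inst <- selectInstruments(protein$replication, protein$gene, protein$ld,
                            p_threshold = params$p_threshold,
                            f_threshold = params$f_threshold,
                            clump_r2 = params$clump_r2,
                            cis_window_bp = params$cis_window_bp)
  if (nInstruments(inst) == 0)
    return(list(beta = NA_real_, pvalue = NA_real_, status = "not_replicable",
                mr = NULL))
  mr <- tryCatch({
    pairs <- harmonize(instrumentTable(inst), outcome,
                       palindrome_eaf_window = params$palindrome_eaf_window)
    mrEstimate(pairs, exposure_id = exposureId(inst),
               outcome_id = traitId(outcome),
               random_effects = params$random_effects)
  }, error = function(e) NULL)
  if (is.null(mr))
    return(list(beta = NA_real_, pvalue = NA_real_, status = "not_replicable",
                mr = NULL))
  # replication requires p < 0.05 and a direction concordant with the primary
  ok <- pValue(mr) < 0.05 && sign(mrBeta(mr)) == sign(primary_beta)
  list(beta = mrBeta(mr), pvalue = pValue(mr),
       status = if (ok) "replicated" else "not_replicated", mr = mr)
}

#' Run the full proteome-wide MR screen
#'
#' Executes, per protein: cis-pQTL instrument selection, harmonization to the
#' outcome, Wald-ratio/IVW estimation, Bonferroni prioritization at
#' `alpha / n_tests`, and — for prioritized proteins — pleiotropy scanning
#' against `catalog`, MR Steiger filtering, bidirectional MR, Bayesian
#' colocalization of the cis region, and external replication when an
#' alternative pQTL source is supplied. Final statuses:
#' \describe{
#'   \item{not_instrumentable}{no instrument survived the filters (or none
#'     was usable against the outcome).}
#'   \item{not_significant}{estimate above the Bonferroni threshold.}
#'   \item{prioritized}{significant, but not (yet) validated.}
#'   \item{validated_target}{prioritized, no reverse-causality evidence,
#'     colocalized (PPH4 above threshold), replicated with concordant
#'     direction, and (by default) no pleiotropy flag.}
#' }
#' Stages lacking their optional input (catalog, replication source) are
#' recorded as missing, never silently passed; a protein cannot reach
#' `validated_target` without a replication source.
#'
#' @param proteins named list; each element a list with `pgwas`
#'   ([SummaryStats-class]), `ld` ([LDMatrix-class]), `gene` (list/row with
#'   `gene_id`, `chrom`, `tss`) and optional `replication`
#'   ([SummaryStats-class]), or a `SimulatedDataset` from [simulateRegion()].
#' @param outcome the outcome GWAS ([SummaryStats-class]).
#' @param catalog optional pleiotropy catalog (see [readTraitCatalog()]).
#' @param p_threshold,f_threshold,clump_r2,cis_window_bp instrument criteria.
#' @param alpha,n_tests prioritization uses `pvalue < alpha / n_tests`;
#'   `n_tests` defaults to the number of proteins screened.
#' @param palindrome_eaf_window see [harmonize()].
#' @param coloc_p1,coloc_p2,coloc_p12,pph4_threshold see [colocABF()].
#' @param bidirectional run reverse MR (default `TRUE`).
#' @param demote_pleiotropic a pleiotropy flag keeps a protein at
#'   `prioritized` (default `TRUE`); it is always reported either way.
#' @param random_effects see [mrIVW()].
#' @return A [ScreenReport-class]; `reportTable()` has one row per protein,
#'   `screenDetails()` the underlying objects.
#' @export
runScreen <- function(proteins, outcome, catalog = NULL,
                      p_threshold = 5e-8, f_threshold = 10, clump_r2 = 0.001,
                      cis_window_bp = 1e6, alpha = 0.05,
                      n_tests = length(proteins),
                      palindrome_eaf_window = 0.08,
                      coloc_p1 = 1e-4, coloc_p2 = 1e-4, coloc_p12 = 1e-5,
                      pph4_threshold = 0.8, bidirectional = TRUE,
                      demote_pleiotropic = TRUE, random_effects = FALSE) {
  stopifnot(methods::is(outcome, "SummaryStats"))
  if (length(proteins) == 0) .stopf("no proteins supplied")
  if (is.null(names(proteins)))
    names(proteins) <- sprintf("protein_%d", seq_along(proteins))
  params <- list(p_threshold = p_threshold, f_threshold = f_threshold,
                 clump_r2 = clump_r2, cis_window_bp = cis_window_bp,
                 alpha = alpha, n_tests = n_tests,
                 palindrome_eaf_window = palindrome_eaf_window,
                 coloc_p1 = coloc_p1, coloc_p2 = coloc_p2,
                 coloc_p12 = coloc_p12, pph4_threshold = pph4_threshold,
                 bidirectional = bidirectional,
                 demote_pleiotropic = demote_pleiotropic,
                 random_effects = random_effects)
  p_sig <- bonferroniThreshold(alpha, n_tests)
  rows <- vector("list", length(proteins))
  details <- vector("list", length(proteins))
  names(details) <- names(proteins)

  for (i in seq_along(proteins)) {
    pid <- names(proteins)[i]
    prot <- .asProteinInput(proteins[[i]], pid)
    row <- .emptyReportRow(pid)
    det <- list(gene = prot$gene, ld = prot$ld)

    inst <- selectInstruments(prot$pgwas, prot$gene, prot$ld,
                              p_threshold = p_threshold,
                              f_threshold = f_threshold, clump_r2 = clump_r2,
                              cis_window_bp = cis_window_bp)
    det$instruments <- inst
    cts <- stageCounts(inst)
    row$n_candidates <- cts[["candidates"]]; row$n_cis <- cts[["cis"]]
    row$n_significant <- cts[["significant"]]; row$n_strong <- cts[["strong"]]
    row$n_instruments <- cts[["clumped"]]

    pairs <- if (nInstruments(inst) > 0)
      tryCatch(harmonize(instrumentTable(inst), outcome,
                         palindrome_eaf_window = palindrome_eaf_window),
               error = function(e) NULL) else NULL
    mr <- if (!is.null(pairs))
      tryCatch(mrEstimate(pairs, exposure_id = pid,
                          outcome_id = traitId(outcome),
                          random_effects = random_effects),
               error = function(e) NULL) else NULL
    if (is.null(mr)) {
      row$status <- "not_instrumentable"
      rows[[i]] <- row; details[[i]] <- det
      next
    }
    det$pairs <- pairs
    det$mr <- mr
    or <- oddsRatio(mr)
    row$method <- mrMethod(mr); row$beta <- mrBeta(mr); row$se <- mrSE(mr)
    row$pvalue <- pValue(mr); row$or <- or[["or"]]
    row$ci_low <- or[["ci_low"]]; row$ci_high <- or[["ci_high"]]
    row$significant <- pValue(mr) < p_sig
    if (!row$significant) {
      row$status <- "not_significant"
      rows[[i]] <- row; details[[i]] <- det
      next
    }

    # pleiotropy scan (advisory)
    if (!is.null(catalog)) {
      inst <- flagPleiotropy(inst, catalog)
      det$instruments <- inst
      row$pleiotropic <- isPleiotropic(inst)
      traits <- unique(unlist(pleiotropyFlags(inst)))
      row$pleiotropy_traits <- if (length(traits))
        paste(traits, collapse = ";") else ""
    }

    # directionality
    steiger <- steigerTest(det$pairs)
    det$steiger <- steiger
    row$steiger_verdict <- steigerVerdict(steiger)
    row$steiger_pvalue <- pValue(steiger)
    rev_mr <- NULL
    if (bidirectional) {
      region_out <- tryCatch(
        subsetVariants(outcome, variantIds(prot$pgwas)),
        error = function(e) NULL)
      rev_mr <- if (is.null(region_out)) mrNotTestable(traitId(outcome), pid)
        else bidirectionalMR(region_out, prot$pgwas, prot$ld,
                             p_threshold = p_threshold,
                             f_threshold = f_threshold, clump_r2 = clump_r2,
                             palindrome_eaf_window = palindrome_eaf_window,
                             random_effects = random_effects)
      det$reverse_mr <- rev_mr
      row$reverse_mr_pvalue <- if (isTestable(rev_mr)) pValue(rev_mr) else NA_real_
    }
    row$reverse_verdict <- reverseCausalityVerdict(steiger, rev_mr)

    # colocalization over the cis region
    gene <- as.list(prot$gene)
    pv <- variants(prot$pgwas)
    cis_ids <- pv$variant_id[pv$chrom == as.character(gene$chrom) &
                               abs(pv$pos - as.numeric(gene$tss)) <= cis_window_bp]
    coloc <- tryCatch({
      region <- harmonize(prot$pgwas, outcome, variant_ids = cis_ids,
                          palindrome_eaf_window = palindrome_eaf_window)
      region <- .usablePairs(region)
      colocABF(data.frame(variant_id = region$variant_id,
                          beta = region$beta_exp, se = region$se_exp),
               data.frame(variant_id = region$variant_id,
                          beta = region$beta_out, se = region$se_out),
               p1 = coloc_p1, p2 = coloc_p2, p12 = coloc_p12,
               prior_sd_exp = 0.15, prior_sd_out = 0.2,
               pph4_threshold = pph4_threshold)
    }, error = function(e) NULL)
    if (!is.null(coloc)) {
      det$coloc <- coloc
      pp <- posteriors(coloc)
      row$pph0 <- pp[["pph0"]]; row$pph1 <- pp[["pph1"]]
      row$pph2 <- pp[["pph2"]]; row$pph3 <- pp[["pph3"]]
      row$pph4 <- pp[["pph4"]]
      row$colocalized <- isColocalized(coloc)
    }

    # external replication
    rep <- .replicateOne(prot, outcome, primary_beta = mrBeta(mr), params)
    det$replication <- rep$mr
    row$replication_beta <- rep$beta
    row$replication_pvalue <- rep$pvalue
    row$replication_status <- rep$status

    validated <- row$reverse_verdict == "no_reverse_evidence" &&
      isTRUE(row$colocalized) &&
      identical(rep$status, "replicated") &&
      !(demote_pleiotropic && isTRUE(row$pleiotropic))
    row$status <- if (validated) "validated_target" else "prioritized"
    rows[[i]] <- row; details[[i]] <- det
  }

  methods::new("ScreenReport", table = do.call(rbind, rows),
               details = details, params = params)
}

#' Re-run replication for prioritized proteins
#'
#' Re-runs instrument selection and MR against an alternative pQTL source for
#' every prioritized/validated protein in a report and updates the
#' replication columns and statuses. A protein absent from `replication` is
#' marked `not_replicable`; a significant opposite-direction effect is
#' `not_replicated`.
#'
#' @param report a [ScreenReport-class] from [runScreen()].
#' @param replication named list of [SummaryStats-class], keyed by protein id.
#' @param outcome the outcome GWAS used in the primary screen.
#' @return The updated [ScreenReport-class].
#' @export
replicateTargets <- function(report, replication, outcome) {
  stopifnot(methods::is(report, "ScreenReport"))
  tab <- report@table
  details <- report@details
  params <- report@params
  for (i in seq_len(nrow(tab))) {
    if (!tab$status[i] %in% c("prioritized", "validated_target")) next
    pid <- tab$protein_id[i]
    det <- details[[pid]]
    prot <- list(pgwas = NULL, ld = det$ld, gene = det$gene,
                 replication = replication[[pid]])
    rep <- .replicateOne(prot, outcome, primary_beta = tab$beta[i], params)
    details[[pid]]$replication <- rep$mr
    tab$replication_beta[i] <- rep$beta
    tab$replication_pvalue[i] <- rep$pvalue
    tab$replication_status[i] <- rep$status
    validated <- tab$reverse_verdict[i] == "no_reverse_evidence" &&
      isTRUE(tab$colocalized[i]) && identical(rep$status, "replicated") &&
      !(params$demote_pleiotropic && isTRUE(tab$pleiotropic[i]))
    tab$status[i] <- if (validated) "validated_target" else "prioritized"
  }
  methods::new("ScreenReport", table = tab, details = details, params = params)
}

#' Write a screen report to a directory
#'
#' Writes `report.tsv` (the full per-protein table), `mr_results.tsv`
#' (exposure, method, instrument count, OR with CI, p, significance) and
#' `coloc.tsv` (posteriors). Output is deterministic for identical inputs.
#'
#' @param report a [ScreenReport-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeScreenReport <- function(report, dir) {
  stopifnot(methods::is(report, "ScreenReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- reportTable(report)
  wt <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(tab, "report.tsv")
  wt(tab[c("protein_id", "method", "n_instruments", "or", "ci_low", "ci_high",
           "pvalue", "significant")], "mr_results.tsv")
  wt(tab[c("protein_id", "n_instruments", "pph0", "pph1", "pph2", "pph3",
           "pph4", "colocalized")], "coloc.tsv")
  invisible(dir)
}

#' Run a screen from a plain-text configuration file
#'
#' Reads a YAML key-value configuration naming the input files and
#' thresholds, loads everything through the package readers, and calls
#' [runScreen()]. Expected keys: `outcome` (path), `outcome_trait_id`,
#' `proteins` (list of `gene_id`, `chrom`, `tss`, `pgwas`, `ld`, optional
#' `replication` paths), optional `catalog`, and any [runScreen()] threshold
#' under `thresholds` (e.g. `p_threshold`, `alpha`, `n_tests`,
#' `pph4_threshold`).
#'
#' @param config path to the YAML file, or an equivalent list.
#' @param genome_build build label asserted for every file read.
#' @return A [ScreenReport-class].
#' @export
runScreenFromConfig <- function(config, genome_build = "unspecified") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outcome) || is.null(config$proteins))
    .stopf("config must name 'outcome' and 'proteins'")
  outcome <- readSummaryStats(config$outcome,
                              trait_id = config$outcome_trait_id %||% "outcome",
                              trait_type = "binary", genome_build = genome_build)
  proteins <- lapply(config$proteins, function(p) {
    list(pgwas = readSummaryStats(p$pgwas, trait_id = p$gene_id,
                                  trait_type = "quantitative",
                                  genome_build = genome_build),
         ld = readLDMatrix(p$ld),
         gene = list(gene_id = p$gene_id, chrom = as.character(p$chrom),
                     tss = as.integer(p$tss)),
         replication = if (!is.null(p$replication))
           readSummaryStats(p$replication, trait_id = p$gene_id,
                            trait_type = "quantitative",
                            genome_build = genome_build) else NULL)
  })
  names(proteins) <- vapply(config$proteins, function(p) p$gene_id, character(1))
  catalog <- if (!is.null(config$catalog)) readTraitCatalog(config$catalog)
  args <- c(list(proteins = proteins, outcome = outcome, catalog = catalog),
            config$thresholds)
  do.call(runScreen, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
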