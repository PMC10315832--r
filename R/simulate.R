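# Synthetic GWAS summary statistics with known ground truth.
#
# Marginal effects are generated directly on the summary-statistic scale
# (LD-convolved truth + sampling noise) rather than via individual-level
# genotypes: the pipeline consumes only summary statistics, and this exactly
# controls the truth. Disease effects are generated on the log-odds scale
# with the quantitative-trait standard-error formula as an approximation;
# case/control counts enter only as reported metadata.

.SCENARIOS <- c("null", "causal", "shared_coloc", "distinct_coloc", "reverse")

#' Simulation configuration
#'
#' Builds the parameter set for [simulateRegion()]. Scenario presets encode
#' the study conditions the generator emulates (a plasma-protein GWAS of
#' 7,213 participants, a varicose-veins case-control GWAS of 22,037 cases and
#' 437,665 controls, a 35,559-sample replication pGWAS); any field can be
#' overridden. Scenarios:
#' \describe{
#'   \item{causal}{three independent cis-pQTLs (effect 1 SD per allele) and a
#'     true protein-on-disease effect `theta` (default -0.2 log-odds/SD).}
#'   \item{null}{same instruments, `theta = 0`.}
#'   \item{shared_coloc}{a single causal variant driving both traits in a
#'     200-variant region with AR-1 LD (decay 0.95).}
#'   \item{distinct_coloc}{the protein and the disease each driven by their
#'     own causal variant, far enough apart that r^2 < 0.01.}
#'   \item{reverse}{the causal variants act on the disease; the protein is
#'     downstream with effect `reverse_effect` (default 0.3), measured in a
#'     100,000-sample pGWAS.}
#' }
#'
#' @param scenario one of `"causal"`, `"null"`, `"shared_coloc"`,
#'   `"distinct_coloc"`, `"reverse"`.
#' @param seed RNG seed for this region.
#' @param n_variants region size.
#' @param ld_decay adjacent-variant correlation of the AR-1 LD structure,
#'   in \[0, 1).
#' @param maf_range range the minor-allele frequencies are drawn from.
#' @param n_exp,n_out,n_cases,n_rep sample sizes (exposure GWAS, outcome
#'   GWAS, outcome cases, replication GWAS).
#' @param causal_variants data.frame with `index`, `effect`: causal effects
#'   on the protein (on the disease under `scenario = "reverse"`).
#' @param theta true protein-on-disease effect, log-odds per SD.
#' @param pleiotropy data.frame with `index`, `effect`: direct (horizontal)
#'   effects on the disease.
#' @param reverse_effect disease-on-protein effect under `"reverse"`.
#' @param chrom,pos_start,pos_step variant coordinates (evenly spaced).
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(scenario = c("causal", "null", "shared_coloc",
                                          "distinct_coloc", "reverse"),
                             seed = 1L, n_variants = NULL, ld_decay = NULL,
                             maf_range = c(0.1, 0.5), n_exp = NULL,
                             n_out = 459702, n_cases = 22037, n_rep = 35559,
                             causal_variants = NULL, theta = NULL,
                             pleiotropy = NULL, reverse_effect = NULL,
                             chrom = "1", pos_start = 1e6, pos_step = 5000) {
  scenario <- match.arg(scenario)
  preset <- switch(scenario,
    causal = list(n_variants = 60L, ld_decay = 0.6, n_exp = 7213,
                  causal_variants = data.frame(index = c(10L, 30L, 50L),
                                               effect = c(1, 1, 1)),
                  theta = -0.2, pleiotropy = NULL, reverse_effect = 0),
    null = list(n_variants = 60L, ld_decay = 0.6, n_exp = 7213,
                causal_variants = data.frame(index = c(10L, 30L, 50L),
                                             effect = c(1, 1, 1)),
                theta = 0, pleiotropy = NULL, reverse_effect = 0),
    shared_coloc = list(n_variants = 200L, ld_decay = 0.95, n_exp = 7213,
                        causal_variants = data.frame(index = 100L, effect = 1),
                        theta = -0.2, pleiotropy = NULL, reverse_effect = 0),
    distinct_coloc = list(n_variants = 200L, ld_decay = 0.95, n_exp = 7213,
                          causal_variants = data.frame(index = 50L, effect = 1),
                          theta = 0,
                          pleiotropy = data.frame(index = 150L, effect = 0.1),
                          reverse_effect = 0),
    reverse = list(n_variants = 60L, ld_decay = 0.6, n_exp = 1e5,
                   causal_variants = data.frame(index = c(10L, 30L, 50L),
                                                effect = c(0.15, 0.15, 0.15)),
                   theta = 0, pleiotropy = NULL, reverse_effect = 0.3))
  cfg <- list(scenario = scenario, seed = as.integer(seed),
              n_variants = if (is.null(n_variants)) preset$n_variants else as.integer(n_variants),
              ld_decay = if (is.null(ld_decay)) preset$ld_decay else ld_decay,
              maf_range = maf_range,
              n_exp = if (is.null(n_exp)) preset$n_exp else n_exp,
              n_out = n_out, n_cases = n_cases, n_rep = n_rep,
              causal_variants = if (is.null(causal_variants)) preset$causal_variants else causal_variants,
              theta = if (is.null(theta)) preset$theta else theta,
              pleiotropy = if (is.null(pleiotropy)) preset$pleiotropy else pleiotropy,
              reverse_effect = if (is.null(reverse_effect)) preset$reverse_effect else reverse_effect,
              chrom = chrom, pos_start = pos_start, pos_step = pos_step)
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1) .stopf("ld_decay must lie in [0, 1)")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] >= 1 ||
      cfg$maf_range[1] > cfg$maf_range[2]) .stopf("invalid maf_range")
  if (any(c(cfg$n_exp, cfg$n_out, cfg$n_rep) < 10)) .stopf("sample sizes too small")
  idx <- c(cfg$causal_variants$index,
           if (!is.null(cfg$pleiotropy)) cfg$pleiotropy$index)
  if (length(idx) && (any(idx < 1) || any(idx > cfg$n_variants)))
    .stopf("causal/pleiotropy indices must lie in 1..n_variants")
  class(cfg) <- "SimulationConfig"
  cfg
}

# LD-convolved true marginal effect from sparse causal effects
.marginalTruth <- function(r, effects_df, n_variants) {
  truth <- numeric(n_variants)
  if (is.null(effects_df) || nrow(effects_df) == 0) return(truth)
  for (j in seq_len(nrow(effects_df)))
    truth <- truth + r[, effects_df$index[j]] * effects_df$effect[j]
  truth
}

#' Simulate one cis region's summary statistics
#'
#' Generates an AR-1 LD matrix (r_ij = ld_decay^|i-j|), true marginal effects
#' as the LD convolution of the configured causal effects, and observed
#' effects beta-hat ~ Normal(truth, se^2) with the standard GWAS
#' se = 1 / sqrt(2 maf (1 - maf) n). The disease's true marginal effect is
#' theta times the protein's truth plus any direct (pleiotropic)
#' contributions; under `scenario = "reverse"` the causal effects act on the
#' disease and the protein inherits `reverse_effect` times the disease truth.
#' P-values that underflow double precision are clamped to the smallest
#' positive double. The same config and seed reproduce the dataset exactly.
#'
#' @param config a `SimulationConfig` from [simulationConfig()].
#' @param gene_id label used for the protein trait and the gene annotation
#'   (TSS at the region midpoint).
#' @param include_replication also draw an independent replication pGWAS of
#'   size `n_rep` from the same truth.
#' @return A list of class `SimulatedDataset`: `protein_stats`,
#'   `disease_stats`, optionally `replication_stats` ([SummaryStats-class]),
#'   `ld` ([LDMatrix-class]), `gene` (one-row annotation data.frame) and
#'   `truth` (the config plus the true marginal effect vectors).
#' @export
simulateRegion <- function(config, gene_id = "GENE1", include_replication = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_variants
  ids <- sprintf("%s_v%03d", gene_id, seq_len(n))
  pos <- as.integer(config$pos_start + (seq_len(n) - 1L) * config$pos_step)
  r <- config$ld_decay^abs(outer(seq_len(n), seq_len(n), "-"))
  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])

  if (config$scenario == "reverse") {
    disease_truth <- .marginalTruth(r, config$causal_variants, n)
    if (!is.null(config$pleiotropy))
      disease_truth <- disease_truth + .marginalTruth(r, config$pleiotropy, n)
    protein_truth <- config$reverse_effect * disease_truth
  } else {
    protein_truth <- .marginalTruth(r, config$causal_variants, n)
    disease_truth <- config$theta * protein_truth +
      .marginalTruth(r, config$pleiotropy, n)
  }

  draw <- function(truth, n_samp, trait_id, trait_type, n_cases = NA,
                   n_controls = NA) {
    se <- 1 / sqrt(2 * maf * (1 - maf) * n_samp)
    beta <- stats::rnorm(n, truth, se)
    SummaryStats(data.frame(
      variant_id = ids, chrom = config$chrom, pos = pos,
      effect_allele = "A", other_allele = "G", eaf = maf,
      beta = beta, se = se, pvalue = .zToP(beta / se), n = n_samp,
      n_cases = n_cases, n_controls = n_controls,
      stringsAsFactors = FALSE),
      trait_id = trait_id, trait_type = trait_type, genome_build = "synthetic")
  }
  protein_stats <- draw(protein_truth, config$n_exp, gene_id, "quantitative")
  disease_stats <- draw(disease_truth, config$n_out, "disease", "binary",
                        n_cases = config$n_cases,
                        n_controls = config$n_out - config$n_cases)
  replication_stats <- if (include_replication)
    draw(protein_truth, config$n_rep, gene_id, "quantitative") else NULL

  out <- list(protein_stats = protein_stats, disease_stats = disease_stats,
              replication_stats = replication_stats,
              ld = LDMatrix(r, variant_ids = ids),
              gene = data.frame(gene_id = gene_id, chrom = config$chrom,
                                tss = pos[ceiling(n / 2)],
                                stringsAsFactors = FALSE),
              truth = list(config = config, protein_effect = protein_truth,
                           disease_effect = disease_truth))
  class(out) <- "SimulatedDataset"
  out
}

#' Simulate a multi-protein screen
#'
#' Generates independent regions, one per protein (each on its own
#' chromosome label, with a deterministic per-protein seed `seed + index`),
#' a combined outcome GWAS over all regions, and a truth table.
#'
#' @param n_proteins number of proteins (>= 1).
#' @param base_config `SimulationConfig` applied to every protein.
#' @param overrides list, indexed by protein position, of named config fields
#'   overriding `base_config` for that protein (e.g.
#'   `list(NULL, list(theta = 0))`).
#' @param seed master seed; protein i uses `seed + i`.
#' @param include_replication see [simulateRegion()].
#' @return List with `datasets` (named list of `SimulatedDataset`), `outcome`
#'   (the combined disease [SummaryStats-class]) and `truth` (data.frame:
#'   `protein_id`, `scenario`, `theta`, `seed`).
#' @export
simulateScreen <- function(n_proteins, base_config = simulationConfig("causal"),
                           overrides = list(), seed = 1L,
                           include_replication = FALSE) {
  if (n_proteins < 1) .stopf("n_proteins must be >= 1")
  datasets <- vector("list", n_proteins)
  names(datasets) <- sprintf("P%03d", seq_len(n_proteins))
  for (i in seq_len(n_proteins)) {
    cfg <- base_config
    ov <- if (i <= length(overrides)) overrides[[i]] else NULL
    if (!is.null(ov)) for (field in names(ov)) cfg[[field]] <- ov[[field]]
    cfg$seed <- as.integer(seed + i)
    cfg$chrom <- as.character(i)
    datasets[[i]] <- simulateRegion(cfg, gene_id = names(datasets)[i],
                                    include_replication = include_replication)
  }
  disease_tabs <- lapply(datasets, function(d) variants(d$disease_stats))
  outcome <- SummaryStats(do.call(rbind, disease_tabs), trait_id = "disease",
                          trait_type = "binary", genome_build = "synthetic")
  truth <- data.frame(
    protein_id = names(datasets),
    scenario = vapply(datasets, function(d) d$truth$config$scenario, character(1)),
    theta = vapply(datasets, function(d) d$truth$config$theta, numeric(1)),
    seed = vapply(datasets, function(d) d$truth$config$seed, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(datasets = datasets, outcome = outcome, truth = truth)
}

#' Write a simulated dataset to a directory
#'
#' Writes `protein.tsv`, `disease.tsv`, `ld.tsv`, `truth.yaml` (and
#' `replication.tsv` when present) in the package's standard text formats.
#'
#' @param dataset a `SimulatedDataset` from [simulateRegion()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedDataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "SimulatedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSummaryStats(dataset$protein_stats, file.path(dir, "protein.tsv"))
  writeSummaryStats(dataset$disease_stats, file.path(dir, "disease.tsv"))
  if (!is.null(dataset$replication_stats))
    writeSummaryStats(dataset$replication_stats, file.path(dir, "replication.tsv"))
  writeLDMatrix(dataset$ld, file.path(dir, "ld.tsv"))
  truth <- dataset$truth
  cfg <- unclass(truth$config)
  cfg$causal_variants <- as.list(cfg$causal_variants)
  if (!is.null(cfg$pleiotropy)) cfg$pleiotropy <- as.list(cfg$pleiotropy)
  yaml::write_yaml(list(config = cfg,
                        protein_effect = truth$protein_effect,
                        disease_effect = truth$disease_effect),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
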