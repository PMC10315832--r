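# The ground-truth summary-statistics generator.

test_that("standard errors follow 1/sqrt(2 maf (1-maf) n)", {
  cfg <- simulationConfig("null", seed = 1, n_variants = 10,
                          maf_range = c(0.5, 0.5), n_exp = 10000,
                          causal_variants = data.frame(index = 5L, effect = 1))
  ds <- simulateRegion(cfg)
  expect_equal(variants(ds$protein_stats)$se, rep(1 / sqrt(5000), 10))
  expect_equal(variants(ds$protein_stats)$se[1], 0.01414, tolerance = 1e-3)
})

test_that("the generator is deterministic given a seed, including on disk", {
  cfg <- simulationConfig("causal", seed = 99)
  d1 <- simulateRegion(cfg, gene_id = "G")
  d2 <- simulateRegion(cfg, gene_id = "G")
  expect_equal(variants(d1$protein_stats), variants(d2$protein_stats))
  expect_equal(variants(d1$disease_stats), variants(d2$disease_stats))
  expect_identical(ldR(d1$ld), ldR(d2$ld))

  t1 <- file.path(tempdir(), "simA"); t2 <- file.path(tempdir(), "simB")
  writeSimulatedDataset(d1, t1)
  writeSimulatedDataset(d2, t2)
  for (f in c("protein.tsv", "disease.tsv", "ld.tsv", "truth.yaml"))
    expect_identical(readLines(file.path(t1, f)), readLines(file.path(t2, f)))
})

test_that("generated data satisfy the container invariants and round-trip", {
  ds <- simulateRegion(simulationConfig("causal", seed = 4), gene_id = "G",
                       include_replication = TRUE)
  expect_true(validObject(ds$protein_stats))
  expect_true(validObject(ds$disease_stats))
  expect_true(validObject(ds$replication_stats))
  expect_true(validObject(ds$ld))
  f <- tempfile()
  writeSummaryStats(ds$disease_stats, f)
  back <- readSummaryStats(f, trait_id = "disease", trait_type = "binary",
                           genome_build = "synthetic")
  expect_equal(variants(back), variants(ds$disease_stats), tolerance = 1e-12)
})

test_that("the LD structure is AR-1 and truth is its convolution", {
  cfg <- simulationConfig("shared_coloc", seed = 2, n_variants = 50,
                          causal_variants = data.frame(index = 25L, effect = 1))
  ds <- simulateRegion(cfg)
  r <- ldR(ds$ld)
  expect_equal(r[1, 2], 0.95)
  expect_equal(r[1, 3], 0.95^2)
  expect_equal(r[10, 40], 0.95^30)
  # marginal truth decays with LD away from the causal variant
  cv <- cfg$causal_variants$index[1]
  expect_equal(ds$truth$protein_effect[cv], cfg$causal_variants$effect[1])
  expect_equal(ds$truth$protein_effect[cv + 5],
               0.95^5 * cfg$causal_variants$effect[1])
  expect_equal(ds$truth$disease_effect, cfg$theta * ds$truth$protein_effect)
})

test_that("null-scenario disease z-scores are standard normal", {
  z <- unlist(lapply(1:10, function(i) {
    cfg <- simulationConfig("null", seed = 500 + i, n_variants = 500)
    ds <- simulateRegion(cfg)
    v <- variants(ds$disease_stats)
    v$beta / v$se
  }))
  expect_equal(length(z), 5000L)
  ks <- suppressWarnings(ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling noise is calibrated against the nominal standard errors", {
  resid <- unlist(lapply(1:20, function(i) {
    cfg <- simulationConfig("causal", seed = 700 + i, n_variants = 500,
                            causal_variants = data.frame(index = 250L, effect = 1))
    ds <- simulateRegion(cfg)
    v <- variants(ds$protein_stats)
    (v$beta - ds$truth$protein_effect) / v$se
  }))
  expect_gte(length(resid), 1e4)
  expect_equal(sd(resid), 1, tolerance = 0.05)
})

test_that("simulateScreen builds unique independent regions with a truth table", {
  scr <- simulateScreen(5, seed = 77,
                        overrides = list(NULL, list(theta = 0), NULL,
                                         list(theta = 0), NULL))
  expect_equal(nrow(scr$truth), 5L)
  expect_equal(scr$truth$theta, c(-0.2, 0, -0.2, 0, -0.2))
  expect_equal(scr$truth$seed, 77L + 1:5)
  all_ids <- unlist(lapply(scr$datasets, function(d) variantIds(d$protein_stats)))
  expect_false(anyDuplicated(all_ids) > 0)
  expect_equal(nVariants(scr$outcome), length(all_ids))

  single <- simulateScreen(1, seed = 3)
  expect_length(single$datasets, 1L)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(simulationConfig("causal", ld_decay = 1), "ld_decay")
  expect_error(simulationConfig("causal", maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulationConfig("causal",
                                causal_variants = data.frame(index = 99L, effect = 1),
                                n_variants = 50), "indices")
})
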