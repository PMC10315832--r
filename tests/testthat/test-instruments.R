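# Instrument selection: PVE, F, clumping, cis restriction, pleiotropy.

test_that("computePVE matches hand evaluations and guards inputs", {
  expect_equal(computePVE(0, 0.1, 100), 0)
  expect_equal(computePVE(0.5, 0.05, 1000), 0.25 / 2.75)     # 0.0909...
  expect_equal(computePVE(0.1, 0.1, 100), 0.01 / 1.01)       # 0.009901
  expect_error(computePVE(0.1, 0, 100), "se")
  expect_error(computePVE(0.1, 0.1, 0), "n")
})

test_that("computeFStat matches hand evaluations and is monotone in PVE", {
  expect_equal(computeFStat(0, 1000), 0)
  pve <- 0.25 / 2.75
  expect_equal(computeFStat(pve, 1000), pve * 998 / (1 - pve))  # ~99.8
  expect_equal(computeFStat(pve, 1000), 99.8, tolerance = 1e-3)
  pves <- seq(0, 0.9, by = 0.05)
  expect_true(all(diff(computeFStat(pves, 500)) > 0))
  expect_error(computeFStat(0.1, 2), "n must exceed")
})

test_that("F > 10 at k = 1 is equivalent to PVE > 10 / (n + 8)", {
  for (n in c(100, 1000, 7213, 459702)) {
    crit <- 10 / (n + 8)
    expect_equal(computeFStat(crit, n), 10)
    expect_gt(computeFStat(crit * 1.001, n), 10)
    expect_lt(computeFStat(crit * 0.999, n), 10)
  }
})

test_that("greedy clumping reproduces the hand-worked example", {
  cand <- data.frame(variant_id = c("A", "B", "C"), chrom = "1",
                     pos = c(100L, 200L, 300L), effect_allele = "A",
                     other_allele = "G", eaf = 0.3, beta = 1, se = 0.1,
                     pvalue = c(1e-10, 1e-9, 1e-8), n = 1000,
                     stringsAsFactors = FALSE)
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- sqrt(0.5)       # r2(A,B) = 0.5
  r[1, 3] <- r[3, 1] <- sqrt(0.0005)
  r[2, 3] <- r[3, 2] <- sqrt(0.0005)
  ld <- LDMatrix(r, variant_ids = c("A", "B", "C"))
  kept <- clumpVariants(cand, ld, 0.001)
  expect_equal(kept$variant_id, c("A", "C"))

  expect_equal(clumpVariants(cand[1, ], ld)$variant_id, "A")
  expect_equal(nrow(clumpVariants(cand[0, ], ld)), 0L)
  cand2 <- cand
  cand2$variant_id[3] <- "missing"
  expect_error(clumpVariants(cand2, ld), "missing")
})

test_that("greedy clumping agrees with the exhaustive oracle", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:12, 1)
    ids <- sprintf("v%02d", seq_len(n))
    r <- randomLDish(n)
    p <- runif(n, 1e-12, 1e-4)
    cand <- data.frame(variant_id = ids, chrom = "1", pos = seq_len(n) * 100L,
                       effect_allele = "A", other_allele = "G", eaf = 0.3,
                       beta = 1, se = 0.1, pvalue = p, n = 1000,
                       stringsAsFactors = FALSE)
    thr <- sample(c(0.001, 0.01, 0.1, 0.5), 1)
    kept <- sort(match(clumpVariants(cand, LDMatrix(r, ids), thr)$variant_id, ids))
    oracle <- exhaustiveClumpOracle(p, r^2, thr)
    expect_equal(kept, oracle)
    r2kept <- (r^2)[kept, kept, drop = FALSE]
    expect_true(all(r2kept[upper.tri(r2kept)] < thr))
  }
})

test_that("selectInstruments applies cis, p, F and clump filters in order", {
  ids <- c("cis_strong", "cis_weakp", "far_strong")
  ss <- makeSS(ids, beta = c(0.8, 0.15, 0.8), se = c(0.02, 0.028, 0.02),
               pos = c(1000000L, 1010000L, 3100000L), n = 7213,
               trait_id = "PROT")
  ld <- LDMatrix(diag(3), variant_ids = ids)
  gene <- list(gene_id = "PROT", chrom = "1", tss = 1000000L)
  inst <- selectInstruments(ss, gene, ld, cis_window_bp = 1e6)
  # far_strong is 2.1 Mb from the TSS; cis_weakp has p ~ 8e-8 > 5e-8
  expect_equal(instrumentTable(inst)$variant_id, "cis_strong")
  cts <- stageCounts(inst)
  expect_equal(unname(cts), c(3L, 2L, 1L, 1L, 1L))
  expect_true(all(diff(unname(cts)) <= 0))
})

test_that("selectInstruments recovers independent significant cis variants and is order-invariant", {
  ds <- simulateRegion(simulationConfig("causal", seed = 5), gene_id = "G")
  inst <- selectInstruments(ds$protein_stats, ds$gene, ds$ld)
  expect_equal(nInstruments(inst), 3L)

  # brute-force reference filter: cis + p + F, then greedy clump
  df <- variants(ds$protein_stats)
  keep <- abs(df$pos - ds$gene$tss) <= 1e6 & df$chrom == ds$gene$chrom &
    df$pvalue < 5e-8
  df <- df[keep, ]
  pve <- df$beta^2 / (df$beta^2 + df$n * df$se^2)
  df <- df[pve * (df$n - 2) / (1 - pve) > 10, ]
  expect_setequal(instrumentTable(inst)$variant_id,
                  clumpVariants(df, ds$ld, 0.001)$variant_id)

  # permuting the input rows changes nothing
  shuf <- variants(ds$protein_stats)[sample(nrow(variants(ds$protein_stats))), ]
  ss2 <- SummaryStats(shuf, traitId(ds$protein_stats), "quantitative",
                      genome_build = "synthetic")
  inst2 <- selectInstruments(ss2, ds$gene, ds$ld)
  expect_equal(sort(instrumentTable(inst2)$variant_id),
               sort(instrumentTable(inst)$variant_id))
})

test_that("flagPleiotropy marks genome-wide-significant catalog hits only", {
  ds <- simulateRegion(simulationConfig("causal", seed = 5), gene_id = "G")
  inst <- selectInstruments(ds$protein_stats, ds$gene, ds$ld)
  v1 <- instrumentTable(inst)$variant_id[1]
  catalog <- data.frame(
    variant_id = c(v1, v1, "unrelated"),
    trait = c("waist circumference", "red blood cell count", "height"),
    pvalue = c(1e-12, 1e-6, 1e-30), stringsAsFactors = FALSE)
  flagged <- flagPleiotropy(inst, catalog)
  expect_true(isPleiotropic(flagged))
  expect_equal(pleiotropyFlags(flagged)[[1]], "waist circumference")

  none <- flagPleiotropy(inst, catalog[0, ])
  expect_false(isPleiotropic(none))
})
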