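# Reading, writing and harmonizing summary statistics.

writeRaw <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("readSummaryStats parses well-formed files and resolves synonyms", {
  f <- writeRaw(c("SNP\tCHR\tPOS\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
                  "rs1\t1\t100\tA\tG\t0.2\t0.5\t0.05\t1e-20\t7213",
                  "rs2\t1\t200\tC\tT\t0.4\t-0.1\t0.02\t1e-6\t7213",
                  "rs3\t2\t300\tG\tA\t0.1\t0.0\t0.10\t1.0\t7213"))
  ss <- readSummaryStats(f, trait_id = "PROT")
  expect_s4_class(ss, "SummaryStats")
  expect_equal(nVariants(ss), 3L)
  expect_equal(variants(ss)$beta, c(0.5, -0.1, 0))

  # synonym header, comma-delimited, extra column preserved
  f2 <- writeRaw(c("rsid,chromosome,position,a1,a2,freq,effect,standard_error,pval,sample_size,note",
                   "rs9,3,50,A,C,0.25,0.3,0.1,0.0027,500,hello"))
  ss2 <- readSummaryStats(f2, trait_id = "X")
  expect_equal(variants(ss2)$se, 0.1)
  expect_equal(variants(ss2)$note, "hello")
})

test_that("invalid rows are dropped with a message; fatal problems error", {
  f <- writeRaw(c("SNP\tCHR\tPOS\tEA\tOA\tBETA\tSE\tP\tN",
                  "rs1\t1\t100\tA\tG\t0.5\t0\t1e-20\t100",     # se = 0
                  "rs2\t1\t200\tA\tA\t0.1\t0.1\t0.5\t100",     # identical alleles
                  "rs3\t1\t300\tA\tG\t0.1\t0.1\t0.5\t100"))
  expect_message(ss <- readSummaryStats(f, trait_id = "X"),
                 "dropped 2 invalid row")
  expect_equal(variantIds(ss), "rs3")

  f_nose <- writeRaw(c("SNP\tCHR\tPOS\tEA\tOA\tBETA\tP\tN",
                       "rs1\t1\t100\tA\tG\t0.5\t1e-20\t100"))
  expect_error(readSummaryStats(f_nose, trait_id = "X"), "se")

  f_allbad <- writeRaw(c("SNP\tCHR\tPOS\tEA\tOA\tBETA\tSE\tP\tN",
                         "rs1\t1\t100\tA\tG\t0.5\t0\t1e-20\t100"))
  expect_error(suppressMessages(readSummaryStats(f_allbad, trait_id = "X")),
               "no valid rows")
})

test_that("lowercase alleles are upper-cased and survive a round-trip", {
  f <- writeRaw(c("SNP\tCHR\tPOS\tEA\tOA\tBETA\tSE\tP\tN",
                  "rs1\t1\t100\ta\tg\t0.5\t0.05\t1e-20\t100"))
  ss <- readSummaryStats(f, trait_id = "X")
  expect_equal(variants(ss)$effect_allele, "A")
  expect_equal(variants(ss)$other_allele, "G")
  out <- tempfile(fileext = ".tsv")
  writeSummaryStats(ss, out)
  back <- readSummaryStats(out, trait_id = "X")
  expect_equal(variants(back), variants(ss))
})

test_that("write/read round-trip is the identity on a synthetic trait", {
  set.seed(42)
  beta <- rnorm(100, 0, 0.2)
  ss <- makeSS(sprintf("rs%03d", 1:100), beta, se = runif(100, 0.01, 0.1),
               eaf = runif(100, 0.05, 0.95), trait_id = "SIM")
  f <- tempfile(fileext = ".tsv")
  writeSummaryStats(ss, f)
  back <- readSummaryStats(f, trait_id = "SIM")
  expect_equal(variants(back), variants(ss), tolerance = 1e-12)

  # binary traits carry case/control columns through the round-trip
  bb <- makeSS("rs1", 0.1, 0.02, trait_id = "VV", trait_type = "binary",
               n = 459702, n_cases = 22037, n_controls = 437665)
  fb <- tempfile(fileext = ".tsv")
  writeSummaryStats(bb, fb)
  hdr <- strsplit(readLines(fb, n = 1), "\t")[[1]]
  expect_true(all(c("N_CASES", "N_CONTROLS") %in% hdr))
  back_b <- readSummaryStats(fb, trait_id = "VV", trait_type = "binary")
  expect_equal(variants(back_b), variants(bb))
})

test_that("degenerate containers are rejected", {
  expect_error(makeSS(character(0), numeric(0), numeric(0)), "no variants")
  bad <- data.frame(variant_id = "rs1", chrom = "1", pos = 1L,
                    effect_allele = "A", other_allele = "G", eaf = 0.5,
                    beta = 0.1, se = 0.1, pvalue = 0.5, n = 10,
                    n_cases = 6, n_controls = 5)
  expect_error(SummaryStats(bad, "x", "binary"), "n_cases")
})

test_that("harmonize aligns, flips, complements and drops correctly", {
  exp_ss <- makeSS(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   beta = c(0.1, 0.1, 0.1, 0.1, 0.1), se = 0.02,
                   ea = c("A", "A", "A", "A", "A"),
                   oa = c("G", "G", "G", "G", "T"),
                   eaf = c(0.3, 0.3, 0.3, 0.3, 0.50), trait_id = "P")
  out_ss <- makeSS(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   beta = c(-0.05, -0.05, -0.05, -0.05, -0.05), se = 0.01,
                   ea = c("A", "G", "T", "A", "A"),
                   oa = c("G", "A", "C", "C", "T"),
                   eaf = c(0.3, 0.7, 0.3, 0.3, 0.5),
                   trait_id = "D", trait_type = "binary")
  h <- harmonize(exp_ss, out_ss, palindrome_eaf_window = 0.08)
  expect_equal(h$status,
               c("ok", "flipped", "ok", "dropped_mismatch",
                 "dropped_palindromic"))
  expect_equal(h$beta_out[1], -0.05)          # aligned: untouched
  expect_equal(h$beta_out[2], +0.05)          # swapped: negated
  expect_equal(h$eaf_out[2], 0.3)             # and frequency reflected
  expect_equal(h$beta_out[3], -0.05)          # strand complement, same order
})

test_that("palindromic strand is inferred from allele frequency outside the window", {
  exp_ss <- makeSS(c("rs1", "rs2"), beta = c(0.2, 0.2), se = 0.02,
                   ea = "A", oa = "T", eaf = c(0.2, 0.2), trait_id = "P")
  # rs1 agrees (same strand); rs2's frequency sits on the other side: flipped
  out_ss <- makeSS(c("rs1", "rs2"), beta = c(0.1, 0.1), se = 0.02,
                   ea = "A", oa = "T", eaf = c(0.19, 0.81), trait_id = "D")
  h <- harmonize(exp_ss, out_ss)
  expect_equal(h$status, c("ok", "flipped"))
  expect_equal(h$beta_out, c(0.1, -0.1))
  expect_equal(h$eaf_out, c(0.19, 0.19))

  # missing EAF on a palindromic variant: strand cannot be inferred
  out_na <- makeSS("rs1", 0.1, 0.02, ea = "A", oa = "T", eaf = NA, trait_id = "D")
  h_na <- harmonize(subsetVariants(exp_ss, "rs1"), out_na)
  expect_equal(h_na$status, "dropped_palindromic")
})

test_that("harmonization is involution-safe and errors sensibly", {
  ss <- makeSS(c("rs1", "rs2"), beta = c(0.3, -0.2), se = 0.05,
               eaf = c(0.2, 0.8), trait_id = "P")
  h <- harmonize(ss, ss)
  expect_true(all(h$status == "ok"))
  expect_equal(h$beta_out, variants(ss)$beta)
  expect_equal(h$eaf_out, variants(ss)$eaf)

  other <- makeSS("zz9", 0.1, 0.05, trait_id = "D")
  expect_error(harmonize(ss, other), "no overlapping variants")

  b37 <- makeSS("rs1", 0.1, 0.05, genome_build = "GRCh37")
  b38 <- makeSS("rs1", 0.1, 0.05, genome_build = "GRCh38")
  expect_error(harmonize(b37, b38), "genome build mismatch")
})

test_that("recoding the exposure's effect allele leaves the MR estimate unchanged", {
  set.seed(7)
  ds <- simulateRegion(simulationConfig("causal", seed = 3), gene_id = "G")
  inst <- selectInstruments(ds$protein_stats, ds$gene, ds$ld)
  tab <- instrumentTable(inst)
  mr1 <- mrEstimate(harmonize(tab, ds$disease_stats))
  # recode: swap alleles, negate beta, reflect eaf
  tab2 <- tab
  tab2$effect_allele <- tab$other_allele
  tab2$other_allele <- tab$effect_allele
  tab2$beta <- -tab$beta
  tab2$eaf <- 1 - tab$eaf
  mr2 <- mrEstimate(harmonize(tab2, ds$disease_stats))
  expect_equal(mrBeta(mr2), mrBeta(mr1))  # outcome re-aligns: estimate unchanged
  expect_equal(mrSE(mr2), mrSE(mr1))
  expect_equal(pValue(mr2), pValue(mr1))
})

test_that("readLDMatrix validates shape, bounds, diagonal and symmetry", {
  f <- tempfile()
  writeLDMatrix(LDMatrix(diag(2), variant_ids = c("rs1", "rs2")), f)
  ld <- readLDMatrix(f)
  expect_s4_class(ld, "LDMatrix")
  expect_equal(variantIds(ld), c("rs1", "rs2"))
  expect_equal(ldR(ld), diag(2), ignore_attr = TRUE)

  writeBad <- function(r) {
    df <- data.frame(ID = c("a", "b"), r)
    names(df) <- c("ID", "a", "b")
    fb <- tempfile()
    write.table(df, fb, sep = "\t", quote = FALSE, row.names = FALSE)
    fb
  }
  expect_error(readLDMatrix(writeBad(matrix(c(1, 1.2, 1.2, 1), 2))), "\\|r\\| > 1")
  expect_error(readLDMatrix(writeBad(matrix(c(1, 0.5, 0.5, 0.9), 2))), "diagonal")
  expect_error(readLDMatrix(writeBad(matrix(c(1, 0.2, 0.6, 1), 2))), "asymmetry")

  # asymmetry far below tolerance is averaged away
  r <- matrix(c(1, 0.5, 0.5 + 1e-12, 1), 2)
  fb <- writeBad(r)
  ld2 <- readLDMatrix(fb)
  expect_identical(ldR(ld2), t(ldR(ld2)))
})

test_that("gene annotation and trait catalog readers work", {
  fg <- tempfile()
  writeLines(c("GENE\tCHR\tTSS", "RSPO3\t6\t127439749"), fg)
  g <- readGeneAnnotation(fg)
  expect_equal(g$gene_id, "RSPO3")
  expect_equal(g$tss, 127439749L)

  fc <- tempfile()
  writeLines(c("SNP\tTRAIT\tP", "rs1892172\tWaist circumference\t1e-12"), fc)
  cat <- readTraitCatalog(fc)
  expect_equal(cat$trait, "Waist circumference")
})
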