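# Wald ratio, IVW, odds-ratio reporting, Bonferroni threshold.

test_that("waldRatio matches the hand-worked example", {
  pair <- makePairs(beta_exp = 0.1, se_exp = 0.01, beta_out = 0.05,
                    se_out = 0.01)
  mr <- waldRatio(pair)
  expect_equal(mrBeta(mr), 0.5)
  expect_equal(mrSE(mr), 0.1)
  expect_equal(pValue(mr), 2 * pnorm(-5))
  expect_equal(nSnps(mr), 1L)
  expect_equal(mrMethod(mr), "wald_ratio")
})

test_that("waldRatio handles nulls, recoding and the zero-exposure error", {
  null_pair <- makePairs(0.1, 0.01, 0, 0.01)
  expect_equal(mrBeta(waldRatio(null_pair)), 0)
  expect_equal(pValue(waldRatio(null_pair)), 1)

  pair <- makePairs(0.1, 0.01, 0.05, 0.01)
  recoded <- pair
  recoded$beta_exp <- -pair$beta_exp
  recoded$beta_out <- -pair$beta_out
  expect_equal(mrBeta(waldRatio(recoded)), mrBeta(waldRatio(pair)))
  expect_equal(mrSE(waldRatio(recoded)), mrSE(waldRatio(pair)))

  expect_error(waldRatio(makePairs(0, 0.01, 0.05, 0.01)), "zero")
})

test_that("mrIVW matches the hand-worked weights and pools correctly", {
  # ratios 0.4 (s = 0.1) and 0.8 (s = 0.2): weights 100 and 25
  pairs <- makePairs(beta_exp = c(1, 1), se_exp = c(1e-6, 1e-6),
                     beta_out = c(0.4, 0.8), se_out = c(0.1, 0.2))
  mr <- mrIVW(pairs)
  expect_equal(mrBeta(mr), 0.48)
  expect_equal(mrSE(mr), sqrt(1 / 125))
  expect_equal(mrSE(mr), 0.08944, tolerance = 1e-4)
  expect_equal(mrMethod(mr), "ivw")
  expect_false(is.na(mr@q_stat))

  # two identical instruments: same point estimate, se / sqrt(2)
  one <- makePairs(1, 1e-6, 0.4, 0.1)
  dup <- rbind(one, one)
  expect_equal(mrBeta(mrIVW(dup)), 0.4)
  expect_equal(mrSE(mrIVW(dup)), 0.1 / sqrt(2))
})

test_that("IVW estimate lies within the per-instrument ratios with a smaller se", {
  set.seed(30)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    pairs <- makePairs(beta_exp = runif(k, 0.2, 1), se_exp = runif(k, 0.01, 0.05),
                       beta_out = rnorm(k, 0.1, 0.05), se_out = runif(k, 0.01, 0.1))
    ratios <- pairs$beta_out / pairs$beta_exp
    ses <- pairs$se_out / abs(pairs$beta_exp)
    mr <- mrIVW(pairs)
    expect_gte(mrBeta(mr), min(ratios))
    expect_lte(mrBeta(mr), max(ratios))
    expect_lt(mrSE(mr), min(ses))
  }
})

test_that("mrEstimate dispatches on instrument count and drops zero-exposure pairs", {
  one <- makePairs(0.1, 0.01, 0.05, 0.01)
  expect_equal(mrBeta(mrEstimate(one)), mrBeta(waldRatio(one)))
  expect_equal(mrMethod(mrEstimate(one)), "wald_ratio")

  three <- makePairs(c(1, 1, 0), c(0.01, 0.01, 0.01),
                     c(0.4, 0.8, 0.2), c(0.1, 0.2, 0.1))
  expect_warning(mr <- mrEstimate(three), "zero exposure effect")
  expect_equal(nSnps(mr), 2L)
  expect_equal(mrBeta(mr), 0.48)

  none <- makePairs(1, 0.01, 0.4, 0.1)
  none$status <- "dropped_mismatch"
  expect_error(mrEstimate(none), "no usable instrument")
})

test_that("random-effects IVW never shrinks the standard error", {
  pairs <- makePairs(c(1, 1, 1), rep(1e-6, 3), c(0.1, 0.9, 0.5),
                     c(0.05, 0.05, 0.05))
  fe <- mrIVW(pairs)
  re <- mrIVW(pairs, random_effects = TRUE)
  expect_equal(mrBeta(re), mrBeta(fe))
  expect_gt(mrSE(re), mrSE(fe))   # strong heterogeneity here
})

test_that("toOddsRatio matches the reporting convention", {
  or0 <- toOddsRatio(0, 0.1)
  expect_equal(unname(or0["or"]), 1)
  expect_equal(unname(or0["ci_low"] * or0["ci_high"]), 1)  # symmetric on log scale

  # consistency with a published-style row: log(0.88) with the se implied
  # by a printed 0.84-0.92 interval
  or <- toOddsRatio(-0.1278, 0.0232)
  expect_equal(unname(round(or["or"], 2)), 0.88)
  expect_equal(unname(round(or["ci_low"], 2)), 0.84)
  expect_equal(unname(round(or["ci_high"], 2)), 0.92)

  tight <- toOddsRatio(log(2), 1e-12)
  expect_equal(unname(tight["or"]), 2)
  expect_equal(unname(tight["ci_high"] - tight["ci_low"]), 0, tolerance = 1e-9)
})

test_that("bonferroniThreshold divides the alpha", {
  expect_equal(bonferroniThreshold(0.05, 2004), 0.05 / 2004)
  expect_equal(bonferroniThreshold(0.05, 2004), 2.495e-5, tolerance = 1e-5)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.05, 525), 9.5238e-5, tolerance = 1e-4)
  expect_error(bonferroniThreshold(0.05, 0), "n_tests")
})

test_that("not-testable results are explicit and non-significant", {
  nt <- mrNotTestable("disease", "PROT")
  expect_false(isTestable(nt))
  expect_false(isSignificant(nt))
  expect_equal(nSnps(nt), 0L)
  expect_true(all(is.na(oddsRatio(nt))))
})
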