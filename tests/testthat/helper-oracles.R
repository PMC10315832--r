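# Independent oracles and small fixture builders used across the suite.

# Build a SummaryStats from parallel vectors with sensible defaults.
makeSS <- function(ids, beta, se, pvalue = NULL, eaf = 0.3, n = 10000,
                   chrom = "1", pos = NULL, ea = "A", oa = "G",
                   trait_id = "trait", trait_type = "quantitative",
                   genome_build = "unspecified", n_cases = NA, n_controls = NA) {
  k <- length(ids)
  if (is.null(pos)) pos <- seq_len(k) * 1000L
  if (is.null(pvalue)) pvalue <- pmax(2 * pnorm(-abs(beta / se)),
                                      .Machine$double.xmin)
  SummaryStats(data.frame(variant_id = ids, chrom = rep_len(chrom, k),
                          pos = pos, effect_allele = rep_len(ea, k),
                          other_allele = rep_len(oa, k),
                          eaf = rep_len(eaf, k),
                          beta = beta, se = rep_len(se, k), pvalue = pvalue,
                          n = rep_len(n, k),
                          n_cases = rep_len(n_cases, k),
                          n_controls = rep_len(n_controls, k),
                          stringsAsFactors = FALSE),
               trait_id = trait_id, trait_type = trait_type,
               genome_build = genome_build)
}

# Build an already-harmonized pair table directly (bypasses harmonize()).
makePairs <- function(beta_exp, se_exp, beta_out, se_out,
                      n_exp = 10000, n_out = 100000, eaf = 0.3) {
  k <- length(beta_exp)
  data.frame(variant_id = sprintf("rs%d", seq_len(k)),
             effect_allele = "A", other_allele = "G",
             beta_exp = beta_exp, se_exp = se_exp, eaf_exp = eaf,
             pvalue_exp = pmax(2 * pnorm(-abs(beta_exp / se_exp)),
                               .Machine$double.xmin),
             n_exp = n_exp,
             beta_out = beta_out, se_out = se_out, eaf_out = eaf,
             pvalue_out = pmax(2 * pnorm(-abs(beta_out / se_out)),
                               .Machine$double.xmin),
             n_out = n_out, status = "ok", stringsAsFactors = FALSE)
}

# Naive colocalization oracle: per-variant Bayes factors from the marginal
# Gaussian densities (a route independent of the log-ABF formula) and direct
# hypothesis enumeration without log-space tricks. Only safe for small |z|.
naiveColocOracle <- function(b1, s1, b2, s2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             sd1 = 0.15, sd2 = 0.2) {
  bf <- function(b, s, w) dnorm(b, 0, sqrt(s^2 + w^2)) / dnorm(b, 0, s)
  bf1 <- bf(b1, s1, sd1)
  bf2 <- bf(b2, s2, sd2)
  n <- length(b1)
  h3 <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j) h3 <- h3 + bf1[i] * bf2[j]
  m <- c(1, p1 * sum(bf1), p2 * sum(bf2), p1 * p2 * h3, p12 * sum(bf1 * bf2))
  setNames(m / sum(m), paste0("pph", 0:4))
}

# Exhaustive clumping oracle: enumerate every subset that is pairwise
# independent at the threshold and return the one that lexicographically
# prefers smaller p-values (equivalent to greedy selection, derived
# independently of the greedy code path).
exhaustiveClumpOracle <- function(pvals, r2mat, threshold) {
  n <- length(pvals)
  stopifnot(n <= 15, !anyDuplicated(pvals))
  masks <- 0:(2^n - 1)
  indep <- rep(TRUE, length(masks))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (r2mat[i, j] >= threshold) {
      pm <- bitwOr(bitwShiftL(1L, i - 1L), bitwShiftL(1L, j - 1L))
      indep[bitwAnd(masks, pm) == pm] <- FALSE
    }
  }
  rank <- match(seq_len(n), order(pvals))
  score <- numeric(length(masks))
  for (k in seq_len(n)) {
    has <- bitwAnd(masks, bitwShiftL(1L, k - 1L)) != 0
    score[has] <- score[has] + 2^(n - rank[k])
  }
  best <- masks[indep][which.max(score[indep])]
  which(bitwAnd(best, bitwShiftL(1L, seq_len(n) - 1L)) != 0)
}

# random LD-like matrix: symmetric, unit diagonal, entries in [-1, 1]
randomLDish <- function(n) {
  r <- matrix(runif(n * n, -1, 1), n, n)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}
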