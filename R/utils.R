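# internal numeric helpers

# z multiplier for a 95% Wald interval
.CI_Z <- 1.959964

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# two-sided normal p-value; clamped away from 0 so the (0, 1] invariant
# survives extreme z-scores that underflow double precision
.zToP <- function(z) {
  pmin(pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin), 1)
}

.complementAllele <- function(a) chartr("ACGT", "TGCA", a)

# single-base alleles that are their own strand complement (A/T, C/G)
.isPalindromic <- function(ea, oa) {
  nchar(ea) == 1L & nchar(oa) == 1L & .complementAllele(ea) == oa
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
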