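---
title: "Methods: proteome-wide MR drug-target screening with proteoMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR drug-target screening with proteoMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoMR)
```

# The model

`proteoMR` screens a plasma proteome for causal effects on a binary disease
outcome with two-sample Mendelian randomization. The structural model for
protein $X$ (in SD units) and disease liability (log-odds) $Y$ is

$$ X = \beta_{G} G + u_X, \qquad
   \mathrm{logit}\,P(Y=1) = \theta X + \alpha G + u_Y, $$

where $G$ are genotypes near the protein's gene. Under the usual instrument
assumptions (relevance, independence from confounders $u$, and exclusion
restriction $\alpha = 0$), the ratio of marginal GWAS coefficients at an
instrument estimates $\theta$. The package operates entirely on summary
statistics: per-variant marginal estimates $(\hat\beta, \widehat{se})$ for
each trait, plus a signed LD correlation matrix for each region.

Each stage of the screen attacks one failure mode of that model:

* **cis restriction** — instruments within ±1 Mb of the gene's TSS, because
  a variant acting through the local gene is least likely to violate the
  exclusion restriction.
* **Strength filters** — $p < 5\times 10^{-8}$ and $F > 10$, with
  $\mathrm{PVE} = \hat\beta^2 / (\hat\beta^2 + N\,\widehat{se}^2)$ and
  $F = \mathrm{PVE}(N-2)/(1-\mathrm{PVE})$ for a single variant; weak
  instruments bias ratio estimates toward the confounded association.
* **LD clumping** — greedy by significance at $r^2 < 0.001$, so the
  inverse-variance weights of the pooled estimator treat instruments as
  independent.
* **Steiger filtering and bidirectional MR** — reject proteins whose
  "instruments" are really disease variants (reverse causation).
* **Colocalization** — distinguish a shared causal variant from two distinct
  variants in LD (confounding by linkage).
* **Replication and pleiotropy scanning** — external consistency and a
  catalog check of instruments against other traits.

# Estimators

For one instrument, the Wald ratio
$\hat\theta = \hat\beta_{out}/\hat\beta_{exp}$ with first-order
delta-method error $se = \widehat{se}_{out}/|\hat\beta_{exp}|$. For $k \ge 2$
instruments, the fixed-effect IVW estimate pools the per-instrument ratios
$b_i$ with weights $w_i = 1/s_i^2$:
$\hat\theta = \sum w_i b_i / \sum w_i$, $se = (\sum w_i)^{-1/2}$.
P-values are two-sided normal — the summary-statistic MR convention — and
95% intervals use $z = 1.959964$. Cochran's $Q$ across ratios is always
computed and stored; a multiplicative random-effects inflation
($se \times \sqrt{\max(1, Q/(k-1))}$) is available as a toggle
(`random_effects`), with fixed effects as the default because it is the
minimal reading of "inverse-variance weighted" and the instruments have
already been filtered for independence. Estimates on a binary outcome are
reported as odds ratios per SD of protein.

The Steiger test sums PVE over the clumped instruments per trait, converts
to correlations $r = \sqrt{\mathrm{PVE}}$, and compares Fisher-z transforms:
$z = (\mathrm{atanh}\,r_{exp} - \mathrm{atanh}\,r_{out}) /
\sqrt{1/(n_{exp}-3) + 1/(n_{out}-3)}$. The verdict is *passed* iff the
direction is correct **and** $p < 0.05$. For the binary outcome the same
observed-scale PVE formula is used with total $N$; this is an approximation
(no liability-scale conversion) and is consistent between the forward and
reverse applications, which is what the verdict compares.

# Colocalization

`colocABF()` implements the single-causal-variant enumeration with Wakefield
log approximate Bayes factors per variant,
$\log\mathrm{ABF} = \tfrac12[\log(V/(V+W)) + z^2 W/(V+W)]$ with $V =
\widehat{se}^2$ and prior effect variance $W$. Hypothesis masses are
$1,\; p_1 S_1,\; p_2 S_2,\; p_1 p_2 (S_1 S_2 - S_{12}),\; p_{12} S_{12}$
where $S_1, S_2, S_{12}$ are sums of $e^{l_1}$, $e^{l_2}$, $e^{l_1+l_2}$.
All sums run in log space (log-ABFs above 700 are routine at biobank sample
sizes) and posteriors are clamped to $[0,1]$ after normalization. With one
variant, $S_1 S_2 - S_{12} = 0$ exactly, so H3 is impossible — the
implementation reproduces this limit by construction.

Defaults: priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ (the canonical
choices for this model); prior effect SD 0.15 for quantitative traits (SD
scale) and 0.2 for binary traits (log-odds scale), picked automatically from
the trait type and overridable. The colocalization region is the same ±1 Mb
cis window used for instrument selection, and the call is strict:
colocalized iff PPH4 > 0.8.

# Reverse-causality verdict

Reverse causation is *confirmed* when the reverse (disease-on-protein) MR is
significant at 0.05 **or** Steiger filtering failed; a reverse MR with no
surviving instruments is an explicit "not testable" result that counts as
non-significant, never as a silent pass.

One design choice deserves emphasis. Reverse-MR instruments are selected
from the disease GWAS with the same strength/independence criteria (no cis
restriction), and by default each candidate must also explain more variance
in the disease than in the protein (a per-variant Steiger direction check,
`steiger_filter_instruments`). Without this, any true protein-to-disease
effect makes every strong pQTL a genome-wide-significant disease variant,
and a reverse MR run inside the cis region would "confirm" reverse causation
for exactly the true targets. The filter is the standard remedy and makes
the reverse test informative in both directions: under true forward
causation it removes all shared instruments (reverse MR: not testable; no
reverse evidence), while under true reverse causation disease variants
dominate their downstream protein echoes and survive.

# The synthetic-data generator

`simulateRegion()` draws summary statistics directly:

* LD is AR-1: $r_{ij} = \rho^{|i-j|}$ with adjacent correlation $\rho$.
* True marginal effects are the LD convolution of sparse causal effects:
  variant $i$'s truth is $\sum_c r_{ic}\,\beta_c$.
* Observed effects are $\hat\beta_i \sim N(\text{truth}_i, se_i^2)$ with the
  standard GWAS error $se_i = 1/\sqrt{2 f_i (1-f_i) N}$, MAF $f_i$ drawn
  uniformly from `maf_range`.
* The disease truth is $\theta$ times the protein truth plus any direct
  (pleiotropic) contributions; in the reverse scenario the causal effects
  act on the disease and the protein inherits `reverse_effect` times the
  disease truth.

Scenario presets encode the emulated study conditions: a 7,213-sample
protein GWAS, a 22,037-case / 437,665-control outcome GWAS (total 459,702),
a 35,559-sample replication pGWAS, and a 100,000-sample pGWAS in the reverse
scenario. Lead cis-pQTL effects default to 1 SD per allele — at MAF ~0.3
that is PVE ≈ 0.3, typical of the strongest plasma cis-pQTLs — and the
default causal protein effect is $\theta = -0.2$ log-odds/SD. Coloc
scenarios use 200-variant regions with $\rho = 0.95$ and causal variants
placed so that the distinct-variant pair has $r^2 < 0.01$; the
replicate-heavy causal/null scenarios use 60-variant regions with
$\rho = 0.6$, a problem size chosen so that large replicate counts stay
cheap while clumping still has real LD to remove.

What the generator does **not** emulate, and what that implies:

* **Sampling noise is independent across variants.** In a single cohort the
  errors of marginal estimates at linked variants are correlated through the
  genotype LD. With independent noise and very large $|z|$, the
  highest-ABF variant occasionally differs decisively between the two
  traits, and single-causal-variant colocalization then splits to H3. This
  is why the shared-causal scenario yields PPH4 > 0.8 in about 90% of
  replicates rather than in all of them; passing that property demonstrates
  the enumeration is correct under the stated model, not that coloc is
  immune to this failure mode on real data (it is not).
* **Disease effects are generated on the log-odds scale with the
  quantitative-trait error formula**; case/control counts enter only as
  metadata. Adequate for calibration of estimators that consume
  $(\hat\beta, \widehat{se})$, but absolute PVE values for the binary trait
  are observed-scale approximations.
* No minor-allele-frequency spectrum, no strand ambiguity, no missingness:
  harmonization edge cases are exercised by dedicated unit fixtures instead.

P-values that underflow double precision are clamped to the smallest
positive double so the $(0,1]$ invariant holds; selection only ever compares
them against thresholds far above that floor.

# Pipeline decisions

* **Validation rule.** `validated_target` requires: Bonferroni-significant,
  no reverse-causality evidence, PPH4 > 0.8, replication at $p<0.05$ with
  concordant direction, and no pleiotropy flag. Direction concordance goes
  beyond a bare $p<0.05$ replication rule because a significant
  opposite-direction effect is not a replication; the pleiotropy demotion is
  a toggle (`demote_pleiotropic`) since a catalog hit sometimes reflects the
  protein's own downstream biology — the flag and the traits are always
  reported so users can apply their own judgment. A missing replication
  source caps a protein at `prioritized`.
* **Harmonization.** Positions are 1-based; both traits must declare the
  same genome-build label (mismatch is a hard error; no liftover).
  Palindromic variants are dropped when either trait's EAF is missing or in
  $0.5 \pm 0.08$; outside the window strand is inferred from frequency
  agreement. Indels are matched exactly and never treated as palindromic.
  Alleles are upper-cased on read; unknown columns ride along untouched.
* **Clumping ties** are broken by (chromosome, position, variant id) so the
  retained set is deterministic; the greedy solution is verified against an
  exhaustive-enumeration oracle in the tests.
* **Filter order** is fixed (cis → p → F → clump) so the per-stage counts
  reported in the screen ledger are reproducible; PVE/F are only computed
  for significant cis candidates.
* **PheW-MR** adjusts across the disease battery with Benjamini–Hochberg by
  default (a Bonferroni toggle exists); effects are standardized by
  $\ln(0.9)/\hat\theta_{VV}$, the signed protein change whose predicted
  effect equals a 10% risk reduction in the primary outcome, with CI bounds
  swapped when the factor is negative.

# Test problem sizes

The statistical properties are checked at these sizes: IVW parameter
recovery over 200 simulated proteins (outcome $N = 400{,}000$); type-I
calibration over 2,000 null replicates (rejection rate within
$[0.03, 0.07]$); colocalization against a naive enumeration oracle on 100
random regions of ≤10 variants (agreement to $10^{-10}$) and scenario
discrimination over 50 replicates each; Steiger orientation and reverse
detection over 200 replicates each; clumping against the exhaustive oracle
on 500 random instances of ≤15 variants. `scripts/acceptance.R` recomputes
all of these from a single `--seed`.

# Known limitations

Single-causal-variant colocalization only (no multi-signal decomposition or
conditional analysis); observed-scale PVE for binary traits; fixed-effect
IVW as default with heterogeneity reported rather than modeled; LD is an
input, never computed from genotypes; no genome-build liftover; published
per-protein results from real proteome screens require the original external
GWAS sources, which are not shipped.
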