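# proteoMR

Proteome-wide Mendelian randomization (MR) screening of candidate drug
targets from GWAS summary statistics.

## The problem

Observational associations between circulating proteins and disease are
confounded and can run in either direction. Two-sample MR uses genetic
variants as instruments: a variant that shifts a protein's plasma level
(a *cis*-pQTL, lying near the encoding gene) perturbs the protein from
conception onward, so its downstream association with disease estimates the
protein's causal effect. Screening a full plasma proteome this way — as has
been done for outcomes such as varicose veins — surfaces proteins whose
modulation is predicted to change disease risk, i.e. candidate drug targets.

`proteoMR` implements the whole screen for users with protein GWAS
("pGWAS") and disease GWAS summary statistics:

1. **Instrument selection** (`selectInstruments()`): cis window around the
   gene TSS (±1 Mb default), genome-wide significance (p < 5×10⁻⁸),
   instrument strength (F > 10, with PVE = β²/(β² + N·se²) and
   F = PVE·(N−2)/(1−PVE)), greedy LD clumping (r² < 0.001).
2. **Causal estimation** (`mrEstimate()`): Wald ratio β_out/β_exp for a
   single instrument; fixed-effect inverse-variance-weighted (IVW) pooling
   of per-instrument ratios otherwise, reported as odds ratios per SD of
   protein with 95% CIs, prioritized at a Bonferroni threshold
   (`bonferroniThreshold(0.05, n)`).
3. **Reverse-causality testing** (`steigerTest()`, `bidirectionalMR()`):
   MR Steiger filtering (instruments must explain more variance in the
   protein than in the disease; Fisher-z comparison of the implied
   correlations) plus reverse MR with disease instruments; either failing
   confirms reverse causation (`reverseCausalityVerdict()`).
4. **Colocalization** (`colocABF()`): Wakefield approximate Bayes factors
   per variant and enumeration of the five single-causal-variant hypotheses;
   PPH4 > 0.8 supports a shared causal variant.
5. **Pleiotropy scan** (`flagPleiotropy()`): instruments checked against a
   local SNP–trait catalog at p < 5×10⁻⁸ (advisory, never silently drops).
6. **Replication** (`replicateTargets()`): re-estimation from an alternative
   pQTL source; replicated means p < 0.05 with concordant direction.
7. **PheW-MR** (`phewasScreen()`): the protein tested against a battery of
   disease GWASs, effects standardized to the protein change giving a 10%
   reduction in the primary outcome's risk
   (`scalingToTarget()` = ln 0.9 / β), BH-FDR across the battery.

`runScreen()` orchestrates 1–6 end to end; `simulateRegion()` /
`simulateScreen()` generate summary statistics with known ground truth
(AR-1 LD blocks, shared/distinct causal variants, horizontal pleiotropy,
reverse causation) so everything is testable without external downloads.

## Worked example

```r
library(proteoMR)

# four synthetic proteins: two causal (theta = -0.2 log-odds/SD), two null
scr <- simulateScreen(4, seed = 42, include_replication = TRUE,
                      overrides = list(NULL, list(theta = 0),
                                       NULL, list(theta = 0)))
report <- runScreen(scr$datasets, scr$outcome, n_tests = 4)
report
#> ScreenReport: 4 protein(s)
#>   not_instrumentable 0
#>   not_significant    2
#>   prioritized        0
#>   validated_target   2

tab <- reportTable(report)
tab[c("protein_id", "n_instruments", "or", "pvalue",
      "steiger_verdict", "pph4", "replication_status", "status")]
#>   protein_id n_instruments    or    pvalue steiger_verdict pph4 replication_status           status
#> 1       P001             3 0.823 2.23e-308          passed    1         replicated validated_target
#> 2       P002             3 1.001  6.40e-01            <NA>   NA               <NA>  not_significant
#> 3       P003             3 0.815 2.23e-308          passed    1         replicated validated_target
#> 4       P004             3 0.999  3.87e-01            <NA>   NA               <NA>  not_significant

screenDetails(report)$P001$mr
#> MRResult P001 -> disease [ivw, 3 SNP(s)]
#>   OR 0.823 (95% CI 0.821-0.825), p = 2.23e-308
```

The two proteins simulated with a protective effect (true OR per SD
exp(−0.2) ≈ 0.819) are recovered with three cis instruments each, pass the
Bonferroni cut, Steiger/bidirectional directionality, colocalization
(PPH4 = 1) and replication, and end as `validated_target`; the null
proteins remain `not_significant`. `writeScreenReport(report, dir)` writes
the report as TSV tables.

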