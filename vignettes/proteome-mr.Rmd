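---
title: "Proteome-wide Mendelian randomization with protmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-wide Mendelian randomization with protmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(protmr)
```

protmr screens plasma proteins as causal candidates for a binary disease
outcome using two-sample Mendelian randomization (MR) on GWAS and pQTL
summary statistics. Genetic variants that alter a protein's circulating
level are assigned at conception, so — under the usual instrumental-variable
assumptions — an association between those variants and disease risk implies
a causal effect of the protein, free of the confounding and reverse
causation that plague observational proteomics.

This vignette walks through the data model, each analysis stage and its
statistical definition, the triangulation rules that combine several
exposure–outcome cohort pairings, and the design of the synthetic-data
generator used to validate all of it.

## Data model

All inputs are `sumstats()` tables: one row per variant with
`variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
`beta`, `se`, `pval`, `n` (optionally `eaf`, `n_cases`, `n_controls`), plus
trait metadata. The constructor validates every field, drops invalid rows,
and records why in a `drop_log` attribute. `read_sumstats()` ingests TSV or
CSV files, with a `column_map` for non-standard headers.

`harmonize()` aligns an exposure and an outcome table to a common effect
allele. Alleles that match after swapping or strand complementation flip the
outcome effect sign (and allele frequency); palindromic variants (A/T, C/G),
whose orientation is ambiguous, are excluded, as are incompatible allele
pairs. The per-variant decision is kept in the `action` column and an
`action_log` attribute.

## Instrument selection

`build_instrument_set()` applies, in order:

1. **cis filter** — variants within a window (default 1 Mb) of the
   protein-coding gene, since cis-pQTLs are less prone to pleiotropy;
2. **significance** — pQTL p-value strictly below 5×10⁻⁸;
3. **LD clumping** — greedy selection by ascending p-value, removing
   variants with r² above 0.001 with an already-kept variant;
4. **palindromic exclusion**;
5. **strength** — per-variant r² = 2·EAF(1−EAF)·β² and
   F = r²(n−2)/(1−r²); instruments with F below 10 are dropped.

Removals are logged per stage in `filter_log`.

## MR estimators

Dispatch depends on the surviving instrument count: one variant gives the
Wald ratio; two give inverse-variance weighted (IVW) only; three or more add
MR-Egger, the weighted median, and the weighted mode.

- **Wald ratio**: β = β_GY/β_GX with the first-order delta-method SE.
- **IVW**: the weighted mean of the per-variant ratios with weights
  β_GX²/se_GY² (equivalently, a zero-intercept WLS fit). Under-dispersion is
  not rewarded: when Cochran's Q per degree of freedom exceeds 1, the SE is
  inflated by √(Q/(n−1)) (multiplicative random effects).
- **MR-Egger**: WLS of β_GY on β_GX with a free intercept, after orienting
  all β_GX ≥ 0. The intercept estimates directional pleiotropy; its
  one-sided test is the pleiotropy diagnostic. Inference uses t-tests with
  n−2 degrees of freedom and no shrinking of the residual SE below 1.
- **Weighted median**: the interpolated weighted median of the per-variant
  ratios (Bowden's estimator, with cumulative weight points
  p_j = (cum_j − w_j/2)/Σw), consistent when valid instruments carry at
  least half the weight. SE by parametric bootstrap.
- **Weighted mode**: the mode of a weighted Gaussian kernel density over the
  ratios, with the modified Silverman bandwidth
  0.9·min(sd, mad)·n^(−1/5) times a tunable factor; consistent when the
  largest group of instruments sharing a ratio is valid. SE by parametric
  bootstrap.

Results are reported as log odds ratios with ORs and 95% CIs.

## Directionality: Steiger filtering and reverse MR

`steiger_filter()` computes per-variant variance explained on both sides
from the z-score form r² = z²/(z² + n − 2) and keeps variants whose
exposure r² significantly exceeds the outcome r² (one-sided Fisher-z test).
For a binary outcome this uses the observed-scale approximation, which is
conservative for a rare disease: outcome r² is small, so genuine
protein→disease instruments are rarely lost.

`reverse_mr()` treats the disease as the exposure. Diseases often have few
genome-wide-significant variants, so if fewer than a minimum count survive
at 5×10⁻⁸, selection retries at a lenient 5×10⁻⁶ (recorded in the result's
attributes). Fewer than the minimum even then yields a `not_testable`
status rather than a forced estimate.

## Colocalization

A significant MR signal can be driven by a nearby variant in LD rather than
the protein's own causal variant. `coloc_abf()` computes posterior
probabilities of the five standard hypotheses (no association; exposure
only; outcome only; two distinct causal variants; one shared causal
variant) from Wakefield approximate Bayes factors,
log ABF = ½log(1−r) + ½·r·z² with r = W/(V+W), prior effect SDs 0.15
(quantitative) and 0.2 (case-control), and per-variant priors
p1 = p2 = 10⁻⁴, p12 = 10⁻⁵. All sums are done in log space. The decision
rule `coloc_decision()` requires PP(H3) + PP(H4) strictly above 0.5: a
shared regional signal, whether or not the same variant is distinguishable,
supports the MR finding; a sum of exactly 0.5 fails.

## Triangulation and gating

`analyze_panel()` runs three exposure–outcome pairings per protein (two
pQTL cohorts crossed with two disease cohorts). `triangulate_proteins()`
labels a protein a **candidate** when it is present in all three analyses,
nominally significant (p < 0.05) in at least two, and directionally
consistent in all; BH false-discovery-rate adjustment is applied within
each analysis and reported alongside. `gate_candidates()` then promotes a
candidate to **validated** only if colocalization passes in all three
analyses and reverse MR is clear (no reverse signal; a `not_testable`
reverse analysis counts as clear but is flagged). `run_pipeline()` wraps
the whole flow and writes TSV outputs plus a JSON manifest.

```{r example}
panel <- simulate_panel(n_proteins = 4, n_causal = 1, n_protective = 0,
                        true_beta = 0.6, n_snps = 6, n_exposure = 6000,
                        n_outcome = 8000, case_fraction = 0.2, seed = 31)
report <- analyze_panel(panel, protmr_config(n_boot = 20, seed = 31))
report$gated[, c("protein_id", "candidate", "coloc_pass_count",
                 "reverse_mr_clear", "validated")]
panel$truth$protein_id[panel$truth$causal]
```

## The synthetic-data generator

Because real pQTL/GWAS data cannot ship with the package, every stage is
validated against `simulate_pair()` and `simulate_panel()`, which generate
individual-level data with known ground truth and then summarize it,
exactly as a GWAS would:

- **Genotypes** are Hardy–Weinberg dosages coupled through a Gaussian
  copula with a latent AR(1) correlation. The latent correlation of each
  adjacent pair is calibrated by root-finding so that the *dosage*
  correlation equals the requested `ld_decay`; when unequal allele
  frequencies make the target unattainable (the Fréchet bound), the
  calibration caps at the bound instead of failing.
- **Protein levels** are linear in the genotypes with unit residual
  variance (the generator refuses configurations whose genetic variance
  approaches 1).
- **Disease status** is Bernoulli with a logistic link; the intercept is
  calibrated by root-finding to hit the requested case fraction. The
  outcome association scan is logistic regression per variant, so outcome
  effects are genuine log odds ratios with all the finite-sample noise of a
  real case-control GWAS.
- **Scenarios** (`mr_scenario()`) cover the null, a causal effect,
  balanced and directional pleiotropy (a configurable fraction of invalid
  instruments with direct outcome effects), reverse causation, and the
  colocalization hypotheses H3 (two distinct regional causal variants) and
  H4 (one shared variant). Extremely strong associations clamp p-values at
  10⁻³⁰⁰ rather than dropping variants.

All simulation and analysis randomness is controlled by integer seeds, with
independent streams derived per component, so results are byte-identical
across runs.

## Validation studies

The acceptance tests (in `tests/testthat/test-acceptance.R`, with a
reduced-replicate JSON report via `scripts/acceptance.R`) run fixed
Monte-Carlo designs, sized a priori:

- estimator recovery of a true log OR of 0.3 (30 instruments,
  50k/50k samples) within 0.02 (IVW) or 0.05 (sensitivity estimators);
- IVW type-I error within [0.035, 0.065] over 1000 null replicates;
- weighted-median bias under 40% invalid instruments below one third of
  the IVW bias;
- Egger intercept power above 50% (this design uses 100 instruments with a
  wide strength range and large samples, because intercept power is driven
  by the relative spread of instrument strengths, not the instrument count
  alone);
- Steiger retention of forward instruments ≥ 95% and removal of reverse
  instruments ≥ 90%;
- colocalization PP(H4) > 0.9 in ≥ 95% of H4 replicates and H3 top-ranked
  in ≥ 80% of H3 replicates, with posteriors summing to 1 within 10⁻¹⁰;
- exact or tolerance-bounded agreement of clumping, the weighted median,
  colocalization, and BH adjustment with independent oracle
  implementations;
- end-to-end panel recovery of at least 5 of 6 causal proteins with at
  most 2 false admissions in every replicate.

## Limitations

- The simulator's reverse-MR inputs reuse the regional disease scan as a
  proxy for a genome-wide disease GWAS; the reverse direction is therefore
  exercised structurally (thresholds, fallback, Steiger) rather than
  calibrated against a realistic disease genetic architecture.
- Steiger r² on the binary outcome is an observed-scale approximation
  without a liability-scale correction.
- Colocalization assumes at most one causal variant per trait in the
  region, as in the standard single-variant ABF framework.
- Weak-instrument bias is controlled only through the F ≥ 10 gate; no
  winner's-curse correction is applied to the exposure effects.
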