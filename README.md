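# protmr

Proteome-wide Mendelian randomization (MR) for causal plasma protein
discovery from summary statistics.

## The problem

Observational associations between circulating protein levels and disease
are confounded and subject to reverse causation: the disease process itself
changes the plasma proteome. Two-sample MR sidesteps both by using genetic
variants that regulate a protein's level (pQTLs) as instruments: genotypes
are fixed at conception, so — under the instrumental-variable assumptions —
a consistent association between protein-raising alleles and disease risk
implies a causal effect of the protein. protmr implements the full screening
workflow for a panel of proteins against a binary (case-control) disease
outcome:

- **summary statistics**: validated ingestion (`sumstats()`,
  `read_sumstats()`) and allele harmonization with strand-flip resolution
  and palindromic-variant exclusion (`harmonize()`);
- **instrument selection**: cis window, genome-wide significance, greedy LD
  clumping, F ≥ 10 strength filter (`build_instrument_set()`);
- **estimators**: Wald ratio, IVW with multiplicative random effects,
  MR-Egger (slope + pleiotropy intercept test), Bowden interpolated weighted
  median, and Hartwig weighted mode with bootstrap SEs (`run_mr()`);
- **directionality**: Steiger filtering (`steiger_filter()`) and reverse MR
  with a lenient-threshold fallback (`reverse_mr()`);
- **colocalization**: Wakefield approximate-Bayes-factor posteriors for the
  five hypotheses with a strict PP(H3)+PP(H4) > 0.5 gate (`coloc_abf()`);
- **triangulation**: candidates need nominal significance in ≥ 2 of 3
  cohort pairings with consistent direction; validation additionally needs
  colocalization in all three and clear reverse MR
  (`triangulate_proteins()`, `gate_candidates()`, `analyze_panel()`,
  `run_pipeline()`);
- **simulation**: a ground-truth generator producing realistic pQTL/GWAS
  summary statistics (copula-coupled genotypes, logistic case-control
  outcome, pleiotropy/reverse/colocalization scenarios) so the whole
  pipeline is testable offline (`simulate_pair()`, `simulate_panel()`).

## Worked example

Simulate one protein with a true causal log odds ratio of 0.3, select
instruments, and run all estimators:

```r
library(protmr)

sim <- simulate_pair(mr_scenario("causal", true_beta = 0.3, seed = 42,
                                 n_exposure = 50000, n_outcome = 50000,
                                 case_fraction = 0.1))
iset <- build_instrument_set(sim$exposure, sim$truth$region, sim$truth$ld^2)
run_mr(iset, sim$outcome, protmr_config(n_boot = 100, seed = 1,
                                        steiger = FALSE))
#>            method n_snps  beta     se     pval or_value ci_low ci_high
#> 1             ivw     30 0.305 0.0268 4.73e-30     1.36   1.29    1.43
#> 2           egger     30 0.244 0.0796 4.83e-03     1.28   1.09    1.49
#> 3 weighted_median     30 0.301 0.0310 2.56e-22     1.35   1.27    1.44
#> 4   weighted_mode     30 0.296 0.0470 3.14e-10     1.34   1.23    1.47
```

End to end on a small panel — the analysis validates exactly the protein
that was simulated as causal:

```r
panel <- simulate_panel(n_proteins = 4, n_causal = 1, n_protective = 0,
                        true_beta = 0.6, n_snps = 6, n_exposure = 6000,
                        n_outcome = 8000, case_fraction = 0.2, seed = 31)
report <- analyze_panel(panel, protmr_config(n_boot = 20, seed = 31))
report$gated[, c("protein_id", "candidate", "coloc_pass_count",
                 "reverse_mr_clear", "validated")]
#>   protein_id candidate coloc_pass_count reverse_mr_clear validated
#> 1    PROT001     FALSE                0             TRUE     FALSE
#> 2    PROT002     FALSE                0             TRUE     FALSE
#> 3    PROT003      TRUE                3             TRUE      TRUE
#> 4    PROT004     FALSE                0             TRUE     FALSE
panel$truth$protein_id[panel$truth$causal]
#> [1] "PROT003"
```

`run_pipeline()` wraps simulation + analysis and writes TSV result tables
and a JSON manifest to a report directory.

## License

MIT (see `LICENSE`).
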