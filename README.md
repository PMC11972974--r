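# oaprs — overlap-adjusted polygenic risk scores

When the target cohort used to evaluate a polygenic risk score (PRS)
contributed samples to the consortium GWAS that trained it, the score
partially memorizes those individuals and its apparent performance is
inflated. `oaprs` removes the known overlapping samples' contribution
directly from the consortium summary statistics, so the full target cohort
can be used without overfitting — no individual-level consortium data
required, only a GWAS run on the overlapping samples themselves.

## What it implements

Treat the consortium statistics for variant *j* as a fixed-effect
meta-analysis of the overlap cohort (*o*) with an unobserved remainder
(*s*), and solve for the remainder:

- **IVW inversion** — from effects and standard errors:
  σ²ₛ = 1 / (1/σ²ₐₗₗ − 1/σ²ₒ), bₛ = σ²ₛ (bₐₗₗ/σ²ₐₗₗ − bₒ/σ²ₒ).
  Variants where the overlap is at least as precise as the consortium are
  flagged unstable and dropped, with counts.
- **Z-score inversion** — from sample-size weighted Z statistics:
  zₛ = (√nₐₗₗ zₐₗₗ − √nₒ zₒ) / √nₛ with nₛ = nₐₗₗ − nₒ; effect sizes are
  rebuilt as β = z/√(2f(1−f)n) under a phenotype scaled to mean 0, SD 1.
- **De-correlation comparator** — ζₐₗₗ = (zₐₗₗ − ρ zₒ)/√(1−ρ²) with
  ρ = n_c·cor(Y₁,Y₂)/√(nₐₗₗ nₒ), for when only the overlap count is known.

Both inversions are *exact*: re-applying the forward meta-analysis to the
adjusted output reproduces the consortium input to floating-point accuracy.
Around the core sit allele harmonization for the common tab-delimited
sumstats dialects, a clumping + P-value-thresholding PRS constructor,
AUROC / OR-per-SD evaluation stratified by overlap status, a visual
diagnostic that traces AUROC while progressively excluding associated
variants (an adjusted summary decays to 0.5 on the overlap group; a
contaminated one does not), and a synthetic overlap-injection simulator
used to validate everything end to end.

## Worked example

Simulate the standard contaminated design (8,000 training + 2,000 target
samples, 2,000 variants, 50 causal, liability h² = 0.5, prevalence 0.3,
30% of the target merged into training), then adjust and evaluate:

```r
library(oaprs)

cfg <- sim_config(seed = 11)
res <- run_cell(cfg)   # simulate -> GWAS -> adjust -> PRS -> evaluate

res$evaluations$unadjusted
#>         group    n n_cases auroc or_per_sd
#> 1       total 2000     558 0.802      3.84
#> 2     overlap  600     158 0.887      7.93
#> 3 non_overlap 1400     400 0.762      3.03

res$evaluations$zscore
#>         group    n n_cases auroc or_per_sd
#> 1       total 2000     558 0.749      2.76
#> 2     overlap  600     158 0.731      2.41
#> 3 non_overlap 1400     400 0.756      2.93
```

The unadjusted score looks 0.125 AUROC better on the 600 samples the
training GWAS memorized than on the 1,400 it never saw — pure overfitting.
After the Z-score meta-inverse the two groups agree (0.731 vs 0.756,
within Monte-Carlo noise of this single realization), i.e. overlap samples
now behave like held-out samples and the whole target can be used.

The same adjustment on files:

```r
adjust_table(consortium, overlap_gwas, method = "zscore")
#> overlap adjustment (method: zscore)
#> variant status: adjusted=2000, passthrough=0, dropped_unstable=0
#> adjusted table: 2000 variants
```

or from a shell, `exec/oaprs adjust --consortium cons.tsv --overlap ov.tsv
--method zscore --out-prefix adjusted` (subcommands: `simulate`, `adjust`,
`score`, `evaluate`, `diagnose`, `experiment`).

To check an adjustment you cannot verify directly, draw the diagnostic
trajectory:

```r
ds  <- res$dataset
tgt <- partition_indices(ds, "target")
traj <- threshold_trajectory(res$summaries, ds$genotypes[tgt, ],
                             ds$phenotype[tgt], ds$partition[tgt],
                             run_gwas(ds, "target"))
plot_trajectory(traj, "diagnostic")   # writes diagnostic.png + .tsv
```

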