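---
title: "Removing sample-overlap overfitting from summary-statistic PRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing sample-overlap overfitting from summary-statistic PRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Polygenic risk scores (PRS) are built from consortium GWAS summary
statistics and evaluated on a target cohort with individual-level genotypes.
Large consortia aggregate many contributing cohorts, and the target cohort
is often one of them: some target individuals then sit on both sides of the
analysis. Their phenotypes leak into the per-variant effect estimates, and
any score built from those estimates partially memorizes them. The result is
an inflated AUROC on the overlapping samples — and on the target set as a
whole — that does not generalize. Dropping the overlapping individuals from
the target wastes power for downstream phenotype association work;
regenerating the consortium GWAS without them is usually impossible because
the consortium's individual-level data are not accessible.

`oaprs` removes the overlap contribution at the summary-statistic level.
It needs (a) the consortium summary table, and (b) a GWAS run on the
overlapping samples alone, which the analyst can compute because they hold
the target's individual-level data.

## The meta-inverse adjustments

Both adjustments treat the consortium statistics as the fixed-effect
meta-analysis of the overlap cohort with an unobserved "remainder" cohort,
and solve for the remainder.

**Inverse-variance weighting (IVW).** The forward meta-analysis of
per-variant effects $(b_o, \sigma_o)$ and $(b_s, \sigma_s)$ is

$$
b_{all} = \frac{b_o/\sigma_o^2 + b_s/\sigma_s^2}
               {1/\sigma_o^2 + 1/\sigma_s^2},
\qquad
\frac{1}{\sigma_{all}^2} = \frac{1}{\sigma_o^2} + \frac{1}{\sigma_s^2}.
$$

Solving for the remainder gives

$$
\sigma_s^2 = \frac{1}{1/\sigma_{all}^2 - 1/\sigma_o^2},
\qquad
b_s = \sigma_s^2\left(\frac{b_{all}}{\sigma_{all}^2}
                      - \frac{b_o}{\sigma_o^2}\right).
$$

When $1/\sigma_{all}^2 - 1/\sigma_o^2 \le \varepsilon$ the overlap carries
at least as much precision as the whole consortium and the inversion is
undefined; such variants are flagged `dropped_unstable` rather than floored
($\varepsilon$ defaults to `1e-12` and is configurable). This instability is
real in practice whenever the two studies have similar standard errors, and
dropping with an auditable count is the conservative remedy.

**Sample-size weighted Z scores.** With sample sizes $n_{all} = n_o + n_s$,

$$
z_{all} = \frac{\sqrt{n_o}\, z_o + \sqrt{n_s}\, z_s}{\sqrt{n_{all}}},
\qquad\Longrightarrow\qquad
z_s = \frac{\sqrt{n_{all}}\, z_{all} - \sqrt{n_o}\, z_o}{\sqrt{n_s}},
\quad n_s = n_{all} - n_o.
$$

The $\sqrt{n}$ weights are the canonical sample-size weighting; they are
also the only weighting for which composing the inverse with the forward
combination is an exact identity, which is the property the whole approach
rests on: if the consortium really were a meta-analysis that included the
overlap summaries, the adjusted table equals the meta-analysis of the
remaining cohorts, exactly. Both inversions satisfy their round trips to
floating-point accuracy, and the test suite enforces this over $10^4$ random
tuples.

After the Z inversion the full record is rebuilt assuming a phenotype
standardized to mean 0, SD 1:

$$
\sigma = \frac{1}{\sqrt{2\,f(1-f)\,n}}, \qquad \beta = z\,\sigma,
$$

with $f$ the allele frequency. The consortium frequency is the default
source; data-specific frequencies are recommended when precise effect sizes
matter, and `maf_source = "overlap"` switches the source.

**De-correlation comparator.** When only the overlap count $n_c$ and the
phenotype correlation $\mathrm{cor}(Y_1, Y_2)$ on shared samples are known,
the cross-statistic null correlation is
$\rho = \frac{n_c}{\sqrt{n_{all}\, n_o}}\,\mathrm{cor}(Y_1, Y_2)$ and the
transform

$$
\zeta_{all} = \frac{z_{all} - \rho\, z_o}{\sqrt{1 - \rho^2}}
$$

residualizes the consortium statistic against the overlap statistic. Under a
bivariate-normal null with correlation $\rho$, $\zeta_{all}$ has unit
variance and zero correlation with $z_o$. This re-weights rather than
removes the overlap contribution: it is implemented as a comparator because
the literature uses it, not as the recommended adjustment. Estimating an
unknown $\rho$ from LD-score regression is out of scope; the de-correlation
path requires user-supplied $n_c$ and $\mathrm{cor}(Y_1, Y_2)$.

## Harmonization conventions

Summary tables are joined on variant id (rsID-keyed files are the norm;
chromosome/position are carried as annotation only). When the overlap
record's alleles are swapped relative to the consortium, its effect and Z
change sign and its allele frequency is complemented; applying the flip
twice restores the record exactly. Strand-ambiguous palindromic variants
(A/T, C/G) are dropped and counted — frequency-based strand resolution is
deliberately not attempted. Consortium variants absent from the overlap
table carry no overlap signal and pass through unadjusted, with status
`passthrough`. Within a table, the Z chain is authoritative: `zscore` is
recomputed from `beta/se` and `pvalue` from `zscore` whenever they disagree
beyond $10^{-6}$ relative tolerance (with a warning), because every
adjustment above operates on that chain.

## The visual diagnostic

Adjustment cannot be verified directly — the uncontaminated consortium GWAS
is unobservable. The diagnostic instead removes association signal and
watches what is left. Stage 1 deletes every variant with $p < p_{high}$
(default $10^{-4}$) in either the consortium or the target GWAS, together
with LD neighbors ($r^2 \ge 0.1$ within a 250 kb window against the
supplied reference genotypes). Stage 2 keeps only variants with
$p \ge t$ in both tables, for a grid of thresholds $t \in \{0, 0.01, 0.05,
0.1, 0.2, 0.5\}$ ($t = 0$ means "stage 1 only", since no variant has
$p \le 0$). Weights are the surviving variants' effect sizes as-is — no
re-thresholding or re-fitting, because the diagnostic probes residual
overfitting signal and any re-selection would mask it. A summary free of
overlap contamination loses all predictive power on the overlap group as
$t$ grows (AUROC $\to 0.5$); a contaminated one keeps predicting the
samples it memorized. `plot_trajectory()` draws AUROC against $t$ per
method and group, with a rule at 0.5 and a dotted reference trajectory when
one is supplied.

## The simulator

`simulate_population()` emulates the overlap-injection design used to
quantify the bias: biallelic dosages drawn as $\mathrm{Binomial}(2, p_j)$
with $p_j \sim U(0.05, 0.5)$ (Hardy–Weinberg, linkage equilibrium by
default); a liability-threshold disease model in which `n_causal` variants
receive effects $\mathcal{N}(0, h^2/n_{causal})$, the genetic score is
standardized to variance $h^2$ and completed with independent noise of
variance $1 - h^2$, and cases are liabilities above the
$1 - \mathrm{prevalence}$ quantile; a disjoint train/target split, with a
chosen fraction of the target merged into the training GWAS as overlap
(or explicit case/control overlap counts for small-target scenarios).

Defaults are the package's standard contaminated-consortium study: 8,000
training and 2,000 target samples, 2,000 variants with 50 causal,
$h^2 = 0.5$, prevalence 0.3, overlap fraction 0.3. These sizes keep every
end-to-end check comfortably on a single CPU while leaving all group-level
AUROC estimates well separated from their Monte-Carlo noise; the classic
evaluation grid (training fractions 0.5–0.9 by ratio, overlap fractions
1%–90%) instantiates 40 configurations via `make_design_grid()`.

The GWAS engine is per-variant ordinary least squares on the standardized
binary phenotype, vectorized across variants. Linear-on-binary is a
deliberate match to the scaling assumption of the Z-score algebra above: it
makes the full-sample GWAS decompose near-exactly into the sample-size
weighted combination of its partition GWASs (correlation > 0.99 in the test
suite), which is the property the meta-inverse exploits. Monomorphic
variants in a subset are emitted with $z = 0$ and a missing standard error,
and counted.

An optional block-LD mode draws latent block-equicorrelated Gaussians and
thresholds them through the binomial quantile (a Gaussian copula). The
genotype-scale correlation is attenuated relative to the latent correlation
— latent 0.95 typically yields genotype $r^2$ between roughly 0.2 and 0.7
depending on the frequency mismatch — which is sufficient for exercising
clumping and the diagnostic's neighbor removal, but it is not a model of
real LD structure. What the simulator does not emulate: reference-panel LD,
imputation error, relatedness, population structure, covariates. Passing
tests demonstrate the adjustment algebra and the overfitting phenomenology,
not robustness to those features of real data.

## PRS construction and evaluation

The self-contained constructor is clumping + thresholding: greedy selection
by ascending P value (ties broken by variant id), accepting a variant when
its squared correlation with every accepted variant inside the window is
below `r2_threshold` (default 0.1, window 250 kb), followed by a P-value
cut. `build_prs_ct()` scans the grid
$\{5\cdot10^{-8}, 10^{-5}, 10^{-3}, 0.01, 0.05, 0.1, 0.5, 1\}$ and keeps
the threshold with the best total-target AUROC.

The experiment pipeline (`run_cell()`, `run_experiment()`) deliberately
does **not** use that selection by default. With a modest number of
well-powered causal variants, best-threshold selection picks a sparse score
containing only true signals — and a sparse score barely touches the null
variants through which overlap overfitting expresses itself, so the very
bias the package exists to remove becomes invisible. Genome-wide dense
constructors, which dominate applied practice, include those variants.
`run_cell()` therefore scores all clumped variants (`selection = "dense"`),
and `selection = "best"` restores the PRSice-style scan. The inflation this
choice exposes is substantial: at the default design the unadjusted
overlap-group AUROC exceeds the non-overlap group's by well over 0.05,
while after either meta-inverse adjustment the two groups agree to within
Monte-Carlo noise and match a PRS built from a GWAS computed directly on
the non-overlap training samples.

AUROC is the exact Mann–Whitney statistic from midranks (no ROC binning);
the odds ratio per SD is the exponentiated coefficient of the standardized
score in a logistic fit, with separation and non-convergence flagged rather
than raised. Evaluation is stratified into total, overlap and non-overlap
target groups; groups missing a case or control are reported not-evaluable.

One subtlety worth stating: overlap overfitting is signal-independent. Even
at $h^2 = 0$ a dense unadjusted PRS predicts the overlap group above
chance, because the weights contain those individuals' phenotype noise.
Null-calibration checks therefore assert chance-level AUROC for the
adjusted summaries and for groups that never touched the training GWAS, but
not for the unadjusted score on its own training members. Relatedly, when
inflation is traced across overlap fractions the monotone quantity is the
AUROC on the whole target set (the share of memorized samples grows); the
per-individual inflation within the overlap group itself actually shrinks
slightly as the injected overlap enlarges the training set. The
zero-overlap point of such a trace uses the total-target AUROC as its
uninflated baseline, since an overlap group does not exist there.

## Numerical and design choices

- IVW stability floor $\varepsilon = 10^{-12}$ on the remainder precision;
  unstable variants are excluded from the adjusted table, never floored.
- `n_s = n_{all} - n_o` per variant when per-variant sample sizes are
  present; no case/control effective-sample-size conversion is applied.
- Flipped overlap records store the complemented allele frequency; any
  frequency above 0.5 is folded back before entering
  $2f(1-f)$ (which is symmetric in $f \leftrightarrow 1-f$).
- Exclusion-threshold grids treat $t = 0$ as "strong-signal removal only".
- Clumping ties are broken by (P value, then variant id) so runs are
  deterministic; reference-missing variants pass through unclumped and are
  counted.
- Per-cell seeds in `make_design_grid()` are derived deterministically from
  the base seed and the cell coordinates, so grids are reproducible and
  embarrassingly parallel.
- P values are never trusted from input files when they disagree with the
  Z chain; they are recomputed with a warning.

## Limitations

- The meta-inverse is exact only insofar as the consortium truly is a
  fixed-effect combination that included the overlap summaries. Consortia
  built with other weighting schemes, genomic control, or sample overlap
  across contributing cohorts will be adjusted only approximately; the
  visual diagnostic exists precisely to check the result.
- A GWAS computed jointly on train-plus-overlap individuals is not exactly
  a fixed-effect meta of its partitions, so simulation-based recovery is
  near-exact (correlation > 0.999) rather than exact.
- The Z-score path needs per-variant `n` and allele frequencies; its
  effect-size scale inherits whatever error is in the supplied frequencies.
- Binary traits are handled through the standardized-phenotype linear
  approximation throughout; no liability-scale or logistic effect-size
  conversion is provided.
- The de-correlation comparator assumes bivariate normality under the null
  and a known, constant $\rho$ across variants.

## A compact example

```{r example}
library(oaprs)

cfg <- sim_config(seed = 11)           # the standard contaminated design
res <- run_cell(cfg)                   # simulate, adjust, score, evaluate
res$evaluations$unadjusted             # inflated on the overlap group
res$evaluations$zscore                 # inflation removed

ds <- res$dataset
tgt <- partition_indices(ds, "target")
traj <- threshold_trajectory(
  res$summaries,
  ds$genotypes[tgt, ], ds$phenotype[tgt], ds$partition[tgt],
  run_gwas(ds, "target"))
plot_trajectory(traj, "diagnostic")
```
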