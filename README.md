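# rhythmboot

Bootstrap-robust rhythmicity detection for long-series time-course
expression data.

## The problem

In oscillatory systems (circadian clock, cell cycle, metabolic cycles),
whether a gene is declared *rhythmic* from probe-level expression data can
depend heavily on the normalization method used during pre-processing: the
same gene may look clearly periodic after quantile normalization and flat
after constant scaling. For genome-wide screens — where rhythmic gene
lists feed pharmacological and toxicological follow-up — that makes part
of the result an artifact of pre-processing. rhythmboot is for analysts of
such long-series designs (dozens of equally spaced arrays spanning two or
more cycles) who want rhythmicity calls that survive the choice of
normalization.

## The method

Per gene, log2 probe intensities are decomposed by two-way median polish,

    log2 X[p, t] = overall + alpha_p + beta_t + eps[p, t],

into probe effects, array (time) effects and residuals, with residual
variance `sigma2` = MSE of the fit. Given a normalization `n` and detector
`a` with Benjamini–Hochberg adjusted p-values, the standard measure is

    M^g(n, a) = 1 − adjusted p-value^g(n, a),

and a gene is called rhythmic when `M ≥ 0.99`. A parametric bootstrap
regenerates `B` probe-level datasets from the fitted signal,

    log2 X*b[p, t] = overall + alpha_p + beta_t + N(0, sigma2),

pushes each replicate through the *identical*
normalization → summarization → detection pipeline, and combines the
replicate measures `theta*b` with the original measure `theta` into

    M_Robust = E_hat − RMSE_hat,
    E_hat    = mean_b(theta*b),
    RMSE_hat = sqrt( Σ_b (theta*b − theta)² / (B − 1) ).

`RMSE_hat` penalizes genes whose apparent rhythmicity is unstable under
resampling — exactly the genes normalization methods disagree about — so
`M_Robust` correlates far better across normalization methods than `M`.
It can legitimately be negative (variability exceeding the measure) and
is not clipped.

The package provides: dense probe-level data structures with TSV I/O;
median-polish fitting and RMA-style summarization (Rcpp core); the
bootstrap engine with reproducible per-(replicate, gene) substreams;
quantile, constant, cyclic-loess and rank-invariant-set normalization
behind a pluggable registry; cosinor-F and rank-template reference
detectors plus external p-value plug-ins; cross-normalization
correlation/concordance reporting; and a synthetic-data generator with
known ground truth and injectable array-level technical bias. Variance
stabilizing transforms (`2*sqrt(x)` Poisson, `asinh(sqrt(x/dispersion))`
negative binomial) provide an entry point for count data.

## Worked example

Simulate the default study design (300 genes × 8 probes × 48 hourly
arrays spanning two 24 h periods, 30% rhythmic) with smooth nonlinear
array drift — the technical artifact that makes normalization methods
disagree — then score it under quantile and constant normalization with
the cosinor detector and B = 50 bootstrap replicates:

```r
library(rhythmboot)

cfg <- synthetic_config(bias_model = "nonlinear", bias_magnitude = 0.3,
                        seed = 1L)
ds   <- generate_dataset(cfg)$dataset
meth <- detector_method("cosinor_f", 24)
bc   <- bootstrap_config(B = 50L, seed = 1L)

rq <- score_pipeline(ds, "quantile", meth, bc)
rc <- score_pipeline(ds, "constant", meth, bc, fits = rq$fits)

robustness_report(
  list(quantile = rq$standard$M, constant = rc$standard$M),
  list(quantile = rq$robust$M_robust, constant = rc$robust$M_robust)
)
```

```
               pair      metric standard_value robust_value   delta
1 quantile:constant    spearman         0.8995        0.975  0.0756
2 quantile:constant     pearson         0.0493        0.938  0.8890
3 quantile:constant concordance        88.9908      100.000 11.0092
```

On the 109 (of 300) union-rhythmic genes (`M ≥ 0.99` under at least one
method), the Spearman correlation between the two normalizations rises
from 0.90 to 0.98, Pearson from 0.05 to 0.94, and call concordance from
89% to 100% after bootstrapping. A typical discordant gene shows why: in
this run `gene_0063` is truly flat, yet

```
gene_0063: M(quantile) = 0.992   M(constant) = 0.268     # rhythmic under one method only
           M_Robust(quantile) = 0.399  M_Robust(constant) = 0.154
```

the standard measure calls it rhythmic under quantile normalization alone
(an artifact of the injected drift), while the robust measure keeps it
below threshold under both.

A command-line front end wraps the same pipeline
(`inst/scripts/rhythmboot.R` with subcommands `simulate`, `score`,
`evaluate`); every run writes a manifest with the config and seed so
outputs are reproducible bit for bit.

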