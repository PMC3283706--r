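# serocluster

Analysis toolkit for quantitative autoantibody serology panels in systemic
lupus erythematosus (SLE). The package works on patient-by-antigen titer
tables in light units (LU), the readout of luciferase immunoprecipitation
(LIPS) assays, and implements the full path from raw titers to clinically
interpretable patient clusters:

1. **Cutoff calibration** — for each antigen, the seropositivity cutoff is
   the healthy-control mean plus three sample standard deviations;
   ROC-optimal cutoffs (maximum Youden *J* = sensitivity + specificity − 100)
   are computed as a second, separately reported policy.
2. **Z-scores** — each titer is expressed as
   *Z* = (titer − cutoff) / SD<sub>control</sub>, so a titer at the cutoff
   scores 0 and the control mean scores −3; the Z matrix drives the
   black-to-green heatmap.
3. **Relative-ratio clustering** — each SLE patient with at least one
   seropositive call among the six core antigens is assigned by
   RR = (Sm-D3 + RNP-A + RNP-70k) / (Ro52 + Ro60 + La): RR ≥ 1 gives the
   Sm/RNP cluster, RR < 1 the Ro/La cluster; patients with no positive call
   form a seronegative remainder.
4. **Association testing** — two-sided Fisher's exact tests of clinical
   manifestations and antibody frequencies between clusters (with
   Benjamini–Hochberg adjustment as labeled supplementary output),
   Mann–Whitney *U* (exact under ties for small samples), Spearman rank
   correlation (exact permutation for n ≤ 10), and pooled *t*-tests on
   log10 titers with geometric mean titers. A reconstruction helper inverts
   printed percentages back to integer contingency tables, with a rounding
   consistency check.
5. **Mixture assay** — a model of the single-well six-antigen mixture test
   as the sum of individual titers under multiplicative lognormal noise,
   compared to the sum by Spearman correlation and its own ROC cutoff.

A synthetic-cohort generator with latent Sm/RNP / Ro/La / seronegative
classes, calibrated control titer distributions and cluster-dependent
clinical-manifestation rates makes every stage testable without patient
data; the latent truth is kept in a separate table so it can never leak
into the pipeline under test.

Intended users: groups analyzing multiplexed serology panels who need a
reproducible, scriptable version of this cutoff/Z-score/ratio-clustering
workflow, and methodologists who want to stress-test it on simulated
cohorts.

## Worked example

```r
library(serocluster)

sim <- simulate_cohort(default_sim_config(seed = 42))
fit <- lips_profile(sim$cohort)
fit
#> Autoantibody serology profile
#>   129 SLE patients, 15 controls, 6 antigens
#>   core-panel union: sensitivity 98%, specificity 100%
#> Cluster prevalence (n = 129)
#>   Sm/RNP:        67 (52%), pure 33
#>   Ro/La:         60 (47%), pure 3
#>   Seronegative:   2 (2%)
```

98% of simulated SLE patients are seropositive for at least one of the six
core antigens at the calibrated cutoffs, and the ratio rule splits the
cohort into a Sm/RNP and a Ro/La cluster with a small seronegative
remainder — close to the generator's 47% / 51% / 2% latent mix. Because the
cohort is simulated, the assignment can be scored against the latent truth:

```r
recover_latent_labels(fit$assignments, sim$truth)$confusion
#>               latent
#> assigned       SM_RNP RO_LA SERONEGATIVE
#>   SM_RNP           67     0            0
#>   RO_LA             5    55            0
#>   SERONEGATIVE      0     0            2
```

96% of patients recover their generating class; the misassignments are
mixed-reactivity patients whose cross-trio titers tip the ratio. Association
tests run directly on reconstructed count tables; for example, serositis
prevalence by cluster (0% of 66 Ro/La vs 13% of 61 Sm/RNP patients):

```r
fisher_from_percents(0, 66, 13, 61)
#> FISHER test: statistic = 0, two-sided p = 0.002197
#>   effect: pct_row1 = 0, pct_row2 = 13.11
#>   n: 66, 61
```

`plot(fit)` draws the cluster-ordered Z-score heatmap;
`render_heatmap()` writes it to PNG/SVG with a row-order manifest, and
`summary_tables()` emits the per-antigen performance, prevalence and
association tables as CSV and Markdown. A thin command-line front end over
the same functions lives in `inst/scripts/serocluster-cli.R`
(`simulate`, `cutoffs`, `cluster`, `associate`, `mixture`, `heatmap`).

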