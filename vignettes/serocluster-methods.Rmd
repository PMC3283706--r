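---
title: "Methods: serology calibration, ratio clustering and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serology calibration, ratio clustering and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serocluster)
```

# The analysis model

The package operates on patient-by-antigen titer tables in light units
(LU), the luminometer readout of solution-phase luciferase
immunoprecipitation (LIPS) assays. LU titers are strictly positive, span
several orders of magnitude, and in SLE are commonly 10–200-fold higher
than in healthy controls for the core nuclear antigens. Three quantities
are derived from a cohort:

**Cutoffs.** For each antigen the seropositivity cutoff is the healthy
control mean plus three sample standard deviations (denominator $n-1$;
control groups in this setting are small, typically 15–18 sera, so the
sample SD is the appropriate estimator). Seropositive means *strictly*
above the cutoff; a titer exactly at the cutoff is negative. A second,
independent cutoff policy — the ROC-optimal threshold maximizing Youden's
$J = \mathrm{sens} + \mathrm{spec} - 100$ — is computed for diagnostic
tables. The two policies are deliberately never merged: the mean + 3 SD
cutoff is the calibration behind Z-scores and cluster assignment, while the
ROC cutoff characterizes each antigen as a classifier, and nothing
guarantees they coincide.

**Z-scores.** $Z = (\mathrm{titer} - \mathrm{cutoff})/\mathrm{SD}_{HC}$,
so a titer at the cutoff maps to 0 and the control mean maps to exactly
$-3$. Z values are stored unclipped; the heatmap clips negative Z to 0 for
display only, because sub-cutoff magnitudes carry no display meaning on a
scale that encodes "standard deviations above the cutoff".

**Cluster assignment.** Patients seronegative for all six core antigens
(Sm-D3, RNP-A, RNP-70k, Ro52, Ro60, La) are set aside first — they are
reported as a separate remainder and never ratio-assigned. Every other SLE
patient receives the relative ratio
$RR = (\mathrm{SmD3}+\mathrm{RNPA}+\mathrm{RNP70k}) /
(\mathrm{Ro52}+\mathrm{Ro60}+\mathrm{La})$
on **raw titer sums** (not Z-scores: the ratio is defined on summed titers,
and Z-scores exist only for visualization). $RR \ge 1$ assigns the Sm/RNP
cluster, $RR < 1$ the Ro/La cluster; the boundary belongs to Sm/RNP. A
patient is flagged *pure* when every seropositive call falls inside a
single trio. A zero Ro/La denominator — impossible for physical light
units but reachable with hand-built synthetic input — is treated as
$RR = +\infty$, hence Sm/RNP, consistent with the $RR \ge 1$ rule.

# Statistical tests

* **Fisher's exact test** (two-sided) uses the minimum-likelihood rule: the
  sum of hypergeometric point probabilities, over all tables with the
  observed margins, that do not exceed the observed table's probability
  (relative tie tolerance $10^{-7}$). The reported statistic is the plain
  sample odds ratio $ad/bc$, with the usual $\infty/0$ conventions for zero
  cells. A table with an empty margin carries no information; its p-value
  is defined as 1 with a warning rather than an error, so screens over many
  features degrade gracefully.
* **Mann–Whitney U** uses midranks. For combined samples of at most 20 the
  two-sided p is exact by enumeration of all group assignments of the
  pooled values, which remains valid under ties; beyond that, the normal
  approximation with tie correction and a 0.5 continuity correction is
  used. The exact/approximate crossover at 20 keeps the enumeration
  ($\binom{20}{10} \approx 1.8\times10^5$ assignments) inexpensive.
* **Spearman correlation** uses midranks; p is an exact full-permutation
  value for $n \le 10$ (enumeration is chunked over the first index to
  bound memory) and the $t$-approximation with $n-2$ degrees of freedom
  otherwise.
* **Log-titer t-test** is the pooled-variance two-sample test on
  $\log_{10}$ titers — the natural scale for lognormal-like LU data — and
  reports each group's geometric mean titer $10^{\overline{\log_{10} x}}$.
* **Percent reconstruction.** Published tables often print only per-group
  percentages. `counts_from_percent()` inverts the display rounding
  (half away from zero) and then *verifies* that the reconstructed count
  re-rounds to the printed percent. Rows for which no integer count
  re-rounds correctly are refused with the candidate list rather than
  silently guessed; such rows do occur in real tables (e.g. 7% of 66 has
  no consistent preimage) and typically indicate a slightly different
  denominator behind the printed percent.
* **Multiplicity.** Headline output is raw p-values, matching standard
  practice for this analysis; Benjamini–Hochberg adjusted values are
  emitted as a clearly labeled supplementary column, never substituted.

All display percentages round half away from zero to integers; unrounded
values are retained in every returned object.

# The synthetic cohort generator

The generator exists so that every pipeline stage is testable without
patient sera. Its default configuration (`default_sim_config()`) encodes
the study conditions of a validation-scale cohort: 129 SLE patients, 15
healthy controls, latent class mix 47% Sm/RNP, 51% Ro/La, 2% seronegative.

* **Titer model.** Control titers for antigen $j$ are
  $10^{\mu_j + \sigma_j Z}$, $Z\sim N(0,1)$. The lognormal family is a
  modeling choice, not an observed fact: it is motivated by the strictly
  positive support, the 10–200-fold SLE/control separation, and the fact
  that printed normal-theory CIs of titer means sometimes have negative
  lower bounds, which rules out a symmetric model on the natural scale.
  $(\mu_j,\sigma_j)$ are set so the *arithmetic* mean matches published
  healthy-control means (Sm-D3 4,800 LU; RNP-A 12,600; RNP-70k 28,800;
  Ro52 10,000; Ro60 5,000; La 4,700), with the natural-scale SD
  back-computed from the 95% CI half-width as
  $\mathrm{SD} = h\sqrt{n}/1.96$, $n = 15$ — the printed interval is
  assumed to be a normal-theory CI of the mean.
* **Seropositivity.** Each SLE patient draws a latent class; for each
  antigen, the patient is seropositive with a class-specific probability.
  Own-trio probabilities are fixed at 1 (cluster members always react
  against their own trio); cross-trio probabilities are solved so the
  marginal per-antigen seropositive fraction reproduces published
  single-antigen sensitivities (e.g. RNP-70k 85%, Sm 65%, La 71%).
  Seropositive titers shift the location by `pos_log_shift` decades,
  deconvolved from the cohort-level SLE mean via
  $m_{+} \approx (m_{SLE} - (1-p)\,m_{HC})/p$ and floored at one decade so
  that "seropositive" remains a meaningful titer elevation for
  low-prevalence antigens whose printed cohort means barely differ from
  controls (GAD65, TH, IFN-omega hit the floor).
* **Seronegative class.** Patients of the SERONEGATIVE class draw their
  six core titers from the control distribution *truncated at the analytic
  generating cutoff* (closed-form lognormal mean + 3 SD). Plain control
  draws would occasionally exceed the cutoff and violate the class's
  defining property; truncation enforces it by construction. The analysis
  pipeline never sees this generating cutoff — it must re-estimate cutoffs
  from the 15 sampled controls, and a simulated seronegative patient can
  still (rarely) be called positive under the *estimated* cutoff.
* **Clinical flags** are conditionally independent Bernoulli draws given
  the latent class, with per-cluster rates taken from published
  cluster-by-manifestation percentages (serositis 13% in Sm/RNP, 0% in
  Ro/La; the seronegative class, for which no rates are published, uses
  the mean of the two). Only marginal per-cluster rates are emulated; any
  within-patient correlation between manifestations is not.
* **Demographics** use a 13:1 female:male ratio and an age mix consistent
  with onset at 31 ± 12 years (18% under 20, 59% 20–40, 23% over 40);
  ethnicity defaults to 60% Caucasian, 35% African-American, 5% Asian —
  plausible for the cohorts this emulates, since exact group sizes are not
  published. Anti-dsDNA positivity is 58% regardless of class.
* **Determinism.** All randomness is consumed on a fixed schedule (every
  random block is drawn with a fixed shape regardless of branch outcomes),
  so one seed yields a byte-identical cohort; the latent truth is written
  to a separate table so it cannot leak into the analysis input.
* **Mixture assay.** The single-well six-antigen test is modeled as the
  sum of the six core titers times unbiased multiplicative lognormal noise
  with coefficient of variation `mixture_noise_cv` (default 0.2, a
  moderate inter-assay noise level). Additivity is the simplest model
  consistent with the near-unity rank correlation observed between mixture
  readouts and titer sums; antigen competition and luciferase quenching
  are deliberately not modeled.

**What passing tests do and do not show.** The generator reproduces
marginal control distributions, marginal seropositivity rates, latent
cluster structure and cluster-dependent manifestation rates. It does not
reproduce plate effects, inter-assay drift, serum-dilution kinetics,
within-patient correlation of manifestations, or the true joint
distribution of cross-reactivity — so simulation-based results (e.g. the
~96–98% latent-label recovery of the ratio rule, or the mixture
correlation of ~0.97) characterize the algorithms under the stated model,
not the assays on real sera. Quantities published from real cohorts that
depend on undeposited raw titers are correspondingly *not* reproduction
targets; they are replaced by oracle-checked properties (exact tests vs
enumeration, ROC vs brute force, Z-score identities, partition and
recovery guarantees).

# Numerical choices and degenerate inputs

* ROC candidate thresholds are the midpoints between adjacent sorted
  distinct titers plus $\pm\infty$; every achievable classification is
  represented. Ties on $J$ break toward higher specificity, then the
  higher cutoff — the diagnostic emphasis of a screening panel favors
  specificity.
* Fewer than two controls, or zero control variance, abort calibration
  with explicit errors (a continuous assay cannot be thresholded from a
  degenerate control sample).
* All-identical titers abort the ROC scan ("no separation").
* Exact-test tie comparisons use absolute slack $10^{-9}$ on enumerated
  statistics.
* Titer tables tolerate zeros (to keep the $RR=+\infty$ edge reachable in
  synthetic input) but reject negatives and missing cells.
* Summary tables print arithmetic means with normal-theory 95% CIs, which
  can produce negative lower bounds on skewed titer data — this matches
  the convention of the tables this layout follows; geometric means are
  used for testing, not for these columns.

# Problem sizes in the test suite

The suite checks distributional properties at sizes chosen to keep
Monte-Carlo error well below the asserted tolerances while remaining
quick: closed-form marginal checks at $n = 10{,}000$, latent recovery at
$n = 1{,}000$ (point accuracy ≈ 0.977, asserted ≥ 0.95), screen power
over 300 cohorts of $n = 127$ (measured detection rate 0.82 for a 13% vs
0% serositis contrast, asserted ≥ 0.75 — three Monte-Carlo SDs below the
measurement; the contrast sits near the Fisher significance boundary, so
substantially higher power is not attainable at this sample size), and
exact-test oracle sweeps of 200 random instances each.

# Known limitations

* The lognormal titer family and the additive mixture model are
  assumptions; real LIPS data may have heavier tails or saturation.
* Cross-trio seropositivity probabilities are solved from marginal
  sensitivities under own-trio certainty; the real joint reactivity
  pattern is unidentifiable from published marginals.
* The ratio rule's recovery accuracy is reported under the generator's
  separation; cohorts with weaker titer contrasts will recover less.
* Percent-reconstructed contingency tables inherit the printed rounding;
  rows failing the re-rounding consistency check are refused, not
  imputed.
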