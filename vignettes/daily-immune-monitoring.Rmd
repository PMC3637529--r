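---
title: "Daily immune monitoring: simulation model and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daily immune monitoring: simulation model and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dailycyto)
```

# The problem

Cross-sectional cytokine comparisons between chronic fatigue syndrome (CFS)
patients and controls are notoriously inconsistent, partly because fatigue
severity in CFS fluctuates strongly from day to day. A daily immune-monitoring
design instead follows a small cohort over many consecutive days — here, 10
patients and 10 BMI-matched controls over 25 days, with a 51-plex serum
cytokine panel and twice-daily 0–100 visual-analogue (VAS) fatigue reports —
and asks which analytes *track* within-person fluctuation in fatigue. The
canonical finding in this design is that serum leptin, an adipokine with
inflammatory activity, tracks fatigue in a subset of patients but not in
controls.

No raw data from such studies are publicly deposited, so `dailycyto` pairs the
full analysis pipeline with a synthetic cohort generator whose statistical
structure matches what the analysis assumes. Everything downstream — tracking
correlations, the FDR-thresholded correlation network, the extreme-day
classification experiment — runs identically on simulated or real long-format
cohorts.

# The generative model

For subject $i$ on day $t$:

* **Latent fatigue** $f_i(t)$ is a stationary lag-1 autoregression around the
  group baseline $\mu_g$:
  $f_i(t) = \mu_g + \phi\,(f_i(t-1) - \mu_g) + \varepsilon_t$, with stationary
  standard deviation $\sigma_f$. Defaults: $\mu_g = 55$ (patients) / $10$
  (controls) VAS units, $\sigma_f = 15$, $\phi = 0.6$. The AR coefficient
  encodes "abrupt shifts over a couple of days": high enough that adjacent
  days resemble each other, low enough that the series decorrelates within a
  week.
* **VAS reports**: AM and PM fatigue are $f_i(t) \mp \delta/2$ plus
  independent report noise (sd 5), clipped to $[0, 100]$ and rounded to the
  integer resolution of a VAS slider ($\delta = 6$: evenings slightly worse).
  A configurable number of controls (default 2) report exactly 0 on every
  day, exercising the degenerate-series and exclusion paths downstream.
* **Leptin** is log-normal:
  $\log \mathrm{lep}_i(t) = a_i + b_i\, z_i(t) + \epsilon_t$, where $z_i(t)$
  is standardized latent fatigue, $a_i$ depends linearly on BMI
  (slope 0.08 per BMI unit on the log scale, reproducing the strong positive
  BMI–leptin correlation in both groups), and
  $\epsilon_t \sim N(0, \sigma_\epsilon^2)$ pools daily biological noise with
  a diurnal-window term for imperfect scheduling of the blood draw. The
  coupling is solved in closed form so the model-implied correlation of
  log-leptin with latent fatigue equals the subject's target `planted_r`:
  $b = r\,\sigma_\epsilon / \sqrt{1 - r^2}$. Six of the ten patients
  ("responders") draw `planted_r` uniformly from $[0.40, 0.75]$; everyone
  else has $b = 0$. A target in $(0,1)$ is rejected when
  $\sigma_\epsilon = 0$, where only $r = \pm 1$ is attainable.
* **The cytokine nest**: 29 cytokines load on the standardized leptin latent
  signal with per-analyte weights $w_j$, plus log-scale noise
  ($\sigma = 0.5$); the remaining cytokines are independent log-normals. All
  analytes are exponentiated to a positive, right-skewed
  median-fluorescence-like (MFI) scale; couplings act on the log scale, where
  effect sizes are interpretable, while the analysis — like the original —
  standardizes the raw MFI values.

**Why `nest_weight_range = [0.16, 0.33]`.** The leptin–member correlation is
$r_j = w_j / \sqrt{w_j^2 + \sigma^2}$ and the member–member correlation is the
product $r_j r_k$. At the design's pooled $n = 250$ and a 0.01 FDR, the
realized significance threshold sits near $|r| \approx 0.2$. The default
weights put every $r_j$ in $[0.3, 0.55]$ — comfortably above threshold — while
the products straddle it, so each nest member connects to only part of the
nest and leptin is the network's maximum-degree analyte. Heavier weights make
every member pair significant and the hub structure collapses into a clique.

The subject-level draws (demographics, responder assignment, baselines, nest
weights) and the day-level noise use separate seeds derived from the single
configuration seed by a stable string hash (`derive_seed()`), so
`planted_truth()` reproduces the ground truth without simulating trajectories
and every pipeline stage can be re-run in isolation, bit-for-bit.

# Preprocessing

The pipeline order is fixed: **standardize, then smooth.**

1. `subject_center_zscore()` centers each subject's series to mean 0 / sample
   sd 1 (the $n-1$ denominator; correlations are scale-invariant so the
   choice is cosmetic). Zero-variance series are flagged degenerate and
   propagate as `NA` — constant-fatigue subjects appear as `NA` rows in the
   tracking table rather than raising errors.
2. `moving_average()` applies a centered 3-day window that shrinks at the
   boundaries (the first and last day average two values), preserving all 25
   days and hence the pooled $n = 250$. Smoothed series are deliberately not
   re-standardized; on white noise the smoothed variance falls to roughly
   $1/3$ plus boundary terms, and the suite checks this.
3. `aggregate_fatigue()` builds AM, PM and mean daily fatigue from the raw
   reports before standardization; if exactly one report exists on a day the
   mean is that report. The mean variant is smoothed after aggregation —
   whether the original analysis aggregated before or after smoothing is not
   documented, and this choice is recorded here as an assumption rather than
   a fact.

`build_analysis_views()` materializes both views and tags them; network
mapping refuses the smoothed view (`pairwise_matrix()` errors), because
smoothing is exempted there by design, while tracking and classification
consume the smoothed view.

# Correlation tracking and its honesty flag

`per_subject_tracking()` and `pooled_group_correlation()` report Pearson $r$
with two-sided p-values from the t-distribution on $n - 2$ df — the
conventional test, applied to smoothed data exactly as the original analysis
applied it. That test ignores autocorrelation and is therefore
anti-conservative on smoothed series: in null calibrations the per-subject
rejection rate at $\alpha = 0.05$ is near 5% on unsmoothed z-scores but
inflates severalfold after smoothing (a few healthy-control rows earn stars,
which matches the published tracking table's own scattered control stars).
`permutation = TRUE` substitutes an exact circular-shift permutation p-value
(all $n - 1$ rotations), which preserves autocorrelation under the null;
fidelity is the default, rigor is a flag.

The pooled correlation concatenates subject-centered series, so it measures
within-person covariation untouched by between-subject baseline differences;
the default fatigue variant is the daily mean (the variant displayed in the
original tracking figures), recorded as an assumption in the run manifest.

# The FDR network

`pairwise_matrix()` computes all $52 \times 52$ correlations (fatigue plus 51
analytes) on pooled unsmoothed z-scores with pairwise-complete observations.
`bh_threshold()` applies Benjamini–Hochberg over the family of all
$52 \cdot 51 / 2 = 1326$ unique pairs at $q = 0.01$; the procedure is chosen
because the published "corrected $p < 0.0012$ at a 0.01 false-discovery rate"
is exactly a data-adaptive BH threshold. The realized threshold is always
computed from the data, never hard-coded; on default synthetic cohorts it
lands in the same $10^{-3}$ decade. `build_network()` keeps the rejected pairs
as edges and reports leptin's degree and whether fatigue–leptin is an edge;
`fr_layout()` provides the classic Fruchterman–Reingold embedding
(repulsion $k^2/d$, attraction $d^2/k$, linear cooling, seeded and
deterministic) for visualization only — topology, not coordinates, is the
analysis surface.

One deliberate divergence from the published picture: because nest cytokines
inherit part of leptin's fatigue coupling (correlation $r_j \times$
`planted_r`), synthetic patient networks usually show a handful of direct
cytokine–fatigue edges besides leptin's, where the original study found only
leptin. Matching that detail would require tuning the nest against the
fatigue signal, which the generator does not do.

# The extreme-day classification experiment

Per patient, the 9 most and 9 least severe fatigue days (by the smoothed mean
daily score; stable ties broken by day index) become `high`/`low` cases —
$10 \times 18 = 180$ before exclusion — each carrying its 51 smoothed z
analyte values. Score values present in both of a subject's sets are excluded
from both, and constant-fatigue subjects drop out entirely (the all-zero
controls), every removal logged. The classifier is a linear soft-margin SVM at
$C = 1$ (hinge loss, L2 penalty, unpenalized bias — the LibLINEAR-style
model), evaluated by stratified 10-fold cross-validation and by transferring
the frozen patient model to the control cases.

**The leakage finding.** Day-level fold assignment — the original design —
is measurably optimistic: on *fully null* cohorts (no planted coupling
anywhere) it still averages roughly 69% accuracy. Adjacent smoothed days
share two-thirds of their moving-average window, and extreme-day labels
cluster in time because fatigue is autocorrelated, so a test day's temporal
neighbors sit in the training folds with the same label. Subject-grouped
cross-validation (`grouped = TRUE`), which assigns whole subjects to folds,
sits at chance (~49%) under the same null, as does the cross-cohort transfer
(~51%). The package therefore reports both CV modes side by side: the
day-level figure for comparability with the original 78.3%-style headline,
the grouped figure as the honest generalization estimate — and the null
calibration in the test suite asserts chance-level behavior for the
leakage-free instruments while asserting (and thereby documenting) the
day-level inflation. This is the package's most practically important
caveat for interpreting published accuracies from this design.

# What the simulation does and does not emulate

Emulated: between-subject baselines in positive skewed MFI-like analytes,
autocorrelated fatigue with twice-daily noisy reports, BMI-coupled leptin
baselines, a tunable leptin–fatigue coupling confined to a responder subset,
a leptin-correlated cytokine block, and constant-zero reporters that exercise
every degenerate path. Not emulated: assay plate and batch effects, bead-count
QC and detection limits, missed-visit makeup draws (available only as an
off-by-default day-permutation option), medication and comorbidity structure,
and any causal or lagged leptin–fatigue dynamics. Passing tests therefore
show that the pipeline recovers the planted statistical structure — not that
real serum data satisfy these assumptions.

Known quantitative consequences of the model choices: correlating raw
(exponentiated) rather than log analytes attenuates $|r|$ by roughly 10% at
these noise levels, and smoothing inflates it back by a similar amount, so
observed smoothed tracking correlations land close to the planted
(pre-smoothing, latent-scale) values on average — the recovery suite measures
a mean signed error of a few hundredths, with sampling spread of about
$\pm 0.2$ at $n = 25$ days. Detection power for the weakest default couplings
(planted $r \approx 0.4$) is accordingly modest at 25 days; cohorts flag at
least five of the six responders in roughly three-quarters of runs, a
design-level power limit of the 25-day protocol rather than a pipeline
defect.

# Numerical and testing choices

* Degenerate inputs yield `NA` results, never exceptions, end to end.
* All randomness flows from one integer seed; per-stage seeds are derived by
  hashing stage names, and two runs of any stage are byte-identical.
* The SVM uses the libsvm linear C-classification solver (deterministic for
  fixed data) with features consumed as-is; no probability calibration, no
  feature selection.
* The test suite exercises full-depth designs (20 subjects × 25 days) with a
  12-analyte panel for unit tests, reserving the 51-analyte default for the
  end-to-end suites; Monte-Carlo suites use 200 cohorts for recovery, 40 for
  null calibration of the network FDR, and 15 seeds per coupling level for
  the accuracy-monotonicity check.
* Statistical test bands in the suite are fixed in advance from binomial or
  t-based error at the stated Monte-Carlo sizes; thresholds are never
  adjusted to observed outcomes.

# Limitations

The generator's effect sizes are stylized: real cytokine panels are heavier
tailed, cross-correlated beyond a single leptin-driven block, and subject to
detection floors. The t-based inference replicates, by design, an
anti-conservative convention; use the permutation flag when the question is
inferential rather than replicative. And the 25-day, 10-patient design is
simply underpowered for per-subject couplings below $r \approx 0.5$ — a
conclusion the simulation makes quantitative.
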