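---
title: "Methods: from raw serum intensities to metabolome-wide associations in SVD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw serum intensities to metabolome-wide associations in SVD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

metabosvd implements a complete metabolome-wide association workflow for
studies of cerebral small vessel disease (SVD): serum metabolite intensities
measured on LC-MS and NMR platforms are drift-corrected against pooled QC
samples, quality-filtered, variance-stabilized and standardized, and then
associated — per 1-SD of each metabolite — with MRI markers of SVD,
cognition, their annualized changes, and incident dementia. This vignette
documents the statistical model, the tunable parameters, the design
decisions taken where the methodology is genuinely open, and what the
synthetic-data module does and does not emulate.

## The analytical-run model

An analytical run consists of study samples in randomized order, split into
batches, with three kinds of injections:

* **study** samples, one serum sample per subject;
* **pooled QC** samples — a mixture of equal parts of every study sample —
  injected at each batch boundary and after every `qc_interval` study
  samples (default 10, a typical injection scheme; the spacing is
  configurable because acquisition protocols differ);
* a **dilution series** of the pooled QC (10 x 100%, 5 x 80%, 3 x 60%,
  3 x 40%, 5 x 20%, 10 x 1%; 36 injections per block), injected as a full
  block at the start and end of each batch.

The generative model for a raw intensity of feature $f$ in sample $s$ is
multiplicative:

$$ x_{fs} = c_{fs} \cdot d_{b(s)}(t_s) \cdot o_{f,b(s)} \cdot
\varepsilon_{fs}, $$

where $c_{fs}$ is the drift-free ("clean") intensity, $d_b(t)$ a smooth
within-batch drift curve (a quadratic in scaled run position, anchored at 1
at the batch start, with maximum relative excursion `drift_amplitude`),
$o_{f,b}$ a per-(feature, batch) lognormal offset with log-scale SD
`batch_offset_sd`, and $\varepsilon_{fs}$ mean-one lognormal technical
noise whose coefficient of variation is `tech_cv` (so the expected pooled-QC
RSD of a drift-free feature is exactly $100 \times$ `tech_cv`). Clean study
intensities are lognormal around a feature base level with biological CV
`bio_cv`; pooled-QC clean values are the feature-wise mean of the study
samples, and dilution-QC clean values scale proportionally with the
dilution fraction. Batch offsets apply to every injection in a batch — QC
samples included — which is what makes them correctable from the QC series.

Defaults `tech_cv = 0.05` and `bio_cv = 0.50` reflect typical serum
lipidomics precision: pooled-QC RSDs of a few percent against biological
RSDs of tens of percent. The ratio matters: the fidelity of the corrected
data to the clean signal (per-feature Pearson $r \approx
\sqrt{(e^{\sigma_b^2}-1)/(e^{\sigma_b^2+\sigma_t^2}-1)}$) only approaches 1
when biological variance dominates technical variance.

## Drift correction

Per feature and per batch, a locally linear LOESS curve is fitted to
pooled-QC intensity versus run order; every sample is divided by the curve
value at its run order and rescaled to the feature's median pooled-QC
intensity across the whole run. Because the reference is global while the
curves are per batch, within-batch drift and between-batch offsets are
removed in one step, and the median pooled-QC intensity of every feature is
preserved exactly (the rescaling constant is chosen so the median corrected
QC ratio is 1).

Numerical choices:

* **Span.** Default 0.5, locally linear. In batches with few QC injections
  the span is widened so that each local fit sees at least
  `loess_min_window` (default 6) QC points; without this floor the curve
  interpolates through the QC points, absorbs the technical noise, and
  collapses the QC RSD to zero — silently defeating the RSD criterion.
* **Edges.** Beyond the first/last QC injection of a batch the fitted value
  is held constant at the nearest QC position rather than extrapolated;
  local-linear extrapolation at run edges is unstable.
* **Degenerate fits.** Features whose fitted curve is non-positive or whose
  LOESS fit fails are returned uncorrected and flagged in the diagnostics
  rather than corrupted.
* **Platforms.** Correction applies to reverse-phase LC-MS lipid platforms;
  HILIC and NMR labels default to pass-through (`loess_enabled` overrides
  either way). A pass-through still advances the matrix state so the
  pipeline contract is uniform.

## Feature selection

Three criteria, all strict inequalities (ties fail), evaluated on the
corrected matrix:

1. pooled-QC RSD $< 30\%$ (precision),
2. dilution-series Pearson correlation with the dilution fraction $> 0.7$
   (linearity of response; skipped as vacuously true for runs without a
   dilution series, e.g. NMR),
3. study-sample RSD $> 1.1 \times$ pooled-QC RSD (a feature whose
   variation is mostly technical carries no biological signal).

RSD uses the sample (n-1) standard deviation. Undefined metrics (fewer
than two values, non-positive mean, zero variance) fail their criterion
with the reason recorded. Metrics ignore missing values pairwise; features
with more than 50% missing study values fail (configurable via
`max_missing_study`) — intensity matrices at this stage of a real study are
nearly complete, so the default missingness rate in the simulator is 0.
Every decision is reproducible from the stored per-feature metrics and the
thresholds, which is what the oracle-equivalence tests assert.

## Transformation and scaling

The generalized log $\mathrm{glog}(x) = \ln\!\big((x + \sqrt{x^2 +
\lambda})/2\big)$ is applied to the retained features. At $\lambda = 0$ it
is the natural log; for large $x$ it approaches $\ln x$ regardless of
$\lambda$. The default $\lambda$ = `"auto"` estimates the additive noise
floor as the squared median pooled-QC standard deviation of low-intensity
features (those below the median feature mean); a fixed $\lambda \ge 0$ can
be supplied. Features are then autoscaled — centred and divided by the
sample SD computed **over study samples only** (QC columns are excluded
from the statistics but transformed with them), so a unit of every
metabolite is one SD across participants. Zero-variance features are
dropped with a recorded reason rather than emitted as NaN columns.

## Outcome panel

End points are oriented so that higher always means more severe disease:
WMH volume is analysed as $\log$ of its percentage of brain volume; brain
atrophy as the sign-flip of the z-scored total brain volume (an
orientation, not a reciprocal transformation — the choice is recorded in
the scaling table and switchable); MDNPH, the three cognition scores and
the Barthel index are sign-flipped. Each continuous end point is z-scored
so effect sizes are comparable across outcomes. Microbleed and lacune
counts are analysed both as continuous (z-scored counts fitted by ordinary
linear regression; a count model is a documented alternative we did not
adopt) and as presence/absence via logistic models. The simple SVD score
awards one point each for microbleed presence, lacune count $\ge 1$ and
Fazekas grade $\ge 2$; the exact point system of published severity scores
varies, so the cut-offs are arguments.

Annualized change is (latest non-missing value - baseline) / elapsed
years, ignoring intermediate visits; subjects with only a baseline are
excluded. Changes are oriented and z-scored like the baseline end points.
Change models do not adjust for the baseline outcome value by default
(matching the covariate set of the cross-sectional models); adjusting for
baseline is a caller-side covariate choice.

## Association models and multiplicity

For every metabolite x outcome pair: linear regression (continuous),
logistic regression (binary), or Cox proportional hazards with Efron ties
(dementia), under two adjustment sets — demographic (cohort, baseline age,
sex) and extended (plus diabetes, hypertension, hypercholesterolaemia).
Effects are per 1-SD of the metabolite; two-sided Wald p-values and 95% CIs
(effect $\pm 1.96\,$SE) are reported. Complete-case analysis per model,
with `n_used` recorded. Non-estimable fits (collinear designs, perfect
separation, monotone Cox likelihood, fewer than `min_events` = 10 dementia
events) are flagged and excluded from their FDR family.

Benjamini-Hochberg q-values are computed within each (analysis, outcome,
adjustment, stratum) family across metabolites — our reading of FDR control
"per outcome measure" — and `q < 0.05` declares a discovery. Sensitivity
strata: per cohort, age $< 65$ / $\ge 65$ (65 to the older stratum), and
Fazekas $\ge 2$; strata below 25 subjects are skipped with a logged reason
rather than fitted underpowered.

For the linear family with complete data the suite uses a
residualization (Frisch-Waugh-Lovell) fast path that is algebraically
identical to the per-metabolite `lm()` coefficient — the test suite asserts
equality to 1e-10 — and falls back to `lm()` whenever missing values make
the shortcut invalid.

## What the simulator does and does not emulate

The synthetic module reproduces the *structure* the analysis assumes:
run randomization, QC interleaving, the dilution design, multiplicative
drift and batch offsets, lognormal technical/biological variation,
two cohorts with distinct ages, visit schedules (years 0-3 versus 0, 5, 9,
14) and censoring horizons (5 versus 14 years), planted per-1-SD effects
with unit-variance oriented outcomes, logistic presence outcomes, and
exponential dementia times with an age-dependent hazard. Visit schedules,
prevalences, and covariate effect sizes were fixed once at values typical
for symptomatic SVD cohorts.

It does **not** emulate: correlated metabolite panels (features are
independent, so FDR behaviour under strong dependence is untested),
non-proportional hazards, informative censoring or dropout, retention-time
or m/z structure, missing-not-at-random intensities, or cohort-specific
assay differences. Passing tests therefore demonstrate correctness of the
pipeline's computations under the stated model, not robustness to every
pathology of real acquisitions.

## Problem sizes and reproducibility

The test suite and the acceptance script run simulation studies sized to
keep full verification fast while leaving Monte-Carlo error well inside
the asserted bands: QC-oracle equivalence on 500 features with the full
two-cohort run; drift recovery on 250 features; FDR calibration on
200-500 global-null replicates of 369 features x 600 subjects; parameter
recovery on 100-200 replicates at n = 2000 (linear/logistic) and n = 1500
with ~30% events (Cox). Every random draw derives from a single integer
seed; identical config + seed reproduces every matrix, manifest, table and
output file byte for byte.

## Known limitations

* The dilution-series criterion needs at least three distinct fractions
  with data; runs with a degenerate design silently fall back to the
  vacuous-pass rule intended for NMR.
* The variance-ratio criterion sits near ratio 1 for features with almost
  no biological variance, so its decisions are sampling-noisy close to the
  1.1 boundary (the oracle and the pipeline always agree; which side of
  the boundary a borderline feature falls on varies by run).
* Count end points are fitted by ordinary least squares on z-scored
  counts; for heavily zero-inflated counts a dedicated count model would
  be preferable.
* The LOESS correction assumes the pooled QC tracks the same drift as the
  study samples; matrix-effect differences between QC and study material
  are not modelled.
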