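---
title: "Methods: breath-hold and resting-state CVR mapping and their concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath-hold and resting-state CVR mapping and their concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrconcord)
```

## The two CVR metrics

Cerebrovascular reactivity (CVR) is mapped here in two ways, both from BOLD
fMRI at TR = 2 s.

**Breath-hold beta.** The breath-hold paradigm is four 60 s epochs of 40 s
normal breathing, 4 s inhalation and 16 s breath-hold, preceded by a 4 s
equilibration period and followed by 20 s of rest — 264 s, 132 volumes
(`build_breathhold_timing()`). Holding the breath raises blood CO₂, dilates
cerebral vessels, and produces a slow global BOLD response. A voxel's CVR
metric is obtained in two stages:

1. *Personal waveform.* The hold-phase indicator convolved with the canonical
   respiratory response function
   $\mathrm{RRF}(t) = 0.6\,t^{2.1}e^{-t/1.5} - 0.0023\,t^{3.54}e^{-t/4.25}$
   (sampled at the TR over a 60 s support, covering the early positive lobe
   near 3 s and the slow negative lobe) gives an initial regressor. Because
   respiratory latency and shape vary across individuals, the subject's own
   waveform is estimated empirically: the top 1% of gray+white-matter voxels
   with the highest Pearson correlation against the regressor over integer
   delays of 0–4 TR are averaged and smoothed with a three-point
   order-statistic filter.
2. *Lagged regression.* Each voxel's series is regressed (intercept + slope)
   on the personal waveform delayed by 0–4 TR; the delay with the highest
   coefficient of determination wins and its slope (beta) is the voxel's
   breath-hold CVR metric.

**Resting-state CVRe (ALFF).** From a 302-volume resting run, the amplitude
of low-frequency fluctuations: the sum of the single-sided amplitude spectrum
$2|X_k|/N$ over Fourier bins with $0.01 \le f_k \le 0.08$ Hz (band edges
inclusive). Spontaneous CO₂ fluctuations during free breathing make this band
a passive proxy for vascular reactivity.

**Preprocessing contracts.** Breath-hold runs drop the 2 equilibration
volumes plus the next 10, and the final 20 volumes (the last response is not
fully captured): 132 → 100 volumes. Resting runs drop the 2 equilibration
volumes and keep the first 210, roughly matching the analysis window lengths.
Every voxel is then scaled to $100\,x/\bar{x}$ and clipped to $[0, 200]$;
voxels with non-positive means cannot be scaled and are flagged out of the
VOIs.

## Overlap analysis

At a threshold $\theta$ a voxel is *responsive* iff metric $\ge \theta$ (the
boundary counts as responsive; a fixed rule is needed for exact count tests).
Classification against a reference gives TP/TN/FP/FN,
$\mathrm{Acc} = (TP+TN)/(TP+TN+FP+FN)$ and
$\mathrm{Dice} = 2TP/(2TP+FP+FN)$. Three comparisons are built on this:

- `sweep_vs_gray()`: 1D sweep of each map against gray matter within the
  gray+white VOI; the accuracy-maximizing threshold is reported (ties go to
  the smallest, most inclusive threshold — deterministic and
  sensitivity-favoring).
- `cross_metric_surface()`: 2D sweep with the resting map as predictor of the
  breath-hold map within gray matter. Extreme thresholds force all voxels
  into one cell; the corner summaries A1–A4 (all-TN, all-FP, all-FN, all-TP)
  are therefore computed at $\pm\infty$ thresholds where accuracy is exactly
  1, 0, 0, 1 — percentile grids cannot reach the all-negative corner because
  a threshold equal to the maximum still labels the maximal voxel responsive.
  The surface value at the pair of independently 1D-optimized thresholds is
  reported as the saddle point.
- `self_concordance()`: each run's map thresholded at its own 1D optimum,
  cross-classified run against run — an upper bound on attainable
  cross-metric agreement given the metric's run-to-run noise.
- `unthresholded_compare()`: each map robustly normalized (1st–99th
  percentile to $[0,1]$, clipped), Pearson correlation across voxels, a
  difference map, and scatter data clipped to each metric's central 95%.

Threshold grids default to 101 percentiles (0th–100th) of the metric within
the analysis VOI: raw metric units depend on scaling and subject, so
percentile grids adapt per subject; raw-unit grids remain available via
`threshold_grid(type = "raw")`.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `pct_top` | 0.01 | fraction | top 1% most task-correlated voxels feed the waveform |
| `max_lag_tr` | 4 | TR (2 s) | delays of 0–4 TR; no sub-TR interpolation |
| smoother weights | (0.70, 0.15, 0.15) | — | unit sum preserves signal scale (below) |
| ALFF band | 0.01–0.08 | Hz | canonical low-frequency fluctuation band |
| `detrend` | `TRUE` | — | linear drift otherwise leaks into the 0.01 Hz bin |
| `n_grid` | 101 | thresholds | percentile grid over the VOI |
| `bh_average` | `"maps"` | — | fit each run, average the beta maps (below) |
| `rs_runs` | `"both"` | — | mean of the two per-run ALFF maps |

**The smoother weight anomaly.** The three-point order-statistic filter is
sometimes printed with weights (0.7, 1.15, 0.15), which sum to 2 and double a
constant signal. The default here is the unit-sum set (0.70, 0.15, 0.15),
matching the usual convention for such filters and making the smoother
scale-equivariant; the printed variant is available via
`osfilt_weights(printed = TRUE)`.

**Waveform alignment and anchoring.** Averaging top-correlated voxels whose
responses lag each other by 0–4 TR would smear the waveform, so each selected
series is first re-aligned by its own best delay. Those delays are measured
against the *generic* regressor and carry a common offset whenever the
subject's true response latency differs from the generic one; since the
selection scan is one-sided (0–4 TR), the offset cannot be read off the
selected voxels alone. The estimate is therefore re-anchored against the
whole VOI: the waveform is shifted so that the earliest delay class supported
by a non-trivial share (0.5%, at least 3) of well-correlated voxels
(r ≥ 0.4) sits at delay 0. This makes the absolute 0–4 TR lag map
identifiable under the phantom's convention that the earliest true lag is 0.
Without an external timing reference this anchor is a convention, not an
estimate: a subject whose entire brain responds 1 TR late is indistinguishable
from one whose waveform is 1 TR slower.

**Averaging the two breath-hold runs.** "Average of the two runs" is
ambiguous between averaging time series and averaging beta maps; the default
fits each run with its own waveform and averages the maps, which preserves
each run's per-voxel lag freedom (`bh_average = "timeseries"` is the
alternative). When the two runs disagree on a voxel's best lag, the smaller
lag is kept, consistent with the smallest-lag tie rule.

**ALFF estimator.** Rectangular-window DFT amplitude sum — the classic ALFF
definition — rather than a squared-amplitude (power) sum; no taper. The
analytic identity "in-band sinusoid of amplitude A on a Fourier bin returns
A" holds for the plain estimator; the optional linear detrend perturbs a
finite sinusoid slightly through spectral leakage, which is why the analytic
tests disable it.

## The phantom generator

`simulate_subject()` draws, from one integer seed: a concentric ellipsoidal
geometry (gray shell around a white core, ~55% gray by default) — anatomy is
irrelevant to the analysis, only labeled compartments with the stated
contrast matter; per-voxel true CVR amplitudes (gray mean 2.0 on a baseline
of 100, i.e. a realistic ~2% breath-hold BOLD response; gray:white contrast
2.5; ±20% per-voxel jitter); integer response lags uniform on 0–4 TR;
per-subject RRF constants jittered ±20% (emulating individual latency/shape
differences); resting fluctuation amplitudes (gray mean 1.5 SD units, same
contrast); and white Gaussian noise (SD 0.4 = 20% of the gray response
amplitude — the regime in which lag recovery is expected to succeed). The
baseline of 100 means generated data are already in mean-100 scaled units.
An optional spherical zero-CVR lesion emulates a focal neurovascular
uncoupling region.

What the phantom deliberately does *not* emulate: head motion and its
correction, spatial autocorrelation of noise, cardiac/respiratory
physiological noise, EPI distortion, anatomy. The gray:white amplitude ratio
is a free parameter, not an estimate of any real cohort. The two metrics'
amplitude jitters are drawn independently, so the phantom's unthresholded
cross-metric correlation within gray matter is near zero — unlike real data,
where shared vascular structure couples the metrics. Consequently, passing
tests demonstrate the correctness of the estimators and of the
threshold-optimization machinery against known ground truth, not that real
breath-hold and resting maps agree at any particular level; the phantom's
compartments are far more separable than real tissue, so its optimized
accuracies sit near 1.0 where real data plateau around 0.6–0.8.

## Numerical choices and degenerate inputs

- Regression delays shift the waveform later in time; the overhang is
  dropped and the fit uses the overlapping samples only (no fabricated
  pre-task signal). Equal coefficients of determination break toward the
  smaller delay.
- Voxels with zero temporal variance are ineligible for selection and get
  beta 0 / lag 0 in the map (their R² is defined as 0 for every delay).
- A constant waveform, an empty VOI, an empty gray or white compartment, a
  threshold grid with fewer than 2 points, Dice with no positive voxels in
  either labeling, and correlation of a constant map are all rejected with
  explicit errors rather than silently propagating NaN.
- Percentile grids are deduplicated, so the grid is strictly increasing even
  when the metric has ties.
- Reports print percentages at table precision (integers for TP/TN/FP/FN and
  accuracy, one decimal for Dice); full-precision values go to the JSON
  summaries. The configuration hash (MD5 of the canonical JSON encoding) is
  recorded in every bundle.

## Problem sizes

The test suite and the acceptance script run phantoms on 16×16×12 grids
(~1,200 gray+white voxels) with full-length runs (132 and 302 volumes), a
size chosen because every statistic of interest (lag recovery, threshold
recovery, corner forcing, concordance ordering) is already stable there; a
full subject analyzes in about a second. Larger grids change nothing but
runtime: the default `phantom_spec()` grid is 24×24×16 (~3,500 VOI voxels).

## Known limitations

- Lags are integer TR; no sub-TR interpolation, matching the 0–4 TR design.
- The absolute lag anchor is a convention (see above); betas are expressed
  relative to the personal waveform's amplitude, so they are comparable
  within a subject but not in physical units across subjects.
- End-tidal CO₂ regressors, fALFF/mALFF variants, nuisance regression of
  tissue-based signals, and statistical (z-score) thresholding are out of
  scope.
- The worked-example reference table ships printed, rounded percentages; the
  accuracy column reproduces exactly, while Dice recomputed from rounded
  integers can differ from the printed value by up to one printing unit
  (0.1).
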