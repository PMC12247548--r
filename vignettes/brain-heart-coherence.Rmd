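---
title: "Measuring brain-heart coherence in naturalistic fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring brain-heart coherence in naturalistic fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiocohere)
```

## The model

`cardiocohere` quantifies the moment-to-moment association ("coherence")
between heart rate and brain activity during naturalistic fMRI. The
package is deliberately agnostic about direction: every measure is
correlational, and we make no claim about whether the brain drives the
heart or the reverse. The pipeline has five stages — cardiac
preprocessing, neural preprocessing, dynamic connectivity, coherence
estimation, and group inference — plus a synthetic-data generator that
provides ground truth for all of them.

### Cardiac preprocessing

The input is a beats-per-minute series at ~1 Hz (heartbeat detection from
the raw oximeter waveform happens upstream and is out of scope). The chain
is fixed in this order:

1. **Gap interpolation.** Interior missing samples are filled with a cubic
   spline through the valid samples; leading/trailing gaps are
   back-/forward-filled with the first/last valid value. With fewer than 4
   valid points a cubic spline is underdetermined, so the fill falls back
   to linear interpolation and the fallback is recorded in provenance. We
   use Forsythe–Malcolm–Moler end conditions, which reproduce a single
   cubic polynomial exactly.
2. **Savitzky–Golay smoothing.** The smoothing scale is a free parameter
   of the method; we default to a 15-sample window (15 s at 1 Hz) with a
   cubic local polynomial, a typical scale for heart-rate series that
   suppresses beat-detection jitter while preserving multi-second
   dynamics. Both parameters are configurable.
3. **Resampling to the TR grid with a hemodynamic lag.** The continuous
   (linear) interpolant is evaluated at `t_k = k·TR − lag`, with
   `lag = 6 s` by default — the canonical delay between neural events and
   the peak BOLD response, applied to the heart-rate series so that the
   bivariate measure compares BOLD against the heart rate that preceded it
   by one hemodynamic delay. The lag is realized in continuous time
   (exactly 6 s), not rounded to a whole number of TRs; at TR = 0.7 s the
   nominal shift is 8.57 TRs, and rounding would silently change the lag
   by up to 0.35 s. Head samples before the first observation take the
   first value.
4. **Detrending.** Low-frequency drift is removed by projecting onto
   Legendre polynomials on time mapped to [−1, 1], with automatic order
   `1 + floor(duration / 150 s)` — one order per 150 s of data, the
   standard automatic rule for fMRI drift removal — so an 8-minute run
   gets order 4 and a 5.5-minute run order 3. The same order is applied to
   the heart rate as to the paired fMRI run, so both sides of every
   correlation live in the same frequency band.
5. **Z-normalization** with the n−1 denominator. Coherence correlations
   are scale-invariant, so the denominator convention only affects
   reported traces, never statistics.

Whether the shift should precede or follow detrending is ambiguous in
principle; a 6 s shift changes the polynomial projection negligibly for
runs of several minutes, and we fix the order shift-then-detrend.

### Neural preprocessing

ROI series (mean over mask voxels) and voxel series are residualized
against a joint design: Legendre drift columns, CSF and WM mean signals,
and the 24-parameter motion set (6 realignment parameters, their first
temporal differences with a leading zero, and the squares of all 12).
Because the projection is joint, the result is invariant to whether tissue
signals were extracted before or after detrending. Residualization is a
single least-squares projection, hence idempotent, and it commutes with
ROI averaging when the design is shared — both properties are tested.

For voxel-wise analyses only, volumes are smoothed with a separable 3D
Gaussian at 6 mm FWHM (σ = FWHM/√(8 ln 2) converted to voxels per axis,
reflecting boundary, mass-conserving). This is plain smoothing *to* the
target width, a documented simplification of iterative smooth-to-FWHM
schemes; on unsmoothed synthetic data the two coincide in effect.

### Dynamic connectivity

For each ROI pair, a per-timepoint weighted Pearson correlation is
computed under a Gaussian kernel centered at that timepoint, truncated to
±14 TRs (window width 29 TRs = 20.3 s at TR 0.7 s) and renormalized. The
window width follows the study design this package implements; the kernel
sd within the window is not pinned by that design and defaults to
`window/3` (≈9.7 TRs), which keeps over 99% of the untruncated Gaussian
mass inside the stated width. It is the chief free parameter for
sensitivity analyses. Output is full length — edge windows are truncated
rather than dropped — so connectivity series stay sample-aligned with the
heart-rate trace. Correlations are Fisher-transformed with |r| clipped at
1 − 1e−7 to keep z finite (a perfectly correlated pair yields the finite
ceiling atanh(1 − 1e−7) ≈ 8.41), then z-normalized; a constant z series
(e.g. a self-pair) cannot be z-normalized and is flagged instead.

### Coherence estimators

- **Bivariate coherence**: atanh of the Pearson correlation between the
  lagged, z-scored heart-rate trace and the z-scored neural series.
- **Dynamic time warping**: squared-difference local cost, symmetric
  steps (diagonal/left/up), endpoints anchored, Sakoe–Chiba band of
  ±14 TRs (~10 s). The band focuses the alignment on fast co-fluctuations
  rather than slow processes (digestion, circadian drift). The distance is
  the square root of the accumulated cost with *no* path-length
  normalization; because DTW distance grows with series length, conditions
  of unequal duration are first matched by dropping the *head* of the
  longer condition (the opening section, which is also the least
  condition-specific part of a suspense manipulation). Distances are only
  ever compared within equal-length conditions.
- **Cross-correlation maximum**: the largest *positive* correlation over
  a whole-TR delay grid, with the achieving delay. The grid only scans
  delays of the neural series behind the heart-rate trace, so to cover
  BOLD *preceding* the hemodynamically lagged heart rate the trace is
  advanced (shifted earlier, tail-padded) by an extra 10 s offset before
  the search; a grid delay d then corresponds to a lag of d·TR − 10 s
  relative to the 6 s-lagged heart rate, covering −10 s (BOLD precedes) to
  +16 s (heart rate precedes). The offset is realized as the nearest whole
  number of TRs (14 TRs = 9.8 s at TR 0.7 s) so that the plain bivariate
  alignment lies exactly on the grid. Sub-TR delay estimation is not
  attempted. A minimum overlap of 30 samples guards against spurious
  maxima at extreme delays, and "no positive peak" is recorded as 0 with a
  flag rather than as a negative maximum, since the estimator is defined
  as a positive-correlation maximum. Note the maximum over a grid is
  positively biased under the null — voxel-wise maps are therefore only
  interpreted through the paired contrast, where the bias cancels.

### Group inference

Per target × measure, subjects' condition differences go into a paired
t-test (t = mean/ (sd/√n), df = n − 1, two-tailed p) with paired Cohen's
d = mean/sd. Two Bonferroni families mirror the preregistration structure
of the design: the 5 hypothesis activation ROIs (bilateral amygdala,
bilateral anterior insula, dmPFC) at α/5 = .01, and the exploratory family
of all 10 activation ROIs plus 45 connectivity edges at α/55 ≈ .0009. A
target belongs to one family label, but the exploratory divisor is always
the full 55-test family.

Voxel-wise difference maps are corrected by sign-flip permutation: the
observed paired-t map is thresholded two-tailed at the cluster-forming
voxel p (.001 by default), clusters are formed by face connectivity
(NN1; NN2/NN3 available — the choice is configurable because no single
convention is universal), and the null distribution of the maximum cluster
extent over random per-subject sign flips (exhaustive when 2^n fits within
the permutation budget, Monte-Carlo otherwise) sets the extent threshold
at the ceiling of its 1 − α quantile. The threshold is always recomputed
from the data's own null rather than taken from any published value, since
cluster-extent thresholds are dataset-specific. Cluster-forming is
two-tailed to match the two-tailed group tests. Negating all difference
maps negates the t map and leaves extents unchanged — a tested symmetry.

## What the synthetic generator emulates

`sim_config()` defines a two-movie-plus-rest study of 29 subjects
(suspense 480 s, control 330 s, rest 420 s; TR 0.7 s) — the retained
sample and condition durations of the design this package implements.
Heart rate is a subject baseline (population 66 ± 9 bpm) plus a
condition offset (suspense +1.4, control −1.4, rest +0.5 bpm, giving
population means of about 67.4 / 64.6 / 66.5), a slow sinusoidal drift
(amplitude 2 bpm, period 60–180 s) and an AR(1) fluctuation (coefficient
0.9, innovation sd 0.5 bpm at 1 Hz); a 5% fraction of samples is masked
missing completely at random. BOLD activity is
`β·zHR(t − 6 s) + drift + noise` in standardized units, so the population
correlation with the lagged z-scored heart rate is the closed form
β/√(β² + σ²) — an analytic handle the tests verify by Monte-Carlo.
Connectivity coupling uses the simplest mechanism that produces
heart-rate-tracked dynamic correlation: a shared standard-normal latent
entering both ROIs with gain `clip(a + b·zHR(t − lag), 0, g_max)`
(a = 0.6, g_max = 2), with slope b = +0.4 in control and −0.4 in suspense
on the amygdala_R–dmPFC pair by default — encoding a positive coherence
under control that reverses under suspense.

The generator does **not** emulate pulse waveforms, respiratory or
vascular noise, oximeter artifact structure (missingness is MCAR), spatial
autocorrelation of BOLD noise, or between-subject variation in coupling
strength or hemodynamic delay. Passing tests therefore demonstrate that
the estimators recover the coupling structure they assume, at realistic
noise levels — not that real data satisfy those assumptions. The default
condition offsets reproduce the qualitative heart-rate separation of the
target design, not any exact effect size, and the paired t on the coupled
edge is far larger than values typical of real data because between-
subject coupling heterogeneity is absent by construction.

## Numerical choices

- Fisher transform clip at |r| = 1 − 1e−7 (finite z ≈ 8.41).
- Collinearity in nuisance designs is rejected at a scaled condition
  number of 1e10, naming the offending columns.
- Weighted correlations clamp to [−1, 1]; zero weighted variance is an
  error, not NaN.
- DTW on equal-length series is always feasible for any band ≥ 0; the
  kernel asserts reachability rather than silently returning infinity.
- The banded DTW recursion is compiled (Rcpp); an independent memoized
  recursive implementation in the test suite serves as its oracle,
  exhaustively on all ternary series pairs up to length 4 and on a seeded
  sample of lengths 5–8.
- Degenerate inputs error by name: constant series in `zscore`,
  zero-variance differences in `paired_t`, empty masks, non-monotone or
  non-uniform BPM time grids.

## Problem sizes used by the test suite

Statistical validation runs at sizes chosen to make the Monte-Carlo
evidence sharp while keeping the suite fast: type-I calibration of the ROI
contrast uses 1000 replicates of 29 subjects with 120 s conditions (the
rejection rate is duration-invariant under the null); the sign-flip
cluster correction is calibrated on 200 meta-replicates of 12 smoothed
8×8×8 null maps at a 0.01 cluster-forming p, where the null extent
distribution is rich enough for the family-wise error to sit near α
rather than below it (at 0.001 on small grids the discreteness of extents
makes the procedure strictly conservative); lag recovery uses 50
replicates of 240 s single-blob volumes; and the directional coupling
reversal uses 100 replicates of the full per-subject chain on the coupled
edge at the design's native durations.

## Known limitations

- Smoothing-to-FWHM is approximated by a fixed-width Gaussian; boundary
  handling is reflecting, which will differ at brain edges from tools
  using other conventions.
- The DTW distance is unnormalized by design; comparing distances across
  different lengths requires external normalization.
- The cross-correlation delay grid is whole-TR; reported lags inherit
  that quantization (±0.35 s at TR 0.7 s).
- `run_pipeline` ingests BPM + ROI-table datasets; volume-based inputs go
  through the same exported functions (`read_volume`, `gaussian_smooth`,
  `residualize`, `lag_map`, `cluster_correct`) but are composed by the
  user.
- Group inference is a paired contrast only: no covariates, no
  mixed-effects models, no unequal-variance corrections.
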