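---
title: "Methods: dual-modality connectivity pipelines and their simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality connectivity pipelines and their simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(connmri)
```

`connmri` re-implements, as tested reusable code, the analysis chain of a
longitudinal small-animal MRI study design: several treatment groups scanned
at two time points, with resting-state BOLD feeding a functional-connectivity
arm and single-shell diffusion MRI feeding a tractography arm. This vignette
is the package's account of the underlying methods: the models, the
parameters and their defaults, what the simulation module does and does not
emulate, and the numerical and design choices that were genuinely open.

## The functional model

Resting-state functional connectivity treats the slow (0.01–0.08 Hz)
spontaneous BOLD fluctuations of two regions as samples from a stationary
bivariate process and summarizes their coupling by the Pearson correlation
`r` of the ROI-average time series, variance-stabilized through the Fisher
transformation `z = atanh(r)`. The z scale is what everything downstream
operates on: per-subject matrices are averaged *after* the transform
(averaging correlations first and transforming afterwards is biased toward
zero and is deliberately not offered), group contrasts are rank tests on
edge-wise z samples, and longitudinal change is a regression on edge
scatters of z values.

Before correlation, each dataset passes a four-step chain, in this order:

1. **Nuisance regression.** One OLS fit per voxel against an intercept,
   polynomial drifts up to order 2, the recorded respiratory trace, and six
   motion-parameter series. Linear detrending is subsumed: with the drift
   columns present, detrend-then-regress and one joint regression give
   identical residuals, and the joint form is easier to verify (residuals
   are orthogonal to the design to machine precision).
2. **In-plane smoothing**, Gaussian, FWHM 0.3 mm by default, strictly 2D
   (nothing crosses slices or frames). With ~0.18 mm in-plane voxels this
   FWHM is under two pixels, so a plain Gaussian is used; the edge-preserving
   smoothers some toolchains apply differ negligibly at this kernel size.
   Edges are handled by kernel renormalization (divide by the smoothed
   all-ones image), which preserves constants exactly and interior mass to
   better than 1e-6.
3. **Band-pass, 0.01–0.08 Hz.** The filter is a zero-phase forward–backward
   Butterworth of order 4 — a standard resting-state choice; zero phase
   matters because phase shifts would distort correlations. No specific
   filter family is dictated by the problem, so the choice is recorded here.
   Implementation detail: the line through the series endpoints is removed
   before filtering (DC and linear trend are out-of-band anyway), which
   zeroes both endpoints and keeps the warm-up transients that any zero-phase
   IIR filter produces confined and small. The stated attenuation figures
   (≥ 20 dB in the stop band, ≥ 90% amplitude retention in-band) are
   steady-state properties, measured away from the series ends; this matches
   how reference implementations behave, whose own edge excursions are
   larger than ours on the same signals.
4. **Normalization**, interpreted as per-voxel temporal z-scoring. "The data
   were normalized" admits several readings (grand-mean scaling, per-volume
   scaling); per-voxel z-scoring was chosen because Pearson correlations are
   invariant under any per-voxel affine map, so the reading cannot change
   any connectivity result — it only standardizes the numeric range.
   Zero-variance voxels are set to zero and flagged rather than producing
   NaNs.

Whether smoothing preceded or followed nuisance regression in the original
toolchains is usually underdetermined; the listed order (regression first)
is fixed here and asserted in tests. The chain's normalization step is
idempotent, so re-running it is harmless.

**Intra-node strength** is the mean over all unordered voxel pairs within
one ROI of the Fisher-z voxel correlation — transform first, then average,
mirroring the inter-node convention. Degenerate (constant) voxels are
excluded and counted.

**Clipping.** `|r|` is clipped at `1 - 1e-7` before `atanh`, keeping z finite
on degenerate synthetic inputs while perturbing realistic correlations by
less than 1e-7. Clip counts are carried on the objects.

## Group statistics

The edge-wise track is nonparametric throughout, justified by a
Shapiro–Wilk screen offered at report level (it does not gate individual
edges). Within each group, the two paired time points are compared by a
Friedman test with subjects as blocks; with k = 2 conditions and ties
handled by the standard correction the statistic reduces to `d²/m` where
`d` is the count of increases minus decreases and `m` the number of untied
subjects. The default p-value uses the χ²(1) reference; an exact
sign-permutation option (closed-form binomial tail, verified against full
2^n enumeration to 1e-9) is recommended — and used by the pipeline — at the
study's group sizes (n ≤ 8), where the χ² approximation is coarse.

Between groups, each edge gets a tie-corrected Kruskal–Wallis H with
χ²(g−1) p-value, followed by Dunn's pairwise rank comparisons
`z = (R̄_i − R̄_j) / sqrt(σ² (1/n_i + 1/n_j))` with the tie-corrected
variance. Pairwise p-values are two-sided normal tails multiplied by the
number of pairwise comparisons (capped at 1) — the Bonferroni-family
adjustment that mainstream graphing/statistics packages apply under the
label "Dunn's post hoc correction"; unadjusted values are retained
alongside. No correction is applied *across* edges, matching the per-edge
reporting convention of the study design this mirrors; an FDR pass over the
edge-wise p matrix is easy to add downstream but is off by default, and the
tests verify the per-edge type-I level (≈ 0.043–0.05 at n = 8/8/7; the χ²
reference is slightly conservative at these sizes). Star tiers use strict
inequalities: p < 0.05 and p < 0.005.

## Longitudinal slope

For two matrices of the same group at consecutive time points, the package
fits a least-squares line through the origin to the scatter of unique
off-diagonal edges, later time point on the vertical axis:
`slope = Σxy / Σx²`. A slope of 1 is the identity line (no change); the
deviation from 1 measures global increase or decrease. Minimizing vertical
residuals with x = earlier time point is a deliberate, asserted convention —
swapping the axes gives `Σxy / Σy²`, *not* the reciprocal. Group-average
matrices are the default input (per-subject pooling is possible by passing
stacked matrices); the noise-free contract `slope(m, c·m) = c` holds to
machine precision.

## The diffusion model

Analytic Q-ball reconstruction expresses the normalized single-shell signal
in the real, even-order spherical-harmonic basis (order L = 8, 45
coefficients, identifiable from 126 directions) fitted by regularized least
squares with the Laplace–Beltrami penalty `λ Σ l²(l+1)² c²`, λ = 0.006. The
Funk–Radon transform is applied analytically by scaling order-l coefficients
with `2π P_l(0)`; even-only orders make the ODF antipodally symmetric by
construction. The ODF is sampled on an icosahedral mesh subdivided to an
edge frequency of 8 (642 directions, 321 per hemisphere) — the "8-fold
tessellation" convention of the originating toolchain, whose exact vertex
count is not material as long as the mesh is fine enough (several hundred
hemispheric directions) and recorded in provenance.

Peaks are strict discrete local maxima over the mesh adjacency, collapsed
across antipodes. **Quantitative anisotropy** of a peak is its ODF value
minus the voxel's ODF minimum, normalized by the largest such value in the
mask, giving QA ∈ [0, 1]; the published QA definitions vary in their
normalization, and this brain-relative form makes the 0.03 termination
threshold a fraction of the strongest voxel's anisotropy. A relative floor
(1e-8 of the field's ODF magnitude) keeps numerically flat (isotropic) ODFs
from reporting spurious peaks.

The deterministic tracker seeds random subvoxel positions (reproducible
from the RNG seed) in every voxel whose top QA reaches the threshold, and
propagates in both directions: at each 0.5 mm step it looks up the nearest
voxel's peaks (no trilinear peak interpolation — nearest-voxel lookup
matches discrete-peak deterministic tracking and keeps the oracle
tractable), selects the peak most parallel to the incoming direction among
those above the QA threshold, stops if none qualifies or the turn exceeds
55°, and advances along `(1−w)·peak + w·incoming` with w = 0.1. The "0.1
weighting" of the reference tool is interpreted as this direction momentum
(the main alternative reading, ODF-weighted interpolation, is incompatible
with nearest-voxel peak lookup); the choice is flagged here. Retained
streamlines lie within 5–120 mm.

**Fiber density** between ROIs i and j counts streamlines touching both
(each once per pair) and divides by `voxels(i) + voxels(j)` — "voxel
normalization" is underspecified in the field, and the symmetric sum is the
simplest convention that makes the threshold "one fiber per voxel"
meaningful for a pair; entries below 1 are set to exactly 0. For groups,
per-subject densities are averaged *before* zeroing (normalize → average →
zero, following the sentence order of the convention this mirrors); both
orders are available.

## What the simulator emulates — and what it does not

`simulate_study_cohort()` reproduces the *statistical* structure the
pipelines consume: three groups (default n = 8/8/7) × two time points, 105
frames at TR 2.84 s, a positive-semidefinite target correlation matrix over
12 named mouse-brain ROIs (two-factor structure: a default-mode-like block
and a sensorimotor block over a global factor, within-network r ≈ 0.5,
between ≈ 0.2), with the transgenic groups' off-diagonal scaled to 0.5 at
baseline and 1.0 after treatment — the "half-strength baseline, full
recovery" scenario. The 0.5 scale is a modeling choice: the motivating
observations say "approximately half", and no fitted effect size exists to
copy.

Latent ROI signals are white Gaussian series restricted to 0.01–0.08 Hz by
a frequency-domain brick-wall filter (so band-limitation is exact), then
mixed by the symmetric square root of the target correlation matrix. By
default the latent block is empirically whitened first, which makes the
latent sample correlation *equal* the target, not merely in expectation.
This is the same device as `mvrnorm(..., empirical = TRUE)` and is what
makes parameter-recovery tests sharp: at 105 frames a band-limited series
has only ~40 effective degrees of freedom, so without empirical mixing the
per-subject sampling error of z would be ±0.16 and recovery bounds would be
dominated by simulation noise rather than by the pipeline under test. With
empirical mixing, residual error reflects what the pipeline adds (voxel
noise attenuation, regression projection, filter edges) — measured at under
0.02 bias on the z scale, against a 2·SE tolerance of 0.07. Set
`empirical = FALSE` for fully stochastic cohorts.

On top of the latent signals, every in-ROI voxel receives white noise
(SD 0.5 relative to the unit-SD latent signal — a mid-range contrast-to-noise
for ROI-level rodent rs-fMRI), random-coefficient linear and quadratic
drifts, a respiratory sinusoid (1.2 Hz, sampled at the TR and therefore
aliased, exactly as a recorded trace would be), and small loadings on six
smoothed-random-walk motion series. The returned nuisance set contains the
injected traces exactly, which exercises the regression path end to end.
Block ROIs are separated by background gaps so 0.3 mm smoothing cannot mix
neighbouring ROIs.

Not emulated: hemodynamic response shape, spatially correlated physiological
noise, EPI distortion, inter-frame motion requiring realignment, partial
voluming at ROI borders, and atlas misregistration. Passing recovery tests
therefore demonstrates that the pipeline's arithmetic is faithful under its
own assumptions, not that those confounds are handled — brain extraction,
slice-wise motion correction and atlas coregistration are explicitly
upstream of this package.

The diffusion phantoms use axially symmetric tensors (axial 1.7e-3, radial
0.3e-3 mm²/s — white-matter-like; isotropic 2.0e-3 mm²/s, CSF-like, giving
realistic contrast at b = 2000) over known tube geometries, with Rician
magnitude noise (`sqrt((S+n₁)² + n₂²)`) because diffusion magnitude data are
Rician, and a Gaussian approximation would understate the floor at low SNR.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full study design
(46 BOLD datasets of 21×16×4 voxels × 105 frames; diffusion phantoms of up
to 40×12×8 voxels × 134 volumes) — sizes chosen so the complete dual-arm
analysis, run twice for bit-reproducibility checks, finishes in a few
minutes on one CPU while keeping every ROI large enough (32 voxels) for
stable ROI averages and intra-node statistics. Every random draw descends
from one master seed through fixed arithmetic, so cohort generation,
tracking and the entire pipeline are pure functions of their inputs; the
tests assert bit-identical reruns.

## Known limitations

* The Friedman exact option covers k = 2 conditions (the two-time-point
  design); more conditions fall back to the χ² reference.
* QA is normalized per reconstruction (brain-relative), so QA values are
  comparable within a dataset but not across scanners without calibration —
  the 0.03 threshold assumes this normalization.
* The tracker's nearest-voxel peak lookup quantizes direction fields at the
  voxel scale; sub-voxel curvature below the step size is not followed.
* Matrix tables store the diagonal as `NA` by convention; consumers that
  need self-connectivity must fill it explicitly.
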