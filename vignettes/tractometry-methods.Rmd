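---
title: "Methods: longitudinal tractometry on synthetic DWI cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal tractometry on synthetic DWI cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `tractwise`, in the order the pipeline runs:
simulate → fit → track → extract → profile → stats.

## 1. The phantom model

### Signal model

The generator produces diffusion-weighted volumes from a voxel-wise
tensor field under the monoexponential Stejskal–Tanner model,
$S = S_0 \exp(-b\, \mathbf{g}^\top D \mathbf{g})$, with magnitude noise
formed from two independent Gaussian quadrature channels,
$\tilde S = \sqrt{(S + n_1)^2 + n_2^2}$, $n_i \sim N(0, S_0/\mathrm{SNR})$
— the Rician distribution of magnitude MRI. SNR is defined on the $b=0$
signal. The default acquisition mirrors a mid-2000s 1.5 T clinical
protocol: 25 diffusion directions at $b = 1000\ \mathrm{s/mm^2}$ plus 5
$b = 0$ volumes; directions are a deterministic Fibonacci sphere lattice,
which gives a well-conditioned design without a stored direction table.
An acquisition protocol does not pin down a noise floor, so the default
SNR 25 is simply a typical clinical value and is exposed as a parameter;
it is a free parameter of the phantom, not a reproduction of any
scanner's noise characteristics.

### Geometry

Fiber bundles are tubes of radius 4 mm around parametric centerlines.
Three fixtures cover the tangent-field regimes that stress a
deterministic tracker: a straight tube, a C-shaped quarter-circle arc,
and an S-curve with an inflection. They live in a 40 × 40 × 20 voxel grid
at 2 mm isotropic — deliberately smaller than a clinical field of view so
that a full cohort runs on a desktop in minutes; nothing in the code
depends on this size. In-tube voxels carry an axially symmetric tensor
$D = \lambda_3 I + (\lambda_1 - \lambda_3)\, \mathbf{t}\mathbf{t}^\top$
whose principal axis is the local centerline tangent; the background is
isotropic with the same trace, so background FA is exactly 0. Integer
seed/target labels are painted as spheres of the bundle radius at the two
curve ends, playing the role that anatomical segmentation labels play on
real data (label volumes are always *consumed*, never computed, by this
package).

The tensor trace is fixed at $2.1 \times 10^{-3}\ \mathrm{mm^2/s}$
(typical adult white matter); "aging" changes only the anisotropy. Given
a target FA and trace, the eigenvalues follow in closed form: writing
$\lambda = m(1+2x), m(1-x), m(1-x)$ with $m = \mathrm{trace}/3$,
$\mathrm{FA} = \sqrt{3x^2/(1+2x^2)}$, inverted by
$x = \mathrm{FA}/\sqrt{3 - 2\,\mathrm{FA}^2}$.

### Longitudinal design

`phantom_cohort_spec()` encodes the study conditions the cohort emulates:
baseline age 59 ± 7 years; two or three waves separated by 3.6 ± 0.3
years (per-subject jitter); per-bundle baseline FA 0.45; and true
per-subject annual FA change rates drawn as
$N(\text{mean decline}, \text{SD})$ with default 1.5 ± 0.5 %/year —
declines of 0–2 %/year with inter-individual variability. The decline is
applied to the *generative eigenvalues* at each wave
($\mathrm{FA}(t) = \mathrm{FA}_0 (1 - r t / 100)$), so noisy FA estimates
vary around a known truth; ground truth (ages, intervals, rates, per-wave
FA) is recorded for parameter-recovery checks. Waves share one grid: the
synthetic cohort is co-registered by construction, standing in for the
eddy-current correction and multimodal registration that real data would
need (out of scope here). No T1 simulation, EPI distortion or motion
model is attempted.

Determinism: one master seed drives the cohort design, and each
subject-wave acquisition uses a seed derived arithmetically from
(master, subject, wave), so cohorts are byte-identical across runs and
any subject-wave can be regenerated in isolation.

## 2. Tensor fitting

`fit_tensor()` is ordinary least squares on the log signal with 7
unknowns (6 tensor components + $\ln S_0$) — the classical estimator of
the era's tensor tools, exact on noiseless monoexponential data (the
round-trip property asserted in the tests). Weighted or fully nonlinear
variants are deliberately not the default; a nonlinear LS fit appears
only as an independent oracle in the test suite. Numerical conventions:

* signals are clamped to $10^{-6} \bar S_0$ (per-voxel mean $b=0$) before
  the log, so Rician noise can never feed a non-positive value to it;
* a brain mask can be derived by Otsu thresholding of the mean $b=0$
  volume (`mask = "otsu"`); ties in the Otsu criterion — an empty valley
  between modes — resolve to the valley midpoint. The phantom has uniform
  $S_0$, so the default is to fit every voxel;
* eigenvalues are sorted descending; negative eigenvalues (possible under
  noise) are clamped to $10^{-12}$ *for FA only*, the raw values being
  kept for diagnostics; non-finite tensors are flagged invalid and leave
  the mask. FA of the all-zero triple is undefined (NA), distinct from a
  true FA of 0.

Per-voxel 3 × 3 eigensystems and streamline propagation are implemented
in compiled code (Rcpp/RcppArmadillo), as is usual for DTI tooling; the
rest is vectorized R.

## 3. FACT tracking

From every voxel with FA ≥ `fa_stop`, a streamline is propagated
bidirectionally along the principal eigenvector and the two half-tracks
concatenated. The tracker advances with a fixed step of half the smallest
voxel dimension, using trilinearly interpolated directions in which each
contributing voxel's eigenvector is sign-aligned with the incoming
direction (eigenvectors are line fields: $v$ and $-v$ are the same
orientation). Termination: leaving the volume, interpolated FA below
`fa_stop`, or a turning angle above `angle_stop`; an exact 90° flip
terminates. At an exactly orthogonal corner the blend uses the vector's
canonical orientation (first non-zero component positive), which makes
tracking invariant under a global sign flip of the field — an invariant
the test suite asserts.

Defaults `fa_stop = 0.15`, `angle_stop = 35°`, one seed per voxel at the
voxel centre: tracker settings of the Diffusion-Toolkit era were rarely
reported, so these defaults are declared assumptions chosen to match
common FACT practice, all config-exposed. Coordinates are "voxel-mm" (0-based voxel index scaled by
voxel size, voxel centre at index + 0.5), the TrackVis convention, so the
`.trk` files the package writes open in standard viewers and round-trip
bit-exactly through its reader (points are float32, the format's
precision).

## 4. Bundle extraction and tract mean FA

A streamline joins a seed→target bundle iff it has at least one point in
each label mask ("any-point" membership is the default; an endpoint-only mode exists as
a flag for workflows that require streamline *endpoints* in the masks). Retained streamlines are trimmed
to the sub-polyline between their last seed-mask point and first
target-mask point, reversing first if needed so members leave seed-first;
extraction is symmetric in seed/target up to that orientation. When seed
and target coincide, membership requires two separate visits to the mask.
ROI masks are used exactly as labelled, with no dilation.

Recognition criteria follow the longitudinal design the phantom
emulates: a
bundle is a proper tract with ≥ 20 continuous fibers (boundary
inclusive), and a connection qualifies for group analysis when detected
in ≥ ceiling(0.9 × cohort) subjects — with 76 subjects that is ≥ 69, and
applying the rule to the shipped detection table selects 19 connections.
ceiling() is the reading consistent with a 69-count qualifying while 68
does not. In the longitudinal setting a subject counts as "detected" only
if the bundle passes the fiber threshold at *every* wave, since only
those subjects support a change analysis.

Tract mean FA is the unweighted mean over the set of *unique* voxels
visited by at least one member streamline ("grand average of the FA-map
region" reading); it is therefore invariant to duplicating streamlines. A
per-streamline-point mean is available as a config alternative
(`mode = "point"`).

## 5. Along-tract parameterization

"Equidistant data points" is implemented as arc-length-uniform
resampling per streamline — spacing $L/(n-1)$, endpoints preserved — the
only reading invariant to the tracking step size. FA is sampled at each
resampled point by trilinear interpolation (nearest-neighbour as config).
Segment means and standard errors are taken across streamlines at fixed
segment index; a single-streamline bundle has SE 0 by convention, an
empty bundle an all-missing profile. Three modes:

* **two-ROI** (`profile_two_roi`): segment 1 at the seed, segment 100 at
  the target, on the oriented, trimmed bundle;
* **single defining ROI** (`profile_single_roi`, corticospinal-style):
  each streamline is parameterized by arc distance from its point nearest
  the ROI centroid toward its distal end, normalized over the bundle's
  common extent (the shortest distal reach among members), so segment 1
  anchors at the ROI and segment *n* at the common distal cut;
* **midline-split** (`profile_acf`, callosal-style): each streamline is
  split at its midsagittal crossing and each half profiled outward from
  the midline (segment 1) to the cortical end, tagged left/right —
  2 × 100 segments. The midline defaults to the volume-centre x-plane,
  which is exact for the symmetric synthetic space; real data would
  supply the anatomical midsagittal plane.

Whether a cohort analysis should average segment FA across streamlines
within subject before group statistics, or pool points, is an open
reading; within-subject averaging is implemented (each subject
contributes one value per segment), matching how the cohort-level SE
bands are described in this literature. Cohort-level segment SEs are
computed across subjects on those per-subject segment means.

## 6. Longitudinal statistics

All group statistics run on a long cohort table (subject, wave, age,
interval, connection, tract mean FA):

* **Annual percentage change**: $100 (FA_b - FA_a)/FA_a / \Delta t$,
  computed per subject with that subject's own inter-scan interval
  (cohort mean 3.6 years as fallback when missing), then averaged across
  the sample — mean-of-subject-rates, not rate-of-means. For three waves
  the default is the mean of the two per-interval rates; the overall
  wave-1→3 rate is a config alternative, the wording "calculated over
  these two intervals" admitting both readings. Summaries over
  connections use magnitudes; the shipped tables' printed values all
  share sign, so both conventions agree there.
* **Outlier rule**: values deviating more than 2.5 sample SDs (n−1
  denominator) from the sample mean are excluded, single pass, no
  re-iteration; zero-variance samples exclude nothing. Note the rule
  cannot fire below n = 7 (the maximum attainable z is $(n-1)/\sqrt n$).
  It is applied to the per-subject annual rates in two-wave analyses;
  three-wave analyses use listwise deletion without it, matching the
  tables it mirrors.
* **Tests**: classical paired *t* (pairwise deletion; df = n−1;
  zero-difference degeneracy returns p = 1 by convention) between two
  waves; one-way within-subject ANOVA (listwise deletion, df = (w−1),
  (w−1)(s−1), no sphericity correction — with two waves it reduces
  exactly to the squared paired t) for three. Implemented via `t.test()`
  and `aov(y ~ wave + Error(subject/wave))`, with a scale-relative guard
  mapping a numerically-zero wave effect to F = 0, p = 1; the tests
  validate both against textbook sums-of-squares oracles and calibrate
  type-I error by simulation.
* **Correction**: Bonferroni, reported rounded to 4 decimals — 0.05/22 =
  0.0023 for tract-mean analyses (22 = the tract families tested),
  0.05/100 = 0.0005 for the 100 segment-wise tests. The significance flag
  uses the rounded level, which is the level the mirrored tables state.
  One shipped two-wave table row is marked significant at "p < 0.005"
  rather than the computed 0.0023; the package follows the computed rule
  and simply carries the table's flag column as printed.
* **Age correlation**: Pearson r between baseline age and yearly change,
  two-sided t-based p; degenerate (zero-variance) input is an error, not
  a silent NA.

## 7. Problem sizes and runtime

Sizes used by the test suite and acceptance script, chosen as the
package's own desk-scale defaults: the 40 × 40 × 20 three-bundle phantom
for all geometric checks; a 76-subject, two-wave, SNR-25 cohort with one
bundle declining 1.5 ± 0.5 %/year for parameter recovery (the estimated
cohort decline lands within ±0.3 %/year of the generative mean and the
declining connection is flagged at α = 0.0023); 2000 replicates for the
paired-t null calibration and 500 × 100 segment tests for the
segment-wise null (expected significant segments per profile
= 100 × 0.0005 = 0.05).

## 8. What the phantoms do and do not show

Passing on phantoms establishes the pipeline's internal correctness:
exact round-trips where mathematics promises them, geometric fidelity of
tracking on known curves, correct bookkeeping of the selection rules and
statistics, and unbiased recovery of generative decline rates under
Rician noise. Real data differ in ways the generator deliberately omits:
crossing and branching fibers within a voxel (the single-tensor model
cannot represent them), partial-volume mixing at tract borders and the
gray-matter sheet, geometric EPI distortion, imperfect registration
across sessions, atrophy-driven anatomical change, and spatially varying
noise. Findings about *those* effects cannot be claimed from this test
bed; what can be claimed is that any failure on real data is not a defect
of the analysis chain itself. Mixed-effects longitudinal models,
sphericity corrections and FDR-style alternatives are intentionally out
of scope.
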