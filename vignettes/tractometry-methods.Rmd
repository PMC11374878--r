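---
title: "Models and methods behind the tractometry pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the tractometry pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the numerical choices, what the synthetic data emulate, and
what passing tests do and do not establish about real acquisitions.

## The problem

Tractometry asks, per white matter tract and per subject: how big is the
tract, and what do quantitative diffusion metrics look like along it? The
package implements that chain end to end — from a multi-shell
diffusion-weighted signal to per-tract volumes (raw and normalized to
total brain and white matter volume), along-tract metric means, and a
Bonferroni-controlled two-group comparison with effect sizes — together
with a synthetic phantom and cohort generator so every stage can be
exercised, with known ground truth, on a laptop.

The emulated acquisition geometry follows a connectome-style protocol:
three shells at b = 1000, 2000, 3000 s/mm², 90 directions per shell
(configurable), 6 b = 0 volumes, 1.25 mm isotropic voxels. The emulated
cohort is two groups of healthy young adults (men/women) with realistic
total brain volume (1290 ± 102 vs 1128 ± 90 cm³) and white matter volume
(476 ± 49 vs 409 ± 42 cm³) distributions.

## Signal models

**Diffusion tensor.** `simulateSignalTensor()` implements
S = S₀·exp(−b·gᵀDg). `fitDti()` inverts it by weighted linear least
squares on the log signal: an ordinary LLS pass followed by one IRLS step
with squared-predicted-signal weights — the standard estimator, and still
an exact inverse at zero noise. Only the b = 0 and b = 1000 s/mm² volumes
enter the tensor fit; the innermost shell is where the Gaussian model is
adequate, and the package treats that restriction as an invariant (tests
corrupt the outer shells and require an identical fit). Negative
eigenvalues are clamped to zero before scalar computation and counted in
the fit's QC slot. FA of an all-zero tensor is defined as 0.

**Constant-solid-angle Q-ball.** `fitCsaOdf()` reconstructs orientation
distribution functions per shell from the double-log transform
log(−log E) of the normalized signal, expanded in the real even
spherical-harmonic basis with Laplace–Beltrami regularization
(λ = 0.006), followed by the Funk–Radon transform through the Legendre
eigenvalues and the spherical Laplacian. E is clamped to [δ, 1−δ] with
δ = 10⁻³ before the double log. The three shells are combined by
averaging the per-shell ODF SH coefficients with equal weights — the
simplest fusion consistent with "computed using all shells", and easy to
test. The SH order defaults to 8 (45 coefficients, supported by 90
directions per shell) and is configurable from 4 to 8; the demo pipeline
uses order 6 with 30 directions per shell, a deliberate desk-scale
problem size.

GFA is the population standard deviation over root-mean-square of the
sampled, clamped, normalized ODF; it is 0 for a uniform ODF and
√((N−1)/N) ≈ 0.995 for a one-hot ODF on N = 100 directions.

**NODDI.** `simulateSignalNoddi()` is the three-compartment model:
Watson-dispersed sticks (intrinsic parallel diffusivity
d∥ = 1.7·10⁻³ mm²/s), an extracellular zeppelin with the tortuosity
coupling d⊥ = d∥(1 − ν_ic), and an isotropic ball
(d_iso = 3.0·10⁻³ mm²/s); both diffusivities are the conventional fixed
values of the model. The stick orientation average is computed by
3072-point spherical Fibonacci quadrature — simpler than hypergeometric
series and testable against the high-κ (no attenuation across the fiber)
and low-κ (isotropic) limits. The extracellular compartment uses the
dispersion-averaged tensor, i.e. the Watson second moment
τ₁ = E[(μ·n)²] folds the zeppelin into a single Gaussian — the standard
formulation of the model. `fitNoddi()` inverts by a coarse dictionary
search (ν_ic, ν_iso ∈ {0, 0.1, …, 1}, κ ∈ {0.25 … 64} in octaves, 30
candidate orientations) followed by bounded L-BFGS-B refinement of the
sum of squared residuals against the *same* forward model; voxels where
refinement fails to improve fall back to the grid optimum and are flagged
in a QC mask. The orientation dispersion index is ODI = (2/π)·atan(1/κ).

## Phantoms and noise

`buildPhantom()` rasterizes parametric tube bundles (polyline centerline
plus radius) onto the grid. In-tube voxels carry the bundle's anisotropic
ground truth oriented along the local tangent; the background is
isotropic free water. Tubes are best placed with their centerline on
voxel centers; the discretized tube then matches the analytic cylinder
volume closely (a centerline midway between voxel centers biases the
voxelized volume upward by ~20–30% at radius ≈ 2 voxels — ordinary
discretization behavior worth knowing when choosing geometries). Voxels
claimed by two tubes are either an error or, in crossing mode, carry an
equal-fraction two-orientation mixture with both orientations recorded —
sufficient to test ODF maxima and crossing tractography without modeling
full fiber ODFs.

Noise is Rician by default (magnitude MRI): |S + ε₁ + iε₂| with
ε ~ N(0, σ²); a Gaussian option exists for analytic tests. The emulated
protocol's SNR is not a published quantity; the phantom default σ = S₀/30
is a configuration choice. True bundles are returned as tractograms: the
centerline plus parallel copies filling the tube cross-section on a
sunflower pattern, so density masks of the true bundle approximate the
tube.

## Tractography

`track()` implements regularized probabilistic streamlining with the
protocol defaults: 8 seeds per voxel uniformly jittered inside each
propagation-domain voxel, 30° aperture, 0.3 mm forward and backward
steps, retained length range 1.25–300 mm (discarding both noise-scale
fragments and runaway loops), sampler temperature T = 1. The propagation
domain is the white-matter mask dilated by one voxel (the package has no
anatomical T1 image to derive it from, so the mask stands in). Stopping
occurs on leaving the domain or when no candidate direction carries
positive ODF mass; SH coefficients are interpolated trilinearly at
off-grid positions.

The direction law was the one genuinely open design point. The sampler
draws from a 724-direction tessellation restricted to the aperture cone,
with probability proportional to a sharpened, min–max-normalized ODF:

p(v) ∝ (ψ(v) − ψ_floor)^(γ/T),

where ψ_floor combines the voxel's global ODF minimum with the cone-local
minimum. Plain ODF-proportional sampling (γ = 1) is far too diffusive
for band-limited Q-ball ODFs: an order-8 single-fiber ODF still carries
~50% of its peak value 30° off-axis, and with the sin θ solid-angle
weighting the walk approaches maximal angular diffusion and cannot
follow a straight fiber. Min–max normalization and exponentiation are the
classical Q-ball remedies (sharpening leaves the maxima untouched and
plays the role of a deconvolution); γ = 6 was fixed once as the smallest
integer at which sampling in an ideal single-fiber field concentrates
within the tessellation's angular resolution, giving a mean per-step
deviation of ~10° — inside the half-aperture invariant the tracker is
required to satisfy. The temperature keeps its Gibbs semantics: larger T
flattens the law, T → 0 approaches deterministic maximum-following.

Per-step GFA values are not stored with the streamlines: no stage
consumes them (GFA-based stopping is deliberately not applied; the
domain is the only stopping criterion), and computing them would add a
full-sphere ODF evaluation per step for dead weight.

## Bundle labeling and measures

Labeling uses the flip-symmetrized maximum corresponding-point distance
on 21 equidistant resampled points: d(a, b) = min(max‖aᵢ−bᵢ‖,
max‖aᵢ−b_rev,i‖). A streamline is assigned to the closest atlas centroid
among those whose threshold it satisfies, else left unlabeled — each
streamline gets exactly one label, so labels partition the tractogram.
The wording of distance-based labeling in the literature mixes "maximum"
(the point-wise aggregation) and "minimum" (the assignment rule); this
package reads the max as the per-pair distance and the min as the
assignment, which satisfies both sentences and is the strict
(Guevara-style) convention. Real atlases publish per-tract thresholds;
the packaged toy atlas uses 10 mm everywhere, and thresholds are always
data, never hard-coded.

Volumes come from density masks: a voxel belongs to a bundle's mask when
at least 5 *distinct* streamlines (not points — 0.1 mm resampling must
not inflate counts) put a resampled point inside it. Mask volume is
reported in cm³ and normalized to TBV and WMV (voxel counts of the brain
and white matter masks). Along-tract metric means resample every
streamline to 0.1 mm, interpolate the map trilinearly at every point,
and pool *points* (longer streamlines weigh more — the literal reading
of "mean of the values at all fiber points"). A Shapiro–Wilk p-value of
the pooled values is recorded per metric as QC and never gates the mean.
Atlas-to-subject alignment is rigid/affine only (a 4×4 matrix applied by
`transformTractogram()`); diffeomorphic registration is out of scope, as
the phantoms are generated directly in atlas space.

## Cohort statistics

`groupCompare()` records Shapiro–Wilk (per group) and Levene (center =
mean) p-values as QC columns, but the reported p always comes from the
two-sided pooled-variance Student's t — no fallback test is switched in,
because none is specified for the procedure being reproduced. Cohen's d
uses the df-weighted pooled SD; positive d and positive relative
difference mean men > women. Relative differences use the men-group
denominator: this reproduces the printed TBV (+12.6%) and genu (−7.3%)
values exactly, though no denominator convention reproduces the printed
WMV figure from its rounded group means (those were evidently computed
on unrounded data); the convention here is a documented decision.
Effect-size bins split |d| at 0.2/0.5/0.8; the published inequalities
are open at the boundaries, so exact boundary values are assigned
upward.

The comparison family is computed from the data, never hard-coded: per
tract the two normalized volumes and eight metrics, plus TBV and WMV —
10·T + 2 comparisons, which is 772 for a 77-tract atlas, with threshold
0.05/772 = 6.4767·10⁻⁵. The ANCOVA is ordinary least squares of
normalized volume on TBV, sex, and their interaction; the interaction F
tests slope equality between the sexes, complementing the per-sex
regressions.

## The demo pipeline and problem sizes

`runDemoPipeline()` runs the full chain per seed: a 16³ phantom at
1.25 mm with the three toy-atlas bundles (tensor forward model, Rician
SNR 30, 30 directions per shell, SH order 6, dictionary-only NODDI) goes
through fit → track → label → measure; then a 10 + 10 cohort is drawn
with a planted genu-like deficit on one tract (men 2.06 ± 0.27 vs women
2.21 ± 0.27 %TBV, true d = −0.56) and the full comparison plus ANCOVA
runs. These sizes are the package's desk-scale choices; the grid, shell
count, and SH order scale up by argument.

One caveat the package states plainly: at n = 10 + 10 the sampling
distribution of the d estimate is 0.447·t(18, ncp = −1.252) — a standard
deviation near 0.46. A single 20-subject draw therefore lands in the
medium bin (−0.8, −0.5] only about a quarter of the time, and is merely
*negative* about 89% of the time. Recovering the planted bin reliably at
that cohort size is statistically impossible, which the acceptance suite
reflects honestly rather than papering over; at the full cohort scale
(490/575) the same machinery recovers the bin essentially always.

## What the phantoms do not show

The generator emulates acquisition geometry, single- and two-fiber
microstructure, and group structure — not anatomy. It has no
gyrification, no partial-volume gradient between tissue types beyond the
tube boundary, no susceptibility or eddy artifacts (the emulated data
are "already corrected"), no T1 contrast, and Gaussian-group cohort
measures with independent metrics. Passing tests therefore establish
correctness of the algorithms and calibration of the statistics under
the stated models — not robustness to real-scanner confounds. Tract
means near tube boundaries are slightly diluted by interpolation across
the mask edge, exactly as partial-volume effects dilute real along-tract
means near CSF; the tests quantify that rather than hiding it.

## Numerical details worth knowing

- Direction sets: spherical Fibonacci for full-sphere quadrature and
  tessellations; hemisphere Fibonacci with a seeded random rotation per
  shell for gradient schemes (axial uniformity, minimum pairwise angle
  > 10° at 90 directions).
- Watson weights are computed with the max subtracted in the exponent,
  so κ up to the 10³ range is stable.
- All RNG goes through an internal `withSeed()` that saves and restores
  the caller's RNG state; same seed ⇒ bit-identical phantom, tractogram
  and cohort.
- TCK is the native streamline format (world mm, RAS); TRK round-trips
  through its corner-based voxel-mm convention via the header's
  vox-to-ras matrix. NIfTI affines are written as sform (code 2) and
  read sform-first.
- Interpolation of maps tolerates the outer half-voxel rim (clamped to
  edge values); genuinely out-of-support bundles raise an error naming
  the offending extent.
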