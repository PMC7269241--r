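---
title: "Simulating MR attenuation-correction error in automated FDG-PET Alzheimer scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating MR attenuation-correction error in automated FDG-PET Alzheimer scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mracpet)
```

## Background

PET/MR scanners cannot measure photon attenuation directly; atlas-based
MR attenuation correction (MRAC) estimates it from MR images and
misestimates it, chiefly near skull bone. Because attenuation enters the
reconstruction multiplicatively, the result is a smooth, spatially
structured multiplicative error field on the reconstructed uptake image.
For dementia diagnostics the question is whether that field moves an
automated score across its decision cutoff.

This package reproduces the logic of that question end to end with
synthetic data. The design separates three ingredients that are usually
entangled in scanner data:

* a **cohort model** (who is scanned: disease groups, ages, disease
  effect sizes),
* an **error model** (what MRAC does: a calibrated multiplicative field),
* a **scoring model** (how images are judged: an age-regressed voxel-wise
  t-statistic summed over AD-related voxels).

## The scoring chain

Scoring follows the classical automated Alzheimer's-discrimination
procedure. For an input volume $u$ and subject age $x$:

1. *Spatial normalization* (affine; synthetic subjects are generated in
   template space, so this step is exercised only by deliberately
   perturbed inputs) and *smoothing* with a 12 mm FWHM Gaussian.
2. *Intensity normalization*: divide by the mean over the AD-preserved
   mask, the region whose uptake is typically spared in AD. All scores
   are therefore exactly invariant under global rescaling of the input.
3. *Expected values*: a per-voxel ordinary least squares regression of
   normalized uptake on age over $n$ reference controls gives intercept
   $a_v$, slope $b_v$ and residual SD $s_v$.
4. *t-map*:
   $$t_v = \frac{a_v + b_v x - u_v}
   {s_v \sqrt{1 + 1/n + (x - \bar{x})^2 / S_{xx}}}.$$
   Positive $t$ means hypometabolism. The denominator includes the
   prediction-interval inflation for comparing one new observation
   against a regression database; `t_denominator = "residual"` gives the
   plain residual-SD variant. Voxels with $s_v = 0$ contribute $t = 0$
   and are counted in a diagnostic.
5. *AD t-sum and PET score*: the t-sum is the signed sum over the
   AD-related mask (negative values subtract; `clip_negative_t` clips
   them), and the PET score is $\log_2(\text{t-sum}/11089 + 1)$. The
   constant 11089 — configurable, since it is cohort-derived — is the
   95 % prediction limit of the t-sum in healthy controls, so a t-sum at
   the limit maps to PET score 1.0, the AD-versus-normal cutoff;
   0.79 is the MCI-conversion cutoff.

The signed sum is the default because it keeps the score defined for
hyper-normal scans; the score is undefined at t-sums at or below
$-11089$, and any (subject, map) pair reaching that bound is recorded as
a flagged row and excluded from aggregates rather than crashing the run.

## The error model

A synthetic error map is, inside the brain mask,
$$e(v) = 1 + g + r(v) + o(\text{region}(v)),$$
and exactly 1 outside, clipped to $[0.7, 1.3]$ to keep the perturbation
physiological. The three terms:

* $g \sim N(-0.0137,\ 0.0198)$, one draw per map — the between-map
  distribution of the whole-brain mean error (−1.37 % ± 1.98 %).
* $r(v)$: white noise smoothed to 20 mm FWHM, centred over the brain mask
  and rescaled to within-map SD 0.02. Centring makes the per-map brain
  mean depend on $g$ alone; the regional means then carry extra
  variance from $r$, which is why the AD-mask SD slightly exceeds the
  brain SD — the same ordering seen in measured maps. The 20 mm
  correlation length is a free choice (the spatial autocorrelation of
  real MRAC error is not reported); it sets how independent the regional
  means are but not their calibrated levels.
* $o$: +0.0051 on the AD-related mask and −0.0022 elsewhere in the
  brain, making the expected AD-mask mean −0.86 % and the non-AD mean
  −1.59 %.

These three regional levels are mutually consistent only if the AD mask
occupies $f \approx 0.30$ of the brain
($f(-0.86) + (1{-}f)(-1.59) = -1.37$), which is why the phantom's
AD-related patches are sized to ~30 % of the brain mask.

Measured reconstruction pairs follow the same path: ratio with a guarded
denominator (voxels below 5 % of the in-mask mean are neutralized and
counted — scanner data near air/background would otherwise explode the
ratio), resampling to the template with the CTAC-derived transform, 12 mm
smoothing, brain masking with fill 1. Both sources share the `error_map`
type, so the cross simulation is agnostic to where a map came from.

## The phantom cohort

The template is a deterministic geometric phantom on a 46×55×46 grid at
4 mm (half-resolution MNI-like; a 91×109×91 / 2 mm configuration is a
config switch away): an ellipsoidal brain (semi-axes 0.40 of each grid
dimension, guaranteeing ≥ 2 voxel layers of smoothing headroom), a
low-uptake deep core, bilateral posterior/lateral AD-related cortical
patches, a superior/central preserved patch and an inferior
infratentorial blob; the preserved region (normalization mask) is the
patch plus the blob. The geometry is schematic on purpose — the scoring
mathematics sees only masks, never anatomy.

Subject volumes are
$$u(v) = \text{baseline}(v)\,(1 + \beta (x - x_0))\,(1 - \delta(v)) + \varepsilon(v),$$
with baseline 1.0 in gray-matter labels, 0.25 in the core, 0 outside;
$\beta = -0.003$/year about $x_0 = 72.5$; and the hypometabolic effect
$\delta$ equal to 0.20 inside the AD mask for AD subjects, 60 % / 20 % of
that for MCI converters / stable MCI, and 0 for controls. Ages are
uniform on [55, 90] by default — uniform ages spread leverage for the
regression-recovery tests; a normal(76.0, 6.3) option matches the
observed cohort age structure. Cohort sizes default to 48/59/96 with 33
converters, 20 + 27 error maps and 60 references.

The noise $\varepsilon$ is a Gaussian random field: white noise smoothed
to 6 mm FWHM and then rescaled to SD 0.05. Rescaling *after* smoothing —
the same construction as the error texture $r$ — makes the noise
amplitude independent of its correlation scale. This matters: without
the rescale, the 6 mm + 12 mm smoothing chain would shrink the reference
residual SD to ~0.4 % of uptake, t-values would be inflated by two
orders of magnitude, and a sub-percent error contrast would push AD
t-sums below the −11089 domain bound for essentially every pair,
leaving the whole evaluation undefined.

## Why error shifts scores at all

A spatially constant error map cannot change any score: intensity
normalization is rerun per simulated image, so global factors cancel
exactly (an asserted invariant). What moves the score is the *contrast*
between the error in the AD mask and the error in the preserved mask.
Calibrated maps underestimate the preserved region more than the AD
region, so normalized AD-mask uptake rises by ~0.7 %, t-values fall, and
PET scores shift downward — the underestimation direction, which the
default study reproduces in 40 of 47 maps (seed 1).

## Numerical choices

* World coordinates are RAS+; voxel indices 0-based; the affine maps
  indices to millimetres with the origin at the grid centre.
* Smoothing kernels are FWHM-specified, sampled at integer offsets,
  truncated at 4σ, normalized to sum 1; boundaries use nearest-edge
  replication. Mass is conserved away from boundaries to 1e−6.
* Resampling is pull-back trilinear interpolation with out-of-field
  voxels set to 0; coordinates within 1e−9 of an integer are snapped so
  identity and whole-voxel translations are bit-exact.
* Registration minimizes mean squared intensity difference (the pipeline
  is mono-modal) by Nelder–Mead over translation → rigid+scale → full
  degrees of freedom, coarse-to-fine, with centroid pre-alignment, a
  deterministic rotation-offset multi-start when the coarse fit is poor,
  and a fresh-simplex restart at full resolution. Convergence is claimed
  only when the inputs overlapped at the starting transform and the
  final cost clears the trivial-cost bar. The optimizer consumes no
  global RNG state.
* Residual SDs at floating-point rounding level (a noise-free cohort)
  are floored to zero rather than left as 0/0 t-values.
* The Wilson score interval is used for proportions (stable at 0 and 1);
  predictions use score ≥ cutoff, so the boundary counts as positive.
* Error-map ranking is by accuracy, ties broken by sensitivity then map
  id; the across-map "average/worst/best" are per-metric extremes, and
  best-k/worst-k map ids under the ranking are also reported since both
  readings of a summary table are plausible.
* One master seed fans out to named per-stage substreams (subjects,
  reference, error maps), so each stage is independently reproducible
  and the whole study is a pure function of (config, seed).

## Problem sizes

The default study — 203 subjects + 60 references on the 4 mm grid, 47
maps, 9541 scored pairs — runs in well under a minute on one CPU; the
cross simulation evaluates only AD-mask and preserved-mask voxels (the
only voxels a score depends on), and its equivalence with the full
volume-by-volume scoring path is itself a tested property.
Registration-recovery properties use a 28×32×28 / 5 mm phantom with
asymmetric landmark bumps added: a smooth symmetric ellipsoid is nearly
rotation-degenerate (several-degree rotations change the cost by less
than the interpolation floor), so recovery accuracy is only measurable —
as with real brains — on images with asymmetric features.

## What the synthetic study does and does not show

The generator reproduces the *structure* the analysis relies on: cohort
composition, an age trend, group-ordered hypometabolism, and error
fields with calibrated regional statistics. It deliberately omits
between-subject anatomical variability, partial-volume and scanner PSF
effects, dose/duration differences (institutions differ only by label),
and any real atlas-AC physics. Two consequences deserve emphasis:

* Reference variability here is measurement noise only, far below
  biological variability, so absolute t-sums and PET scores are inflated
  and group separation saturates: AD-vs-NC accuracy is 100 % at the 1.0
  cutoff, and every stable-MCI phantom also clears the 0.79 cutoff.
  Absolute accuracies from this simulation say nothing about clinical
  accuracy; the meaningful endpoints are structural (cardinalities,
  calibration of error statistics, invariances) and directional (the
  sign of the score shift, its dependence on the AD-vs-preserved error
  contrast, the absence of an institution effect).
* The error model is additive-in-offsets by construction, so regional
  calibration is recoverable without real data — that is its purpose,
  not evidence about real MRAC spatial structure.

## Limitations

Affine-only normalization (no nonlinear warp), trilinear interpolation
only, mono-modal MSE registration only, no CT/MR handling, no partial
volume modelling, one scoring tool. The division guard threshold for
measured pairs (5 % of in-mask mean) is this package's addition; measured
maps with true near-zero CTAC uptake inside the brain mask will have
those voxels neutralized and counted rather than propagated.
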