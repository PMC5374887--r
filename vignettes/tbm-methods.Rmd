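---
title: "Tensor-based morphometry for small-animal MRI: models, phantom design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor-based morphometry for small-animal MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

`tbmpipe` implements a complete tensor-based morphometry (TBM) analysis
for 3D structural MRI of the mouse brain, together with a synthetic
phantom cohort generator that stands in for real paired in vivo / ex
vivo scans. TBM asks, voxel by voxel, where one group of brains is
locally larger or smaller than another. The measurement chain is:

1. **Preprocessing** — intensity non-uniformity correction, piecewise
   linear intensity standardization, multi-atlas brain masking.
2. **Group-wise registration** — all subjects are rigidly aligned to a
   randomly chosen target, then iteratively affine-registered (12 dof,
   normalized cross-correlation) and non-rigidly registered (cubic
   B-spline free-form deformation, normalized mutual information) to an
   evolving intensity average, which sharpens toward the group's mean
   morphology.
3. **Jacobian analysis** — for each subject the composite transform
   `T(y) = A(y + u(y))` maps average space to that subject; the log of
   `det DT` at each voxel is the subject's local volume relative to the
   average (`log J > 0` = locally larger). Maps are smoothed with a
   0.2 mm FWHM Gaussian.
4. **Statistics** — voxelwise pooled-variance two-tailed t-tests
   (equivalent to the two-group GLM), Benjamini–Hochberg FDR at
   q = 0.05, Cohen's d with pooled SD, and the per-voxel sample size

   N_arm = ceil( 2 (Z_{α/2} + Z_{1-β})² sd_WT² / 0.25² )

   with Z_{0.975} = 1.96 and Z_{0.8} = 0.84 — the animals per arm needed
   to detect a 25% local volume difference at α = 0.05 and power 0.8.
5. **Distortion mapping** — each ex vivo scan is registered to its own
   in vivo scan; the mean positional distance (MPD) is the per-voxel
   mean norm of the *non-rigid* displacement components across
   subjects, a map of fixation-induced tissue distortion.
6. **Quality metrics** — ROI SNR (mean signal / background noise SD),
   gray–white CNR ((cortex − corpus callosum) / noise SD), total brain
   volume (TBV) from the brain mask, and group percentage contrasts.

## The phantom: a stated world

No real data ship with the package; every downstream stage is tested
against a seeded synthetic cohort whose ground truth is known
analytically. The phantom's defaults encode the study conditions the
pipeline is designed around:

* three groups — 8 wild-type (WT), 10 untreated transgenic (TG), 7
  treated transgenic (TG_DOX);
* paired modalities — in vivo at 150 μm isotropic and ex vivo at 40 μm
  (the test-suite profile coarsens the ex vivo grid to keep runtimes
  sane; nothing else changes);
* TG brains 21% smaller in TBV than WT and 16% smaller than TG_DOX,
  with 25% local volume loss imposed in cortex, hippocampus, caudate
  putamen and hypothalamus (10%, in a cortex/hippocampus/caudate
  subset, for TG_DOX);
* ex vivo scans 10% smaller in TBV than their in vivo pair, with up to
  0.5 mm of extra brainstem/olfactory displacement, emulating
  fixation and decapitation effects on an in-skull preparation;
* ventricular expansion in the transgenics in vivo, damped ex vivo
  (fixation collapses the ventricular space). The paper-world gives no
  magnitude for this, so the default (30% in vivo, 10% ex vivo) is a
  free parameter of the phantom and is not claimed to match any study;
* per-region tissue intensities chosen so that mean/noise reproduces
  the reference SNR table (in vivo SNR higher in 7 of 9 regions,
  ex vivo higher in the cerebellum; ex vivo gray–white CNR several-fold
  larger, and *negative* CNR in vivo, where white matter is brighter on
  T2-weighted contrast).

### Geometry and deformation model

The template brain is a set of nested ellipsoidal regions (12 labels
plus background) with piecewise-constant tissue means, a 5% smooth
sinusoidal intra-region texture at ~0.5 mm period, a thin bright
extra-cranial rind (intensity only, labelled background) to exercise
masking, and a corner noise ROI. The texture matters: real MRI has
intra-tissue contrast, and without it non-rigid registration has no
information in region interiors.

Each subject is produced by composing analytic forward maps, template →
subject:

* a random smooth subject warp (mixture of 10 Gaussian displacement
  bumps, SD 0.05 mm), shared between a subject's two modalities — the
  same animal is scanned twice;
* group atrophy: compact Gaussian-windowed radial contractions of the
  target regions plus a one-sided "cortical thinning" step at the outer
  shell (so the white matter beneath is translated, not compressed),
  plus ventricular expansion;
* ex vivo preparation: a uniform scale with det exactly
  1 − shrinkage about the brain centre, plus Gaussian displacement
  bumps at the brainstem and olfactory bulb.

Because every primitive is analytic, the exact Jacobian determinant of
the composed map is available (central differences at 10⁻³ mm on fields
that vary over ~1 mm — exact for all practical purposes), and the exact
pull-back used to render each subject is returned as its ground-truth
displacement field.

**Calibration is part of the stated world.** The contraction amplitudes
are solved (damped coordinate descent with `uniroot`) so that the
*composed* group field's det J integrates to 1 − f over each target
region within 0.5%; the global scale of each transgenic group is then
set in closed form so the measured TBV contrast equals the configured
21% (TG) and ~6% (TG_DOX). The ex vivo distortion bumps sit at the
brain boundary and are not volume-neutral, so a small compensating
scale keeps the measured ex vivo TBV reduction at exactly the
configured 10% while the named shrink primitive keeps det = 0.90.

### What a green test does not establish

The phantom has sharp piecewise-constant contrast, Gaussian (not
Rician) noise, no motion, no susceptibility or bias artefacts beyond
what the tests inject, no skull/extra-cranial anatomy beyond a thin
rind, and subject variability far smoother than real anatomical
variation. Green tests establish that the *pipeline machinery* is
correct and that effects of the designed magnitude are recoverable in
this regime — not that the pipeline would perform identically on real
mouse MRI.

## Numerical choices

* **NIfTI-1 I/O** is implemented in the package (sform-based geometry,
  gzip, float/int types); no R NIfTI reader is available in the target
  environment. The writer/reader round-trips bit-exactly and was
  checked against nibabel.
* **Bias correction** is a log-domain low-order polynomial fit (degree
  from the smoothness scale; linear at the default 3 mm). When the mask
  is a label map, per-region intensity indicators enter the regression,
  unified-segmentation style: without them, genuine anatomy with
  low-order spatial structure (the phantom's anterior-posterior
  contrast gradient) leaks into the bias estimate and the corrected
  image misses the 3% recovery contract. Full N4 (B-spline-smoothed
  histogram sharpening) is intentionally not reimplemented.
* **Standardization** uses landmarks {1st percentile, deciles 10–90,
  99th}, anchored to [0, 100]; the standard scale is the mean anchored
  landmark vector. Landmarks are type-1 (inverse-ECDF) quantiles, which
  commute with monotone transforms — this makes re-standardizing an
  already standardized image *exactly* the identity, not approximately.
  Fitted per modality by default.
* **Mask fusion** registers each atlas affinely and fuses by global
  majority vote (ties → foreground), then keeps the largest 6-connected
  component. Locally-ranked fusion adds no testable behaviour with a
  handful of synthetic atlases.
* **Linear registration** directly optimizes NCC (Nelder–Mead over a
  2–3 level pyramid, BFGS polish on a strided view). Block matching is
  replaced by continuous optimization of the same similarity: the
  contract — a local optimum of NCC, never worse than the
  initialization — is preserved with far less machinery.
* **Non-rigid registration** maximizes Studholme NMI
  ((H_f + H_m)/H_joint, 64 bins, cubic Parzen window on the moving
  intensities) by gradient ascent with the analytic gradient with
  respect to the B-spline coefficients, an adaptive step, and a small
  bending-energy penalty (second differences of the coefficient grid,
  weight 0.001). Two numerical traps required explicit treatment:
  (1) *grid-aligned interpolation artefacts* — on matching grids NMI
  has a spurious maximum at the identity that traps sub-voxel
  deformations; both images are pre-smoothed (0.7 voxel) before
  histogramming, and a scale-space schedule (smoothing 2.2 → 1.2 → 0.7
  voxels, control spacing 2× then 1×) is used for cold starts;
  (2) *domain-boundary discontinuities* — voxels entering/leaving the
  moving image's domain make the similarity discontinuous, so the
  evaluation voxel set is frozen to those mapping well inside the
  moving grid under the linear pre-alignment.
  "Symmetric" free-form deformation is approximated only in testing
  (swapped-role inverse-consistency checks); no symmetric penalty is
  on by default, since no parameters are stated for it.
* **Jacobians** of the B-spline part are analytic (tensor-product
  basis derivatives), not finite differences; an affine contributes
  log |det M| exactly. Voxels with det ≤ 0 are set to NaN and excluded
  from the statistical family rather than clamped; more than 0.1%
  folded voxels inside the mask is an error.
* **Composite vs non-rigid-only Jacobians**: group TBV differences are
  part of the morphometry, so the composite (affine included) is the
  default for statistics; `nonrigid_only` is available. MPD, by
  definition, uses non-rigid components only and rejects fields
  carrying global parts.
* **FDR** is the independence BH step-up (the dependence-robust variant
  is a flag). Degenerate voxels (zero variance, folded Jacobian) are
  excluded from the family so m stays well defined.
* **z-quantiles** in the power map are the conventional two-decimal
  values (1.96, 0.84 at the defaults), matching how such calculations
  are reported.
* **Configuration files** are JSON (the target environment has no YAML
  reader); the structure is identical to what a YAML interface would
  carry.

## Design decisions on genuinely open points

* The interpolation order for resampling during registration is not
  stated in the source methodology; trilinear is used (nearest for
  labels).
* Whether standardization was fitted per modality or jointly is
  unstated; per modality is the default, with the training set under
  the caller's control.
* Whether the affine was included in the published Jacobian analyses,
  the NMI bin count, and the bending weight are all unstated; they are
  configuration with the defaults above, without any claim of fidelity
  to the original implementation's settings.
* The acceptance fixture for parameter recovery imposes a *single*
  calibrated 25% hippocampal contraction (n = 6/group) — the stated
  detectable effect in its cleanest form. With the full four-region
  transgenic phantom, recovery is accurate in the hippocampus and
  caudate but weaker in the cortex (a thin shell whose compression is
  at the limit of a 4-voxel control grid) and hypothalamus (nearly
  isointense with the midbrain, so its boundary is almost invisible to
  the similarity) — the same low-contrast registration failure mode the
  TBM literature reports on real data. Multi-region detection is tested
  by FDR-cluster overlap instead of det-value recovery.

## Known limitations

* Non-rigid recovery of localized displacement is partial: roughly half
  of the 0.38 mm ground-truth non-rigid residual of the ex vivo
  brainstem distortion is recovered at desk scale. The MPD criterion
  therefore asserts the hand-computed cases and the qualitative
  brainstem ≫ cortex ordering, not absolute displacement magnitudes.
* The registration is not diffeomorphic; invertibility is monitored
  (det J flagging) rather than enforced.
* Runtime: the deployment-scale profile (20 NRR iterations, 40 μm
  ex vivo grids) is hours on one CPU; tests and the acceptance report
  use documented reduced profiles (fewer iterations, coarser ex vivo
  spacing), which change no statistical parameter.
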