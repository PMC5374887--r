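# tbmpipe

Tensor-based morphometry (TBM) for three-dimensional structural MRI of
the mouse brain, with a fully synthetic, seeded phantom cohort standing
in for real paired in vivo / ex vivo scans.

## The scientific problem

Transgenic mouse models of neurodegeneration (for example tau-
overexpressing lines with forebrain atrophy) are phenotyped by asking
*where* their brains differ locally in volume from wild-type controls.
TBM answers this without pre-specifying regions: all subjects are
brought into a common average space by group-wise registration, and the
Jacobian determinant of each subject's deformation measures local
volume relative to the group average,

    log J(y) = log det D[T_subject](y),   T(y) = A(y + u(y)),

with `log J > 0` where the subject is locally larger. Voxelwise
two-tailed t-tests on smoothed log-J maps (FDR-corrected, q = 0.05)
localize group differences; Cohen's d (pooled SD) and the per-voxel
sample size

    N_arm = ceil( 2 (Z_a/2 + Z_1-b)^2 sd_WT^2 / 0.25^2 ),
    Z_0.975 = 1.96, Z_0.8 = 0.84

inform future study design for detecting a 25% local volume effect.
The package also quantifies the in vivo / ex vivo trade-off: ROI
signal-to-noise (SNR = mean signal / background SD), gray–white
contrast-to-noise (CNR), total brain volume (TBV) shrinkage from
fixation, and mean positional distance (MPD) maps of the non-rigid
tissue distortion between a subject's ex vivo and in vivo scans.

It is aimed at preclinical imaging methodologists: every stage —
NIfTI-1 I/O, bias correction, piecewise-linear intensity
standardization, multi-atlas masking, NCC affine and NMI B-spline
non-rigid registration, the group-wise average loop, Jacobian/MPD maps,
and the statistical layer — is exposed as a documented R function, and
the phantom generator provides analytic ground truth to validate all of
it without downloading any data.

## A worked example

```r
library(tbmpipe)

# a desk-scale phantom cohort: 3 groups, known ground truth
spec <- phantom_spec(spacing_exvivo = 0.12,
                     n_per_group = c(WT = 4L, TG = 4L, TG_DOX = 4L))
cohort <- synthesize_cohort(spec, "cohort_dir", modalities = "invivo")

# quality metrics
qc <- quality_report(cohort)
subset(qc$snr, region == "hippocampus" & subject_id == "WT_01")$snr
#> [1] 18.402          # design target 19.3, within sampling error

# end-to-end TBM: TG vs WT
res <- tbm_compare(cohort, c("TG", "WT"), "invivo",
                   n_affine = 2, n_nrr = 4, seed = 1,
                   out_dir = "tbm_out")
sum(res$stats$fdr_mask)        # FDR-significant voxels
range(res$power$n_arm[res$mask])

# the number the pipeline must recover: imposed 25% contraction
rec <- tbmpipe:::recovery_experiment(seed = 1)
rec$recovered_det
#> [1] 0.7709432       # true value 0.75, tolerance 0.05
```

The last number is the region-mean Jacobian determinant contrast
(TG relative to WT) recovered by the full pipeline for a calibrated
25% hippocampal contraction — i.e. the pipeline recovers a 22.9% local
volume loss where 25% was imposed.

Command-line use (after install):

```sh
Rscript -e 'tbmpipe::tbm_cli()' all --out results --seed 42 --profile smoke
```

## Layout

- `R/` — implementation (containers + NIfTI I/O, phantom, preprocess,
  registration, statistics, quality, pipeline/CLI).
- `src/` — Rcpp kernels: trilinear sampling, B-spline FFD evaluation
  and analytic Jacobian, NMI value + analytic gradient.
- `vignettes/tbm-methods.Rmd` — models, phantom design, numerical
  choices and limitations.
- `scripts/acceptance.R` — the acceptance report.
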