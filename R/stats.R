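# Voxelwise statistics on log-Jacobian maps: Gaussian smoothing,
# two-sample t maps, FDR control, Cohen's d and per-voxel sample size.

#' Statistical configuration for TBM
#'
#' Defaults mirror the analysis conditions the pipeline is built around:
#' 0.2 mm FWHM smoothing of the log-Jacobian maps, FDR q = 0.05, and a
#' power analysis at alpha = 0.05, beta = 0.2 for a 25% local volume
#' effect. `z_alpha_half` and `z_one_minus_beta` are the conventional
#' two-decimal normal quantiles (1.96 and 0.84 at the defaults).
#'
#' @param fwhm_mm Gaussian smoothing FWHM in mm.
#' @param q FDR level.
#' @param alpha significance level.
#' @param beta type-II error rate.
#' @param effect_fraction detectable local volume difference (of log J).
#' @param jacobian_source "composite" (affine included) or
#'   "nonrigid_only".
#' @export
stat_config <- function(fwhm_mm = 0.2, q = 0.05, alpha = 0.05, beta = 0.2,
                        effect_fraction = 0.25,
                        jacobian_source = c("composite", "nonrigid_only")) {
  jacobian_source <- match.arg(jacobian_source)
  stopifnot(fwhm_mm > 0, q > 0, q < 1, alpha > 0, alpha < 1,
            beta > 0, beta < 1, effect_fraction > 0, effect_fraction < 1)
  structure(list(fwhm_mm = fwhm_mm, q = q, alpha = alpha, beta = beta,
                 effect_fraction = effect_fraction,
                 jacobian_source = jacobian_source,
                 z_alpha_half = round(qnorm(1 - alpha / 2), 2),
                 z_one_minus_beta = round(qnorm(1 - beta), 2)),
            class = "stat_config")
}

#' Smooth a Jacobian map with a Gaussian kernel
#'
#' FWHM is given in mm and converted per axis to voxels via the map's
#' spacing (sigma = FWHM / (2 sqrt(2 ln 2))). Smoothing is renormalized
#' over the mask (non-finite voxels are excluded), so a constant map stays
#' constant. A FWHM below half a voxel triggers a warning and a no-op.
#'
#' @param m a `jacobian_map` (or plain `tbm_volume`).
#' @param fwhm_mm kernel FWHM, mm.
#' @param mask optional logical array restricting the support.
#' @export
smooth_map <- function(m, fwhm_mm, mask = NULL) {
  arr <- if (inherits(m, "jacobian_map")) m$log_jdet else vol_data(m)
  if (fwhm_mm < min(m$spacing) / 2) {
    warning("FWHM below half a voxel; smoothing skipped")
    return(m)
  }
  sig_vox <- fwhm_to_sigma(fwhm_mm) / m$spacing
  ok <- is.finite(arr)
  if (!is.null(mask)) ok <- ok & mask
  work <- arr
  work[!ok] <- 0
  sm <- smooth_masked(work, ok, sig_vox)
  out <- arr
  out[ok] <- sm[ok]
  if (inherits(m, "jacobian_map")) {
    m$log_jdet <- out
    m
  } else {
    tbm_volume(out, spacing = m$spacing, affine = m$affine)
  }
}

jm_array <- function(x) {
  if (inherits(x, "jacobian_map")) x$log_jdet
  else if (inherits(x, "tbm_volume")) x$data
  else as.array(x)
}

stack_maps <- function(maps) {
  mats <- lapply(maps, function(m) as.vector(jm_array(m)))
  do.call(cbind, mats)
}

#' Voxelwise two-sample t-test
#'
#' Pooled-variance two-tailed t-test at each voxel of the (smoothed)
#' log-Jacobian maps, df = N_A + N_B - 2; equivalent to the two-group
#' general linear model with an intercept and a group indicator. Voxels
#' with zero pooled variance, or any non-finite subject value, are flagged
#' and get t = 0, p = 1; flagged voxels are excluded from the
#' multiple-testing family by [fdr_correct()].
#'
#' @param jmaps_A,jmaps_B lists of `jacobian_map`s (>= 2 each), one per
#'   subject, in a common average space.
#' @param mask logical array (or `tbm_labelmap`) of analysis voxels.
#' @return object of class `stat_maps`: `t_map`, `p_map`, `direction`
#'   (sign of mean(A) - mean(B)), `df`, `mask`, `flagged`, geometry.
#' @export
voxelwise_ttest <- function(jmaps_A, jmaps_B, mask) {
  nA <- length(jmaps_A); nB <- length(jmaps_B)
  if (nA < 2 || nB < 2) stop("need >= 2 subjects per group")
  g <- jmaps_A[[1]]
  dims <- dim(jm_array(g))
  m <- as_mask_array(mask, dims)
  XA <- stack_maps(jmaps_A)
  XB <- stack_maps(jmaps_B)
  mA <- rowMeans(XA); mB <- rowMeans(XB)
  vA <- rowSums((XA - mA)^2) / (nA - 1)
  vB <- rowSums((XB - mB)^2) / (nB - 1)
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / df
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tt <- (mA - mB) / se
  flagged <- !is.finite(tt)
  tt[flagged] <- 0
  pp <- 2 * pt(-abs(tt), df)
  pp[flagged] <- 1
  structure(list(t_map = array(tt, dims), p_map = array(pp, dims),
                 direction = array(sign(mA - mB), dims), df = df,
                 mask = m, flagged = array(flagged, dims),
                 spacing = g$spacing, affine = g$affine),
            class = "stat_maps")
}

#' @export
print.stat_maps <- function(x, ...) {
  cat(sprintf("<stat_maps df=%d, %d mask voxels%s>\n", x$df, sum(x$mask),
              if (!is.null(x$fdr_mask))
                sprintf(", %d FDR-significant", sum(x$fdr_mask)) else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction over a mask
#'
#' Step-up rule under independence: order the m masked p-values, find
#' k* = max{k : p(k) <= k q / m}, reject all p <= p(k*). The
#' dependence-robust variant divides q by sum(1/i). Flagged (degenerate)
#' voxels are excluded from the family.
#'
#' @param stats a `stat_maps` from [voxelwise_ttest()] (or a bare p-value
#'   array).
#' @param q FDR level.
#' @param mask analysis mask (defaults to the one in `stats`).
#' @param dependent use the dependence-robust variant.
#' @return `stat_maps` with `fdr_mask` (logical) and `p_threshold` filled
#'   in (or, for a bare array input, the logical rejection array).
#' @export
fdr_correct <- function(stats, q = 0.05, mask = NULL, dependent = FALSE) {
  bare <- !inherits(stats, "stat_maps")
  p <- if (bare) as.array(stats) else stats$p_map
  if (is.null(mask)) {
    if (bare) stop("a mask is required for a bare p-value array")
    mask <- stats$mask & !stats$flagged
  } else {
    mask <- as_mask_array(mask, dim(p))
    if (!bare) mask <- mask & !stats$flagged
  }
  if (!any(mask)) stop("empty mask")
  pv <- p[mask]
  m <- length(pv)
  qeff <- if (dependent) q / sum(1 / seq_len(m)) else q
  o <- sort(pv)
  ks <- which(o <= seq_len(m) * qeff / m)
  thr <- if (length(ks)) o[max(ks)] else -Inf
  rej <- array(FALSE, dim(p))
  rej[mask] <- pv <= thr
  if (bare) return(rej)
  stats$fdr_mask <- rej
  stats$p_threshold <- if (is.finite(thr)) thr else NA_real_
  stats
}

#' Cohen's d effect-size maps with pooled standard deviation
#'
#' d = (mean(UT) - mean(WT)) / sigma_pooled per voxel, with
#' sigma_pooled^2 = ((N_WT - 1) sd_WT^2 + (N_UT - 1) sd_UT^2) /
#' (N_WT + N_UT - 2). Zero pooled SD flags the voxel (d = NaN).
#'
#' @param jmaps_UT,jmaps_WT per-subject smoothed log-Jacobian maps.
#' @param cfg a [stat_config()].
#' @return object of class `power_maps`: `cohens_d`, `pooled_stdev`,
#'   `wt_stdev`, `n_arm`, z constants, geometry.
#' @export
effect_size_maps <- function(jmaps_UT, jmaps_WT, cfg = stat_config()) {
  if (length(jmaps_UT) < 2 || length(jmaps_WT) < 2)
    stop("need >= 2 subjects per group")
  g <- jmaps_WT[[1]]
  dims <- dim(jm_array(g))
  XU <- stack_maps(jmaps_UT); XW <- stack_maps(jmaps_WT)
  nU <- ncol(XU); nW <- ncol(XW)
  mU <- rowMeans(XU); mW <- rowMeans(XW)
  vU <- rowSums((XU - mU)^2) / (nU - 1)
  vW <- rowSums((XW - mW)^2) / (nW - 1)
  sp <- sqrt(((nW - 1) * vW + (nU - 1) * vU) / (nW + nU - 2))
  d <- (mU - mW) / sp
  d[sp == 0] <- NaN
  wt_sd <- sqrt(vW)
  narm <- n_arm_from_sd(wt_sd, cfg)
  structure(list(cohens_d = array(d, dims),
                 pooled_stdev = array(sp, dims),
                 wt_stdev = array(wt_sd, dims),
                 n_arm = narm$n_arm_map(dims),
                 degenerate = narm$degenerate_map(dims),
                 z_alpha_half = cfg$z_alpha_half,
                 z_one_minus_beta = cfg$z_one_minus_beta,
                 spacing = g$spacing, affine = g$affine),
            class = "power_maps")
}

n_arm_from_sd <- function(wt_sd, cfg) {
  if (cfg$effect_fraction <= 0) stop("effect_fraction must be positive")
  zz <- (cfg$z_alpha_half + cfg$z_one_minus_beta)^2
  raw <- 2 * zz * wt_sd^2 / cfg$effect_fraction^2
  n <- ceiling(raw)
  degen <- wt_sd == 0 | !is.finite(wt_sd)
  n[n < 2] <- 2L   # a two-sample comparison needs at least 2 per arm
  n[!is.finite(wt_sd)] <- NA_integer_
  list(n_arm_map = function(dims) array(as.integer(n), dims),
       degenerate_map = function(dims) array(degen, dims))
}

#' Per-voxel sample size map
#'
#' N_arm = ceiling(2 (Z_{alpha/2} + Z_{1-beta})^2 sd_WT^2 / effect^2),
#' the animals per study arm needed to detect the configured fractional
#' volume effect at each voxel, rounded up. Voxels with zero WT variance
#' are degenerate and reported at the floor of 2.
#'
#' @param jmaps_WT per-subject WT log-Jacobian maps (>= 2).
#' @param cfg a [stat_config()].
#' @return `power_maps` with `n_arm`, `wt_stdev`, `degenerate`.
#' @export
sample_size_map <- function(jmaps_WT, cfg = stat_config()) {
  if (length(jmaps_WT) < 2) stop("need >= 2 WT subjects")
  g <- jmaps_WT[[1]]
  dims <- dim(jm_array(g))
  XW <- stack_maps(jmaps_WT)
  wt_sd <- sqrt(rowSums((XW - rowMeans(XW))^2) / (ncol(XW) - 1))
  narm <- n_arm_from_sd(wt_sd, cfg)
  structure(list(n_arm = narm$n_arm_map(dims),
                 wt_stdev = array(wt_sd, dims),
                 degenerate = narm$degenerate_map(dims),
                 z_alpha_half = cfg$z_alpha_half,
                 z_one_minus_beta = cfg$z_one_minus_beta,
                 spacing = g$spacing, affine = g$affine),
            class = "power_maps")
}

#' End-to-end TBM group comparison
#'
#' Runs the full chain on one modality of a cohort: group-wise
#' registration of both groups pooled, per-subject log-Jacobian maps in
#' average space, 0.2 mm FWHM smoothing, voxelwise two-tailed t-tests,
#' FDR correction, and Cohen's d / N_arm maps (group A in the UT role,
#' group B in the WT/reference role). The analysis mask is the majority
#' vote of the subjects' brain masks warped into average space.
#'
#' @param manifest a `cohort_manifest`.
#' @param groups length-2 character: (A, B), compared as A - B.
#' @param modality "invivo" or "exvivo".
#' @param cfg a [stat_config()].
#' @param legend label-map legend of the cohort.
#' @param n_affine,n_nrr,control_spacing_vox,seed registration schedule.
#' @param out_dir if non-NULL, all maps are written there as NIfTI.
#' @param ... passed to [groupwise_register()].
#' @return list: `stats` (`stat_maps`), `power` (`power_maps`),
#'   `groupwise`, `jmaps` (per subject), `mask`, `groups`.
#' @export
tbm_compare <- function(manifest, groups, modality, cfg = stat_config(),
                        legend = c(background = 0L, PHANTOM_REGIONS),
                        n_affine = 4L, n_nrr = 20L,
                        control_spacing_vox = 4L, seed = 1L,
                        out_dir = NULL, ...) {
  rows <- which(manifest$modality == modality &
                manifest$group %in% groups)
  if (length(rows) == 0) stop("no subjects for modality ", modality)
  grp <- manifest$group[rows]
  if (any(table(factor(grp, levels = groups)) < 3))
    stop("need >= 3 subjects per group for ", modality)
  subjects <- lapply(rows, function(i) load_subject(manifest, i, legend))
  images <- lapply(subjects, `[[`, "volume")

  gw <- groupwise_register(images, n_affine = n_affine, n_nrr = n_nrr,
                           seed = seed,
                           control_spacing_vox = control_spacing_vox, ...)
  avg <- gw$average_image

  # analysis mask: majority vote of warped subject brain masks
  votes <- array(0L, vol_dim(avg))
  for (i in seq_along(subjects)) {
    tr <- gw$transforms[[i]]
    lm <- subjects[[i]]$labels
    mv <- tbm_volume(array(as.double(brain_mask(lm)), vol_dim(lm)),
                     spacing = lm$spacing, affine = lm$affine)
    w <- resample_composite(mv, avg, tr$affine, tr$bspline,
                            interpolation = "nearest")
    votes <- votes + as.integer(vol_data(w) > 0.5)
  }
  mask <- votes * 2L >= length(subjects)

  jmaps <- lapply(seq_along(subjects), function(i) {
    jm <- jacobian_log_det(gw$transforms[[i]], reference = avg,
                           source = cfg$jacobian_source, mask = mask)
    smooth_map(jm, cfg$fwhm_mm, mask = mask)
  })
  ja <- jmaps[grp == groups[1]]
  jb <- jmaps[grp == groups[2]]
  stats <- voxelwise_ttest(ja, jb, mask)
  stats <- fdr_correct(stats, q = cfg$q)
  power <- effect_size_maps(ja, jb, cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wv <- function(arr, nm)
      write_nifti(tbm_volume(array(as.double(arr), vol_dim(avg)),
                             spacing = avg$spacing, affine = avg$affine),
                  file.path(out_dir, paste0(nm, ".nii.gz")))
    wv(avg$data, "average")
    wv(stats$t_map, "tstat")
    wv(stats$p_map, "pval")
    wv(stats$fdr_mask, "fdr_mask")
    # signed thresholded t map: negative where group A is locally smaller
    tsig <- stats$t_map * stats$fdr_mask
    wv(tsig, "tstat_fdr_thresholded")
    wv(power$cohens_d, "cohens_d")
    wv(power$n_arm, "n_arm")
    wv(mask, "analysis_mask")
  }
  list(stats = stats, power = power, groupwise = gw, jmaps = jmaps,
       mask = mask, groups = groups, grp = grp)
}
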