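# Acceptance experiments: self-contained, seeded end-to-end computations
# shared between the test suite and scripts/acceptance.R. Each builds its
# phantom cohort from scratch, runs the pipeline stages, and measures the
# quantity of interest.

# Criterion 4: a cohort whose only group effect is a single calibrated
# 25% contraction of the hippocampus; full group-wise TBM; recovered
# region-mean det J of the smoothed composite log-Jacobian difference.
recovery_experiment <- function(seed, n_per_group = 6L, n_affine = 2L,
                                n_nrr = 6L, nrr_steps = 25L,
                                fwhm_mm = 0.2) {
  spec <- phantom_spec(tbv_contrast_TG = NA_real_,
                       ventricle_expansion = c(invivo = 0, exvivo = 0),
                       atrophy_targets_TG = "hippocampus",
                       n_per_group = c(WT = n_per_group, TG = n_per_group,
                                       TG_DOX = 2L),
                       seed = 42L + seed %% 10000L)
  calib <- phantom_calibration(spec)
  n <- n_per_group
  subs <- c(lapply(seq_len(n), function(i)
              synthesize_subject(spec, "TG", "invivo", i, calib)),
            lapply(seq_len(n), function(i)
              synthesize_subject(spec, "WT", "invivo", i, calib)))
  gw <- groupwise_register(lapply(subs, `[[`, "volume"),
                           n_affine = n_affine, n_nrr = n_nrr,
                           seed = seed, nrr_steps = nrr_steps)
  avg <- gw$average_image
  jm <- lapply(seq_len(2 * n), function(i)
    smooth_map(jacobian_log_det(gw$transforms[[i]], reference = avg,
                                source = "composite"), fwhm_mm))
  grid <- world_grid(avg)
  lab <- phantom_labels_at(spec, grid)
  geom <- phantom_geometry(spec)
  r <- geom$regions$hippocampus
  core <- array(lab == PHANTOM_REGIONS[["hippocampus"]] &
                  (ell_rho2(grid, r$c, r$s) <= 1 |
                   ell_rho2(grid, r$c * c(-1, 1, 1), r$s) <= 1),
                vol_dim(avg))
  m_tg <- mean(vapply(seq_len(n), function(i)
    mean(jm[[i]]$log_jdet[core], na.rm = TRUE), numeric(1)))
  m_wt <- mean(vapply(n + seq_len(n), function(i)
    mean(jm[[i]]$log_jdet[core], na.rm = TRUE), numeric(1)))

  # detection: FDR-significant contraction clusters vs the analytic
  # ground-truth atrophy footprint (true composed det J < 0.9)
  brain <- lab >= 1L & lab <= 11L
  mask <- array(brain, vol_dim(avg))
  st <- fdr_correct(voxelwise_ttest(jm[seq_len(n)], jm[n + seq_len(n)],
                                    mask), q = 0.05)
  tg_prims <- calib[["TG.invivo"]]$prims
  truth_det <- rep(1, nrow(grid))
  if (length(tg_prims) > 1)
    truth_det[brain] <- phantom_forward_det(
      tg_prims[seq_len(length(tg_prims) - 1L)],
      grid[brain, , drop = FALSE])
  truth <- array(truth_det < 0.9, vol_dim(avg)) & mask
  sig_smaller <- st$fdr_mask & st$direction < 0
  truth_dil <- truth
  for (rep2 in 1:2) truth_dil <- dilate6(truth_dil)
  outside <- mask & !truth_dil
  list(recovered_det = exp(m_tg - m_wt), imposed_det = 0.75,
       n_voxels = sum(core),
       dice_detection = dice(sig_smaller, truth),
       purity = 1 - sum(sig_smaller & outside) / max(sum(outside), 1),
       n_significant = sum(st$fdr_mask))
}

# Criterion 5: null phantom (WT subjects split into two arms) through
# registration, Jacobians, smoothing, t-tests and FDR; the false
# discovery proportion is 1 whenever anything is rejected (every
# discovery is false under the null).
null_fdp_experiment <- function(seed, n_replicates = 20L, n_per_arm = 3L,
                                q = 0.05) {
  fdp <- numeric(n_replicates)
  rejections <- integer(n_replicates)
  for (r in seq_len(n_replicates)) {
    spec <- phantom_spec(grid_shape = c(22, 22, 22),
                         spacing_invivo = 0.4, spacing_exvivo = 0.4,
                         n_per_group = c(WT = 2L * n_per_arm, TG = 1L,
                                         TG_DOX = 1L),
                         seed = (seed * 1013L + r * 7L) %% 1000003L)
    calib <- phantom_calibration(spec)
    subs <- lapply(seq_len(2 * n_per_arm), function(i)
      synthesize_subject(spec, "WT", "invivo", i, calib))
    gw <- groupwise_register(lapply(subs, `[[`, "volume"),
                             n_affine = 1L, n_nrr = 1L,
                             seed = seed + r, nrr_steps = 4L,
                             linear_maxit = c(100L, 60L, 50L),
                             linear_polish = 4L)
    avg <- gw$average_image
    votes <- array(0L, vol_dim(avg))
    for (i in seq_along(subs)) {
      lm <- subs[[i]]$labels
      mv <- tbm_volume(array(as.double(brain_mask(lm)), vol_dim(lm)),
                       spacing = lm$spacing, affine = lm$affine)
      w <- resample_composite(mv, avg, gw$transforms[[i]]$affine,
                              gw$transforms[[i]]$bspline,
                              interpolation = "nearest")
      votes <- votes + as.integer(vol_data(w) > 0.5)
    }
    mask <- votes * 2L >= length(subs)
    jm <- lapply(seq_along(subs), function(i)
      smooth_map(jacobian_log_det(gw$transforms[[i]], reference = avg,
                                  source = "composite"), 0.2))
    st <- voxelwise_ttest(jm[seq_len(n_per_arm)],
                          jm[n_per_arm + seq_len(n_per_arm)], mask)
    st <- fdr_correct(st, q = q)
    rejections[r] <- sum(st$fdr_mask)
    fdp[r] <- as.numeric(rejections[r] > 0)
  }
  list(fdp = fdp, rejections = rejections)
}

# Criterion 7: paired ex vivo -> in vivo registration of phantom
# subjects; mean positional distance of the non-rigid residuals by
# anatomical region.
mpd_experiment <- function(seed, n_subjects = 2L, nrr_steps = 25L,
                           spacing_exvivo = 0.12) {
  spec <- phantom_spec(spacing_exvivo = spacing_exvivo,
                       n_per_group = c(WT = n_subjects, TG = 1L,
                                       TG_DOX = 1L),
                       seed = 42L + seed %% 10000L)
  calib <- phantom_calibration(spec)
  fields <- list(); reference <- NULL
  for (i in seq_len(n_subjects)) {
    iv <- synthesize_subject(spec, "WT", "invivo", i, calib)
    ev <- synthesize_subject(spec, "WT", "exvivo", i, calib)
    if (is.null(reference)) reference <- iv$volume
    A <- register_linear(ev$volume, iv$volume, dof_class = "affine")
    nrr <- register_nonrigid(ev$volume, iv$volume, init_affine = A,
                             max_steps = nrr_steps)
    fields[[i]] <- nonrigid_field(nrr)
  }
  mpd <- mean_positional_distance(fields, reference)
  tpl <- build_template(spec, "invivo")
  bs <- tpl$labels$labels == PHANTOM_REGIONS[["brainstem"]]
  cx <- tpl$labels$labels == PHANTOM_REGIONS[["cortex"]]
  list(mpd = mpd,
       brainstem_mean = mean(mpd$mpd[bs]),
       cortex_mean = mean(mpd$mpd[cx]),
       brainstem_peak = max(mpd$mpd[bs]))
}

# Criterion 8: measured TBV calibration of the default phantom world.
tbv_calibration_experiment <- function(seed, n_subjects = 6L,
                                       spacing_exvivo = 0.12) {
  spec <- phantom_spec(spacing_exvivo = spacing_exvivo,
                       seed = 42L + seed %% 10000L)
  calib <- phantom_calibration(spec)
  tb <- function(grp, mod) vapply(seq_len(n_subjects), function(i)
    synthesize_subject(spec, grp, mod, i, calib)$true_tbv, numeric(1))
  wt_iv <- tb("WT", "invivo")
  wt_ev <- tb("WT", "exvivo")
  tg_iv <- tb("TG", "invivo")
  list(exvivo_invivo_ratio = mean(wt_ev / wt_iv),
       tg_wt_contrast_pct = 100 * (1 - mean(tg_iv) / mean(wt_iv)),
       wt_mean_tbv = mean(wt_iv))
}
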