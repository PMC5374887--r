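# Synthetic in vivo / ex vivo mouse-brain phantom cohorts.
#
# The phantom is a stated world: a canonical "brain" of nested ellipsoidal
# regions, deformed per subject by an analytic chain of smooth maps
# (random subject warp -> group atrophy / ventricle change -> global
# fixation shrinkage + regional ex vivo distortion) and corrupted by
# additive Gaussian noise. Every map is analytic, so the ground-truth
# Jacobian determinant the morphometry must recover is available to
# machine precision via high-order finite differences of the analytic
# forward map (step 1e-3 mm on fields that vary over ~1 mm).

PHANTOM_GROUPS <- c("WT", "TG", "TG_DOX")
PHANTOM_MODALITIES <- c("invivo", "exvivo")

PHANTOM_REGIONS <- c(cortex = 1L, corpus_callosum = 2L, hippocampus = 3L,
                     caudate_putamen = 4L, thalamus = 5L, hypothalamus = 6L,
                     midbrain = 7L, cerebellum = 8L, olfactory_bulb = 9L,
                     brainstem = 10L, ventricles = 11L, noise = 12L)

#' Phantom cohort specification
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' group sizes 8 WT / 10 TG / 7 TG_DOX, 25% local volume loss in the TG
#' forebrain target regions (10% in the treated group, restricted to
#' cortex/hippocampus/caudate), a 21% total-brain-volume deficit in TG
#' (TG 16% smaller than TG_DOX), 10% global ex vivo shrinkage, up to
#' 0.5 mm ex vivo brainstem/olfactory distortion, and per-region tissue
#' intensities calibrated so mean/noise reproduces the reference SNR table
#' (in vivo higher SNR in 7 of 9 regions, ex vivo higher in cerebellum;
#' ex vivo gray-white CNR several-fold larger).
#'
#' @param grid_shape voxels per axis of the in vivo grid.
#' @param spacing_invivo,spacing_exvivo isotropic voxel size, mm.
#' @param n_per_group named integer vector (WT, TG, TG_DOX).
#' @param atrophy_fraction_TG,atrophy_fraction_TGDOX fractional local
#'   volume loss imposed in each group's target regions.
#' @param tbv_contrast_TG,tbv_contrast_TGDOX fractional total-brain-volume
#'   deficit of each transgenic group relative to WT.
#' @param exvivo_volume_shrinkage fractional TBV loss from fixation.
#' @param exvivo_extra_distortion_mm peak brainstem displacement, mm.
#' @param ventricle_expansion named (invivo, exvivo) fractional ventricular
#'   volume gain in TG; damped ex vivo (fixation collapses the ventricles).
#'   The magnitude is a free parameter of the phantom, not a study value.
#' @param tissue_means list with `invivo` and `exvivo` named vectors of
#'   region mean intensities (plus `rind`, the bright extra-cranial shell).
#' @param noise_sd named (invivo, exvivo) additive Gaussian noise SD.
#' @param subject_variability_sd SD of random smooth per-subject warps, mm.
#' @param atrophy_targets_TG optional character vector overriding the TG
#'   group's atrophy target regions (default cortex, hippocampus,
#'   caudate putamen, hypothalamus); used to build single-effect
#'   parameter-recovery fixtures.
#' @param seed master RNG seed; the whole cohort is a pure function of it.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48),
                         spacing_invivo = 0.15,
                         spacing_exvivo = 0.04,
                         n_per_group = c(WT = 8L, TG = 10L, TG_DOX = 7L),
                         atrophy_fraction_TG = 0.25,
                         atrophy_fraction_TGDOX = 0.10,
                         tbv_contrast_TG = 0.21,
                         tbv_contrast_TGDOX = 1 - 0.79 / 0.84,
                         exvivo_volume_shrinkage = 0.10,
                         exvivo_extra_distortion_mm = 0.5,
                         ventricle_expansion = c(invivo = 0.30,
                                                 exvivo = 0.10),
                         tissue_means = NULL,
                         noise_sd = c(invivo = 10, exvivo = 10),
                         subject_variability_sd = 0.05,
                         atrophy_targets_TG = NULL,
                         seed = 42L) {
  if (is.null(tissue_means)) {
    tissue_means <- list(
      # mean/noise_sd reproduces the reference per-region SNR values
      invivo = c(cortex = 142, corpus_callosum = 156, hippocampus = 193,
                 caudate_putamen = 144, thalamus = 124, hypothalamus = 112,
                 midbrain = 111, cerebellum = 76, olfactory_bulb = 148,
                 brainstem = 110, ventricles = 230, rind = 220),
      exvivo = c(cortex = 100, corpus_callosum = 42, hippocampus = 108,
                 caudate_putamen = 93, thalamus = 78, hypothalamus = 115,
                 midbrain = 69, cerebellum = 114, olfactory_bulb = 109,
                 brainstem = 70, ventricles = 20, rind = 130))
  }
  fr <- c(atrophy_fraction_TG, atrophy_fraction_TGDOX, tbv_contrast_TG,
          tbv_contrast_TGDOX, exvivo_volume_shrinkage)
  if (any(fr[!is.na(fr)] < 0 | fr[!is.na(fr)] >= 1))
    stop("fractions must lie in [0, 1)")
  spec <- structure(list(
    grid_shape = as.integer(grid_shape),
    spacing_invivo = spacing_invivo, spacing_exvivo = spacing_exvivo,
    n_per_group = n_per_group,
    atrophy_fraction_TG = atrophy_fraction_TG,
    atrophy_fraction_TGDOX = atrophy_fraction_TGDOX,
    tbv_contrast_TG = tbv_contrast_TG,
    tbv_contrast_TGDOX = tbv_contrast_TGDOX,
    exvivo_volume_shrinkage = exvivo_volume_shrinkage,
    exvivo_extra_distortion_mm = exvivo_extra_distortion_mm,
    ventricle_expansion = ventricle_expansion,
    tissue_means = tissue_means, noise_sd = noise_sd,
    subject_variability_sd = subject_variability_sd,
    atrophy_targets_TG = atrophy_targets_TG,
    seed = as.integer(seed)), class = "phantom_spec")
  geom <- phantom_geometry(spec)
  margin <- (spec$grid_shape * spacing_invivo) / 2 - geom$brain_semi
  if (any(margin < 3 * spacing_invivo))
    stop("grid too small: brain template needs a >= 3 voxel margin")
  spec
}

# region layout in mm about the brain centre (world origin); x right,
# y anterior, z superior. `side` duplicates paired structures.
phantom_geometry <- function(spec) {
  brain_semi <- c(2.4, 3.0, 2.1)
  reg <- list(
    olfactory_bulb  = list(c = c(0,  2.45, -0.10), s = c(0.70, 0.75, 0.70)),
    cerebellum      = list(c = c(0, -2.20,  0.55), s = c(1.30, 0.95, 0.95)),
    brainstem       = list(c = c(0, -2.10, -0.90), s = c(0.85, 1.10, 0.75)),
    ventricles      = list(c = c(0.85, 0.55, 0.35), s = c(0.28, 0.85, 0.45),
                           paired = TRUE),
    hippocampus     = list(c = c(1.05, -0.40, 0.55), s = c(0.75, 0.90, 0.60),
                           paired = TRUE),
    caudate_putamen = list(c = c(1.25, 1.05, -0.25), s = c(0.70, 0.85, 0.75),
                           paired = TRUE),
    thalamus        = list(c = c(0, -0.25,  0.00), s = c(1.00, 0.85, 0.70)),
    hypothalamus    = list(c = c(0,  0.30, -1.15), s = c(0.90, 0.85, 0.60)),
    midbrain        = list(c = c(0, -1.25, -0.20), s = c(0.95, 0.80, 0.75)))
  list(brain_semi = brain_semi, regions = reg,
       cc_shell = c(0.68, 0.78),   # corpus callosum: ellipsoidal shell
       rind_shell = c(1.02, 1.10)) # bright extra-cranial rind
}

phantom_affine <- function(spec, modality) {
  sp <- if (modality == "invivo") spec$spacing_invivo else spec$spacing_exvivo
  dims <- phantom_dims(spec, modality)
  aff <- diag(c(rep(sp, 3), 1))
  aff[1:3, 4] <- -(dims - 1) / 2 * sp   # world origin at grid centre
  aff
}

phantom_dims <- function(spec, modality) {
  if (modality == "invivo") return(spec$grid_shape)
  as.integer(round(spec$grid_shape * spec$spacing_invivo /
                   spec$spacing_exvivo))
}

# squared normalized ellipsoid radius of pts (N x 3) for centre/semi
ell_rho2 <- function(pts, centre, semi) {
  ((pts[, 1] - centre[1]) / semi[1])^2 +
  ((pts[, 2] - centre[2]) / semi[2])^2 +
  ((pts[, 3] - centre[3]) / semi[3])^2
}

# analytic template labelling at world points; returns integer labels
# (PHANTOM_REGIONS ids; 13 = rind, handled by callers as background)
phantom_labels_at <- function(spec, pts) {
  geom <- phantom_geometry(spec)
  n <- nrow(pts)
  lab <- integer(n)
  rho2 <- ell_rho2(pts, c(0, 0, 0), geom$brain_semi)
  rho <- sqrt(rho2)
  inside <- rho <= 1
  rind <- rho > geom$rind_shell[1] & rho < geom$rind_shell[2]
  lab[rind] <- 13L
  assign_first <- function(lab, name) {
    r <- geom$regions[[name]]
    sides <- if (isTRUE(r$paired)) c(1, -1) else 1
    for (sgn in sides) {
      cc <- r$c * c(sgn, 1, 1)
      hit <- inside & lab == 0L & ell_rho2(pts, cc, r$s) <= 1
      lab[hit] <- PHANTOM_REGIONS[[name]]
    }
    lab
  }
  for (nm in c("olfactory_bulb", "cerebellum", "brainstem", "ventricles",
               "hippocampus", "caudate_putamen", "thalamus", "hypothalamus",
               "midbrain"))
    lab <- assign_first(lab, nm)
  # shell structures on what is left
  shell <- inside & lab == 0L
  cc_hit <- shell & rho >= geom$cc_shell[1] & rho < geom$cc_shell[2]
  ctx_hit <- shell & rho >= geom$cc_shell[2]
  lab[cc_hit] <- PHANTOM_REGIONS[["corpus_callosum"]]
  lab[ctx_hit] <- PHANTOM_REGIONS[["cortex"]]
  # interior filler: nearest of the three central gray structures
  left <- which(inside & lab == 0L)
  if (length(left)) {
    cand <- c("thalamus", "hypothalamus", "midbrain")
    dmat <- sapply(cand, function(nm) {
      cc <- geom$regions[[nm]]$c
      (pts[left, 1] - cc[1])^2 + (pts[left, 2] - cc[2])^2 +
        (pts[left, 3] - cc[3])^2
    })
    lab[left] <- PHANTOM_REGIONS[cand[max.col(-dmat)]]
  }
  lab
}

# deterministic smooth intra-region texture (fractional modulation).
# Real structural MRI has intra-tissue contrast at the sub-structure
# scale; without it, non-rigid registration has no information in region
# interiors. 5% amplitude at ~0.5 mm period; the three incommensurate
# periods keep region means within a fraction of a percent of the
# nominal tissue means.
phantom_texture <- function(pts) {
  0.05 * sin(2 * pi * pts[, 1] / 0.45 + 0.5) *
         sin(2 * pi * pts[, 2] / 0.52 + 1.1) *
         sin(2 * pi * pts[, 3] / 0.48 + 2.0)
}

# noise ROI: a cube in the grid corner, in undeformed world coordinates
phantom_noise_box <- function(spec, modality) {
  aff <- phantom_affine(spec, modality)
  lo <- aff[1:3, 4]
  cbind(lo + 0.15, lo + 1.05)
}

# ---- deformation primitives (forward maps, template -> subject) --------

prim_scale <- function(s, centre = c(0, 0, 0)) {
  list(type = "scale", s = s,
       d = function(p) (s - 1) * sweep(p, 2, centre))
}

prim_blob_contract <- function(centre, semi, amp, width = 0.55) {
  list(type = "blob", amp = amp,
       d = function(p) {
         e <- exp(-ell_rho2(p, centre, semi) / (2 * width^2))
         -amp * e * sweep(p, 2, centre)
       })
}

# cortical thinning: inward radial displacement that switches on across
# the outer shell (one-sided in the ellipsoid radius, so the white matter
# beneath the cortex is translated, not compressed), smoothly restricted
# in y so the cerebellum, brainstem and olfactory bulbs -- which also
# live at shell radii -- are untouched
prim_shell_contract <- function(brain_semi, amp, rho0 = 0.84,
                                tau = 0.045, y_range = c(-1.2, 1.8),
                                y_tau = 0.35) {
  list(type = "shell", amp = amp,
       d = function(p) {
         rho <- sqrt(ell_rho2(p, c(0, 0, 0), brain_semi))
         e <- 1 / (1 + exp(-(rho - rho0) / tau)) /
           (1 + exp(-(p[, 2] - y_range[1]) / y_tau)) /
           (1 + exp((p[, 2] - y_range[2]) / y_tau))
         -amp * e * p
       })
}

prim_bump <- function(centre, sigma, vec) {
  list(type = "bump",
       d = function(p) {
         r2 <- (p[, 1] - centre[1])^2 + (p[, 2] - centre[2])^2 +
               (p[, 3] - centre[3])^2
         e <- exp(-r2 / (2 * sigma^2))
         cbind(e * vec[1], e * vec[2], e * vec[3])
       })
}

prim_gauss_mixture <- function(centres, sigmas, vecs) {
  list(type = "mixture",
       d = function(p) {
         out <- matrix(0, nrow(p), 3)
         for (j in seq_len(nrow(centres))) {
           r2 <- (p[, 1] - centres[j, 1])^2 + (p[, 2] - centres[j, 2])^2 +
                 (p[, 3] - centres[j, 3])^2
           e <- exp(-r2 / (2 * sigmas[j]^2))
           out <- out + cbind(e * vecs[j, 1], e * vecs[j, 2], e * vecs[j, 3])
         }
         out
       })
}

phantom_apply_forward <- function(prims, pts) {
  for (p in prims) pts <- pts + p$d(pts)
  pts
}

# invert the composed forward map by fixed-point iteration (contractive:
# all displacement gradients are well below 1 in the phantom regime)
phantom_invert <- function(prims, pts, iters = 20, tol = 1e-7) {
  x <- pts
  for (it in seq_len(iters)) {
    xn <- pts - (phantom_apply_forward(prims, x) - x)
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol) break
  }
  x
}

# determinant of the forward map's spatial Jacobian by central differences
phantom_forward_det <- function(prims, pts, h = 1e-3) {
  J <- vector("list", 3)
  for (a in 1:3) {
    dp <- matrix(0, nrow(pts), 3); dp[, a] <- h
    J[[a]] <- (phantom_apply_forward(prims, pts + dp) -
               phantom_apply_forward(prims, pts - dp)) / (2 * h)
  }
  J[[1]][, 1] * (J[[2]][, 2] * J[[3]][, 3] - J[[2]][, 3] * J[[3]][, 2]) -
  J[[2]][, 1] * (J[[1]][, 2] * J[[3]][, 3] - J[[1]][, 3] * J[[3]][, 2]) +
  J[[3]][, 1] * (J[[1]][, 2] * J[[2]][, 3] - J[[1]][, 3] * J[[2]][, 2])
}

# ---- calibration -------------------------------------------------------

# amplitude of a windowed contraction such that the Jacobian determinant
# of the COMPOSED group field, integrated over the target region, equals
# 1 - fraction (fraction < 0 yields an expansion, e.g. the ventricles);
# `others` holds the remaining primitives of the composition
calibrate_amp <- function(make_prim, region_pts, fraction,
                          others = list()) {
  f <- function(a) mean(phantom_forward_det(c(others, list(make_prim(a))),
                                            region_pts)) - (1 - fraction)
  lo <- -0.6; hi <- 0.9
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    # target unreachable in-range: pick the closer endpoint
    return(if (abs(flo) < abs(fhi)) lo else hi)
  }
  uniroot(f, c(lo, hi), tol = 1e-8)$root
}

phantom_target_regions <- function(group, spec = NULL) {
  if (group == "TG" && !is.null(spec) &&
      !is.null(spec$atrophy_targets_TG))
    return(spec$atrophy_targets_TG)
  switch(group,
         TG = c("cortex", "hippocampus", "caudate_putamen", "hypothalamus"),
         TG_DOX = c("cortex", "hippocampus", "caudate_putamen"),
         WT = character())
}

.phantom_calib_cache <- new.env(parent = emptyenv())

# all spec-derived deformation parameters; pure function of the spec
# (memoized: calibration costs seconds and specs are reused heavily)
phantom_calibration <- function(spec) {
  # the calibration is seed-independent (pure geometry/effect-size
  # computation), so the cache key excludes the seed
  key <- config_hash(unclass(spec)[setdiff(names(spec), "seed")])
  hit <- get0(key, envir = .phantom_calib_cache)
  if (!is.null(hit)) return(hit)
  out <- phantom_calibration_impl(spec)
  assign(key, out, envir = .phantom_calib_cache)
  out
}

phantom_calibration_impl <- function(spec) {
  geom <- phantom_geometry(spec)
  aff <- phantom_affine(spec, "invivo")
  grid_w <- vox2world(aff, voxel_grid(spec$grid_shape))
  lab <- phantom_labels_at(spec, grid_w)
  voxvol <- spec$spacing_invivo^3
  mask <- lab >= 1L & lab <= 11L
  v0 <- sum(mask) * voxvol

  # blob window from a set of core label voxels: centroid, 2-sigma
  # per-axis semi-axes, width reaching ~0.3 at the 95th percentile
  # radius -- compact enough that neighbouring structures see almost
  # nothing of it
  blob_maker <- function(pts) {
    cc <- colMeans(pts)
    semi <- pmax(2 * apply(pts, 2, sd), 0.15)
    rho <- sqrt(ell_rho2(pts, cc, semi))
    width <- max(quantile(rho, 0.95) / 1.55, 0.25)
    function(a) prim_blob_contract(cc, semi, a, width = width)
  }

  # calibration/evaluation mask of a blob region: label voxels inside the
  # nominal ellipsoid (excludes nearest-structure filler far from the
  # core, which the imposed field deliberately does not reach)
  core_pts <- function(nm, sgn = NULL) {
    r <- geom$regions[[nm]]
    keep <- lab == PHANTOM_REGIONS[[nm]]
    if (!is.null(sgn) && isTRUE(r$paired))
      keep <- keep & sgn * grid_w[, 1] >= 0
    cc <- r$c
    if (!is.null(sgn)) cc <- cc * c(sgn, 1, 1)
    keep <- keep & ell_rho2(grid_w, cc, r$s) <= 1
    grid_w[keep, , drop = FALSE]
  }

  region_prims <- function(group, fraction, vent_exp) {
    units <- list()   # (maker, pts, fraction) per primitive
    for (nm in phantom_target_regions(group, spec)) {
      if (nm == "cortex") {
        pts <- grid_w[lab == PHANTOM_REGIONS[[nm]], , drop = FALSE]
        units[[length(units) + 1L]] <- list(
          maker = function(a) prim_shell_contract(geom$brain_semi, a),
          pts = pts, fraction = fraction)
      } else {
        r <- geom$regions[[nm]]
        for (sgn in (if (isTRUE(r$paired)) c(1, -1) else 1)) {
          side_pts <- core_pts(nm, if (isTRUE(r$paired)) sgn else NULL)
          units[[length(units) + 1L]] <- list(
            maker = blob_maker(side_pts), pts = side_pts,
            fraction = fraction)
        }
      }
    }
    if (vent_exp > 0 && group %in% c("TG", "TG_DOX")) {
      scale_exp <- if (group == "TG_DOX") 0.5 else 1
      for (sgn in c(1, -1)) {
        side_pts <- core_pts("ventricles", sgn)
        units[[length(units) + 1L]] <- list(
          maker = blob_maker(side_pts), pts = side_pts,
          fraction = -vent_exp * scale_exp)
      }
    }
    if (!length(units)) return(list())
    # solo calibration of each compact window, then a couple of light
    # sequential refinement sweeps to absorb the (weak) residual
    # coupling between neighbouring windows
    amps <- vapply(units, function(u)
      calibrate_amp(u$maker, u$pts, u$fraction), numeric(1))
    for (sweep in 1:3) {
      for (j in seq_along(units)) {
        others <- lapply(seq_along(units)[-j],
                         function(k) units[[k]]$maker(amps[k]))
        amps[j] <- calibrate_amp(units[[j]]$maker, units[[j]]$pts,
                                 units[[j]]$fraction, others)
      }
      all_p <- lapply(seq_along(units),
                      function(k) units[[k]]$maker(amps[k]))
      resid <- vapply(seq_along(units), function(k)
        abs(mean(phantom_forward_det(all_p, units[[k]]$pts)) -
            (1 - units[[k]]$fraction)), numeric(1))
      if (max(resid) < 0.005) break
    }
    lapply(seq_along(units), function(j) units[[j]]$maker(amps[j]))
  }

  calib <- list(v0 = v0, geom = geom)
  # ex vivo preparation: the named uniform shrink has det exactly
  # 1 - shrinkage, but the brainstem/olfactory displacement bumps sit at
  # the brain boundary and are not volume-neutral over the mask; a small
  # compensating scale keeps the measured TBV reduction at the stated
  # fraction
  ex_prims <- phantom_exvivo_prims(spec)
  vex <- sum(phantom_forward_det(ex_prims,
                                 grid_w[mask, , drop = FALSE])) * voxvol
  s_fix <- ((1 - spec$exvivo_volume_shrinkage) * v0 / vex)^(1 / 3)
  calib$exvivo_prims <- c(ex_prims, list(prim_scale(s_fix)))
  for (grp in c("TG", "TG_DOX")) {
    fraction <- if (grp == "TG") spec$atrophy_fraction_TG else
      spec$atrophy_fraction_TGDOX
    contrast <- if (grp == "TG") spec$tbv_contrast_TG else
      spec$tbv_contrast_TGDOX
    for (mod in PHANTOM_MODALITIES) {
      prims <- region_prims(grp, fraction, spec$ventricle_expansion[[mod]])
      # NA contrast: no global scale -- the group's TBV deficit is
      # whatever the regional contractions alone produce (used for pure
      # parameter-recovery fixtures)
      if (is.na(contrast)) {
        g <- 1
      } else {
        vreg <- sum(phantom_forward_det(prims,
                                        grid_w[mask, , drop = FALSE])) *
          voxvol
        g <- ((1 - contrast) * v0 / vreg)^(1 / 3)
      }
      calib[[paste(grp, mod, sep = ".")]] <-
        list(prims = c(prims, list(prim_scale(g))), g = g)
    }
  }
  for (mod in PHANTOM_MODALITIES)
    calib[[paste("WT", mod, sep = ".")]] <- list(prims = list(), g = 1)
  calib
}

# ex vivo preparation: global fixation shrinkage (det exactly
# 1 - shrinkage) plus brainstem / olfactory-bulb displacement bumps
phantom_exvivo_prims <- function(spec) {
  geom <- phantom_geometry(spec)
  s <- (1 - spec$exvivo_volume_shrinkage)^(1 / 3)
  a <- spec$exvivo_extra_distortion_mm
  bs <- geom$regions$brainstem$c
  ob <- geom$regions$olfactory_bulb$c
  list(prim_scale(s),
       prim_bump(bs, 0.7, a * c(0, -0.8, -0.6)),
       prim_bump(ob, 0.6, 0.6 * a * c(0, 0.9, -0.436)))
}

phantom_subject_seed <- function(spec, group, index, salt = 0L) {
  gid <- match(group, PHANTOM_GROUPS)
  as.integer((as.double(spec$seed) * 7919 + gid * 1299709 +
              index * 104729 + salt * 15485863) %% 2147483647)
}

with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# random smooth anatomical warp shared between a subject's two scans
phantom_subject_prim <- function(spec, group, index) {
  if (spec$subject_variability_sd <= 0) return(NULL)
  geom <- phantom_geometry(spec)
  with_seed(phantom_subject_seed(spec, group, index), function() {
    m <- 10L
    centres <- cbind(runif(m, -1, 1) * geom$brain_semi[1] * 0.8,
                     runif(m, -1, 1) * geom$brain_semi[2] * 0.8,
                     runif(m, -1, 1) * geom$brain_semi[3] * 0.8)
    vecs <- matrix(rnorm(3 * m, 0, spec$subject_variability_sd), m, 3)
    prim_gauss_mixture(centres, rep(0.8, m), vecs)
  })
}

#' Forward deformation chain of one phantom subject
#'
#' Exposes the exact analytic maps used by the generator, for oracle
#' checks: `phi` maps template world coordinates to subject world
#' coordinates, `psi` is its numeric inverse (the pull-back used for
#' resampling), and `logdet(pts)` is the log Jacobian determinant of `phi`
#' (positive where the subject is locally larger than the template).
#'
#' @param spec a [phantom_spec()].
#' @param group,modality,index subject identity.
#' @param calib optional cached [phantom_calibration()] result.
#' @export
phantom_forward_map <- function(spec, group, modality, index,
                                calib = NULL) {
  if (!group %in% PHANTOM_GROUPS) stop("unknown group: ", group)
  if (!modality %in% PHANTOM_MODALITIES) stop("unknown modality: ", modality)
  if (is.null(calib)) calib <- phantom_calibration(spec)
  prims <- list()
  subj <- phantom_subject_prim(spec, group, index)
  if (!is.null(subj)) prims <- c(prims, list(subj))
  prims <- c(prims, calib[[paste(group, modality, sep = ".")]]$prims)
  if (modality == "exvivo") prims <- c(prims, calib$exvivo_prims)
  list(prims = prims,
       phi = function(pts) phantom_apply_forward(prims, pts),
       psi = function(pts) phantom_invert(prims, pts),
       logdet = function(pts) log(phantom_forward_det(prims, pts)))
}

#' Build the canonical phantom brain template
#'
#' A noise-free piecewise-constant "brain" of nested ellipsoidal regions
#' with a small smooth intra-region texture, a bright extra-cranial rind
#' (intensity only; labelled background) and a corner noise ROI.
#'
#' @param spec a [phantom_spec()].
#' @param modality which tissue-contrast/grid to build.
#' @return list with `volume` ([tbm_volume()]) and `labels`
#'   ([tbm_labelmap()]).
#' @export
build_template <- function(spec, modality = "invivo") {
  stopifnot(modality %in% PHANTOM_MODALITIES)
  dims <- phantom_dims(spec, modality)
  aff <- phantom_affine(spec, modality)
  pts <- vox2world(aff, voxel_grid(dims))
  img <- phantom_render(spec, modality, pts, pts, dims, aff)
  img
}

# shared renderer: anatomical coordinates `apts` (pre-deformation) decide
# label/intensity; grid coordinates `gpts` decide the noise ROI placement
phantom_render <- function(spec, modality, apts, gpts, dims, aff) {
  lab <- phantom_labels_at(spec, apts)
  means <- spec$tissue_means[[modality]]
  inten <- numeric(length(lab))
  for (nm in names(PHANTOM_REGIONS)) {
    if (nm == "noise") next
    inten[lab == PHANTOM_REGIONS[[nm]]] <- means[[nm]]
  }
  inten[lab == 13L] <- means[["rind"]]
  inten <- inten * (1 + phantom_texture(apts))
  lab[lab == 13L] <- 0L
  nb <- phantom_noise_box(spec, modality)
  in_box <- gpts[, 1] >= nb[1, 1] & gpts[, 1] <= nb[1, 2] &
            gpts[, 2] >= nb[2, 1] & gpts[, 2] <= nb[2, 2] &
            gpts[, 3] >= nb[3, 1] & gpts[, 3] <= nb[3, 2]
  lab[in_box & lab == 0L] <- PHANTOM_REGIONS[["noise"]]
  legend <- c(background = 0L, PHANTOM_REGIONS)
  vol <- tbm_volume(array(inten, dims),
                    spacing = rep(aff[1, 1], 3), affine = aff)
  list(volume = vol,
       labels = tbm_labelmap(array(lab, dims), legend, geometry = vol))
}

#' Synthesize one phantom subject
#'
#' The subject image is the template evaluated through the subject's exact
#' pull-back map plus modality noise; the returned field is that exact
#' composite (grid world position y samples the template at y + u(y)), so
#' resampling the template through it reproduces the subject. Output is a
#' deterministic function of (spec, group, modality, index).
#'
#' @inheritParams phantom_forward_map
#' @return list: `volume`, `labels`, `field` (the exact composite
#'   pull-back, parts global+nonrigid), `true_tbv` (mm^3, from the label
#'   map), `fmap` (the [phantom_forward_map()] chain).
#' @export
synthesize_subject <- function(spec, group, modality, index,
                               calib = NULL) {
  fmap <- phantom_forward_map(spec, group, modality, index, calib)
  dims <- phantom_dims(spec, modality)
  aff <- phantom_affine(spec, modality)
  gpts <- vox2world(aff, voxel_grid(dims))
  apts <- fmap$psi(gpts)
  out <- phantom_render(spec, modality, apts, gpts, dims, aff)
  noise_seed <- phantom_subject_seed(spec, group, index,
                                     salt = match(modality,
                                                  PHANTOM_MODALITIES))
  nsd <- spec$noise_sd[[modality]]
  if (nsd > 0) {
    noise <- with_seed(noise_seed, function()
      rnorm(prod(dims), 0, nsd))
    out$volume$data <- out$volume$data + array(noise, dims)
  }
  u <- apts - gpts
  parts <- if (max(abs(u)) < 1e-9) character() else c("global", "nonrigid")
  field <- tbm_field(array(u, c(dims, 3)), geometry = out$volume,
                     parts = parts)
  voxvol <- prod(rep(aff[1, 1], 3))
  tbv <- sum(out$labels$labels >= 1L & out$labels$labels <= 11L) * voxvol
  list(volume = out$volume, labels = out$labels, field = field,
       true_tbv = tbv, group = group, modality = modality, index = index,
       fmap = fmap)
}

#' Synthesize and write a full phantom cohort
#'
#' Writes every subject's volume, label map and exact deformation field as
#' NIfTI under `out_dir`, a cohort manifest CSV, the spec as JSON and a
#' ground-truth sidecar JSON (per-subject true TBV and the calibrated
#' group deformation parameters).
#'
#' @param spec a [phantom_spec()].
#' @param out_dir writable output directory (created if needed).
#' @param modalities subset of c("invivo", "exvivo").
#' @param compress write .nii.gz instead of .nii.
#' @return the [read_manifest()]-loaded manifest.
#' @export
synthesize_cohort <- function(spec, out_dir,
                              modalities = PHANTOM_MODALITIES,
                              compress = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("out_dir not writable: ", out_dir)
  calib <- phantom_calibration(spec)
  ext <- if (compress) ".nii.gz" else ".nii"
  rows <- list(); truth <- list()
  for (grp in names(spec$n_per_group)) {
    for (i in seq_len(spec$n_per_group[[grp]])) {
      sid <- sprintf("%s_%02d", grp, i)
      for (mod in modalities) {
        s <- synthesize_subject(spec, grp, mod, i, calib)
        vp <- sprintf("%s_%s%s", sid, mod, ext)
        lp <- sprintf("%s_%s_labels%s", sid, mod, ext)
        fp <- sprintf("%s_%s_field%s", sid, mod, ext)
        write_nifti(s$volume, file.path(out_dir, vp))
        write_nifti(s$labels, file.path(out_dir, lp))
        write_nifti(s$field, file.path(out_dir, fp))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = grp, modality = mod,
          volume_path = vp, labelmap_path = lp,
          rng_seed = phantom_subject_seed(spec, grp, i),
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- list(
          subject_id = sid, modality = mod, group = grp,
          true_tbv_mm3 = s$true_tbv, field_path = fp)
      }
    }
  }
  m <- do.call(rbind, rows)
  write_manifest(structure(m, class = c("cohort_manifest", class(m))),
                 file.path(out_dir, "manifest.csv"))
  gt <- list(
    subjects = truth,
    atrophy_fraction_TG = spec$atrophy_fraction_TG,
    atrophy_fraction_TGDOX = spec$atrophy_fraction_TGDOX,
    tbv_contrast_TG = spec$tbv_contrast_TG,
    exvivo_volume_shrinkage = spec$exvivo_volume_shrinkage,
    global_scales = lapply(
      calib[grep("\\.", names(calib))],
      function(x) x$g))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(spec[setdiff(names(spec), character())],
                       file.path(out_dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  read_manifest(file.path(out_dir, "manifest.csv"))
}

#' Expected per-region SNR of the phantom design
#'
#' Design-time table: each region's tissue mean divided by the noise SD,
#' per modality. Used to pick intensity defaults so the phantom's
#' in vivo / ex vivo SNR ordering matches the reference measurements.
#'
#' @param spec a [phantom_spec()].
#' @return data frame region x modality of expected SNR.
#' @export
calibrate_noise <- function(spec) {
  if (any(spec$noise_sd <= 0)) stop("noise_sd must be positive")
  regions <- setdiff(names(PHANTOM_REGIONS), "noise")
  out <- data.frame(region = regions)
  for (mod in PHANTOM_MODALITIES) {
    out[[mod]] <- as.numeric(spec$tissue_means[[mod]][regions]) /
      spec$noise_sd[[mod]]
  }
  out
}
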