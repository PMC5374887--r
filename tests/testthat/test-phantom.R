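# Synthetic cohort generator: template construction, determinism,
# imposed-effect calibration, cohort round trip.

test_that("template has the full legend, pure regions, one component", {
  tpl <- cached_template("invivo")
  legend <- tpl$labels$legend
  expect_length(legend, 13L)   # background + 12 regions
  expect_setequal(names(legend),
                  c("background", names(tbmpipe:::PHANTOM_REGIONS)))
  tab <- table(tpl$labels$labels)
  expect_true(all(as.character(legend) %in% names(tab)))
  # one 6-connected brain component
  bm <- brain_mask(tpl$labels)
  expect_equal(sum(tbmpipe:::largest_component6(bm)), sum(bm))
  # measured ROI means within 1% of designed tissue means (no noise)
  means <- test_spec()$tissue_means$invivo
  for (nm in setdiff(names(tbmpipe:::PHANTOM_REGIONS), "noise")) {
    m <- mean(tpl$volume$data[tpl$labels$labels == legend[[nm]]])
    expect_lt(abs(m - means[[nm]]) / means[[nm]], 0.01, label = nm)
  }
  # gray-white contrast matches configured means
  gw_diff <- mean(tpl$volume$data[tpl$labels$labels == legend[["cortex"]]]) -
    mean(tpl$volume$data[tpl$labels$labels == legend[["corpus_callosum"]]])
  expect_equal(gw_diff, means[["cortex"]] - means[["corpus_callosum"]],
               tolerance = 0.02)
})

test_that("subject synthesis is deterministic and validates inputs", {
  spec <- test_spec()
  calib <- cached_calibration()
  s1 <- synthesize_subject(spec, "TG", "invivo", 1, calib)
  s2 <- synthesize_subject(spec, "TG", "invivo", 1, calib)
  expect_identical(s1$volume$data, s2$volume$data)
  expect_identical(s1$field$vectors, s2$field$vectors)
  s3 <- synthesize_subject(spec, "TG", "invivo", 2, calib)
  expect_false(identical(s1$volume$data, s3$volume$data))
  expect_error(synthesize_subject(spec, "XX", "invivo", 1, calib),
               "unknown group")
  expect_error(synthesize_subject(spec, "WT", "ct", 1, calib),
               "unknown modality")
})

test_that("all effects off reproduces the template exactly", {
  spec0 <- phantom_spec(subject_variability_sd = 0,
                        noise_sd = c(invivo = 0, exvivo = 0),
                        spacing_exvivo = 0.12)
  w <- synthesize_subject(spec0, "WT", "invivo", 1)
  tpl <- build_template(spec0, "invivo")
  expect_identical(w$volume$data, tpl$volume$data)
  expect_identical(w$labels$labels, tpl$labels$labels)
  expect_length(w$field$parts, 0L)
})

test_that("imposed atrophy integrates to the configured fraction", {
  spec <- test_spec()
  calib <- cached_calibration()
  tpl <- cached_template("invivo")
  # composed group field, without the trailing global scale
  prims <- calib[["TG.invivo"]]$prims
  reg <- prims[seq_len(length(prims) - 1L)]
  for (nm in c("cortex", "hippocampus", "caudate_putamen",
               "hypothalamus")) {
    core <- region_core_mask(spec, tpl$volume, nm)
    pts <- tbmpipe:::world_grid(tpl$volume)[as.vector(core), ,
                                            drop = FALSE]
    dj <- tbmpipe:::phantom_forward_det(reg, pts)
    expect_equal(mean(dj), 1 - spec$atrophy_fraction_TG,
                 tolerance = 0.01, label = nm)
  }
  # ventricular expansion hits its configured (modality-damped) target
  core <- region_core_mask(spec, tpl$volume, "ventricles")
  pts <- tbmpipe:::world_grid(tpl$volume)[as.vector(core), , drop = FALSE]
  expect_equal(mean(tbmpipe:::phantom_forward_det(reg, pts)),
               1 + spec$ventricle_expansion[["invivo"]], tolerance = 0.02)
  # global ex vivo shrink primitive has det exactly 1 - shrinkage
  s <- (1 - spec$exvivo_volume_shrinkage)^(1 / 3)
  expect_equal(s^3, 1 - spec$exvivo_volume_shrinkage, tolerance = 1e-12)
})

test_that("group TBV contrasts and fixation shrinkage are calibrated", {
  spec <- test_spec()
  calib <- cached_calibration()
  tb <- function(g, mod, n) vapply(seq_len(n), function(i)
    synthesize_subject(spec, g, mod, i, calib)$true_tbv, numeric(1))
  wt_iv <- tb("WT", "invivo", 6)
  tg_iv <- tb("TG", "invivo", 6)
  expect_equal(mean(tg_iv) / mean(wt_iv), 1 - spec$tbv_contrast_TG,
               tolerance = 0.02 / (1 - spec$tbv_contrast_TG))
  wt_ev <- tb("WT", "exvivo", 6)
  expect_equal(mean(wt_ev / wt_iv), 1 - spec$exvivo_volume_shrinkage,
               tolerance = 0.01)
})

test_that("true TBV equals mask voxel count times voxel volume", {
  spec <- test_spec()
  s <- synthesize_subject(spec, "WT", "invivo", 3, cached_calibration())
  voxvol <- prod(s$volume$spacing)
  expect_equal(s$true_tbv, sum(brain_mask(s$labels)) * voxvol,
               tolerance = voxvol)
})

test_that("calibrate_noise reproduces the designed SNR table", {
  spec <- test_spec()
  tab <- calibrate_noise(spec)
  expect_equal(tab$invivo[tab$region == "hippocampus"], 19.3,
               tolerance = 1e-9)
  # in vivo SNR higher in 7 of the 9 reference regions, ex vivo higher in
  # the cerebellum
  nine <- c("caudate_putamen", "cerebellum", "corpus_callosum", "cortex",
            "hippocampus", "hypothalamus", "olfactory_bulb", "midbrain",
            "thalamus")
  sub <- tab[tab$region %in% nine, ]
  expect_equal(sum(sub$invivo > sub$exvivo), 7L)
  expect_gt(tab$exvivo[tab$region == "cerebellum"],
            tab$invivo[tab$region == "cerebellum"])
  expect_error(calibrate_noise(phantom_spec(noise_sd = c(invivo = 0,
                                                         exvivo = 10))),
               "positive")
})

test_that("measured SNR on generated subjects tracks the design table", {
  spec <- test_spec()
  calib <- cached_calibration()
  snrs <- vapply(1:6, function(i) {
    s <- synthesize_subject(spec, "WT", "invivo", i, calib)
    roi_snr(s$volume, s$labels, "hippocampus")
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 19.3) / 19.3, 0.15)
})

test_that("synthesize_cohort writes a loadable, consistent cohort", {
  spec <- phantom_spec(n_per_group = c(WT = 2L, TG = 1L, TG_DOX = 1L),
                       spacing_exvivo = 0.15)
  d <- tempfile()
  m <- synthesize_cohort(spec, d)
  expect_equal(nrow(m), 8L)   # 4 subjects x 2 modalities
  expect_true(file.exists(file.path(d, "ground_truth.json")))
  # every referenced volume satisfies the container invariants
  for (i in seq_len(nrow(m))) {
    s <- tbmpipe:::load_subject(m, i, c(background = 0L,
                                        tbmpipe:::PHANTOM_REGIONS))
    expect_s3_class(s$volume, "tbm_volume")
    expect_true(all(is.finite(s$volume$data)))
  }
  # deterministic: regenerating gives bit-identical volumes
  d2 <- tempfile()
  synthesize_cohort(spec, d2)
  f1 <- read_nifti(file.path(d, m$volume_path[1]))
  f2 <- read_nifti(file.path(d2, m$volume_path[1]))
  expect_identical(f1$data, f2$data)
  unlink(c(d, d2), recursive = TRUE)
})
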