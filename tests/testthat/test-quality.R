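# SNR / CNR / TBV quality metrics: definitions, hand-computed cases and
# worked examples from the reference measurements.

mini_labels <- function(vals, labels) {
  dims <- dim(vals)
  v <- tbm_volume(vals, spacing = rep(0.15, 3))
  lm <- tbm_labelmap(labels,
                     c(background = 0L, cortex = 1L, corpus_callosum = 2L,
                       noise = 12L),
                     geometry = v)
  list(v = v, lm = lm)
}

test_that("roi_snr follows its definition, sample-SD convention", {
  vals <- array(0, c(4, 4, 4))
  labs <- array(0L, c(4, 4, 4))
  vals[1:2, 1, 1] <- c(4, 6); labs[1:2, 1, 1] <- 1L
  vals[1:4, 2, 1] <- c(0, 2, 0, 2); labs[1:4, 2, 1] <- 12L
  f <- mini_labels(vals, labs)
  # mean 5 over sample SD sqrt(4/3)
  expect_equal(roi_snr(f$v, f$lm, "cortex"), 5 / sqrt(4 / 3),
               tolerance = 1e-12)

  # constant signal 100 / noise SD 10 -> exactly 10
  set.seed(1)
  vals2 <- array(100, c(8, 8, 8)); labs2 <- array(1L, c(8, 8, 8))
  noise <- rnorm(64, 0, 10)
  noise <- (noise - mean(noise)) / sd(noise) * 10   # force SD exactly 10
  vals2[, , 1] <- noise; labs2[, , 1] <- 12L
  f2 <- mini_labels(vals2, labs2)
  expect_equal(roi_snr(f2$v, f2$lm, "cortex"), 10, tolerance = 1e-9)

  expect_error(roi_snr(f2$v, f2$lm, "corpus_callosum"), "empty region")
  vals2[, , 1] <- 5; f3 <- mini_labels(vals2, labs2)
  expect_error(roi_snr(f3$v, f3$lm, "cortex"), "zero noise")
})

test_that("gray_white_cnr is signed and scale-invariant with roi_snr", {
  vals <- array(0, c(6, 6, 6)); labs <- array(0L, c(6, 6, 6))
  vals[, , 1] <- 120; labs[, , 1] <- 1L   # cortex
  vals[, , 2] <- 60;  labs[, , 2] <- 2L   # corpus callosum
  set.seed(2)
  nz <- rnorm(36); nz <- (nz - mean(nz)) / sd(nz) * 10
  vals[, , 3] <- nz; labs[, , 3] <- 12L
  f <- mini_labels(vals, labs)
  expect_equal(gray_white_cnr(f$v, f$lm), 6, tolerance = 1e-9)
  # global intensity scaling leaves both metrics unchanged... for CNR the
  # numerator and denominator both scale
  f2 <- mini_labels(vals * 3, labs)
  expect_equal(gray_white_cnr(f2$v, f2$lm), gray_white_cnr(f$v, f$lm),
               tolerance = 1e-9)
  expect_equal(roi_snr(f2$v, f2$lm, "cortex"),
               roi_snr(f$v, f$lm, "cortex"), tolerance = 1e-9)
  # null contrast
  vals[, , 2] <- 120; f3 <- mini_labels(vals, labs)
  expect_equal(gray_white_cnr(f3$v, f3$lm), 0, tolerance = 1e-9)
})

test_that("voxel-volume SNR factor: the ~53x worked example", {
  expect_equal(round(voxel_volume_snr_factor(0.15, 0.04)), 53)
  expect_equal(voxel_volume_snr_factor(c(0.1, 0.1, 0.1),
                                       c(0.1, 0.1, 0.1)), 1)
  expect_equal(voxel_volume_snr_factor(0.08, 0.04), 8, tolerance = 1e-12)
  expect_equal(voxel_volume_snr_factor(0.15, 0.04) *
               voxel_volume_snr_factor(0.04, 0.15), 1, tolerance = 1e-12)
  expect_error(voxel_volume_snr_factor(0, 0.04), "positive")
})

test_that("total_brain_volume: arithmetic, scaling, additivity", {
  labs <- array(0L, c(20, 20, 20))
  labs[1:10, 1:10, 1:10] <- 1L   # 1000 voxels
  v <- tbm_volume(array(0, c(20, 20, 20)), spacing = rep(0.15, 3))
  lm <- tbm_labelmap(labs, c(background = 0L, cortex = 1L), geometry = v)
  expect_equal(total_brain_volume(lm), 1000 * 0.15^3, tolerance = 1e-12)
  expect_equal(total_brain_volume(lm, scale_factors = c(1.02, 1, 1)),
               1000 * 0.15^3 * 1.02, tolerance = 1e-12)
  # additive over disjoint components
  labs2 <- labs; labs2[15:16, 15:16, 15:16] <- 1L
  lm2 <- tbm_labelmap(labs2, c(background = 0L, cortex = 1L),
                      geometry = v)
  expect_equal(total_brain_volume(lm2),
               total_brain_volume(lm) + 8 * 0.15^3, tolerance = 1e-12)
  expect_error(total_brain_volume(array(FALSE, c(2, 2, 2)),
                                  spacing = rep(1, 3)), "empty")
})

test_that("percent_difference reproduces the published SNR contrasts", {
  # in-text percentages recomputed from the printed per-region means
  tab <- rbind(c(14.4, 9.3, 55), c(15.6, 4.2, 271), c(14.2, 10.0, 42),
               c(19.3, 10.8, 79), c(14.8, 10.9, 36), c(11.1, 6.9, 61),
               c(12.4, 7.8, 59))
  for (i in seq_len(nrow(tab)))
    expect_equal(percent_difference(tab[i, 1], tab[i, 2]), tab[i, 3])
  # cerebellum: ex vivo 50% greater than in vivo
  expect_equal(percent_difference(11.4, 7.6), 50)
  expect_equal(percent_difference(7, 7), 0)
  expect_error(percent_difference(5, 0), "positive")
})

test_that("group_volume_contrasts reports both conventions", {
  rep <- data.frame(group = rep(c("WT", "TG"), each = 4),
                    tbv_mm3 = c(rep(500, 4), rep(395, 4)))
  out <- group_volume_contrasts(rep)
  row <- out[out$group_a == "TG" & out$group_b == "WT", ]
  expect_equal(row$pct_smaller, 21, tolerance = 1e-9)
  # equal means -> all zero
  rep2 <- data.frame(group = rep(c("A", "B"), each = 2),
                     tbv_mm3 = rep(7, 4))
  expect_true(all(abs(group_volume_contrasts(rep2)$pct_increase) < 1e-12))
  expect_error(group_volume_contrasts(data.frame(group = "A",
                                                 tbv_mm3 = 1)), ">= 2")
})

test_that("phantom ex vivo CNR is at least 3x the in vivo CNR", {
  spec <- test_spec()
  calib <- cached_calibration()
  iv <- synthesize_subject(spec, "WT", "invivo", 1, calib)
  ev <- synthesize_subject(spec, "WT", "exvivo", 1, calib)
  cnr_iv <- gray_white_cnr(iv$volume, iv$labels)
  cnr_ev <- gray_white_cnr(ev$volume, ev$labels)
  expect_gte(abs(cnr_ev) / abs(cnr_iv), 3)
  # T2-weighted in vivo: white matter brighter than gray -> negative CNR
  expect_lt(cnr_iv, 0)
  expect_gt(cnr_ev, 0)
})
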