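# Linear and non-rigid registration, Jacobian maps, MPD maps, the
# group-wise loop on degenerate input.

test_that("tbm_affine validates rigid orthonormality", {
  expect_silent(tbm_affine(diag(4), "rigid"))
  A <- diag(4); A[1, 1] <- 1.1
  expect_error(tbm_affine(A, "rigid"), "orthonormal")
  expect_silent(tbm_affine(A, "affine"))
  A0 <- diag(4); A0[1:3, 1:3] <- 0
  expect_error(tbm_affine(A0), "singular")
})

test_that("register_linear recovers identity, shifts and scales", {
  tpl <- cached_template("invivo")$volume

  # self-registration: identity within 0.05 voxel, rotation < 0.1 deg
  A <- register_linear(tpl, tpl, dof_class = "rigid")
  expect_lt(max(abs(A$matrix[1:3, 4])) / 0.15, 0.05)
  R <- A$matrix[1:3, 1:3]
  ang <- acos(pmin(1, (sum(diag(R)) - 1) / 2)) * 180 / pi
  expect_lt(ang, 0.1)

  # known 3-voxel x-shift, recovered within 0.1 voxel
  sh <- tpl
  sh$affine[1, 4] <- sh$affine[1, 4] + 3 * 0.15
  sh <- tbm_volume(sh$data, spacing = sh$spacing, affine = sh$affine)
  A2 <- register_linear(sh, tpl, dof_class = "rigid")
  expect_lt(max(abs(A2$matrix[1:3, 4] - c(0.45, 0, 0))) / 0.15, 0.1)

  # known 0.90 per-axis scale (the fixation-shrinkage regime)
  scm <- diag(c(0.9, 0.9, 0.9, 1))
  mv <- tbm_volume(tpl$data, spacing = tpl$spacing * 0.9,
                   affine = scm %*% tpl$affine)
  A3 <- register_linear(mv, tpl, dof_class = "affine")
  expect_lt(max(abs(svd(A3$matrix[1:3, 1:3])$d - 0.9)), 0.01)

  cst <- tbm_volume(array(1, dim(tpl$data)), spacing = tpl$spacing,
                    affine = tpl$affine)
  expect_error(register_linear(cst, tpl), "constant")
})

test_that("register_nonrigid: self-registration stays near identity and
           a known contraction is recovered", {
  tpl <- cached_template("invivo")$volume
  nrr0 <- register_nonrigid(tpl, tpl, max_steps = 20)
  u <- tbmpipe:::bspline_dense(nrr0)
  expect_lt(quantile(sqrt(rowSums(u^2)), 0.99) / 0.15, 0.1)

  # known ~25% contraction of a spherical region
  gw <- tbmpipe:::world_grid(tpl)
  ctr <- c(1.0, -0.4, 0.5); semi <- c(0.8, 0.8, 0.8)
  sph <- tbmpipe:::ell_rho2(gw, ctr, semi) <= 1
  mk <- function(a) tbmpipe:::prim_blob_contract(ctr, semi, a,
                                                 width = 0.55)
  amp <- tbmpipe:::calibrate_amp(mk, gw[sph, , drop = FALSE], 0.25)
  prim <- mk(amp)
  psi <- tbmpipe:::phantom_invert(list(prim), gw)
  mv <- tbm_volume(array(tbmpipe:::sample_world(tpl, psi),
                         dim(tpl$data)),
                   spacing = tpl$spacing, affine = tpl$affine)
  nrr <- register_nonrigid(mv, tpl, max_steps = 60)
  # similarity trace is non-decreasing (improving steps only)
  expect_true(all(diff(attr(nrr, "trace")) >= 0))
  jm <- jacobian_log_det(nrr, reference = tpl, source = "nonrigid_only")
  spha <- array(sph, dim(tpl$data))
  rec <- mean(exp(jm$log_jdet[spha]))
  expect_lt(abs(rec - 0.75), 0.05)
  # transform invertibility in the phantom regime
  expect_gt(min(exp(jm$log_jdet)), 0.1)

  # approximate inverse consistency: swapped roles multiply to ~1
  nrr_b <- register_nonrigid(tpl, mv, max_steps = 60)
  jm_b <- jacobian_log_det(nrr_b, reference = mv,
                           source = "nonrigid_only")
  expect_lt(abs(rec * mean(exp(jm_b$log_jdet[spha])) - 1), 0.1)
})

test_that("jacobian_log_det: identity, affine exactness, uniform scale,
           finite-difference oracle, composition", {
  tpl <- cached_template("invivo")$volume
  id_b <- tbmpipe:::bspline_zero(4, tpl)
  jm <- jacobian_log_det(list(affine = diag(4), bspline = id_b),
                         reference = tpl)
  expect_true(all(jm$log_jdet == 0))

  # any affine: log|det M| everywhere to 1e-9
  set.seed(3)
  M <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
  A <- diag(4); A[1:3, 1:3] <- M
  jm2 <- jacobian_log_det(list(affine = A, bspline = id_b),
                          reference = tpl)
  expect_lt(max(abs(jm2$log_jdet - log(abs(det(M))))), 1e-9)

  # uniform scale s = 0.90^(1/3): log J = log 0.90 within 1e-3
  s <- 0.90^(1 / 3)
  jm3 <- jacobian_log_det(tbm_affine(diag(c(s, s, s, 1))),
                          reference = tpl)
  expect_lt(max(abs(jm3$log_jdet - log(0.90))), 1e-3)

  # random B-spline: analytic derivative vs finite differences
  set.seed(4)
  b <- tbmpipe:::bspline_zero(4, tpl)
  b$coef[] <- rnorm(length(b$coef), 0, 0.03)
  jm4 <- jacobian_log_det(list(affine = diag(4), bspline = b),
                          reference = tpl)
  pts <- tbmpipe:::voxel_grid(dim(tpl$data))
  sel <- sample(nrow(pts), 200)
  h <- 1e-3
  J <- array(0, c(200, 3, 3))
  for (a in 1:3) {
    dp <- matrix(0, 200, 3); dp[, a] <- h
    up <- tbmpipe:::bspline_eval_at(b$coef, 4,
                                    pts[sel, , drop = FALSE] + dp)
    dn <- tbmpipe:::bspline_eval_at(b$coef, 4,
                                    pts[sel, , drop = FALSE] - dp)
    J[, , a] <- (up - dn) / (2 * h) / 0.15   # voxel -> mm (isotropic)
  }
  fd_logdet <- vapply(seq_len(200), function(r)
    log(det(diag(3) + J[r, , ])), numeric(1))
  expect_lt(max(abs(fd_logdet - jm4$log_jdet[sel])), 1e-3)

  # composite = affine o nonrigid: log dets add (product rule)
  jm5 <- jacobian_log_det(list(affine = A, bspline = b),
                          reference = tpl, source = "composite")
  jm6 <- jacobian_log_det(list(affine = A, bspline = b),
                          reference = tpl, source = "nonrigid_only")
  expect_lt(max(abs(jm5$log_jdet -
                    (jm6$log_jdet + log(abs(det(M)))))), 1e-9)

  # folding detection: det <= 0 voxels are flagged, error inside mask
  bad <- tbmpipe:::bspline_zero(4, tpl)
  bad$coef[4:9, 4:9, 4:9, 1] <- 4   # violent fold over a wide support
  jmb <- jacobian_log_det(list(affine = diag(4), bspline = bad),
                          reference = tpl)
  expect_gt(length(jmb$flagged), 0)
  expect_true(all(is.nan(jmb$log_jdet[jmb$flagged])))
  mask <- array(TRUE, dim(tpl$data))
  expect_error(jacobian_log_det(list(affine = diag(4), bspline = bad),
                                reference = tpl, mask = mask),
               "non-invertible")
})

test_that("mean_positional_distance: hand cases and contracts", {
  ref <- rand_volume(c(8, 8, 8))
  z <- zero_field(ref)
  mpd0 <- mean_positional_distance(list(z, z), ref)
  expect_true(all(mpd0$mpd == 0))

  f1 <- tbm_field(array(rep(c(1, 2, 2), each = 512), c(8, 8, 8, 3)),
                  geometry = ref, parts = "nonrigid")
  mpd <- mean_positional_distance(list(f1, z), ref)
  expect_equal(max(abs(mpd$mpd - 1.5)), 0, tolerance = 1e-12)
  expect_equal(mpd$n, 2L)

  # order invariance
  mpd2 <- mean_positional_distance(list(z, f1), ref)
  expect_identical(mpd$mpd, mpd2$mpd)

  # fields with global parts are rejected
  g <- tbm_field(array(0.1, c(8, 8, 8, 3)), geometry = ref,
                 parts = c("global", "nonrigid"))
  expect_error(mean_positional_distance(list(g), ref), "global")
})

test_that("groupwise_register: degenerate identical group, determinism", {
  tpl <- cached_template("invivo")$volume
  imgs <- list(tpl, tpl, tpl)
  gw1 <- groupwise_register(imgs, n_affine = 1, n_nrr = 1, seed = 7,
                            nrr_steps = 5)
  expect_equal(nrow(gw1$log), 2L)   # n_affine + n_nrr entries
  for (tr in gw1$transforms) {
    expect_lt(max(abs(tr$affine$matrix - diag(4))), 0.05 * 0.15)
    u <- tbmpipe:::bspline_dense(tr$bspline)
    expect_lt(max(sqrt(rowSums(u^2))) / 0.15, 0.1)
  }
  # the average equals the input up to interpolation of near-identity
  # transforms (sub-0.1-voxel resampling blur)
  expect_gt(cor(as.vector(gw1$average_image$data), as.vector(tpl$data)),
            0.999)
  expect_lt(mean(abs(gw1$average_image$data - tpl$data)) /
              mean(abs(tpl$data)), 0.01)

  gw2 <- groupwise_register(imgs, n_affine = 1, n_nrr = 1, seed = 7,
                            nrr_steps = 5)
  expect_identical(gw1$target_index, gw2$target_index)
  expect_identical(gw1$average_image$data, gw2$average_image$data)

  expect_error(groupwise_register(list(tpl, tpl)), "at least 3")
})
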