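# Containers, NIfTI round trips, reorientation, resampling.

test_that("NIfTI write/read round-trips data, spacing and affine", {
  v <- rand_volume(c(16, 16, 16), spacing = c(0.15, 0.15, 0.15), seed = 42)
  for (ext in c(".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_nifti(v, f, precision = "double")
    v2 <- read_nifti(f)
    expect_identical(dim(v2$data), dim(v$data))
    expect_equal(v2$data, v$data, tolerance = 0)
    expect_lt(max(abs(v2$affine - v$affine)), 1e-6)
    expect_equal(v2$spacing, c(0.15, 0.15, 0.15), tolerance = 1e-6)
    unlink(f)
  }
})

test_that("read_nifti rejects missing, 4D and non-finite input", {
  expect_error(read_nifti(tempfile(fileext = ".nii")), "exist")
  # a 4D file: write a field, then try to read it as a volume
  fld <- zero_field(rand_volume(c(6, 6, 6)))
  f <- tempfile(fileext = ".nii")
  write_nifti(fld, f)
  expect_error(read_nifti(f), "3D")
  unlink(f)
  v <- rand_volume(c(6, 6, 6))
  v$data[2, 2, 2] <- NaN
  f2 <- tempfile(fileext = ".nii")
  tbmpipe:::write_nifti_raw(v$data, v$affine, f2, 64L)
  expect_error(read_nifti(f2), "finite")
  unlink(f2)
})

test_that("displacement fields round-trip as 4D NIfTI", {
  v <- rand_volume(c(8, 9, 10))
  set.seed(3)
  fld <- tbm_field(array(rnorm(8 * 9 * 10 * 3, 0, 0.1), c(8, 9, 10, 3)),
                   geometry = v)
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(fld, f, precision = "double")
  fld2 <- read_field(f)
  expect_equal(fld2$vectors, fld$vectors, tolerance = 1e-12)
  unlink(f)
})

test_that("volume invariants are enforced", {
  expect_error(tbm_volume(array(0, c(4, 4))), "3D")
  expect_error(tbm_volume(array(0, c(4, 4, 4)), spacing = c(0, 1, 1)),
               "positive|spacing")
  aff <- diag(4); aff[1, 1] <- 0
  expect_error(tbm_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1),
                          affine = aff), "singular")
  # spacing must match affine column norms
  aff2 <- diag(c(2, 1, 1, 1))
  expect_error(tbm_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1),
                          affine = aff2), "spacing")
})

test_that("reorient is an exact permutation/flip preserving world coords", {
  set.seed(2)
  d <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  aff <- diag(c(-0.15, 0.15, -0.15, 1)); aff[1:3, 4] <- c(2, -1, 3)
  v <- tbm_volume(d, spacing = rep(0.15, 3), affine = aff)

  expect_identical(reorient(v, v$orientation)$data, v$data)

  r <- reorient(v, "RAS")
  expect_equal(r$orientation, "RAS")
  expect_identical(sort(as.vector(r$data)), sort(as.vector(v$data)))
  # marked voxel keeps its world coordinate
  w1 <- tbmpipe:::vox2world(v$affine, matrix(c(1, 2, 3), 1))
  pos <- which(r$data == d[2, 3, 4], arr.ind = TRUE)
  w2 <- tbmpipe:::vox2world(r$affine, pos - 1)
  expect_lt(max(abs(w1 - w2)), 1e-6)
  # involution restores everything exactly
  rr <- reorient(r, v$orientation)
  expect_identical(rr$data, v$data)
  expect_lt(max(abs(rr$affine - v$affine)), 1e-12)

  expect_error(reorient(v, "RRS"), "repeats")
  expect_error(reorient(v, "XYZ"), "bad orientation")
})

test_that("resample with identity/constant-shift fields behaves exactly", {
  v <- rand_volume(c(12, 12, 12))
  # identity field
  out <- resample(v, zero_field(v))
  expect_equal(out$data, v$data, tolerance = 1e-12)

  # +1 voxel x-shift on a linear ramp: interior shifts by exactly one voxel
  ramp <- tbm_volume(array(rep(seq_len(12), 12 * 12), c(12, 12, 12)),
                     spacing = rep(0.15, 3))
  shift <- zero_field(ramp)
  shift$vectors[, , , 1] <- 0.15   # one voxel in world mm
  shift$parts <- "nonrigid"
  out2 <- resample(ramp, shift)
  expect_equal(out2$data[2:10, , ], ramp$data[3:11, , ], tolerance = 1e-9)

  # nearest-neighbour label resampling conserves the label set
  lm <- tbm_labelmap(array(sample(0:3, 12^3, TRUE), c(12, 12, 12)),
                     c(background = 0L, a = 1L, b = 2L, c = 3L),
                     geometry = v)
  set.seed(5)
  fld <- tbm_field(array(rnorm(12^3 * 3, 0, 0.05), c(12, 12, 12, 3)),
                   geometry = v)
  out3 <- resample(lm, fld)
  expect_true(all(unique(as.vector(out3$labels)) %in% 0:3))
})

test_that("label map and field invariants hold", {
  v <- rand_volume(c(6, 6, 6))
  expect_error(tbm_labelmap(array(2L, c(6, 6, 6)), c(background = 0L,
                                                     a = 1L),
                            geometry = v), "legend")
  expect_error(tbm_field(array(1, c(6, 6, 6, 3)), geometry = v,
                         parts = character()), "identically zero")
  expect_error(tbm_field(array(0, c(6, 6, 6, 2)), geometry = v), "3")
  expect_silent(tbm_field(array(0, c(6, 6, 6, 3)), geometry = v,
                          parts = character()))
})

test_that("manifest round trip and validation", {
  d <- tempfile(); dir.create(d)
  v <- rand_volume(c(6, 6, 6))
  lm <- tbm_labelmap(array(0L, c(6, 6, 6)), c(background = 0L),
                     geometry = v)
  write_nifti(v, file.path(d, "s1.nii"))
  write_nifti(lm, file.path(d, "s1_lab.nii"))
  m <- data.frame(subject_id = "s1", group = "WT", modality = "invivo",
                  volume_path = "s1.nii", labelmap_path = "s1_lab.nii",
                  rng_seed = 1L)
  write_manifest(m, file.path(d, "manifest.csv"))
  m2 <- read_manifest(file.path(d, "manifest.csv"))
  expect_s3_class(m2, "cohort_manifest")
  expect_equal(nrow(m2), 1L)
  # duplicate subject x modality rejected
  m3 <- rbind(m, m)
  write_manifest(m3, file.path(d, "manifest2.csv"))
  expect_error(read_manifest(file.path(d, "manifest2.csv")), "unique")
  unlink(d, recursive = TRUE)
})

test_that("transform and model serializers round-trip", {
  d <- tempfile(); dir.create(d)
  # affine as text
  set.seed(8)
  M <- diag(4); M[1:3, 1:3] <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
  M[1:3, 4] <- rnorm(3)
  A <- tbm_affine(M, "affine")
  f <- file.path(d, "aff.txt")
  write_affine(A, f)
  A2 <- read_affine(f)
  expect_lt(max(abs(A2$matrix - M)), 1e-12)
  expect_equal(A2$dof_class, "affine")

  # B-spline as NIfTI + JSON header
  ref <- rand_volume(c(12, 12, 12), seed = 9)
  b <- tbmpipe:::bspline_zero(4, ref)
  b$coef[] <- rnorm(length(b$coef), 0, 0.1)
  attr(b, "prealign") <- M
  fb <- file.path(d, "bspl.nii")
  write_bspline(b, fb)
  b2 <- read_bspline(fb)
  expect_equal(b2$coef, b$coef, tolerance = 1e-12)
  expect_equal(b2$cps, 4)
  expect_lt(max(abs(attr(b2, "prealign") - M)), 1e-12)
  expect_equal(b2$reference$dim, tbmpipe:::vol_dim(ref))

  # standardization model as JSON
  tpl <- cached_template("invivo")
  set.seed(10)
  n1 <- tbm_volume(tpl$volume$data +
                     array(rnorm(length(tpl$volume$data), 0, 4),
                           dim(tpl$volume$data)),
                   spacing = tpl$volume$spacing,
                   affine = tpl$volume$affine)
  m <- fit_standardization(list(n1, tpl$volume),
                           list(tpl$labels, tpl$labels))
  fm <- file.path(d, "model.json")
  write_std_model(m, fm)
  m2 <- read_std_model(fm)
  expect_equal(m2$standard_scale, m$standard_scale, tolerance = 1e-12)
  s1 <- apply_standardization(n1, tpl$labels, m)
  s2 <- apply_standardization(n1, tpl$labels, m2)
  expect_equal(s1$data, s2$data, tolerance = 1e-9)
  unlink(d, recursive = TRUE)
})
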