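# Multi-iteration group-wise registration: rigid alignment to a randomly
# chosen target, iterated affine registration to the evolving intensity
# average, then iterated non-rigid refinement, after which the average
# approaches the group's mean morphology.

make_average <- function(vols, ref) {
  acc <- Reduce(`+`, lapply(vols, function(v)
    if (is.array(v)) v else vol_data(v)))
  tbm_volume(acc / length(vols), spacing = ref$spacing, affine = ref$affine)
}

mean_gradient_magnitude <- function(v) {
  d <- vol_data(v)
  gx <- d[-1, , , drop = FALSE] - d[-dim(d)[1], , , drop = FALSE]
  gy <- d[, -1, , drop = FALSE] - d[, -dim(d)[2], , drop = FALSE]
  gz <- d[, , -1, drop = FALSE] - d[, , -dim(d)[3], drop = FALSE]
  (mean(abs(gx)) + mean(abs(gy)) + mean(abs(gz))) / 3
}

#' Group-wise registration to an evolving average
#'
#' Schedule: all subjects are rigidly aligned to a randomly chosen target
#' member of the group; then `n_affine` iterations of affine registration
#' to the current intensity average (re-averaging after each); then
#' `n_nrr` iterations of B-spline non-rigid registration to the evolving
#' average (warm-started between iterations, re-averaging after each).
#' The iteration log records one similarity value per affine/NRR
#' iteration plus the average-image sharpness (mean gradient magnitude).
#'
#' @param images list of >= 3 [tbm_volume()]s of a common modality.
#' @param n_affine,n_nrr iteration counts of the two stages.
#' @param seed RNG seed controlling the random target choice; the whole
#'   run is deterministic given (images, parameters, seed).
#' @param control_spacing_vox B-spline control spacing (voxels).
#' @param bending_weight FFD bending-energy penalty weight.
#' @param nrr_steps gradient steps per subject per NRR iteration.
#' @param linear_maxit Nelder-Mead budget per pyramid level.
#' @return list of class `groupwise_result`: `average_image`,
#'   `transforms` (per subject: list(affine, bspline), average space ->
#'   subject), `log` (stage, iter, similarity, sharpness),
#'   `target_index`.
#' @export
groupwise_register <- function(images, n_affine = 4L, n_nrr = 20L,
                               seed = 1L, control_spacing_vox = 4L,
                               bending_weight = 0.001, nrr_steps = 15L,
                               nbins = 64L,
                               linear_maxit = c(250L, 150L, 100L),
                               linear_restarts = 1L,
                               linear_polish = 10L) {
  n <- length(images)
  if (n < 3) stop("group-wise registration needs at least 3 images")
  target_idx <- with_seed(seed, function() sample.int(n, 1L))
  ref <- images[[target_idx]]

  affines <- vector("list", n)
  warped <- vector("list", n)
  for (i in seq_len(n)) {
    A <- tryCatch(
      register_linear(images[[i]], ref, dof_class = "rigid",
                      maxit = linear_maxit, restarts = linear_restarts,
                      polish_maxit = linear_polish),
      error = function(e) stop("rigid stage, subject ", i, ": ",
                               conditionMessage(e)))
    affines[[i]] <- A
    warped[[i]] <- resample_affine(images[[i]], ref, A$matrix)
  }
  average <- make_average(warped, ref)
  log <- list()

  for (it in seq_len(n_affine)) {
    sims <- numeric(n)
    for (i in seq_len(n)) {
      p0 <- attr(affines[[i]], "params")
      p0 <- c(p0, rep(0, 12 - length(p0)))
      A <- tryCatch(
        register_linear(images[[i]], average, dof_class = "affine",
                        init_params = p0, maxit = linear_maxit,
                        restarts = linear_restarts,
                        polish_maxit = linear_polish),
        error = function(e) stop("affine iteration ", it, ", subject ", i,
                                 ": ", conditionMessage(e)))
      affines[[i]] <- A
      warped[[i]] <- resample_affine(images[[i]], average, A$matrix)
      sims[i] <- attr(A, "ncc")
    }
    average <- make_average(warped, average)
    log[[length(log) + 1L]] <- data.frame(
      stage = "affine", iter = it, similarity = mean(sims),
      sharpness = mean_gradient_magnitude(average))
  }

  bspl <- vector("list", n)
  for (it in seq_len(n_nrr)) {
    sims <- numeric(n)
    for (i in seq_len(n)) {
      bspl[[i]] <- tryCatch(
        register_nonrigid(images[[i]], average,
                          control_spacing_vox = control_spacing_vox,
                          bending_weight = bending_weight,
                          init_affine = affines[[i]], init = bspl[[i]],
                          max_steps = nrr_steps, nbins = nbins),
        error = function(e) stop("NRR iteration ", it, ", subject ", i,
                                 ": ", conditionMessage(e)))
      warped[[i]] <- resample_composite(images[[i]], average,
                                        affines[[i]], bspl[[i]])
      sims[i] <- attr(bspl[[i]], "similarity")
    }
    average <- make_average(warped, average)
    log[[length(log) + 1L]] <- data.frame(
      stage = "nrr", iter = it, similarity = mean(sims),
      sharpness = mean_gradient_magnitude(average))
  }

  transforms <- lapply(seq_len(n), function(i) {
    b <- bspl[[i]]
    if (is.null(b)) b <- bspline_zero(control_spacing_vox, average)
    attr(b, "prealign") <- affines[[i]]$matrix
    list(affine = affines[[i]], bspline = b)
  })
  structure(list(average_image = average, transforms = transforms,
                 log = do.call(rbind, log), target_index = target_idx),
            class = "groupwise_result")
}

#' @export
print.groupwise_result <- function(x, ...) {
  cat(sprintf("<groupwise_result: %d subjects, target %d, %d iterations>\n",
              length(x$transforms), x$target_index,
              if (is.null(x$log)) 0L else nrow(x$log)))
  invisible(x)
}
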