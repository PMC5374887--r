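# Jacobian determinant maps and mean positional distance maps.

#' Log Jacobian determinant map of a transform
#'
#' For the composite transform T(y) = A(y + u(y)) from average space to a
#' subject, the spatial Jacobian is M_A (I + Du(y)); its log determinant is
#' the voxel's relative volume in the subject: log J > 0 where the subject
#' is locally larger than the average. The B-spline derivative Du is
#' analytic (tensor-product basis derivatives), not a finite difference.
#'
#' @param t a `tbm_bspline` (with a `prealign` attribute), `tbm_affine`, or
#'   list(affine =, bspline =).
#' @param reference reference (average-space) geometry; defaults to the
#'   B-spline's own reference.
#' @param source "composite" includes the affine's log |det M_A|;
#'   "nonrigid_only" uses just the B-spline part.
#' @param mask optional logical array; non-invertible voxels (det <= 0,
#'   set to NaN) are only tolerated outside it (error if more than 0.1%
#'   of the mask is non-invertible).
#' @return object of class `jacobian_map`: `log_jdet` array + geometry +
#'   `source` + `flagged` (indices of det <= 0 voxels).
#' @export
jacobian_log_det <- function(t, reference = NULL,
                             source = c("composite", "nonrigid_only"),
                             mask = NULL) {
  source <- match.arg(source)
  if (inherits(t, "tbm_affine")) t <- list(affine = t, bspline = NULL)
  else if (inherits(t, "tbm_bspline"))
    t <- list(affine = attr(t, "prealign"), bspline = t)
  A <- if (is.null(t$affine)) diag(4) else
    if (inherits(t$affine, "tbm_affine")) t$affine$matrix else t$affine
  ref <- if (!is.null(reference)) geometry_of(reference) else
    t$bspline$reference
  if (is.null(ref)) stop("a reference geometry is required")
  n <- prod(ref$dim)
  if (is.null(t$bspline)) {
    detF <- rep(1, n)
  } else {
    if (!all(t$bspline$reference$dim == ref$dim))
      stop("transform is not defined over the reference grid")
    Jv <- c_ffd_jac(as.double(t$bspline$coef),
                    as.integer(dim(t$bspline$coef)[1:3]),
                    as.integer(ref$dim), as.double(t$bspline$cps))
    # du/dworld = du/dvox %*% inv(A3_ref); then F = I + du/dworld
    iA <- solve(ref$affine[1:3, 1:3])
    F <- matrix(0, n, 9)
    for (d in 1:3) for (b in 1:3) {
      col <- (b - 1) * 3 + d
      acc <- 0
      for (a in 1:3) acc <- acc + Jv[, (a - 1) * 3 + d] * iA[a, b]
      F[, col] <- acc + as.double(d == b)
    }
    detF <- F[, 1] * (F[, 5] * F[, 9] - F[, 8] * F[, 6]) -
            F[, 4] * (F[, 2] * F[, 9] - F[, 8] * F[, 3]) +
            F[, 7] * (F[, 2] * F[, 6] - F[, 5] * F[, 3])
  }
  logj <- rep(NaN, n)
  pos <- detF > 0
  logj[pos] <- log(detF[pos])
  if (source == "composite")
    logj <- logj + log(abs(det(A[1:3, 1:3])))
  flagged <- which(!pos)
  if (!is.null(mask)) {
    bad <- sum(!pos & as.vector(mask))
    if (bad > 0.001 * sum(mask))
      stop("non-invertible transform: ", bad,
           " voxels with det J <= 0 inside the mask")
  }
  structure(list(log_jdet = array(logj, ref$dim), spacing = ref$spacing,
                 affine = ref$affine, source = source, flagged = flagged),
            class = "jacobian_map")
}

#' @export
print.jacobian_map <- function(x, ...) {
  cat(sprintf("<jacobian_map %s (%s), range [%.3g, %.3g]>\n",
              paste(dim(x$log_jdet), collapse = "x"), x$source,
              min(x$log_jdet, na.rm = TRUE), max(x$log_jdet, na.rm = TRUE)))
  invisible(x)
}

jacobian_as_volume <- function(jm) {
  tbm_volume(jm$log_jdet, spacing = jm$spacing, affine = jm$affine)
}

#' Mean positional distance map
#'
#' Per-voxel mean Euclidean norm (mm) of the non-rigid displacement
#' vectors of N subjects, in a common reference space: the local tissue
#' distortion left after global rigid+affine differences are excluded.
#' Fields carrying a global component are rejected.
#'
#' @param fields list of [tbm_field()]s with parts excluding "global".
#' @param reference common reference geometry; fields on other grids are
#'   resampled component-wise (linear) onto it.
#' @return list of class `mpd_map`: `mpd` array (mm), geometry, `n`.
#' @export
mean_positional_distance <- function(fields, reference) {
  if (!length(fields)) stop("no fields given")
  ref <- geometry_of(reference)
  acc <- numeric(prod(ref$dim))
  for (f in fields) {
    if ("global" %in% f$parts)
      stop("MPD is defined on non-rigid displacements only; ",
           "field contains global components")
    if (all(f$spacing == ref$spacing) &&
        max(abs(f$affine - ref$affine)) < 1e-9 &&
        all(dim(f$vectors)[1:3] == ref$dim)) {
      vmat <- matrix(f$vectors, ncol = 3)
    } else {
      pts <- vox2world(ref$affine, voxel_grid(ref$dim))
      vox <- world2vox(f$affine, pts)
      vmat <- sapply(1:3, function(d)
        c_interp3(as.double(f$vectors[, , , d]),
                  as.integer(dim(f$vectors)[1:3]), vox, 0L, 0, FALSE))
    }
    acc <- acc + sqrt(rowSums(vmat^2))
  }
  structure(list(mpd = array(acc / length(fields), ref$dim),
                 spacing = ref$spacing, affine = ref$affine,
                 n = length(fields)),
            class = "mpd_map")
}
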