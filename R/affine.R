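# Linear (rigid / affine) registration by direct maximization of
# normalized cross-correlation.
#
# An affine transform maps fixed-space world coordinates (mm) to
# moving-space world coordinates; resampling the moving image at A %*% y
# over the fixed grid brings it into fixed space.

#' Affine transform (world mm)
#' @param matrix 4x4 matrix, fixed world -> moving world.
#' @param dof_class "rigid" (6 dof) or "affine" (12 dof).
#' @export
tbm_affine <- function(matrix = diag(4), dof_class = "affine") {
  if (abs(det(matrix[1:3, 1:3])) < 1e-12) stop("affine is singular")
  if (dof_class == "rigid") {
    M <- matrix[1:3, 1:3]
    if (max(abs(t(M) %*% M - diag(3))) > 1e-6 || det(M) < 0)
      stop("rigid transform must have an orthonormal, det +1 linear part")
  }
  structure(list(matrix = matrix, dof_class = dof_class),
            class = "tbm_affine")
}

#' @export
print.tbm_affine <- function(x, ...) {
  cat(sprintf("<tbm_affine (%s)>\n", x$dof_class))
  print(signif(x$matrix, 5))
  invisible(x)
}

# parameter vector -> 4x4 matrix; rotations about `centre` (world mm)
# p = (tx ty tz, rx ry rz[, log-sx log-sy log-sz, hxy hxz hyz])
params_to_affine <- function(p, centre, dof_class) {
  rot1 <- function(a, ax) {
    R <- diag(3); c_ <- cos(a); s_ <- sin(a)
    ij <- setdiff(1:3, ax)
    R[ij[1], ij[1]] <- c_; R[ij[2], ij[2]] <- c_
    R[ij[1], ij[2]] <- -s_; R[ij[2], ij[1]] <- s_
    R
  }
  M <- rot1(p[4], 1) %*% rot1(p[5], 2) %*% rot1(p[6], 3)
  if (dof_class == "affine") {
    S <- diag(exp(p[7:9]))
    H <- diag(3); H[1, 2] <- p[10]; H[1, 3] <- p[11]; H[2, 3] <- p[12]
    M <- M %*% S %*% H
  }
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- centre - M %*% centre + p[1:3]
  A
}

intensity_centroid <- function(v) {
  w <- world_grid(v)
  d <- pmax(as.vector(vol_data(v)), 0)
  s <- sum(d)
  if (s <= 0) return(colMeans(w))
  colSums(w * d) / s
}

# every-s-th-voxel view of a volume (pure subsampling, for similarity
# evaluation only)
stride_view <- function(v, s) {
  d <- vol_dim(v)
  idx <- lapply(d, function(n) seq(1L, n, by = s))
  dat <- vol_data(v)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  aff <- v$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * s
  tbm_volume(dat, spacing = v$spacing * s, affine = aff)
}

ncc_value <- function(moving, fixed, A) {
  warped <- resample_affine(moving, fixed, A, na_outside = TRUE)
  ok <- is.finite(warped)
  if (sum(ok) < 0.2 * length(warped)) return(NA_real_)
  a <- warped[ok]; b <- vol_data(fixed)[ok]
  if (sd(a) < 1e-12 || sd(b) < 1e-12) return(NA_real_)
  cor(a, b)
}

#' Linear registration by NCC maximization
#'
#' Direct continuous optimization (Nelder-Mead over a multi-resolution
#' pyramid) of normalized cross-correlation; 6 dof for rigid, 12 (adding
#' per-axis log-scales and shears) for affine. The returned transform is
#' guaranteed not to be worse than the initialization (NCC(after) >=
#' NCC(before) - 1e-9).
#'
#' @param moving,fixed [tbm_volume()]s with overlapping fields of view.
#' @param dof_class "rigid" or "affine".
#' @param similarity only "NCC".
#' @param init_params optional starting parameter vector
#'   (tx ty tz rx ry rz [log-scales, shears]); defaults to an intensity
#'   centroid alignment.
#' @param max_levels pyramid depth.
#' @param maxit Nelder-Mead budget per level (coarse to fine).
#' @param restarts simplex restarts per level.
#' @param polish_maxit BFGS iterations for the final polish.
#' @return a [tbm_affine()] with attributes `params` and `ncc`.
#' @export
register_linear <- function(moving, fixed, dof_class = c("affine", "rigid"),
                            similarity = "NCC", init_params = NULL,
                            max_levels = 3L, maxit = c(300L, 200L, 150L),
                            restarts = 2L, polish_maxit = 40L) {
  dof_class <- match.arg(dof_class)
  if (similarity != "NCC") stop("only NCC is supported for linear stages")
  if (sd(vol_data(fixed)) < 1e-12 || sd(vol_data(moving)) < 1e-12)
    stop("constant image: linear registration is undefined")
  npar <- if (dof_class == "rigid") 6L else 12L
  centre <- intensity_centroid(fixed)
  p0 <- rep(0, npar)
  if (!is.null(init_params)) p0[seq_along(init_params)] <- init_params
  else p0[1:3] <- intensity_centroid(moving) - centre

  # pyramid, coarse to fine
  pyr_f <- list(fixed); pyr_m <- list(moving)
  while (length(pyr_f) < max_levels && min(vol_dim(pyr_f[[1]])) >= 24) {
    pyr_f <- c(list(downsample2(pyr_f[[1]])), pyr_f)
    pyr_m <- c(list(downsample2(pyr_m[[1]])), pyr_m)
  }
  maxit <- rep(maxit, length.out = length(pyr_f))
  parscale <- c(rep(max(fixed$spacing) * 2, 3), rep(0.05, 3),
                rep(0.05, 6))[seq_len(npar)]
  p <- p0
  for (lev in seq_along(pyr_f)) {
    f <- pyr_f[[lev]]; m <- pyr_m[[lev]]
    if (prod(vol_dim(f)) > 50000) f <- stride_view(f, 2L)
    obj <- function(pp) {
      v <- ncc_value(m, f, params_to_affine(pp, centre, dof_class))
      if (!is.finite(v)) 1 else -v
    }
    for (restart in seq_len(restarts)) {
      fit <- optim(p, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit[lev], reltol = 1e-8,
                                  parscale = parscale))
      if (fit$value <= obj(p)) p <- fit$par
      if (fit$convergence == 0 && restart > 1) break
    }
  }
  # gradient-based polish on the finest (strided) level
  f_pol <- if (prod(vol_dim(fixed)) > 50000) stride_view(fixed, 2L)
           else fixed
  obj_pol <- function(pp) {
    v <- ncc_value(moving, f_pol, params_to_affine(pp, centre, dof_class))
    if (!is.finite(v)) 1 else -v
  }
  fit <- tryCatch(
    optim(p, obj_pol, method = "BFGS",
          control = list(maxit = polish_maxit, reltol = 1e-10,
                         parscale = parscale / 10)),
    error = function(e) NULL)
  if (!is.null(fit) && fit$value <= obj_pol(p)) p <- fit$par

  ncc0 <- ncc_value(moving, fixed, params_to_affine(p0, centre, dof_class))
  ncc1 <- ncc_value(moving, fixed, params_to_affine(p, centre, dof_class))
  if (!is.finite(ncc1) || (is.finite(ncc0) && ncc1 < ncc0 - 1e-9)) p <- p0
  out <- tbm_affine(params_to_affine(p, centre, dof_class), dof_class)
  attr(out, "params") <- p
  attr(out, "ncc") <- max(ncc0, ncc1, na.rm = TRUE)
  out
}
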