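# Non-rigid registration: cubic B-spline free-form deformation driven by
# normalized mutual information (Studholme variant, 64-bin joint histogram
# with a cubic Parzen window on the moving intensities), optimized by
# gradient ascent with an adaptive step and an optional bending-energy
# penalty on the control-point grid.

#' B-spline free-form deformation transform
#'
#' Control-point displacements (mm, world axes) on a regular grid over the
#' reference image; the dense displacement at any voxel is the cubic
#' B-spline tensor-product interpolation of the coefficients. Together
#' with a linear pre-alignment A this forms the composite transform
#' T(y) = A(y + u(y)) from reference (fixed/average) space to the moving
#' subject.
#'
#' @param coef 4D array (ncx, ncy, ncz, 3) of coefficients, mm.
#' @param control_spacing_vox control-point spacing in reference voxels
#'   (>= 2).
#' @param reference reference geometry (a `tbm_volume` or its geometry).
#' @export
tbm_bspline <- function(coef, control_spacing_vox, reference) {
  if (control_spacing_vox < 2) stop("control spacing must be >= 2 voxels")
  dims <- vol_dim(reference)
  need <- floor((dims - 1) / control_spacing_vox) + 4
  if (!all(dim(coef)[1:3] == need) || dim(coef)[4] != 3)
    stop("coefficient grid must be ", paste(need, collapse = "x"), "x3")
  structure(list(coef = coef, cps = control_spacing_vox,
                 reference = geometry_of(reference)),
            class = "tbm_bspline")
}

bspline_zero <- function(control_spacing_vox, reference) {
  dims <- vol_dim(reference)
  need <- floor((dims - 1) / control_spacing_vox) + 4
  tbm_bspline(array(0, c(need, 3)), control_spacing_vox, reference)
}

# dense displacement (N x 3, mm) of a B-spline transform on its grid
bspline_dense <- function(t) {
  c_ffd_dense(as.double(t$coef), as.integer(dim(t$coef)[1:3]),
              as.integer(t$reference$dim), as.double(t$cps))
}

# displacement at arbitrary (possibly off-grid) 0-based voxel coordinates
bspline_eval_at <- function(coef, cps, pts_vox) {
  bw <- function(tt) cbind((1 - tt)^3, 4 - 6 * tt^2 + 3 * tt^3,
                           1 + 3 * tt + 3 * tt^2 - 3 * tt^3, tt^3) / 6
  cd <- dim(coef)[1:3]
  s <- pts_vox / cps
  i0 <- floor(s)
  W <- lapply(1:3, function(ax) bw(s[, ax] - i0[, ax]))
  out <- matrix(0, nrow(pts_vox), 3)
  for (c3 in 0:3) for (c2 in 0:3) for (c1 in 0:3) {
    xx <- i0[, 1] + c1; yy <- i0[, 2] + c2; zz <- i0[, 3] + c3
    ok <- xx >= 0 & xx < cd[1] & yy >= 0 & yy < cd[2] & zz >= 0 & zz < cd[3]
    if (!any(ok)) next
    w <- W[[1]][, c1 + 1] * W[[2]][, c2 + 1] * W[[3]][, c3 + 1]
    idx <- (xx + cd[1] * (yy + cd[2] * zz))[ok] + 1
    for (d in 1:3) {
      comp <- coef[, , , d]
      out[ok, d] <- out[ok, d] + w[ok] * comp[idx]
    }
  }
  out
}

# discrete bending energy of the coefficient grid (mean squared second
# difference along each axis) and its gradient
bend_energy <- function(coef) {
  val <- 0; grad <- array(0, dim(coef))
  n <- 0
  for (ax in 1:3) {
    d <- dim(coef)[ax]
    if (d < 3) next
    idx <- function(sh) {
      i <- lapply(dim(coef), seq_len)
      i[[ax]] <- seq_len(d - 2) + sh
      do.call(`[`, c(list(coef), i, list(drop = FALSE)))
    }
    d2 <- idx(0) - 2 * idx(1) + idx(2)
    val <- val + sum(d2^2)
    n <- n + length(d2)
    pad <- function(sh) {
      g <- array(0, dim(coef))
      i <- lapply(dim(coef), seq_len)
      i[[ax]] <- seq_len(d - 2) + sh
      do.call(`[<-`, c(list(g), i, list(value = d2)))
    }
    grad <- grad + 2 * (pad(0) - 2 * pad(1) + pad(2))
  }
  if (n == 0) return(list(value = 0, grad = grad))
  list(value = val / n, grad = grad / n)
}

scale_to_bins <- function(x, lo, hi, nbins, pad) {
  rng <- hi - lo
  if (rng <= 0) stop("degenerate joint histogram (constant image)")
  pmin(pmax((x - lo) / rng * (nbins - 1 - 2 * pad) + pad, pad),
       nbins - 1 - pad)
}

# NMI (and gradient wrt coefficients) of fixed vs moving warped by
# T(y) = L(y + u(y)); moving sampled at inv(Am) T(y).
# Both images are lightly Gaussian-smoothed (0.7 voxel) first: without
# this, grid-aligned sampling creates a spurious NMI maximum at the
# identity that traps sub-voxel deformations (the classic interpolation
# artifact of histogram-based similarity on matching grids).
nmi_state <- function(fixed, moving, L, nbins, presmooth_vox = 0.7,
                      margin_vox = 5) {
  fd <- gaussian_smooth(vol_data(fixed), presmooth_vox)
  md <- gaussian_smooth(vol_data(moving), presmooth_vox)
  fb <- scale_to_bins(as.double(fd), min(fd), max(fd), nbins, 0)
  mb <- scale_to_bins(as.double(md), min(md), max(md), nbins, 1)
  G <- solve(moving$affine) %*% L
  # freeze the evaluation voxel set: fixed voxels whose linear mapping
  # lands well inside the moving grid. Otherwise voxels on the domain
  # boundary enter/leave the joint histogram as the deformation moves,
  # making the similarity discontinuous exactly at the identity.
  q <- vox2world(G %*% fixed$affine, voxel_grid(vol_dim(fixed)))
  md3 <- vol_dim(moving)
  inside <- q[, 1] >= margin_vox & q[, 1] <= md3[1] - 1 - margin_vox &
            q[, 2] >= margin_vox & q[, 2] <= md3[2] - 1 - margin_vox &
            q[, 3] >= margin_vox & q[, 3] <= md3[3] - 1 - margin_vox
  fb[!inside] <- NA_real_
  list(fb = fb, fdims = as.integer(vol_dim(fixed)), Af = fixed$affine,
       mb = mb, mdims = as.integer(md3),
       G = G, nbins = as.integer(nbins))
}

nmi_eval <- function(st, coef, cps, want_grad) {
  c_nmi_grad(st$fb, st$fdims, st$mb, st$mdims, st$Af, st$G,
             as.double(coef), as.integer(dim(coef)[1:3]),
             as.double(cps), st$nbins, want_grad)
}

#' Non-rigid B-spline registration by NMI gradient ascent
#'
#' Optimizes the control-point displacements of a cubic B-spline FFD to
#' maximize normalized mutual information between the fixed image and the
#' moving image warped through the composite transform L(y + u(y)), where
#' L is the linear pre-alignment. Coarse-to-fine: an initial pass at twice
#' the control spacing seeds the requested grid (unless warm-started with
#' `init`). Only improving steps are accepted, so the similarity is
#' non-decreasing over iterations.
#'
#' @param moving,fixed [tbm_volume()]s; `moving` need not share the fixed
#'   grid (it is sampled through its own affine).
#' @param control_spacing_vox control-point spacing (reference voxels).
#' @param similarity only "NMI".
#' @param bending_weight weight of the coefficient bending-energy penalty.
#' @param init_affine linear pre-alignment (fixed world -> moving world).
#' @param init optional `tbm_bspline` warm start (skips the coarse pass).
#' @param max_steps gradient steps per level.
#' @param nbins joint histogram size.
#' @return a [tbm_bspline()] with attributes `prealign` (the L used),
#'   `similarity` (final NMI) and `trace` (NMI per accepted step).
#' @export
register_nonrigid <- function(moving, fixed, control_spacing_vox = 4L,
                              similarity = "NMI", bending_weight = 0.001,
                              init_affine = NULL, init = NULL,
                              max_steps = 30L, nbins = 64L) {
  if (similarity != "NMI") stop("only NMI is supported for NRR")
  L <- if (is.null(init_affine)) diag(4) else
    if (inherits(init_affine, "tbm_affine")) init_affine$matrix else
      init_affine
  sp <- min(fixed$spacing)

  ascend <- function(st, coef, cps, steps) {
    ev <- nmi_eval(st, coef, cps, TRUE)
    if (!is.finite(ev$value)) stop("degenerate joint histogram")
    be <- bend_energy(coef)
    obj <- ev$value - bending_weight * be$value
    grad <- array(ev$grad, dim(coef)) - bending_weight * be$grad
    eta <- 0.5 * sp
    trace <- ev$value
    for (it in seq_len(steps)) {
      gmax <- max(abs(grad))
      if (gmax < 1e-12) break
      cand <- coef + eta * grad / gmax
      ev2 <- nmi_eval(st, cand, cps, FALSE)
      be2 <- bend_energy(cand)
      obj2 <- ev2$value - bending_weight * be2$value
      if (is.finite(obj2) && obj2 > obj + 1e-12) {
        coef <- cand
        obj <- obj2
        ev <- nmi_eval(st, coef, cps, TRUE)
        be <- bend_energy(coef)
        grad <- array(ev$grad, dim(coef)) - bending_weight * be$grad
        trace <- c(trace, ev$value)
        eta <- eta * 1.2
      } else {
        eta <- eta * 0.5
        if (eta < 1e-3 * sp) break
      }
    }
    list(coef = coef, value = ev$value, trace = trace)
  }

  cps <- control_spacing_vox
  if (is.null(init)) {
    # scale-space schedule: heavy intensity smoothing on a coarse control
    # grid captures the bulk deformation, then the requested grid is
    # refined at decreasing smoothing. Sub-voxel deformations cannot be
    # recovered in a single pass at full sharpness.
    st_c <- nmi_state(fixed, moving, L, nbins, presmooth_vox = 2.2)
    coarse <- bspline_zero(2 * cps, fixed)
    resc <- ascend(st_c, coarse$coef, 2 * cps, max_steps)
    fine0 <- bspline_zero(cps, fixed)
    cd <- dim(fine0$coef)[1:3]
    cp_vox <- (voxel_grid(cd) - 1) * cps   # fine control point positions
    coef <- array(bspline_eval_at(array(resc$coef, dim(coarse$coef)),
                                  2 * cps, cp_vox),
                  c(cd, 3))
    st_m <- nmi_state(fixed, moving, L, nbins, presmooth_vox = 1.2)
    coef <- ascend(st_m, coef, cps, max_steps)$coef
  } else {
    if (init$cps != cps) stop("warm start has mismatched control spacing")
    coef <- init$coef
  }
  st_f <- nmi_state(fixed, moving, L, nbins, presmooth_vox = 0.7)
  res <- ascend(st_f, coef, cps, max_steps)
  out <- tbm_bspline(res$coef, cps, fixed)
  attr(out, "prealign") <- L
  attr(out, "similarity") <- res$value
  attr(out, "trace") <- res$trace
  out
}

# composite displacement field on the reference grid for T(y) = A(y+u(y))
composite_field <- function(bspl, affine = NULL, reference = NULL) {
  A <- if (is.null(affine)) attr(bspl, "prealign") else
    if (inherits(affine, "tbm_affine")) affine$matrix else affine
  if (is.null(A)) A <- diag(4)
  ref <- if (is.null(reference)) bspl$reference else geometry_of(reference)
  y <- vox2world(ref$affine, voxel_grid(ref$dim))
  u <- bspline_dense(bspl)
  Ty <- vox2world(A, y + u)
  parts <- c(if (max(abs(A - diag(4))) > 1e-12) "global",
             if (max(abs(u)) > 1e-12) "nonrigid")
  if (is.null(parts)) parts <- character()
  tbm_field(array(Ty - y, c(ref$dim, 3)), spacing = ref$spacing,
            affine = ref$affine, parts = parts)
}

# nonrigid-only displacement field u(y) of a B-spline transform
nonrigid_field <- function(bspl) {
  ref <- bspl$reference
  u <- bspline_dense(bspl)
  parts <- if (max(abs(u)) > 1e-12) "nonrigid" else character()
  tbm_field(array(u, c(ref$dim, 3)), spacing = ref$spacing,
            affine = ref$affine, parts = parts)
}

# resample `v` through the composite transform into reference space
resample_composite <- function(v, reference, affine, bspl,
                               interpolation = "linear") {
  fld <- composite_field(bspl, affine, reference)
  resample(v, fld, interpolation)
}
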