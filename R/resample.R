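# Resampling volumes through displacement fields.

# sample a volume at world-space points (N x 3), trilinear or nearest
sample_world <- function(v, pts, interpolation = "linear",
                         fill = 0, na_outside = FALSE) {
  vox <- world2vox(v$affine, pts)
  mode <- if (interpolation == "nearest") 1L else 0L
  c_interp3(as.double(vol_data(v)), as.integer(vol_dim(v)), vox, mode,
            fill, na_outside)
}

#' Resample a volume through a displacement field
#'
#' The field's grid defines the output grid. Each output voxel's world
#' position y is sampled from `v` at y + u(y), i.e. the field maps output
#' coordinates into the input volume's world space (the pull-back
#' convention: for a transform T from average space to subject, resampling
#' the subject with T brings it into average space). Out-of-domain samples
#' are filled with the background value 0.
#'
#' @param v input `tbm_volume` or `tbm_labelmap`.
#' @param field a [tbm_field()] defining the output grid and mapping.
#' @param interpolation "linear" or "nearest" (label maps force nearest).
#' @return resampled volume (or label map) on the field's grid.
#' @export
resample <- function(v, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(v, "tbm_labelmap")) interpolation <- "nearest"
  if (!inherits(field, "tbm_field")) stop("field must be a tbm_field")
  dims <- vol_dim(field)
  pts <- world_grid(field) + matrix(field$vectors, ncol = 3)
  vals <- sample_world(v, pts, interpolation, fill = 0)
  if (inherits(v, "tbm_labelmap")) {
    tbm_labelmap(array(as.integer(round(vals)), dims), v$legend,
                 geometry = field)
  } else {
    tbm_volume(array(vals, dims), spacing = field$spacing,
               affine = field$affine)
  }
}

# resample through a plain affine: sample v at A %*% y for every output
# grid voxel of `geometry`
resample_affine <- function(v, geometry, A,
                            interpolation = "linear", fill = 0,
                            na_outside = FALSE) {
  pts <- vox2world(A %*% geometry$affine, voxel_grid(vol_dim(geometry)))
  vals <- sample_world(v, pts, interpolation, fill, na_outside)
  array(vals, vol_dim(geometry))
}

# block-average downsampling by an integer factor (for pyramids)
downsample2 <- function(v) {
  d <- vol_data(v)
  dims <- dim(d)
  nd <- pmax(1L, dims %/% 2L)
  crop <- d[seq_len(nd[1] * 2L), seq_len(nd[2] * 2L), seq_len(nd[3] * 2L),
            drop = FALSE]
  idx1 <- rep(seq_len(nd[1]), each = 2)
  idx2 <- rep(seq_len(nd[2]), each = 2)
  idx3 <- rep(seq_len(nd[3]), each = 2)
  out <- array(0, nd)
  # average the 8 children of each coarse voxel
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    out <- out + crop[seq(1 + dx, 2 * nd[1], by = 2),
                      seq(1 + dy, 2 * nd[2], by = 2),
                      seq(1 + dz, 2 * nd[3], by = 2), drop = FALSE]
  }
  out <- out / 8
  aff <- v$affine
  # coarse voxel center sits halfway between the first two fine centers
  aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep(0.5, 3)
  aff[1:3, 1:3] <- aff[1:3, 1:3] * 2
  tbm_volume(out, spacing = v$spacing * 2, affine = aff)
}
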