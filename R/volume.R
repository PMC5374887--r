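#' @useDynLib tbmpipe, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx cor optim quantile rnorm sd pt qnorm uniroot
#' @importFrom utils read.csv write.csv head
#' @name tbmpipe-internal
NULL

AXIS_LETTERS <- matrix(c("R", "L", "A", "P", "S", "I"), nrow = 2)

#' 3D image volume
#'
#' The universal currency of the pipeline: a 3D scalar grid together with its
#' geometry (voxel spacing in mm, 4x4 voxel-to-world affine, orientation
#' code). Voxel indices are 0-based in world-coordinate computations; world
#' coordinates are in mm following the NIfTI-1 convention (+x right,
#' +y anterior, +z superior).
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, voxel size in mm (all > 0).
#' @param affine 4x4 voxel-to-world matrix; default: diagonal RAS affine
#'   built from `spacing` with the origin at voxel (0,0,0).
#' @return object of class `tbm_volume` with fields `data`, `spacing`,
#'   `affine`, `orientation`.
#' @export
tbm_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("tbm_volume: data must be a 3D array, got ",
         length(dim(data)), "D")
  spacing <- as.numeric(spacing)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  v <- structure(list(data = data, spacing = spacing,
                      affine = affine,
                      orientation = orientation_code(affine)),
                 class = "tbm_volume")
  validate_volume(v)
  v
}

validate_volume <- function(v) {
  stopifnot(inherits(v, "tbm_volume") || inherits(v, "tbm_labelmap"))
  d <- if (inherits(v, "tbm_labelmap")) v$labels else v$data
  if (length(dim(d)) != 3L) stop("volume data must be 3D")
  if (any(v$spacing <= 0)) stop("voxel spacing must be positive")
  R3 <- v$affine[1:3, 1:3]
  if (abs(det(R3)) < 1e-12) stop("affine 3x3 block is singular")
  cn <- sqrt(colSums(R3^2))
  if (any(abs(cn - v$spacing) > 1e-6))
    stop("spacing does not match affine column norms")
  invisible(v)
}

#' @export
print.tbm_volume <- function(x, ...) {
  cat(sprintf("<tbm_volume %s, spacing %s mm, %s>\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$orientation))
  invisible(x)
}

#' Label map with region legend
#'
#' Integer region labels on the same grid as a companion volume. The legend
#' is a named integer vector mapping region names to label ids and must
#' include `background = 0`.
#'
#' @param labels 3D integer array.
#' @param legend named integer vector (region name -> id).
#' @param geometry a `tbm_volume` (or anything with spacing/affine) giving
#'   the grid geometry, or NULL for a default RAS geometry.
#' @param spacing,affine used when `geometry` is NULL.
#' @export
tbm_labelmap <- function(labels, legend, geometry = NULL,
                         spacing = c(1, 1, 1), affine = NULL) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (!is.null(geometry)) {
    spacing <- geometry$spacing
    affine <- geometry$affine
  } else if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  if (is.null(names(legend)) || !("background" %in% names(legend)) ||
      legend[["background"]] != 0L)
    stop("legend must be a named vector including background = 0")
  present <- setdiff(unique(as.vector(labels)), 0L)
  miss <- setdiff(present, as.integer(legend))
  if (length(miss))
    stop("labels present but missing from legend: ",
         paste(miss, collapse = ", "))
  lm <- structure(list(labels = labels, legend = legend,
                       spacing = as.numeric(spacing), affine = affine,
                       orientation = orientation_code(affine)),
                  class = "tbm_labelmap")
  validate_volume(lm)
  lm
}

#' @export
print.tbm_labelmap <- function(x, ...) {
  cat(sprintf("<tbm_labelmap %s, %d regions>\n",
              paste(dim(x$labels), collapse = "x"),
              length(x$legend) - 1L))
  invisible(x)
}

#' Logical brain mask from a label map
#'
#' The brain is the union of all anatomical labels, i.e. everything except
#' background and the noise ROI.
#' @param lm a `tbm_labelmap`.
#' @export
brain_mask <- function(lm) {
  excl <- c(0L, unname(lm$legend[names(lm$legend) %in% "noise"]))
  array(!(as.vector(lm$labels) %in% excl), dim(lm$labels))
}

#' Dense displacement field
#'
#' Per-voxel 3-vector displacements in mm along world axes, defined on its
#' own grid (the output grid of a resampling operation). The field maps a
#' grid voxel's world position y to the sampling position y + u(y) in the
#' source image's world space. `parts` records which transform components
#' are baked in (subset of "global", "nonrigid"); an empty `parts` means the
#' field must be identically zero.
#'
#' @param vectors 4D array (nx, ny, nz, 3), mm.
#' @param geometry a `tbm_volume`-like geometry for the grid, or NULL.
#' @param spacing,affine used when `geometry` is NULL.
#' @param parts character subset of c("global", "nonrigid").
#' @export
tbm_field <- function(vectors, geometry = NULL, spacing = c(1, 1, 1),
                      affine = NULL, parts = c("global", "nonrigid")) {
  vectors <- as.array(vectors)
  dv <- dim(vectors)
  if (length(dv) != 4L || dv[4] != 3L)
    stop("field vectors must be a 4D array with last dimension 3")
  if (!is.null(geometry)) {
    spacing <- geometry$spacing
    affine <- geometry$affine
  } else if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  parts <- as.character(parts)
  if (!all(parts %in% c("global", "nonrigid")))
    stop("parts must be a subset of {global, nonrigid}")
  if (length(parts) == 0L && any(vectors != 0))
    stop("a field with empty parts must be identically zero")
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 affine = affine, orientation = orientation_code(affine),
                 parts = parts),
            class = "tbm_field")
}

#' @export
print.tbm_field <- function(x, ...) {
  cat(sprintf("<tbm_field %s, parts {%s}, max |u| %.3g mm>\n",
              paste(dim(x$vectors)[1:3], collapse = "x"),
              paste(x$parts, collapse = ","),
              sqrt(max(rowSums(matrix(x$vectors, ncol = 3)^2)))))
  invisible(x)
}

#' Zero displacement field on a given geometry
#' @param geometry a `tbm_volume`.
#' @export
zero_field <- function(geometry) {
  d <- vol_dim(geometry)
  tbm_field(array(0, c(d, 3)), geometry = geometry, parts = character())
}

vol_dim <- function(v) {
  if (inherits(v, "tbm_labelmap")) dim(v$labels)
  else if (inherits(v, "tbm_field")) dim(v$vectors)[1:3]
  else dim(v$data)
}

vol_data <- function(v) {
  if (inherits(v, "tbm_labelmap")) v$labels else v$data
}

geometry_of <- function(v) {
  list(spacing = v$spacing, affine = v$affine,
       orientation = v$orientation, dim = vol_dim(v))
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(vol_dim(a) == vol_dim(b)) && all(abs(a$affine - b$affine) < tol)
}

# 0-based voxel index grid of a volume, N x 3
voxel_grid <- function(dims) {
  cbind(rep.int(seq_len(dims[1]) - 1L, dims[2] * dims[3]),
        rep.int(rep(seq_len(dims[2]) - 1L, each = dims[1]), dims[3]),
        rep(seq_len(dims[3]) - 1L, each = dims[1] * dims[2]))
}

# world coordinates (N x 3) of every voxel of a geometry
world_grid <- function(v) {
  dims <- vol_dim(v)
  g <- voxel_grid(dims)
  vox2world(v$affine, g)
}

vox2world <- function(affine, vox) {
  vox <- rbind(t(vox), 1)
  t(affine %*% vox)[, 1:3, drop = FALSE]
}

world2vox <- function(affine, world) {
  vox2world(solve(affine), world)
}

#' Orientation code of an affine
#'
#' Three letters, one per voxel axis, giving the anatomical direction each
#' axis points toward (e.g. "RAS").
#' @param affine 4x4 voxel-to-world matrix.
#' @export
orientation_code <- function(affine) {
  R3 <- affine[1:3, 1:3]
  # greedy assignment of world axes to voxel axes so codes stay a
  # permutation even for mildly oblique affines
  A <- abs(R3)
  letters_out <- character(3)
  taken <- rep(FALSE, 3)
  for (rep_i in 1:3) {
    hit <- which(A == max(A), arr.ind = TRUE)[1, ]
    ax <- hit[1]; j <- hit[2]
    letters_out[j] <- AXIS_LETTERS[if (R3[ax, j] >= 0) 1 else 2, ax]
    A[ax, ] <- -1; A[, j] <- -1
  }
  paste(letters_out, collapse = "")
}

parse_orientation <- function(code) {
  if (!is.character(code) || nchar(code) != 3)
    stop("orientation code must be 3 letters, e.g. RAS")
  lets <- strsplit(toupper(code), "")[[1]]
  ax <- integer(3); sg <- integer(3)
  for (j in 1:3) {
    hit <- which(AXIS_LETTERS == lets[j], arr.ind = TRUE)
    if (nrow(hit) != 1) stop("bad orientation letter: ", lets[j])
    ax[j] <- hit[1, 2]
    sg[j] <- if (hit[1, 1] == 1) 1L else -1L
  }
  if (anyDuplicated(ax)) stop("orientation code repeats an axis: ", code)
  list(axis = ax, sign = sg)
}

#' Reorient a volume to a target orientation code
#'
#' Pure permutation/flip of the voxel grid: world coordinates of every voxel
#' are preserved (within floating point), intensities are only rearranged.
#' Works for `tbm_volume` and `tbm_labelmap`.
#'
#' @param v volume or label map.
#' @param target 3-letter orientation code, e.g. "RAS".
#' @export
reorient <- function(v, target) {
  tgt <- parse_orientation(target)
  cur <- parse_orientation(v$orientation)
  # for each target axis find the source voxel axis on the same world axis
  perm <- match(tgt$axis, cur$axis)
  if (anyDuplicated(perm) || anyDuplicated(tgt$axis))
    stop("unreachable orientation code: ", target)
  flip <- tgt$sign != cur$sign[perm]
  d <- vol_data(v)
  dims <- dim(d)
  nd <- aperm(d, perm)
  A3 <- v$affine[1:3, 1:3][, perm, drop = FALSE]
  origin <- v$affine[1:3, 4]
  for (j in 1:3) {
    if (flip[j]) {
      idx <- rev(seq_len(dim(nd)[j]))
      nd <- switch(j, nd[idx, , , drop = FALSE],
                   nd[, idx, , drop = FALSE], nd[, , idx, drop = FALSE])
      origin <- origin + A3[, j] * (dim(nd)[j] - 1)
      A3[, j] <- -A3[, j]
    }
  }
  aff <- diag(4)
  aff[1:3, 1:3] <- A3
  aff[1:3, 4] <- origin
  if (inherits(v, "tbm_labelmap")) {
    tbm_labelmap(nd, v$legend, spacing = v$spacing[perm], affine = aff)
  } else {
    tbm_volume(nd, spacing = v$spacing[perm], affine = aff)
  }
}
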