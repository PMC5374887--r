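# Minimal NIfTI-1 reader/writer.
#
# The pipeline only needs single-file .nii / .nii.gz with 3D scalar data
# (volumes, label maps) or 4D data whose 4th dimension holds the 3 vector
# components of a displacement field. Geometry is carried in the sform
# (sform_code = 2, aligned); the qform is not written. Data are stored
# little-endian; reading detects byte order from sizeof_hdr.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, mode = "integer"),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  mode = "integer"),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  mode = "integer"),
  `16` = list(what = "numeric", size = 4, signed = TRUE,  mode = "double"),
  `64` = list(what = "numeric", size = 8, signed = TRUE,  mode = "double"))

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr0 <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (hdr0 != 348L) {
    hdr0s <- readBin(writeBin(hdr0, raw()), "integer", 1, size = 4,
                     endian = "big")
    if (hdr0s == 348L) endian <- "big"
    else stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  readBin(con, "raw", 36)                               # bytes 4..39
  dimv <- readBin(con, "integer", 8, size = 2, endian = endian)
  readBin(con, "numeric", 3, size = 4, endian = endian) # intent_p1..3
  readBin(con, "integer", 1, size = 2, endian = endian) # intent_code
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  readBin(con, "integer", 2, size = 2, endian = endian) # bitpix, slice_start
  pixdim <- readBin(con, "numeric", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  readBin(con, "raw", 120 - 120)                        # nothing
  readBin(con, "integer", 1, size = 2, endian = endian) # slice_end
  readBin(con, "raw", 2)                                # slice_code,xyzt
  readBin(con, "numeric", 4, size = 4, endian = endian) # cal/slice_dur/toff
  readBin(con, "integer", 2, size = 4, endian = endian) # glmax glmin
  readBin(con, "raw", 80 + 24)                          # descrip, aux_file
  qform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, size = 2, endian = endian)
  quat <- readBin(con, "numeric", 6, size = 4, endian = endian)
  srow <- matrix(readBin(con, "numeric", 12, size = 4, endian = endian),
                 nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16)                               # intent_name
  magic <- rawToChar(readBin(con, "raw", 4))
  if (!startsWith(magic, "n+1") && !startsWith(magic, "ni1"))
    stop("bad NIfTI magic in ", path)
  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  ndim <- dimv[1]
  dims <- dimv[2:(1 + max(ndim, 1))]
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  affine <- NULL
  if (sform_code > 0) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    affine <- quaternion_affine(quat, pixdim)
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  list(data = array(vals, dims), dims = dims, affine = affine,
       pixdim = pixdim[2:(1 + max(ndim, 3))])
}

quaternion_affine <- function(quat, pixdim) {
  b <- quat[1]; c_ <- quat[2]; d <- quat[3]
  a <- sqrt(max(0, 1 - b^2 - c_^2 - d^2))
  R <- matrix(c(a*a+b*b-c_*c_-d*d, 2*(b*c_+a*d),   2*(b*d-a*c_),
                2*(b*c_-a*d),   a*a+c_*c_-b*b-d*d, 2*(c_*d+a*b),
                2*(b*d+a*c_),   2*(c_*d-a*b),   a*a+d*d-b*b-c_*c_),
              3, 3)
  qfac <- if (pixdim[1] < 0) -1 else 1
  S <- diag(c(pixdim[2], pixdim[3], pixdim[4] * qfac))
  aff <- diag(4)
  aff[1:3, 1:3] <- R %*% S
  aff[1:3, 4] <- quat[4:6]
  aff
}

#' Read a 3D NIfTI-1 volume
#'
#' Accepts single-file `.nii` or `.nii.gz`. Trailing singleton dimensions
#' are dropped; genuinely 4D files are rejected (use [read_field()] for
#' vector fields). Non-finite voxel values are rejected.
#'
#' @param path path to a NIfTI-1 file.
#' @return a [tbm_volume()].
#' @export
read_nifti <- function(path) {
  raw <- read_nifti_raw(path)
  d <- raw$data
  dims <- dim(d)
  while (length(dims) > 3 && dims[length(dims)] == 1L) {
    dims <- dims[-length(dims)]
    dim(d) <- dims
  }
  if (length(dims) != 3L)
    stop("expected a 3D volume, got ", length(dims), "D: ", path)
  if (any(!is.finite(d)))
    stop("volume contains non-finite voxel values: ", path)
  spacing <- sqrt(colSums(raw$affine[1:3, 1:3]^2))
  tbm_volume(d, spacing = spacing, affine = raw$affine)
}

#' Read a NIfTI label map
#' @param path NIfTI file of integer labels.
#' @param legend named integer vector (see [tbm_labelmap()]).
#' @export
read_labelmap <- function(path, legend) {
  v <- read_nifti(path)
  lab <- round(v$data)
  if (max(abs(lab - v$data)) > 1e-4)
    stop("label map is not integer-valued: ", path)
  tbm_labelmap(lab, legend, geometry = v)
}

#' Read a displacement field (4D NIfTI, 3 components last)
#' @param path NIfTI file.
#' @param parts transform components baked into the field.
#' @export
read_field <- function(path, parts = c("global", "nonrigid")) {
  raw <- read_nifti_raw(path)
  d <- raw$data
  if (length(dim(d)) == 5L && dim(d)[4] == 1L)  # NIfTI vector convention
    dim(d) <- dim(d)[-4]
  if (length(dim(d)) != 4L || dim(d)[4] != 3L)
    stop("expected a 4D field with 3 components: ", path)
  spacing <- sqrt(colSums(raw$affine[1:3, 1:3]^2))
  if (all(d == 0)) parts <- character()
  tbm_field(d, spacing = spacing, affine = raw$affine, parts = parts)
}

write_nifti_raw <- function(data, affine, path, datatype) {
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  dims <- dim(data)
  ndim <- length(dims)
  dim8 <- rep(1L, 8); dim8[1] <- ndim; dim8[1 + seq_len(ndim)] <- dims
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  pix8 <- rep(0, 8); pix8[1] <- 1
  pix8[2:4] <- spacing
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wI <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wF <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wR <- function(n) writeBin(raw(n), con)
  wI(348, 4); wR(36)
  wI(dim8, 2)
  wF(c(0, 0, 0)); wI(0, 2)                  # intent
  wI(datatype, 2); wI(dt$size * 8, 2); wI(0, 2)
  wF(pix8)
  wF(352); wF(1); wF(0)                     # vox_offset, scl
  wI(0, 2); wR(2)                           # slice_end, slice_code, xyzt
  wF(c(0, 0, 0, 0)); wI(c(0, 0), 4)         # cal_max/min, ..., glmax/min
  wR(80 + 24)                               # descrip, aux_file
  wI(0, 2); wI(2, 2)                        # qform_code 0, sform_code 2
  wF(rep(0, 6))                             # quaternion
  wF(t(affine[1:3, ]))                      # srow_x, srow_y, srow_z
  wR(16)
  writeBin(charToRaw("n+1"), con); wR(1)    # magic
  wR(4)                                     # extension flag
  if (dt$mode == "integer") {
    writeBin(as.integer(round(as.vector(data))), con, size = dt$size,
             endian = "little")
  } else {
    writeBin(as.double(as.vector(data)), con, size = dt$size,
             endian = "little")
  }
  invisible(path)
}

#' Write a volume, label map or displacement field as NIfTI-1
#'
#' Volumes are written as float32 (float64 with `precision = "double"`),
#' label maps as int16, fields as 4D float32 with the vector dimension
#' last. `.gz` paths are gzip-compressed.
#'
#' @param v `tbm_volume`, `tbm_labelmap` or `tbm_field`.
#' @param path output path (.nii or .nii.gz).
#' @param precision "single" or "double" (volumes and fields only).
#' @export
write_nifti <- function(v, path, precision = c("single", "double")) {
  precision <- match.arg(precision)
  dtf <- if (precision == "double") 64L else 16L
  if (inherits(v, "tbm_labelmap")) {
    dtyp <- if (max(v$labels) > 32000) 8L else 4L
    write_nifti_raw(v$labels, v$affine, path, dtyp)
  } else if (inherits(v, "tbm_field")) {
    write_nifti_raw(v$vectors, v$affine, path, dtf)
  } else {
    write_nifti_raw(v$data, v$affine, path, dtf)
  }
  invisible(path)
}
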