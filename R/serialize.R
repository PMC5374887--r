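# On-disk forms of the non-image objects: standardization models as
# JSON, affine transforms as plain-text 4x4 matrices, B-spline
# transforms as a NIfTI coefficient grid plus a JSON header.

#' Serialize / restore a standardization model
#' @param model a `std_model` from [fit_standardization()].
#' @param path JSON file path.
#' @export
write_std_model <- function(model, path) {
  stopifnot(inherits(model, "std_model"))
  jsonlite::write_json(list(percentiles = model$percentiles,
                            standard_scale = model$standard_scale),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_std_model
#' @export
read_std_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(percentiles = x$percentiles,
                 standard_scale = x$standard_scale),
            class = "std_model")
}

#' Serialize / restore an affine transform as a text matrix
#' @param t a [tbm_affine()].
#' @param path text file path (whitespace-separated 4x4 matrix).
#' @export
write_affine <- function(t, path) {
  stopifnot(inherits(t, "tbm_affine"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# dof_class: ", t$dof_class), con)
  utils::write.table(format(t$matrix, digits = 17), con,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  lines <- readLines(path)
  dof <- if (grepl("rigid", lines[1])) "rigid" else "affine"
  m <- as.matrix(utils::read.table(text = lines[!startsWith(lines, "#")]))
  dimnames(m) <- NULL
  tbm_affine(m, dof)
}

#' Serialize / restore a B-spline transform
#'
#' The control-point displacement grid is written as a 4D NIfTI (vector
#' dimension last) and the control spacing plus reference geometry as a
#' JSON sidecar (`<path>.json`).
#'
#' @param t a [tbm_bspline()].
#' @param path NIfTI path for the coefficient grid.
#' @export
write_bspline <- function(t, path) {
  stopifnot(inherits(t, "tbm_bspline"))
  cd <- dim(t$coef)[1:3]
  aff <- diag(4)   # coefficient grid has its own index space
  write_nifti_raw(t$coef, aff, path, 64L)
  jsonlite::write_json(
    list(control_spacing_vox = t$cps,
         reference = list(dim = t$reference$dim,
                          spacing = t$reference$spacing,
                          affine = t$reference$affine),
         prealign = attr(t, "prealign")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bspline
#' @export
read_bspline <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"),
                             simplifyVector = TRUE)
  raw <- read_nifti_raw(path)
  ref_aff <- matrix(unlist(hdr$reference$affine), 4, 4)
  ref <- tbm_volume(array(0, hdr$reference$dim),
                    spacing = hdr$reference$spacing, affine = ref_aff)
  out <- tbm_bspline(raw$data, hdr$control_spacing_vox, ref)
  if (!is.null(hdr$prealign))
    attr(out, "prealign") <- matrix(unlist(hdr$prealign), 4, 4)
  out
}
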