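#' Cohort manifest
#'
#' A data frame of subject records driving group-wise analysis, with columns
#' `subject_id`, `group` (WT / TG / TG_DOX), `modality` (invivo / exvivo),
#' `volume_path`, `labelmap_path`, `rng_seed`. Paths are stored relative to
#' the manifest's directory.
#'
#' @param path CSV file written by [synthesize_cohort()] or by hand.
#' @param check_paths verify that every referenced file exists.
#' @return data frame of class `cohort_manifest` with attribute `root`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "modality", "volume_path",
            "labelmap_path", "rng_seed")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(paste(m$subject_id, m$modality)))
    stop("subject_id x modality must be unique in the manifest")
  root <- dirname(normalizePath(path))
  if (check_paths) {
    for (p in c(m$volume_path, m$labelmap_path)) {
      if (!file.exists(file.path(root, p)))
        stop("manifest references a missing file: ", p)
    }
  }
  attr(m, "root") <- root
  class(m) <- c("cohort_manifest", class(m))
  m
}

#' @rdname read_manifest
#' @param manifest a `cohort_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("subject_id", "group", "modality", "volume_path",
            "labelmap_path", "rng_seed")
  write.csv(as.data.frame(manifest)[, cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

manifest_path <- function(manifest, p) {
  file.path(attr(manifest, "root"), p)
}

# load volume + labelmap for one manifest row
load_subject <- function(manifest, i, legend) {
  list(volume = read_nifti(manifest_path(manifest, manifest$volume_path[i])),
       labels = read_labelmap(manifest_path(manifest,
                                            manifest$labelmap_path[i]),
                              legend))
}
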