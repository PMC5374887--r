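# ROI-based image quality metrics: SNR, gray-white CNR, theoretical
# voxel-volume SNR scaling, total brain volume and group contrasts.

region_values <- function(v, labels, region) {
  id <- labels$legend[[region]]
  if (is.null(id)) stop("region not in legend: ", region)
  vals <- vol_data(v)[labels$labels == id]
  if (!length(vals)) stop("empty region: ", region)
  vals
}

#' ROI signal-to-noise ratio
#'
#' Mean intensity of the signal region divided by the standard deviation
#' of the noise region (sample SD, n-1 denominator). The noise region is
#' expected to sit in ghost-free background; that placement is the
#' caller's responsibility.
#'
#' @param v image volume.
#' @param labels companion `tbm_labelmap`.
#' @param signal_region,noise_region legend region names.
#' @export
roi_snr <- function(v, labels, signal_region, noise_region = "noise") {
  s <- mean(region_values(v, labels, signal_region))
  nsd <- sd(region_values(v, labels, noise_region))
  if (!is.finite(nsd) || nsd == 0) stop("zero noise SD")
  s / nsd
}

#' Gray-white contrast-to-noise ratio
#'
#' (cortex mean - corpus callosum mean) / noise SD; signed, so it is
#' negative when white matter is brighter than gray matter (as in
#' T2-weighted in vivo images).
#'
#' @inheritParams roi_snr
#' @export
gray_white_cnr <- function(v, labels, noise_region = "noise") {
  g <- mean(region_values(v, labels, "cortex"))
  w <- mean(region_values(v, labels, "corpus_callosum"))
  nsd <- sd(region_values(v, labels, noise_region))
  if (!is.finite(nsd) || nsd == 0) stop("zero noise SD")
  (g - w) / nsd
}

#' Theoretical SNR scaling between voxel sizes
#'
#' SNR scales proportionally with voxel volume, so the expected factor
#' between two acquisitions is the ratio of their voxel volumes, e.g.
#' (0.15/0.04)^3 ~ 53 between 150 um and 40 um isotropic.
#'
#' @param spacing_a,spacing_b mm triples (or scalars, recycled).
#' @export
voxel_volume_snr_factor <- function(spacing_a, spacing_b) {
  spacing_a <- rep(as.numeric(spacing_a), length.out = 3)
  spacing_b <- rep(as.numeric(spacing_b), length.out = 3)
  if (any(spacing_a <= 0) || any(spacing_b <= 0))
    stop("spacings must be positive")
  prod(spacing_a) / prod(spacing_b)
}

#' Total brain volume from a brain mask
#'
#' Mask voxel count times voxel volume, optionally corrected by
#' user-supplied per-axis gradient scaling factors.
#'
#' @param mask `tbm_labelmap` (brain mask taken as all anatomical labels)
#'   or logical array with a `spacing` attribute requirement satisfied via
#'   `spacing`.
#' @param scale_factors per-axis correction factors.
#' @param spacing voxel spacing (taken from the label map if given).
#' @return volume in mm^3.
#' @export
total_brain_volume <- function(mask, scale_factors = c(1, 1, 1),
                               spacing = NULL) {
  if (inherits(mask, "tbm_labelmap")) {
    spacing <- mask$spacing
    m <- brain_mask(mask)
  } else {
    if (is.null(spacing)) stop("spacing required for a bare mask array")
    m <- as.logical(mask)
  }
  n <- sum(m)
  if (n == 0) stop("empty brain mask")
  n * prod(spacing) * prod(scale_factors)
}

#' Percentage difference relative to a reference value
#'
#' 100 * (a - b) / b: the relative increase of `a` over the reference `b`
#' (e.g. in vivo SNR 15.6 vs ex vivo 4.2 gives 271%).
#'
#' @param value_a,value_b positive numbers.
#' @param digits rounding for reporting (default nearest integer percent);
#'   NULL for the raw value.
#' @export
percent_difference <- function(value_a, value_b, digits = 0) {
  if (any(value_b <= 0)) stop("reference value must be positive")
  out <- 100 * (value_a - value_b) / value_b
  if (is.null(digits)) out else round(out, digits)
}

#' Per-subject quality report for a cohort
#'
#' One row per subject x signal region with SNR, plus per-subject CNR and
#' total brain volume. Raw values are emitted for external testing; no
#' inferential machinery is bundled.
#'
#' @param manifest a `cohort_manifest`.
#' @param legend label legend of the cohort.
#' @param regions signal regions to report.
#' @return list: `snr` (long data frame), `summary` (per subject: CNR,
#'   TBV mm^3, modality, group).
#' @export
quality_report <- function(manifest,
                           legend = c(background = 0L, PHANTOM_REGIONS),
                           regions = setdiff(names(PHANTOM_REGIONS),
                                             "noise")) {
  snr_rows <- list(); sum_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    s <- load_subject(manifest, i, legend)
    present <- intersect(regions, names(s$labels$legend))
    for (rg in present) {
      if (!any(s$labels$labels == s$labels$legend[[rg]])) next
      snr_rows[[length(snr_rows) + 1L]] <- data.frame(
        subject_id = manifest$subject_id[i], group = manifest$group[i],
        modality = manifest$modality[i], region = rg,
        snr = roi_snr(s$volume, s$labels, rg), stringsAsFactors = FALSE)
    }
    sum_rows[[length(sum_rows) + 1L]] <- data.frame(
      subject_id = manifest$subject_id[i], group = manifest$group[i],
      modality = manifest$modality[i],
      cnr = gray_white_cnr(s$volume, s$labels),
      tbv_mm3 = total_brain_volume(s$labels), stringsAsFactors = FALSE)
  }
  list(snr = do.call(rbind, snr_rows), summary = do.call(rbind, sum_rows))
}

#' Pairwise group volume contrasts
#'
#' For every ordered pair of groups, the percentage difference of the
#' group mean volumes under both reporting conventions: `pct_increase`
#' (mean_a relative to mean_b as reference) and `pct_smaller` (how much
#' smaller a is than b, relative to b — the convention behind "21%
#' smaller").
#'
#' @param report data frame with columns `group` and `tbv_mm3` (e.g. the
#'   `summary` element of [quality_report()], one modality at a time).
#' @return data frame of ordered group pairs.
#' @export
group_volume_contrasts <- function(report) {
  groups <- unique(report$group)
  if (length(groups) < 2) stop("need >= 2 groups")
  means <- tapply(report$tbv_mm3, report$group, mean)
  if (any(tapply(report$tbv_mm3, report$group, length) == 0))
    stop("group with zero subjects")
  out <- list()
  for (a in groups) for (b in groups) {
    if (a == b) next
    out[[length(out) + 1L]] <- data.frame(
      group_a = a, group_b = b,
      mean_a = unname(means[a]), mean_b = unname(means[b]),
      pct_increase = percent_difference(means[a], means[b], digits = NULL),
      pct_smaller = 100 * (means[b] - means[a]) / means[b],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
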