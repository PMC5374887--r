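# Configuration-driven orchestration of the full study: phantom ->
# preprocessing -> per-modality groupwise TBM (+ power maps) -> MPD ->
# QC, with content-hash stage skipping and a provenance manifest.

#' Pipeline configuration
#'
#' Defaults mirror the reference analysis schedule (4 affine and 20
#' non-rigid iterations, control points every 4 voxels, 0.2 mm FWHM,
#' q = 0.05, alpha = 0.05, beta = 0.2, effect 0.25). The "smoke" profile
#' only shrinks the phantom grid and iteration counts so a full run fits
#' on one CPU in minutes; it changes no statistical parameter.
#'
#' @param out_dir output directory.
#' @param seed master seed (phantom + registration target choice).
#' @param profile "paper" or "smoke".
#' @param phantom list of [phantom_spec()] overrides.
#' @param stats list of [stat_config()] overrides.
#' @param n_affine,n_nrr,control_spacing_vox registration schedule.
#' @param nrr_steps gradient steps per NRR iteration.
#' @param modalities modalities to synthesize and analyse.
#' @param comparisons list of group pairs for TBM.
#' @param stages character vector of stages to run.
#' @export
pipeline_config <- function(out_dir, seed = 42L,
                            profile = c("paper", "smoke"),
                            phantom = list(), stats = list(),
                            n_affine = 4L, n_nrr = 20L,
                            control_spacing_vox = 4L, nrr_steps = 15L,
                            modalities = c("invivo", "exvivo"),
                            comparisons = list(c("TG", "WT"),
                                               c("TG", "TG_DOX")),
                            stages = c("synth", "preprocess", "tbm",
                                       "mpd", "qc")) {
  profile <- match.arg(profile)
  if (profile == "smoke") {
    phantom <- modifyList(list(grid_shape = c(48, 48, 48),
                               spacing_exvivo = 0.12,
                               n_per_group = c(WT = 4L, TG = 4L,
                                               TG_DOX = 4L)),
                          phantom)
    n_affine <- min(n_affine, 2L)
    n_nrr <- min(n_nrr, 5L)
  }
  phantom$seed <- seed
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 profile = profile, phantom = phantom, stats = stats,
                 n_affine = n_affine, n_nrr = n_nrr,
                 control_spacing_vox = control_spacing_vox,
                 nrr_steps = nrr_steps, modalities = modalities,
                 comparisons = comparisons, stages = stages),
            class = "pipeline_config")
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

stage_done <- function(out_dir, stage, hash) {
  f <- file.path(out_dir, "provenance", paste0(stage, ".json"))
  if (!file.exists(f)) return(FALSE)
  prev <- jsonlite::read_json(f)
  identical(prev$hash, as.character(hash)) &&
    all(vapply(prev$outputs, function(p)
      file.exists(file.path(out_dir, p)), logical(1)))
}

stage_record <- function(out_dir, stage, hash, outputs, params) {
  d <- file.path(out_dir, "provenance")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(stage = stage, hash = hash, outputs = outputs, params = params,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(d, paste0(stage, ".json")), auto_unbox = TRUE, digits = NA,
    force = TRUE)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order. A stage is skipped when its
#' parameter hash matches the recorded provenance and its outputs exist;
#' any stage failure halts the run with the stage name. Two runs with the
#' same configuration produce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, the provenance list (stage -> outputs).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  prov <- list()
  spec <- do.call(phantom_spec, config$phantom)
  cfg <- do.call(stat_config, config$stats)
  run_stage <- function(stage, params, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    h <- config_hash(list(stage = stage, params = params,
                          seed = config$seed))
    if (stage_done(out, stage, h)) {
      say("[", stage, "] up to date, skipped")
      prov[[stage]] <<- "skipped"
      return(invisible(NULL))
    }
    say("[", stage, "] running")
    outputs <- tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_record(out, stage, h, outputs, params)
    prov[[stage]] <<- outputs
  }

  cohort_dir <- file.path(out, "cohort")
  run_stage("synth", config$phantom, function() {
    synthesize_cohort(spec, cohort_dir, modalities = config$modalities)
    file.path("cohort", list.files(cohort_dir))
  })
  manifest <- read_manifest(file.path(cohort_dir, "manifest.csv"))
  legend <- c(background = 0L, PHANTOM_REGIONS)

  pre_dir <- file.path(out, "preproc")
  run_stage("preprocess", list(phantom = config$phantom), function() {
    dir.create(pre_dir, showWarnings = FALSE)
    m2 <- manifest
    for (mod in config$modalities) {
      rows <- which(manifest$modality == mod)
      subs <- lapply(rows, function(i) load_subject(manifest, i, legend))
      corrected <- lapply(subs, function(s) {
        # phantom intensities can be <= 0 from noise; bias correction
        # needs positive support, so shift into the positive range first
        v <- s$volume
        lo <- min(v$data)
        if (lo <= 0) v$data <- v$data - lo + 1
        out_v <- correct_bias(v, s$labels)$corrected
        if (lo <= 0) out_v$data <- out_v$data + lo - 1
        out_v
      })
      model <- fit_standardization(corrected,
                                   lapply(subs, `[[`, "labels"))
      for (k in seq_along(rows)) {
        i <- rows[k]
        shifted <- corrected[[k]]
        lo <- min(shifted$data)
        if (lo <= 0) shifted$data <- shifted$data - lo + 1
        std <- apply_standardization(shifted, subs[[k]]$labels, model)
        vp <- file.path(pre_dir, basename(manifest$volume_path[i]))
        write_nifti(std, vp)
        file.copy(manifest_path(manifest, manifest$labelmap_path[i]),
                  file.path(pre_dir,
                            basename(manifest$labelmap_path[i])),
                  overwrite = TRUE)
        m2$volume_path[i] <- basename(manifest$volume_path[i])
        m2$labelmap_path[i] <- basename(manifest$labelmap_path[i])
      }
    }
    write_manifest(m2, file.path(pre_dir, "manifest.csv"))
    file.path("preproc", list.files(pre_dir))
  })
  ana_manifest <- if (file.exists(file.path(pre_dir, "manifest.csv")))
    read_manifest(file.path(pre_dir, "manifest.csv")) else manifest

  run_stage("tbm", list(n_affine = config$n_affine, n_nrr = config$n_nrr,
                        cps = config$control_spacing_vox,
                        stats = config$stats,
                        phantom = config$phantom), function() {
    outs <- character()
    for (cmp in config$comparisons) {
      for (mod in config$modalities) {
        tag <- paste0(cmp[1], "_vs_", cmp[2], "_", mod)
        dir_i <- file.path(out, "tbm", tag)
        res <- tbm_compare(ana_manifest, cmp, mod, cfg, legend = legend,
                           n_affine = config$n_affine,
                           n_nrr = config$n_nrr,
                           control_spacing_vox =
                             config$control_spacing_vox,
                           seed = config$seed, out_dir = dir_i,
                           nrr_steps = config$nrr_steps)
        write.csv(res$groupwise$log,
                  file.path(dir_i, "iteration_log.csv"),
                  row.names = FALSE)
        outs <- c(outs, file.path("tbm", tag, list.files(dir_i)))
      }
    }
    outs
  })

  run_stage("mpd", list(n_nrr = config$n_nrr,
                        phantom = config$phantom), function() {
    if (length(config$modalities) < 2) return(character())
    mpd_pairwise(ana_manifest, legend = legend,
                 out_dir = file.path(out, "mpd"),
                 nrr_steps = config$nrr_steps)
    file.path("mpd", list.files(file.path(out, "mpd")))
  })

  run_stage("qc", list(phantom = config$phantom), function() {
    qc <- quality_report(manifest, legend = legend)
    dir.create(file.path(out, "qc"), showWarnings = FALSE)
    write.csv(qc$snr, file.path(out, "qc", "snr.csv"), row.names = FALSE)
    write.csv(qc$summary, file.path(out, "qc", "subjects.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(snr_by_region_modality = stats::aggregate(
        snr ~ region + modality, qc$snr, mean)),
      file.path(out, "qc", "summary.json"), auto_unbox = TRUE,
      digits = NA, force = TRUE)
    file.path("qc", list.files(file.path(out, "qc")))
  })

  jsonlite::write_json(
    list(seed = config$seed, profile = config$profile,
         stages = names(prov)),
    file.path(out, "provenance", "run.json"), auto_unbox = TRUE,
    force = TRUE)
  invisible(prov)
}

#' Pairwise ex vivo to in vivo distortion mapping
#'
#' Registers each subject's ex vivo image to its own in vivo image
#' (affine + B-spline), keeps the non-rigid displacement only, and
#' averages the per-voxel displacement magnitudes over subjects into a
#' mean positional distance map in the shared in vivo space.
#'
#' @param manifest cohort manifest containing both modalities.
#' @param legend label legend.
#' @param subjects optional subject_id subset.
#' @param out_dir if non-NULL, writes `mpd.nii.gz` there.
#' @param nrr_steps,control_spacing_vox registration parameters.
#' @return list: `mpd` (an `mpd_map`), `fields` (per subject non-rigid
#'   fields), `reference`.
#' @export
mpd_pairwise <- function(manifest, legend = c(background = 0L,
                                              PHANTOM_REGIONS),
                         subjects = NULL, out_dir = NULL,
                         nrr_steps = 20L, control_spacing_vox = 4L) {
  ids <- intersect(manifest$subject_id[manifest$modality == "exvivo"],
                   manifest$subject_id[manifest$modality == "invivo"])
  if (!is.null(subjects)) ids <- intersect(ids, subjects)
  if (!length(ids)) stop("no subjects with both modalities")
  fields <- list(); reference <- NULL
  for (sid in ids) {
    ri <- which(manifest$subject_id == sid & manifest$modality == "invivo")
    re <- which(manifest$subject_id == sid & manifest$modality == "exvivo")
    invivo <- load_subject(manifest, ri, legend)$volume
    exvivo <- load_subject(manifest, re, legend)$volume
    if (is.null(reference)) reference <- invivo
    A <- register_linear(exvivo, invivo, dof_class = "affine")
    nrr <- register_nonrigid(exvivo, invivo,
                             control_spacing_vox = control_spacing_vox,
                             init_affine = A, max_steps = nrr_steps)
    fields[[sid]] <- nonrigid_field(nrr)
  }
  mpd <- mean_positional_distance(fields, reference)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_nifti(tbm_volume(mpd$mpd, spacing = mpd$spacing,
                           affine = mpd$affine),
                file.path(out_dir, "mpd.nii.gz"))
  }
  list(mpd = mpd, fields = fields, reference = reference)
}
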