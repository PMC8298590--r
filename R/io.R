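## Disk layout for one subject directory:
##   dsc.nii.gz      4D (x,y,z,t) DSC time series
##   cest.nii.gz     4D (x,y,z,offset) saturated CEST volumes
##   s0.nii.gz       3D unsaturated reference
##   seg.nii.gz      3D integer segmentation (1 = NC, 2 = ED, 4 = ET)
##   mask.nii.gz     3D brain mask (0/1)
##   offsets.txt     one offset (ppm) per line
##   truth.rds       ground-truth arrays (latents, acidity, B0 field, labels)
##   manifest.json   config, seed, latent distributions, link function

#' Write one phantom subject to a directory
#'
#' @param subject a `phantom_subject`.
#' @param dir output directory (created if needed).
#' @param config the cohort's `phantom_config`, stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir, config = NULL) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create subject directory: ", dir)
  wr <- function(arr, name) {
    path <- file.path(dir, name)
    res <- try(RNifti::writeNifti(arr, path), silent = TRUE)
    if (inherits(res, "try-error")) {
      stop("failed to write NIfTI volume: ", path)
    }
    path
  }
  wr(subject$dsc, "dsc.nii.gz")
  wr(subject$cest$volumes, "cest.nii.gz")
  wr(subject$cest$s0, "s0.nii.gz")
  wr(array(as.numeric(subject$seg), dim = dim(subject$seg)), "seg.nii.gz")
  wr(array(as.numeric(subject$mask), dim = dim(subject$mask)), "mask.nii.gz")
  writeLines(format(subject$cest$offsets, trim = TRUE),
             file.path(dir, "offsets.txt"))
  saveRDS(subject$truth, file.path(dir, "truth.rds"))
  manifest <- list(
    id = subject$id,
    tr_seconds = subject$tr_seconds,
    baseline_frames = subject$baseline_frames,
    config = if (!is.null(config)) unclass(config),
    latent_distributions = .tissue_latents,
    link = .link_params
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read one phantom subject from a directory written by [write_subject()]
#'
#' @param dir subject directory.
#' @return a `phantom_subject`.
#' @export
read_subject <- function(dir) {
  rd <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing volume: ", path)
    as.array(RNifti::readNifti(path))
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  offsets <- as.numeric(readLines(file.path(dir, "offsets.txt")))
  mask <- rd("mask.nii.gz") > 0.5
  truth_path <- file.path(dir, "truth.rds")
  truth <- if (file.exists(truth_path)) readRDS(truth_path) else NULL
  structure(list(
    id = manifest$id,
    dsc = rd("dsc.nii.gz"),
    tr_seconds = manifest$tr_seconds,
    baseline_frames = manifest$baseline_frames,
    cest = list(offsets = offsets, volumes = rd("cest.nii.gz"),
                s0 = rd("s0.nii.gz"), mask = mask),
    mask = mask,
    seg = array(as.integer(round(rd("seg.nii.gz"))),
                dim = dim(mask)),
    truth = truth,
    link = manifest$link
  ), class = "phantom_subject")
}

#' Write a whole cohort (one subdirectory per subject)
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output root.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) {
    write_subject(s, file.path(dir, s$id), config = cohort$config)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort root containing `subject-*` directories.
#' @return a `phantom_cohort` (config reconstructed from the first manifest).
#' @export
read_cohort <- function(dir) {
  dirs <- sort(list.dirs(dir, recursive = FALSE))
  dirs <- dirs[grepl("subject-", basename(dirs))]
  if (!length(dirs)) stop("no subject directories under ", dir)
  subjects <- lapply(dirs, read_subject)
  manifest <- jsonlite::read_json(file.path(dirs[1], "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  config <- if (!is.null(cfg)) {
    phantom_config(
      n_subjects = length(subjects), grid_shape = cfg$grid_shape,
      n_timepoints = cfg$n_timepoints, tr_seconds = cfg$tr_seconds,
      baseline_frames = cfg$baseline_frames, noise_sd_dsc = cfg$noise_sd_dsc,
      noise_sd_cest = cfg$noise_sd_cest,
      b0_amplitude_ppm = cfg$b0_amplitude_ppm,
      link_noise_sd = cfg$link_noise_sd, seed = cfg$seed
    )
  }
  structure(list(config = config, subjects = subjects),
            class = "phantom_cohort")
}
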