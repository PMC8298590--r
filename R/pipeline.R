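#' Build a run configuration
#'
#' Assembles and validates the configuration for a full simulate -> CEST
#' quantification -> temporal PCA -> LOSO regression -> evaluation run. All
#' stage seeds are derived deterministically from the single master seed.
#'
#' @param seed master seed.
#' @param phantom a [phantom_config()] (its seed is overridden by the derived
#'   phantom seed unless `keep_phantom_seed = TRUE`).
#' @param pca list: `n_components`, `per_roi_sample`, `variance_target`,
#'   `mode`, `margin`.
#' @param svr list: `cost`, `epsilon`, `subsample`.
#' @param cest list: `n_clusters`.
#' @param keep_phantom_seed keep the seed already inside `phantom`.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       phantom = phantom_config(),
                       pca = list(),
                       svr = list(),
                       cest = list(),
                       keep_phantom_seed = FALSE) {
  pca <- utils::modifyList(list(n_components = 7L, per_roi_sample = 1000L,
                                variance_target = 0.99, mode = "subject",
                                margin = 0.05), pca)
  svr <- utils::modifyList(list(cost = 1, epsilon = NULL, subsample = 2000L),
                           svr)
  cest <- utils::modifyList(list(n_clusters = 8L), cest)
  seed <- as.integer(seed)
  seeds <- derive_seeds(seed)
  if (!keep_phantom_seed) phantom$seed <- seeds$phantom
  structure(list(seed = seed, seeds = seeds, phantom = phantom, pca = pca,
                 svr = svr, cest = cest), class = "run_config")
}

## deterministic stage seeds below 2^31 from one master seed
derive_seeds <- function(seed) {
  base <- (as.double(seed) %% 1000003L)
  mk <- function(k) as.integer((base * 2654435761 + k * 97) %% 2147483647)
  list(phantom = mk(1), kmeans = mk(2), sampling = mk(3), svr = mk(4))
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys `seed`, `phantom`, `pca`, `svr`, `cest`; the `phantom`
#' block takes any [phantom_config()] argument.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantom_config, utils::modifyList(
    list(), if (is.null(y$phantom)) list() else y$phantom))
  run_config(seed = if (is.null(y$seed)) 1L else y$seed,
             phantom = ph,
             pca = if (is.null(y$pca)) list() else y$pca,
             svr = if (is.null(y$svr)) list() else y$svr,
             cest = if (is.null(y$cest)) list() else y$cest)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = 12, null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Orchestrates the five stages on a synthetic cohort: (1) phantom
#' generation; (2) CEST quantification (B0 estimation and correction, 0.4 ppm
#' window asymmetry at 3 ppm) producing each subject's actual MTR_asym map;
#' (3) alignment/normalization of the DSC curves to the cohort-median
#' minimum index and temporal PCA on the pooled stratified voxel sample;
#' (4) per-subregion Gaussian-kernel SVR under leave-one-subject-out
#' cross-validation producing constructed MTR_asym maps; (5) Spearman
#' evaluation per region and subject. The run is deterministic given the
#' configuration.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; if given, per-subject maps
#'   (NIfTI), the evaluation CSV, and a machine-readable JSON summary are
#'   written.
#' @param verbose print stage progress.
#' @return object of class `pipeline_run`: `summary` (list), `report`
#'   (`eval_report`), `pc_model`, `loso`, `actual` maps, `cohort`.
#' @export
run_all <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (verbose) message("stage 1/5: phantom cohort")
  cohort <- generate_cohort(config$phantom)
  analyze_cohort(cohort, config, out_dir = out_dir, verbose = verbose)
}

#' Run the analysis stages on an existing cohort
#'
#' The CEST-quantification, PCA, LOSO-regression, and evaluation stages of
#' [run_all()], applied to a cohort that already exists (generated in memory
#' or loaded from disk via [read_cohort()]).
#'
#' @param cohort a `phantom_cohort`.
#' @param config a [run_config()].
#' @inheritParams run_all
#' @return a `pipeline_run` (see [run_all()]).
#' @export
analyze_cohort <- function(cohort, config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(...)
  t_start <- Sys.time()
  n <- length(cohort$subjects)
  grid <- dim(cohort$subjects[[1]]$mask)
  n_generated <- n * prod(grid)
  n_masked <- sum(vapply(cohort$subjects, function(s) sum(s$mask), 0))

  say("stage 2/5: CEST quantification")
  actual <- vector("list", n)
  for (i in seq_len(n)) {
    acq <- as_cest_acquisition(cohort$subjects[[i]])
    b0 <- tryCatch(
      estimate_b0(acq, n_clusters = config$cest$n_clusters,
                  seed = config$seeds$kmeans + i),
      error = function(e) stop("stage cest-quant failed for ",
                               cohort$subjects[[i]]$id, ": ",
                               conditionMessage(e)))
    actual[[i]] <- mtr_asym_map(acq, b0)
  }

  say("stage 3/5: curve normalization and temporal PCA")
  curves <- vector("list", n)
  pre_targets <- numeric(n)
  for (i in seq_len(n)) {
    s <- cohort$subjects[[i]]
    cv <- normalize_and_align(s$dsc, s$mask,
                              baseline_frames = s$baseline_frames,
                              mode = config$pca$mode,
                              margin = config$pca$margin)
    pre_targets[i] <- cv$target_index
  }
  target <- as.integer(round(stats::median(pre_targets)))
  for (i in seq_len(n)) {
    s <- cohort$subjects[[i]]
    curves[[i]] <- tryCatch(
      normalize_and_align(s$dsc, s$mask,
                          baseline_frames = s$baseline_frames,
                          mode = config$pca$mode, margin = config$pca$margin,
                          target_index = target),
      error = function(e) stop("stage pca failed for ", s$id, ": ",
                               conditionMessage(e)))
  }
  segs <- lapply(cohort$subjects, function(s) s$seg)
  ids <- vapply(cohort$subjects, function(s) s$id, character(1))
  samp <- sample_training_voxels(curves, segs,
                                 n_per_roi = config$pca$per_roi_sample,
                                 seed = config$seeds$sampling,
                                 subject_ids = ids)
  model <- fit_pca(samp$features, n_components = config$pca$n_components)
  cumvar <- cumsum(model$all_ratios)
  chosen_k <- which(cumvar >= config$pca$variance_target)[1]
  if (is.na(chosen_k)) chosen_k <- length(cumvar)

  say("stage 4/5: LOSO support vector regression")
  subjects_reg <- vector("list", n)
  n_valid <- 0L
  for (i in seq_len(n)) {
    cv <- curves[[i]]
    sc <- pc_scores(model, cv$matrix)
    subjects_reg[[i]] <- list(
      id = ids[i],
      scores = sc,
      roi = segs[[i]][cv$voxels],
      actual = actual[[i]]$values[cv$voxels],
      voxels = cv$voxels,
      grid = grid
    )
    n_valid <- n_valid + nrow(sc)
  }
  sample_rows <- split(samp$provenance$row, samp$provenance$subject)
  loso <- tryCatch(
    loso_cv(subjects_reg, sample_rows = sample_rows,
            cost = config$svr$cost, epsilon = config$svr$epsilon,
            subsample = config$svr$subsample, seed = config$seeds$svr),
    error = function(e) stop("stage predict failed: ", conditionMessage(e)))
  n_predicted <- sum(vapply(loso$folds,
                            function(f) sum(is.finite(f$constructed)), 0))

  say("stage 5/5: evaluation")
  constructed <- lapply(loso$folds, function(f) f$constructed)
  report <- evaluate(constructed, actual, segs, subject_ids = ids)

  summary <- list(
    package_version = as.character(utils::packageVersion("perfph")),
    config_hash = config_hash(config),
    seed = config$seed,
    stage_seeds = config$seeds,
    n_subjects = n,
    grid_shape = grid,
    voxel_accounting = list(
      generated = n_generated, masked = n_masked, valid_curves = n_valid,
      sampled = nrow(samp$features), predicted = n_predicted
    ),
    cumulative_explained_variance = cumvar,
    n_components_for_target = chosen_k,
    variance_target = config$pca$variance_target,
    cohort_mean_r = stats::setNames(as.list(report$summary$mean_r),
                                    report$summary$region),
    folds = lapply(loso$folds, function(f) {
      list(id = f$id, training_subjects = f$provenance)
    }),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t_start,
                                          units = "secs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      sd <- file.path(out_dir, ids[i])
      dir.create(sd, recursive = TRUE, showWarnings = FALSE)
      RNifti::writeNifti(constructed[[i]],
                         file.path(sd, "constructed_mtr_asym.nii.gz"))
      RNifti::writeNifti(actual[[i]]$values,
                         file.path(sd, "actual_mtr_asym.nii.gz"))
    }
    utils::write.csv(report$table, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
    materialized <- unclass(config)
    jsonlite::write_json(materialized, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = 12, null = "null",
                         force = TRUE)
    summary_out <- summary
    summary_out$elapsed_seconds <- NULL   # timing excluded: summary is
    jsonlite::write_json(summary_out,     # reproducible bit-for-bit
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 12, null = "null")
  }

  structure(list(summary = summary, report = report, pc_model = model,
                 loso = loso, actual = actual, curves = curves,
                 cohort = cohort), class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run:", x$summary$n_subjects, "subjects, seed",
      x$summary$seed, "\n")
  cv <- x$summary$cumulative_explained_variance
  k <- min(7L, length(cv))
  cat("  cumulative variance at", k, "components:",
      round(100 * cv[k], 3), "%\n")
  print(x$report)
  invisible(x)
}
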