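## shift one row by `by` frames (positive = to the right), replicating edges
shift_row <- function(x, by) {
  n <- length(x)
  if (by == 0) return(x)
  if (by > 0) c(rep(x[1], by), x[seq_len(n - by)])
  else c(x[seq.int(1 - by, n)], rep(x[n], -by))
}

#' Auto-detect the pre-bolus window
#'
#' The number of pre-bolus frames is estimated from the in-mask mean curve as
#' the index of the steepest negative frame-to-frame difference minus 2, with
#' a floor of 3 frames.
#'
#' @param mean_curve numeric vector, the mask-averaged signal-time curve.
#' @return integer frame count.
#' @export
detect_baseline_frames <- function(mean_curve) {
  j <- which.min(diff(mean_curve))
  max(3L, as.integer(j) - 2L)
}

#' Align and normalize DSC perfusion curves
#'
#' Per voxel: the baseline is the mean of the pre-bolus frames; the curve is
#' divided by its baseline; voxels whose relative drop `1 - min` is below
#' `margin` are flagged as bolus-free and excluded; remaining curves are
#' shifted by an integer number of frames so the global-minimum frame lands
#' on a common target index (the median minimum index, or `target_index` if
#' supplied, e.g. a cohort-wide median), with edge frames replicated.
#'
#' Normalization for baseline and maximum drop then pins two points to fixed
#' values. In `mode = "subject"` (default) the affine map sending the
#' subject's mean-curve baseline to 1 and its minimum to 0 is applied to all
#' voxels, making curves comparable across subjects while preserving
#' within-subject differences in signal level and drop depth (the features
#' the leading principal components encode). In `mode = "voxel"` each row is
#' individually pinned to baseline 1 / minimum 0, which additionally removes
#' per-voxel amplitude information.
#'
#' @param dsc 4D array (x, y, z, t) or matrix (voxels x t).
#' @param mask 3D logical array (ignored when `dsc` is a matrix).
#' @param baseline_frames pre-bolus frame count; NULL to auto-detect via
#'   [detect_baseline_frames()].
#' @param mode `"subject"` or `"voxel"` (see Details).
#' @param margin minimum relative drop below baseline for a voxel to count
#'   as having a bolus.
#' @param target_index common minimum-frame index; NULL to use the median
#'   within this call.
#' @return object of class `normalized_curves`: `matrix` (valid voxels x t),
#'   `voxels` (linear indices of valid voxels), `all_voxels`, `flags`,
#'   `shifts`, `baseline_frames`, `target_index`, `mode`, `scale`.
#' @export
normalize_and_align <- function(dsc, mask = NULL, baseline_frames = NULL,
                                mode = c("subject", "voxel"),
                                margin = 0.05, target_index = NULL) {
  mode <- match.arg(mode)
  if (length(dim(dsc)) == 4L) {
    if (is.null(mask)) stop("mask required for a 4D series")
    grid <- dim(dsc)[1:3]
    vox <- which(mask)
    X <- matrix(dsc, ncol = dim(dsc)[4])[vox, , drop = FALSE]
  } else {
    X <- as.matrix(dsc)
    grid <- NULL
    vox <- seq_len(nrow(X))
  }
  if (!length(vox)) stop("empty mask")
  nt <- ncol(X)
  mean_curve <- colMeans(X)
  bf <- if (is.null(baseline_frames)) detect_baseline_frames(mean_curve)
        else as.integer(baseline_frames)
  if (nt < bf + 8L) stop("time series too short for the pre-bolus window")

  base <- rowMeans(X[, seq_len(bf), drop = FALSE])
  bad_base <- !is.finite(base) | base <= 0
  rel <- X / ifelse(bad_base, NA_real_, base)
  minval <- apply(rel, 1L, min)
  minidx <- apply(rel, 1L, which.min)
  no_bolus <- bad_base | !is.finite(minval) | (1 - minval) < margin
  if (mean(!no_bolus) < 0.5) {
    stop("bolus detectable in fewer than half the mask voxels")
  }
  ok <- which(!no_bolus)
  tgt <- if (is.null(target_index)) {
    as.integer(round(stats::median(minidx[ok])))
  } else as.integer(target_index)

  shifts <- integer(length(vox))
  shifts[ok] <- tgt - minidx[ok]
  Y <- X[ok, , drop = FALSE]
  for (i in seq_along(ok)) {
    s <- shifts[ok[i]]
    if (s != 0) Y[i, ] <- shift_row(Y[i, ], s)
  }

  if (mode == "voxel") {
    b2 <- rowMeans(Y[, seq_len(bf), drop = FALSE])
    m2 <- apply(Y, 1L, min)
    span <- b2 - m2
    degen <- span <= 0
    if (any(degen)) {
      ok <- ok[!degen]
      Y <- Y[!degen, , drop = FALSE]
      b2 <- b2[!degen]; m2 <- m2[!degen]; span <- span[!degen]
    }
    Y <- (Y - m2) / span
    scale_info <- list(baseline = b2, minimum = m2)
  } else {
    ref <- colMeans(Y)
    B <- mean(ref[seq_len(bf)])
    M <- min(ref)
    if (B <= M) stop("degenerate subject reference curve")
    Y <- (Y - M) / (B - M)
    scale_info <- list(ref_baseline = B, ref_minimum = M, ref_curve = ref)
  }
  if (!nrow(Y)) stop("all voxels flagged; no usable curves")
  flags <- rep(TRUE, length(vox))
  flags[ok] <- FALSE
  structure(list(
    matrix = Y,
    voxels = vox[ok],
    all_voxels = vox,
    flags = flags,
    shifts = shifts[ok],
    baseline_frames = bf,
    target_index = tgt,
    mode = mode,
    margin = margin,
    grid = grid,
    scale = scale_info
  ), class = "normalized_curves")
}

#' @export
print.normalized_curves <- function(x, ...) {
  cat("normalized_curves:", nrow(x$matrix), "valid voxels x", ncol(x$matrix),
      "frames (mode", x$mode, "),", sum(x$flags), "flagged\n")
  invisible(x)
}

#' Stratified training-voxel sample across a cohort
#'
#' Uniform sampling without replacement of up to `n_per_roi` valid voxels per
#' subject per tumor subregion (NC = 1, ED = 2, ET = 4), with provenance
#' retained for cross-validation leakage audits. An empty stratum contributes
#' zero voxels with a warning.
#'
#' @param curves list of `normalized_curves`, one per subject.
#' @param segs list of 3D integer label arrays, one per subject.
#' @param n_per_roi voxels requested per subject per subregion.
#' @param seed RNG seed.
#' @param subject_ids optional character ids (defaults to `subject-01`, ...).
#' @return list with `features` (matrix of sampled curve rows), `provenance`
#'   (data.frame: subject, roi, voxel linear index, row index into the
#'   subject's curve matrix).
#' @export
sample_training_voxels <- function(curves, segs, n_per_roi = 1000L,
                                   seed = 1L, subject_ids = NULL) {
  stopifnot(length(curves) == length(segs))
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("subject-%02d", seq_along(curves))
  }
  set.seed(seed)
  rois <- c(NC = 1L, ED = 2L, ET = 4L)
  feat <- list(); prov <- list()
  for (s in seq_along(curves)) {
    cv <- curves[[s]]
    lab <- segs[[s]][cv$voxels]
    for (r in seq_along(rois)) {
      cand <- which(lab == rois[r])
      if (!length(cand)) {
        warning("empty ", names(rois)[r], " stratum for ", subject_ids[s])
        next
      }
      take <- if (length(cand) <= n_per_roi) cand
              else sort(sample(cand, n_per_roi))
      feat[[length(feat) + 1L]] <- cv$matrix[take, , drop = FALSE]
      prov[[length(prov) + 1L]] <- data.frame(
        subject = subject_ids[s],
        roi = names(rois)[r],
        voxel = cv$voxels[take],
        row = take,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(feat)) stop("no voxels sampled in any stratum")
  list(features = do.call(rbind, feat), provenance = do.call(rbind, prov))
}

#' Temporal principal component decomposition
#'
#' Mean-centered principal component analysis of curves (rows) over
#' timepoints (columns), computed by singular value decomposition of the
#' centered matrix. Components are ordered by decreasing explained variance;
#' the sign of each component is fixed so its largest-magnitude loading is
#' positive, making the decomposition deterministic across runs and
#' platforms.
#'
#' @param x numeric matrix, curves x timepoints.
#' @param n_components number of components to retain (default 7).
#' @param strict if TRUE, error when fewer than `n_components` usable
#'   components exist (rank deficiency or zero variance); otherwise reduce
#'   with a flag.
#' @return object of class `pc_model`: `mean` curve, `components`
#'   (n_components x timepoints, orthonormal rows), `explained_variance_ratio`
#'   (retained components), `all_ratios` (every nonzero component),
#'   `n_components`, `degenerate` flag.
#' @export
fit_pca <- function(x, n_components = 7L, strict = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < n_components || p < n_components) {
    stop("need at least n_components rows and columns")
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  sv <- svd(xc)
  var_all <- sv$d^2 / max(n - 1L, 1L)
  total <- sum(var_all)
  if (total <= .Machine$double.eps * p) {
    if (strict) stop("zero total variance: all curves identical")
    comp <- matrix(0, 0, p)
    return(structure(list(mean = mu, components = comp,
                          explained_variance_ratio = numeric(0),
                          all_ratios = numeric(0), n_components = 0L,
                          degenerate = TRUE), class = "pc_model"))
  }
  usable <- sum(sv$d > max(sv$d) * 1e-10)
  k <- min(n_components, usable)
  if (k < n_components && strict) {
    stop("only ", usable, " usable components; ", n_components, " requested")
  }
  comp <- t(sv$v[, seq_len(k), drop = FALSE])
  for (i in seq_len(k)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  ratios <- var_all / total
  structure(list(
    mean = mu,
    components = comp,
    explained_variance_ratio = ratios[seq_len(k)],
    all_ratios = ratios[seq_len(usable)],
    n_components = k,
    degenerate = FALSE
  ), class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("pc_model:", x$n_components, "components over", length(x$mean),
      "timepoints; cumulative variance",
      round(100 * sum(x$explained_variance_ratio), 2), "%\n")
  invisible(x)
}

#' Project curves onto a PC model
#'
#' @param model a `pc_model`.
#' @param x matrix of curves (rows) with the model's timepoint count.
#' @return matrix of scores, rows x n_components.
#' @export
pc_scores <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != length(model$mean)) {
    stop("curve length does not match the model's timepoint count")
  }
  sweep(x, 2L, model$mean) %*% t(model$components)
}

#' Per-voxel PC score maps
#'
#' Projects a subject's valid normalized curves onto the cohort PC model and
#' assembles one 3D score map per component; excluded voxels are NaN.
#'
#' @param curves a `normalized_curves` built from a 4D series.
#' @param model a `pc_model`.
#' @param grid_shape 3D grid dimensions (defaults to the curves' grid).
#' @return 4D array (x, y, z, component) with NaN outside the valid voxels.
#' @export
pc_score_maps <- function(curves, model, grid_shape = NULL) {
  if (is.null(grid_shape)) grid_shape <- curves$grid
  if (is.null(grid_shape)) stop("grid shape unknown; supply grid_shape")
  sc <- pc_scores(model, curves$matrix)
  k <- ncol(sc)
  maps <- array(NaN, dim = c(grid_shape, k))
  nvol <- prod(grid_shape)
  for (j in seq_len(k)) {
    maps[(j - 1L) * nvol + curves$voxels] <- sc[, j]
  }
  maps
}
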