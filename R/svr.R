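#' Train a Gaussian-kernel support vector regressor for one subregion
#'
#' Epsilon-insensitive support vector regression with a radial (Gaussian)
#' kernel, fitted by SMO (libsvm via e1071). Features are standardized by
#' their training mean and SD (the same transform is applied at prediction).
#' The "automatic" kernel scale is the median pairwise Euclidean distance
#' among at most `subsample` standardized training rows (seeded subsample),
#' with `gamma = 1 / (2 * scale^2)`. The default box constraint is 1 and the
#' default epsilon is `IQR(targets) / 13.49` (an SD-consistent tube width).
#'
#' @param x feature matrix (rows = voxels, columns = PC scores); >= 10 rows.
#' @param y numeric targets (MTR_asym values).
#' @param cost box constraint C.
#' @param epsilon insensitive-tube half-width; NULL for the IQR default.
#' @param kernel_scale Gaussian kernel scale; NULL for the median-distance
#'   heuristic.
#' @param subsample maximum rows used by the kernel-scale heuristic.
#' @param seed seed for the heuristic's subsample.
#' @param roi optional subregion tag stored with the model.
#' @param provenance optional character vector of training subject ids.
#' @return object of class `roi_regressor`.
#' @export
train_svr <- function(x, y, cost = 1, epsilon = NULL, kernel_scale = NULL,
                      subsample = 2000L, seed = 1L, roi = NULL,
                      provenance = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) < 10L) stop("at least 10 training rows are required")
  if (nrow(x) != length(y)) stop("feature rows and targets differ in length")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("features and targets must be finite")
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  if (all(scl <= 0)) stop("degenerate features: zero variance in every column")
  scl[scl <= 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  if (is.null(kernel_scale)) {
    set.seed(seed)
    idx <- if (nrow(xs) > subsample) sample(nrow(xs), subsample)
           else seq_len(nrow(xs))
    kernel_scale <- stats::median(stats::dist(xs[idx, , drop = FALSE]))
    if (!is.finite(kernel_scale) || kernel_scale <= 0) kernel_scale <- 1
  }
  gamma <- 1 / (2 * kernel_scale^2)
  if (is.null(epsilon)) {
    epsilon <- max(stats::IQR(y) / 13.49, 1e-6)
  }
  ## constant (or within-tube) targets leave libsvm with no support vectors;
  ## the model then degenerates to its bias, the mean target
  model <- if (stats::sd(y) == 0) NULL else tryCatch(
    e1071::svm(xs, y, type = "eps-regression", kernel = "radial",
               gamma = gamma, cost = cost, epsilon = epsilon,
               scale = FALSE),
    error = function(e) {
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) NULL
      else stop(e)
    })
  structure(list(
    model = model, bias = mean(y), center = ctr, scale = scl, gamma = gamma,
    kernel_scale = kernel_scale, cost = cost, epsilon = epsilon,
    roi = roi, provenance = provenance, n_train = nrow(x)
  ), class = "roi_regressor")
}

#' @export
predict.roi_regressor <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(object$model)) return(rep(object$bias, nrow(newdata)))
  xs <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  as.numeric(stats::predict(object$model, xs))
}

#' @export
print.roi_regressor <- function(x, ...) {
  cat("roi_regressor", if (!is.null(x$roi)) paste0("[", x$roi, "]"), ":",
      x$n_train, "rows, kernel scale", signif(x$kernel_scale, 4),
      ", C", x$cost, ", epsilon", signif(x$epsilon, 4), "\n")
  invisible(x)
}

roi_labels <- c(NC = 1L, ED = 2L, ET = 4L)

#' Leave-one-subject-out cross-validated MTR_asym construction
#'
#' For each held-out subject, one regressor per tumor subregion (ET, NC, ED)
#' is trained on the stratified voxel samples of all *other* subjects
#' (features = PC scores, targets = actual MTR_asym), and every valid voxel
#' of the held-out subject is predicted by the regressor of its own
#' subregion, producing a constructed MTR_asym map over the union of the
#' three subregions. Training provenance is retained per fold and per
#' subregion so leakage can be audited exactly.
#'
#' @param subjects list; each element needs `scores` (matrix voxels x PCs),
#'   `roi` (integer labels per row: 1 NC, 2 ED, 4 ET, 0 otherwise), `actual`
#'   (numeric MTR_asym per row, NA where invalid), `voxels` (linear voxel
#'   indices), `grid` (3D dims), `id`.
#' @param sample_rows optional named list (by subject id) of integer row
#'   indices to train on; NULL uses every labeled row.
#' @param cost,epsilon,kernel_scale,subsample passed to [train_svr()].
#' @param seed seed for the kernel-scale heuristic.
#' @return object of class `loso_result`: per subject a `constructed` 3D
#'   array (NA outside predicted voxels) plus fold `provenance` (list
#'   roi -> training subject ids).
#' @export
loso_cv <- function(subjects, sample_rows = NULL, cost = 1, epsilon = NULL,
                    kernel_scale = NULL, subsample = 2000L, seed = 1L) {
  n <- length(subjects)
  if (n < 3L) stop("leave-one-subject-out requires at least 3 subjects")
  ids <- vapply(subjects, function(s) s$id, character(1))
  train_rows <- function(s) {
    rows <- if (!is.null(sample_rows)) sample_rows[[s$id]]
            else seq_len(nrow(s$scores))
    rows[is.finite(s$actual[rows]) & s$roi[rows] %in% roi_labels]
  }
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    test <- subjects[[i]]
    constructed <- array(NA_real_, dim = test$grid)
    prov <- list()
    for (r in names(roi_labels)) {
      lab <- roi_labels[[r]]
      xs <- list(); ys <- list(); contrib <- character(0)
      for (j in setdiff(seq_len(n), i)) {
        tr <- subjects[[j]]
        rows <- train_rows(tr)
        rows <- rows[tr$roi[rows] == lab]
        if (!length(rows)) next
        xs[[length(xs) + 1L]] <- tr$scores[rows, , drop = FALSE]
        ys[[length(ys) + 1L]] <- tr$actual[rows]
        contrib <- c(contrib, tr$id)
      }
      if (!length(xs)) {
        warning("no training voxels for ", r, " in fold ", test$id)
        next
      }
      reg <- train_svr(do.call(rbind, xs), unlist(ys), cost = cost,
                       epsilon = epsilon, kernel_scale = kernel_scale,
                       subsample = subsample, seed = seed, roi = r,
                       provenance = contrib)
      prov[[r]] <- contrib
      pred_rows <- which(test$roi == lab & is.finite(test$actual))
      if (length(pred_rows)) {
        constructed[test$voxels[pred_rows]] <-
          predict(reg, test$scores[pred_rows, , drop = FALSE])
      }
    }
    folds[[i]] <- list(id = test$id, constructed = constructed,
                       provenance = prov)
  }
  structure(list(folds = folds, ids = ids), class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat("loso_result:", length(x$folds), "folds\n")
  invisible(x)
}
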