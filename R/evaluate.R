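## all permutations of 1..n as a matrix (n! rows); n <= 9 only
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq.int(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[row + seq_len(nrow(sub)), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

#' Spearman correlation with a two-sided p-value
#'
#' The rank correlation of paired observations. For n >= 10 the p-value uses
#' the large-sample t approximation `t = r * sqrt((n-2)/(1-r^2))` on n - 2
#' degrees of freedom; below 10 pairs the exact permutation distribution of
#' the rank correlation is enumerated.
#'
#' @param x,y paired numeric vectors.
#' @return list with `r`, `p`, `n`.
#' @export
spearman_test <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y, method = "spearman")
  if (!is.finite(r)) return(list(r = NA_real_, p = NA_real_, n = n))
  if (n < 10L) {
    rx <- rank(x); ry <- rank(y)
    perms <- all_permutations(n)
    rperm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rperm) >= abs(r) - 1e-12)
  } else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Evaluate constructed against actual MTR_asym maps
#'
#' Per subject and per region (ET, NC, ED, and their union — the whole
#' pathogenic region), the Spearman rank correlation between constructed and
#' actual MTR_asym over paired valid voxels. A region with fewer than 3
#' pairs is marked not-evaluable. The cohort summary is the unweighted mean
#' of the per-subject correlations for each region.
#'
#' @param constructed list of 3D arrays (one per subject) or a single array.
#' @param actual matching list of 3D arrays (or `acidity_map` objects).
#' @param segs matching list of 3D integer label arrays (1 NC, 2 ED, 4 ET).
#' @param subject_ids optional character ids.
#' @return object of class `eval_report`: `table` (data.frame subject,
#'   region, n_voxels, r, p) and `summary` (data.frame region, mean_r,
#'   n_subjects).
#' @export
evaluate <- function(constructed, actual, segs, subject_ids = NULL) {
  aslist <- function(x) if (is.list(x) && is.null(dim(x))) x else list(x)
  constructed <- aslist(constructed)
  actual <- aslist(actual)
  segs <- aslist(segs)
  stopifnot(length(constructed) == length(actual),
            length(actual) == length(segs))
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("subject-%02d", seq_along(constructed))
  }
  regions <- list(ET = 4L, NC = 1L, ED = 2L, union = c(1L, 2L, 4L))
  rows <- list()
  for (s in seq_along(constructed)) {
    con <- constructed[[s]]
    act <- actual[[s]]
    if (inherits(act, "acidity_map")) act <- act$values
    seg <- segs[[s]]
    if (!all(dim(con) == dim(act)) || !all(dim(act) == dim(seg))) {
      stop("constructed, actual and segmentation grids differ for ",
           subject_ids[s])
    }
    for (rg in names(regions)) {
      idx <- which(seg %in% regions[[rg]])
      st <- spearman_test(con[idx], act[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject_ids[s], region = rg, n_voxels = st$n,
        r = st$r, p = st$p, stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(names(regions), function(rg) {
    rr <- tab$r[tab$region == rg]
    data.frame(region = rg, mean_r = mean(rr, na.rm = TRUE),
               n_subjects = sum(is.finite(rr)), stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, summary = summ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report — cohort mean Spearman r by region:\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-6s %.3f  (%d subjects)\n", x$summary$region[i],
                x$summary$mean_r[i], x$summary$n_subjects[i]))
  }
  invisible(x)
}
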