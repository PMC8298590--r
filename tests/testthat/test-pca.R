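make_series <- function(curves, grid = NULL) {
  # stack identical-length curves (rows) into a 4D volume
  n <- nrow(curves)
  if (is.null(grid)) grid <- c(n, 1L, 1L)
  arr <- array(0, c(grid, ncol(curves)))
  for (j in seq_len(ncol(curves))) arr[(j - 1L) * prod(grid) + seq_len(n)] <-
      curves[, j]
  arr
}

bolus_curve <- function(L, D, R = 1, t0 = 12, k = 2, nt = 40L, tr = 1) {
  dsc_expectation((seq_len(nt) - 1) * tr, L, D, R, t0, k)
}

test_that("identical curves normalize to identical rows with zero shifts", {
  cv <- bolus_curve(100, 0.5)
  X <- matrix(rep(cv, each = 20L), nrow = 20L)
  nc <- normalize_and_align(X, baseline_frames = 8L)
  expect_true(all(nc$shifts == 0L))
  expect_equal(nc$matrix, matrix(rep(nc$matrix[1, ], each = 20L), nrow = 20L))
})

test_that("normalized curves are invariant to amplitude rescaling", {
  set.seed(2)
  L <- runif(30, 50, 200)
  X <- t(vapply(L, function(l) bolus_curve(l, 0.4, 0.7), numeric(40L)))
  for (mode in c("subject", "voxel")) {
    a <- normalize_and_align(X, baseline_frames = 8L, mode = mode)
    b <- normalize_and_align(3.7 * X, baseline_frames = 8L, mode = mode)
    expect_equal(a$matrix, b$matrix, tolerance = 1e-12)
  }
  # per-voxel mode also erases which L each row had
  v1 <- normalize_and_align(t(replicate(10, bolus_curve(200, 0.4))),
                            baseline_frames = 8L, mode = "voxel")
  v2 <- normalize_and_align(t(replicate(10, bolus_curve(400, 0.4))),
                            baseline_frames = 8L, mode = "voxel")
  expect_equal(v1$matrix, v2$matrix, tolerance = 1e-12)
})

test_that("per-voxel normalization pins baseline to 1 and minimum to 0", {
  set.seed(3)
  X <- t(replicate(25, bolus_curve(runif(1, 50, 300), runif(1, 0.2, 0.6),
                                   runif(1, 0.5, 1))))
  nc <- normalize_and_align(X, baseline_frames = 8L, mode = "voxel")
  bf <- nc$baseline_frames
  expect_lt(max(abs(rowMeans(nc$matrix[, seq_len(bf)]) - 1)), 1e-6)
  expect_lt(max(abs(apply(nc$matrix, 1L, min))), 1e-6)
})

test_that("flat curves are flagged as bolus-free and excluded", {
  X <- rbind(t(replicate(10, bolus_curve(100, 0.5))),
             matrix(100, 4L, 40L))
  nc <- normalize_and_align(X, baseline_frames = 8L)
  expect_identical(sum(nc$flags), 4L)
  expect_identical(nrow(nc$matrix), 10L)
  # a fully flat series has no detectable bolus anywhere
  expect_error(normalize_and_align(matrix(7, 10L, 40L), baseline_frames = 8L),
               "bolus")
})

test_that("baseline auto-detection lands just before the steepest drop", {
  cv <- bolus_curve(100, 0.5, t0 = 12, k = 2, nt = 40L)
  bf <- detect_baseline_frames(cv)
  expect_gte(bf, 3L)
  expect_lt(bf, which.min(cv))
  # never claims frames after the bolus arrival (t0 = 12 s -> frame 13)
  expect_lte(bf, 13L)
})

test_that("alignment shifts each curve's minimum to the target frame", {
  set.seed(4)
  t0s <- sample(10:16, 24L, replace = TRUE)
  X <- t(vapply(t0s, function(t0) bolus_curve(100, 0.5, t0 = t0, nt = 48L),
                numeric(48L)))
  nc <- normalize_and_align(X, baseline_frames = 8L, target_index = 30L)
  mins <- apply(nc$matrix, 1L, which.min)
  expect_true(all(mins == 30L))
})

test_that("stratified sampling clamps, reproduces, and keeps provenance", {
  co <- clean_cohort()
  curves <- lapply(co$subjects, function(s)
    normalize_and_align(s$dsc, s$mask, baseline_frames = s$baseline_frames))
  segs <- lapply(co$subjects, `[[`, "seg")
  s1 <- sample_training_voxels(curves, segs, n_per_roi = 40L, seed = 7L)
  s2 <- sample_training_voxels(curves, segs, n_per_roi = 40L, seed = 7L)
  expect_identical(s1, s2)
  expect_lte(nrow(s1$features), 3L * 3L * 40L)
  expect_identical(nrow(s1$features), nrow(s1$provenance))
  # clamping: a stratum smaller than the request is taken whole
  counts <- table(s1$provenance$subject, s1$provenance$roi)
  roi_sizes <- t(vapply(seq_along(curves), function(i) {
    lab <- segs[[i]][curves[[i]]$voxels]
    c(ED = sum(lab == 2L), ET = sum(lab == 4L), NC = sum(lab == 1L))
  }, numeric(3)))
  expect_true(all(counts == pmin(roi_sizes, 40L)))
  # no sampled voxel lies outside its stated subregion
  for (i in seq_len(nrow(s1$provenance))) {
    pr <- s1$provenance[i, ]
    sidx <- as.integer(sub("subject-", "", pr$subject))
    lab <- segs[[sidx]][pr$voxel]
    expect_identical(unname(c(NC = 1L, ED = 2L, ET = 4L)[pr$roi]), lab)
  }
})

test_that("fit_pca matches an independent eigendecomposition oracle", {
  set.seed(10)
  for (rep in 1:3) {
    x <- matrix(rnorm(50 * 20), 50, 20)
    model <- fit_pca(x, n_components = 7L)
    ev <- eigen(cov(x), symmetric = TRUE)           # independent route
    oracle_ratio <- ev$values / sum(ev$values)
    expect_equal(model$explained_variance_ratio, oracle_ratio[1:7],
                 tolerance = 1e-8)
    # components span the same directions (up to sign, fixed by convention)
    for (j in 1:7) {
      expect_equal(abs(sum(model$components[j, ] * ev$vectors[, j])), 1,
                   tolerance = 1e-8)
    }
  }
})

test_that("PC model is orthonormal, sign-fixed, and reconstructs its input", {
  set.seed(11)
  x <- matrix(rnorm(40 * 16), 40, 16) %*% diag(seq(2, 0.5, length.out = 16))
  model <- fit_pca(x, n_components = 16L)
  G <- model$components %*% t(model$components)
  expect_equal(G, diag(16L), tolerance = 1e-8)
  expect_true(all(apply(model$components, 1L,
                        function(r) r[which.max(abs(r))] > 0)))
  expect_equal(sum(model$all_ratios), 1, tolerance = 1e-12)
  expect_true(all(diff(model$explained_variance_ratio) <= 1e-12))
  sc <- pc_scores(model, x)
  rec <- sweep(sc %*% model$components, 2L, model$mean, "+")
  expect_equal(rec, x, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rank-1 data yields one component explaining everything", {
  set.seed(12)
  v <- rnorm(20); v <- v / sqrt(sum(v^2))
  a <- rnorm(30)
  x <- outer(a, v) + matrix(rep(rnorm(20), each = 30), 30)
  model <- fit_pca(x, n_components = 7L, strict = FALSE)
  expect_identical(model$n_components, 1L)
  expect_equal(model$explained_variance_ratio[1], 1, tolerance = 1e-10)
  expect_equal(abs(sum(model$components[1, ] * v)), 1, tolerance = 1e-8)
  expect_error(fit_pca(x, n_components = 7L, strict = TRUE), "usable")
})

test_that("degenerate inputs error in strict mode and flag otherwise", {
  x <- matrix(5, 20L, 12L)
  expect_error(fit_pca(x, n_components = 3L, strict = TRUE), "identical")
  model <- fit_pca(x, n_components = 3L, strict = FALSE)
  expect_true(model$degenerate)
  expect_identical(model$n_components, 0L)
  expect_error(fit_pca(matrix(1, 3L, 12L), n_components = 7L), "at least")
})

test_that("scores are zero at the mean and recover injected components", {
  set.seed(13)
  x <- matrix(rnorm(30 * 12), 30, 12)
  model <- fit_pca(x, n_components = 5L)
  expect_equal(as.numeric(pc_scores(model, rbind(model$mean))), rep(0, 5L),
               tolerance = 1e-10)
  probe <- rbind(model$mean + 2 * model$components[1, ])
  expect_equal(as.numeric(pc_scores(model, probe)), c(2, rep(0, 4L)),
               tolerance = 1e-10)
  expect_error(pc_scores(model, matrix(0, 2, 5)), "length")
})

test_that("PC1 scores track the latent perfusion level on the phantom", {
  co <- clean_cohort()
  s <- co$subjects[[1]]
  nc <- normalize_and_align(s$dsc, s$mask,
                            baseline_frames = s$baseline_frames)
  model <- fit_pca(nc$matrix, n_components = 7L)
  sc <- pc_scores(model, nc$matrix)
  L <- s$truth$L[nc$voxels]
  expect_gte(abs(cor(sc[, 1], L, method = "spearman")), 0.8)
})

test_that("score maps carry NaN outside the valid voxels", {
  co <- clean_cohort()
  s <- co$subjects[[1]]
  nc <- normalize_and_align(s$dsc, s$mask,
                            baseline_frames = s$baseline_frames)
  model <- fit_pca(nc$matrix, n_components = 3L)
  maps <- pc_score_maps(nc, model)
  expect_identical(dim(maps), c(dim(s$mask), 3L))
  m1 <- maps[, , , 1]
  expect_true(all(is.nan(m1[!s$mask])))
  expect_true(all(is.finite(m1[nc$voxels])))
})
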