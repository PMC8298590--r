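# assemble the per-subject inputs loso_cv needs from a phantom cohort,
# using the true acidity as the regression target (bypasses CEST timing)
loso_inputs <- function(cohort, n_components = 7L) {
  curves <- lapply(cohort$subjects, function(s)
    normalize_and_align(s$dsc, s$mask, baseline_frames = s$baseline_frames))
  samp <- sample_training_voxels(curves,
                                 lapply(cohort$subjects, `[[`, "seg"),
                                 n_per_roi = 500L, seed = 21L)
  model <- fit_pca(samp$features, n_components = n_components)
  subjects <- lapply(seq_along(cohort$subjects), function(i) {
    s <- cohort$subjects[[i]]
    cv <- curves[[i]]
    list(id = s$id,
         scores = pc_scores(model, cv$matrix),
         roi = s$seg[cv$voxels],
         actual = s$truth$true_acidity[cv$voxels],
         voxels = cv$voxels,
         grid = dim(s$mask))
  })
  list(subjects = subjects, model = model,
       sample_rows = split(samp$provenance$row, samp$provenance$subject))
}

test_that("constant targets collapse the SVR to its bias", {
  set.seed(31)
  x <- matrix(rnorm(60 * 4), 60, 4)
  reg <- train_svr(x, rep(0.042, 60))
  pred <- predict(reg, matrix(rnorm(40), 10, 4))
  expect_equal(pred, rep(0.042, 10L), tolerance = 1e-9)
})

test_that("a noise-free linear map is fitted to 1e-3 with a tight tube", {
  set.seed(32)
  x <- matrix(rnorm(300 * 3), 300, 3)
  y <- drop(x %*% c(0.5, -0.2, 0.1)) + 1
  reg <- train_svr(x, y, cost = 1e4, epsilon = 1e-5)
  expect_lt(max(abs(predict(reg, x) - y)), 1e-3)
})

test_that("training preconditions are enforced", {
  x <- matrix(rnorm(20), 5, 4)
  expect_error(train_svr(x, rnorm(5)), "10")
  expect_error(train_svr(matrix(1, 20, 3), rnorm(20)), "variance")
  xb <- matrix(rnorm(40), 10, 4); xb[1] <- NA
  expect_error(train_svr(xb, rnorm(10)), "finite")
})

test_that("kernel scale heuristic is the median pairwise distance", {
  set.seed(33)
  x <- matrix(rnorm(50 * 5), 50, 5)
  reg <- train_svr(x, rnorm(50))
  xs <- sweep(sweep(x, 2, colMeans(x)), 2, apply(x, 2, sd), "/")
  expect_equal(reg$kernel_scale, median(dist(xs)), tolerance = 1e-12)
  expect_equal(reg$gamma, 1 / (2 * reg$kernel_scale^2), tolerance = 1e-12)
})

test_that("LOSO folds never train on the held-out subject", {
  co <- clean_cohort()
  inp <- loso_inputs(co)
  loso <- loso_cv(inp$subjects, sample_rows = inp$sample_rows)
  expect_length(loso$folds, length(co$subjects))
  for (f in loso$folds) {
    for (prov in f$provenance) {
      expect_false(f$id %in% prov)
      expect_gt(length(prov), 0L)
    }
  }
})

test_that("predictions cover exactly the held-out subject's tumor voxels", {
  co <- clean_cohort()
  inp <- loso_inputs(co)
  loso <- loso_cv(inp$subjects, sample_rows = inp$sample_rows)
  for (i in seq_along(loso$folds)) {
    f <- loso$folds[[i]]
    sub <- inp$subjects[[i]]
    predicted <- which(is.finite(f$constructed))
    tumor <- sub$voxels[sub$roi %in% c(1L, 2L, 4L) & is.finite(sub$actual)]
    expect_setequal(predicted, tumor)
  }
})

test_that("two identical subjects exchange LOSO predictions exactly", {
  co <- clean_cohort()
  inp <- loso_inputs(co)
  # clone subject 1 twice plus one distinct subject: fold for clone A trains
  # on clone B (+ the distinct one) and vice versa, so their constructed
  # maps must coincide
  s1 <- inp$subjects[[1]]
  sA <- s1; sA$id <- "clone-A"
  sB <- s1; sB$id <- "clone-B"
  rows <- inp$sample_rows[[s1$id]]
  loso <- loso_cv(list(sA, sB, inp$subjects[[2]]),
                  sample_rows = list(`clone-A` = rows, `clone-B` = rows,
                                     `subject-02` = inp$sample_rows[["subject-02"]]))
  expect_equal(loso$folds[[1]]$constructed, loso$folds[[2]]$constructed,
               tolerance = 1e-10)
})

test_that("constructed maps are invariant to voxel ordering within an ROI", {
  co <- clean_cohort()
  inp <- loso_inputs(co)
  base <- loso_cv(inp$subjects, sample_rows = inp$sample_rows)
  perm_subjects <- inp$subjects
  s <- perm_subjects[[2]]
  set.seed(40)
  p <- sample(nrow(s$scores))
  perm_subjects[[2]] <- list(id = s$id, scores = s$scores[p, , drop = FALSE],
                             roi = s$roi[p], actual = s$actual[p],
                             voxels = s$voxels[p], grid = s$grid)
  # keep training rows pointing at the same physical voxels
  rows <- inp$sample_rows
  rows[[s$id]] <- match(rows[[s$id]], p)
  perm <- loso_cv(perm_subjects, sample_rows = rows)
  expect_equal(perm$folds[[2]]$constructed, base$folds[[2]]$constructed,
               tolerance = 1e-10)
})

test_that("Spearman evaluation honors identity, reversal, and monotone maps", {
  co <- clean_cohort()
  s <- co$subjects[[1]]
  act <- s$truth$true_acidity
  rep1 <- evaluate(act, act, s$seg)
  expect_equal(rep1$table$r, rep(1, 4L), tolerance = 1e-12)
  rep2 <- evaluate(-act, act, s$seg)
  expect_equal(rep2$table$r, rep(-1, 4L), tolerance = 1e-12)
  rep3 <- evaluate(act^3, act, s$seg)  # rank-preserving transform
  expect_equal(rep3$table$r, rep(1, 4L), tolerance = 1e-12)
  expect_setequal(rep1$table$region, c("ET", "NC", "ED", "union"))
})

test_that("small regions get exact permutation p-values", {
  x <- c(1, 2, 3, 4, 5)
  st <- spearman_test(x, x)
  expect_equal(st$r, 1)
  expect_equal(st$p, 2 / factorial(5))  # only the two extreme orderings
  st2 <- spearman_test(x, c(2, 1, 4, 3, 5))
  expect_gt(st2$p, st$p)
  expect_true(is.na(spearman_test(c(1, 2), c(3, 4))$r))
})

test_that("large-sample p-values follow the t approximation", {
  set.seed(41)
  x <- rnorm(60); y <- x + rnorm(60, 0, 2)
  st <- spearman_test(x, y)
  tt <- st$r * sqrt((st$n - 2) / (1 - st$r^2))
  expect_equal(st$p, 2 * pt(-abs(tt), st$n - 2), tolerance = 1e-12)
})

test_that("regions below three paired voxels are not evaluable", {
  grid <- c(4L, 4L, 2L)
  seg <- array(0L, grid); seg[1:2] <- 4L; seg[3:8] <- 2L
  a <- array(runif(prod(grid)), grid)
  rep <- evaluate(a, a, seg)
  expect_true(is.na(rep$table$r[rep$table$region == "ET"]))
  expect_false(is.na(rep$table$r[rep$table$region == "ED"]))
})

test_that("cohort summary averages per-subject correlations unweighted", {
  co <- clean_cohort()
  segs <- lapply(co$subjects, `[[`, "seg")
  acts <- lapply(co$subjects, function(s) s$truth$true_acidity)
  set.seed(42)
  cons <- lapply(acts, function(a) a + array(rnorm(length(a), 0, 0.01),
                                             dim = dim(a)))
  rep <- evaluate(cons, acts, segs)
  per_subj <- rep$table$r[rep$table$region == "union"]
  expect_equal(rep$summary$mean_r[rep$summary$region == "union"],
               mean(per_subj), tolerance = 1e-12)
})
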