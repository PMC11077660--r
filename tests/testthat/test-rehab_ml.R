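make_gf <- function(n, side) {
  structure(data.frame(
    cycle_index = seq_len(n), side = rep_len(side, n),
    maxaa = stats::rnorm(n, 105, 3), minaa = stats::rnorm(n, 86, 3),
    max_ang_vel = stats::rnorm(n, 50, 5), gcd = stats::rnorm(n, 1.3, 0.1),
    peak_time = seq_len(n) * 1.3, trough_time = seq_len(n) * 1.3 + 0.7),
    class = c("gait_features", "data.frame"))
}

test_that("feature assembly pairs cycles and enforces the column schema", {
  set.seed(1)
  fm <- build_features(make_gf(100, "left"), make_gf(100, "right"),
                       "patient")
  expect_equal(dim(fm), c(100, 9))
  expect_identical(names(fm)[1:8], cifes:::FEATURE_COLUMNS)
  # unequal lengths: unpaired trailing cycles dropped
  fm2 <- build_features(make_gf(100, "left"), make_gf(98, "right"), "p")
  expect_equal(nrow(fm2), 98)
  expect_error(build_features(make_gf(0, "left"), make_gf(5, "right"),
                              "p"), "non-empty")
  # permuted columns are rejected on load
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fm, path)
  expect_s3_class(read_features_csv(path), "feature_matrix")
  shuffled <- fm[, c(2, 1, 3:9)]
  utils::write.csv(shuffled, path, row.names = FALSE)
  expect_error(read_features_csv(path), "schema")
})

test_that("widely separated classes are classified perfectly", {
  set.seed(5)
  # unit-variance features; one feature shifted by 20 within-class SDs
  a <- as.data.frame(matrix(stats::rnorm(60 * 8), 60, 8))
  names(a) <- cifes:::FEATURE_COLUMNS
  b <- a
  b$r_maxaa <- b$r_maxaa + 20
  a$label <- "healthy"; b$label <- "patient"
  rep <- crossval_svm(rbind(a, b), folds = 10, seed = 1)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(sum(diag(rep$confusion)), 120)
})

test_that("identical class distributions score at chance within the 99% binomial band", {
  p <- make_profile("foot_drop")
  a <- sample_cycle_features(p, 300, seed = 41)
  b <- sample_cycle_features(p, 300, seed = 42)
  a$label <- "g1"; b$label <- "g2"
  rep <- crossval_svm(rbind(a, b), folds = 10, seed = 1)
  band <- 2.576 * sqrt(0.25 / 600)
  expect_lt(abs(rep$accuracy - 0.5), band)
})

test_that("folds partition rows into equal stratified validation sets", {
  set.seed(2)
  x <- sample_cycle_features(make_profile("healthy"), 300)
  y <- sample_cycle_features(make_profile("foot_drop"), 300)
  x$label <- "healthy"; y$label <- "patient"
  both <- rbind(x, y)
  rep <- crossval_svm(both, folds = 10, seed = 7)
  expect_length(rep$fold_accuracy, 10)
  expect_equal(sum(rep$confusion), 600)          # every row validated once
  expect_equal(unname(rowSums(rep$confusion)), c(300, 300))
  # determinism given the seed
  rep2 <- crossval_svm(both, folds = 10, seed = 7)
  expect_identical(rep$fold_accuracy, rep2$fold_accuracy)
  expect_error(crossval_svm(both[c(1:15, 301:305), ], folds = 10),
               "at least 10")
  expect_error(crossval_svm(both[1:15, ], folds = 10), "2 classes")
})

test_that("label permutation drives accuracy into the chance band", {
  set.seed(3)
  x <- sample_cycle_features(make_profile("healthy"), 150)
  y <- sample_cycle_features(make_profile("foot_drop"), 150)
  x$label <- "healthy"; y$label <- "patient"
  both <- rbind(x, y)
  both$label <- sample(both$label)
  rep <- crossval_svm(both, folds = 10, seed = 1)
  expect_lt(abs(rep$accuracy - 0.5), 2.576 * sqrt(0.25 / 300) + 0.02)
})

test_that("ROC curves and confusion matrix are coherent", {
  set.seed(9)
  x <- sample_cycle_features(make_profile("healthy"), 50)
  y <- sample_cycle_features(make_profile("foot_drop"), 50)
  x$label <- "healthy"; y$label <- "patient"
  rep <- crossval_svm(rbind(x, y), folds = 5, seed = 1, roc = TRUE)
  expect_named(rep$roc, c("healthy", "patient"))
  for (r in rep$roc) {
    expect_true(all(r$sensitivity >= 0 & r$sensitivity <= 1))
    expect_true(all(diff(r$sensitivity) <= 0 | diff(r$specificity) <= 0))
  }
})

test_that("a synthetic recovery schedule yields a decaying discriminability trend", {
  p_fd <- make_profile("foot_drop")
  p_h <- make_profile("healthy")
  blend <- function(w) make_profile("foot_drop", list(
    maxaa_mean = (1 - w) * p_fd$maxaa_mean + w * p_h$maxaa_mean,
    maxaa_var = (1 - w) * p_fd$maxaa_var + w * p_h$maxaa_var,
    minaa_mean = (1 - w) * p_fd$minaa_mean + w * p_h$minaa_mean,
    minaa_var = (1 - w) * p_fd$minaa_var + w * p_h$minaa_var,
    gcd_mean = (1 - w) * p_fd$gcd_mean + w * p_h$gcd_mean,
    gcd_var = (1 - w) * p_fd$gcd_var + w * p_h$gcd_var))
  trends <- sapply(1:5, function(s) {
    set.seed(100 + s)
    sessions <- lapply(c(0, 0.5, 0.85, 1), function(w)
      sample_cycle_features(blend(w), 60))
    ref <- sample_cycle_features(p_h, 60)
    rehab_trend(sessions, ref, folds = 6, seed = s)
  })
  avg <- rowMeans(trends)
  # discriminability decays toward chance as the gait laws converge
  expect_true(all(diff(avg) <= 0.02))
  expect_gt(avg[1], avg[4] + 0.15)
  expect_lt(avg[4], 0.65)
})

test_that("a fully separable session scores a 1.0 trend point", {
  set.seed(8)
  ref <- as.data.frame(matrix(stats::rnorm(60 * 8), 60, 8))
  names(ref) <- cifes:::FEATURE_COLUMNS
  ses <- ref + 20
  expect_equal(rehab_trend(list(ses), ref, folds = 6, seed = 1), 1.0)
  # sessions indistinguishable from the reference sit at chance
  same <- as.data.frame(matrix(stats::rnorm(60 * 8), 60, 8))
  names(same) <- cifes:::FEATURE_COLUMNS
  acc <- rehab_trend(list(same), ref, folds = 6, seed = 1)
  expect_lt(abs(acc - 0.5), 0.2)
})
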