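test_that("DLDA posterior is symmetric between equidistant centroids", {
  # class means (0,0) and (2,2), equal per-variable spread
  train <- labeled_dataset(
    rbind(c(-1, -1), c(1, 1), c(1, 1), c(3, 3)), c(1, 1, 2, 2))
  m <- fit_dlda(train)
  expect_equal(unname(predict_score(m, matrix(c(1, 1), 1))), 0.5)
  expect_gt(predict_score(m, matrix(c(0, 0), 1)), 0.5)
  expect_lt(predict_score(m, matrix(c(2, 2), 1)), 0.5)
})

test_that("DLDA decisions are invariant under sample duplication", {
  train <- make_null_train(n1 = 6, n2 = 10, p = 8, seed = 41)
  dup <- labeled_dataset(rbind(train$X, train$X), rep(train$y, 2))
  Xte <- with_seed_local(42, matrix(rnorm(40), 5, 8))
  l1 <- classify(fit_dlda(train), Xte, seed = 1)
  l2 <- classify(fit_dlda(dup), Xte, seed = 1)
  expect_identical(as.integer(l1), as.integer(l2))
  # class means and the decision boundary direction are literally unchanged
  expect_equal(fit_dlda(dup)$m1, fit_dlda(train)$m1)
})

test_that("DLDA decisions are shift-invariant after sample normalization", {
  train <- make_null_train(n1 = 6, n2 = 10, p = 8, seed = 43)
  Xte <- with_seed_local(44, matrix(rnorm(40), 5, 8))
  shifted <- labeled_dataset(train$X + 7, train$y)
  m0 <- fit_dlda(labeled_dataset(normalize_samples(train$X), train$y))
  m1 <- fit_dlda(labeled_dataset(normalize_samples(shifted$X), shifted$y))
  expect_equal(predict_score(m0, normalize_samples(Xte)),
               predict_score(m1, normalize_samples(Xte + 7)))
})

test_that("DQDA uses class-specific variances", {
  # fitted class densities N(0,1) vs N(0,4): at x = 0 the ratio is 2:1
  a <- 1 / sqrt(2)
  train <- labeled_dataset(matrix(c(-a, a, -sqrt(2), sqrt(2)), 4, 1),
                           c(1, 1, 2, 2))
  m <- fit_dqda(train)
  expect_equal(unname(predict_score(m, matrix(0))), 2 / 3, tolerance = 1e-12)
  expect_equal(as.integer(classify(m, matrix(0))), 1L)
  # equal class variances: DQDA decisions coincide with DLDA
  tr <- make_null_train(n1 = 8, n2 = 8, p = 4, seed = 45)
  tr_eq <- labeled_dataset(rbind(tr$X[tr$y == 1L, ],
                                 tr$X[tr$y == 1L, ] + 0.3), tr$y)
  Xte <- with_seed_local(46, matrix(rnorm(60), 15, 4))
  expect_identical(as.integer(classify(fit_dqda(tr_eq), Xte, seed = 2)),
                   as.integer(classify(fit_dlda(tr_eq), Xte, seed = 2)))
  # posteriors of the two classes sum to one
  sc <- predict_score(fit_dqda(tr), Xte)
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("k-NN scores equal the brute-force neighbor vote", {
  train <- labeled_dataset(
    rbind(c(0, 0), c(1, 0), c(0, 1), c(4, 4), c(5, 4)),
    c(1, 1, 1, 2, 2))
  Xte <- rbind(c(0.2, 0.2), c(4.5, 4), c(2, 2))
  m3 <- fit_knn(train, 3)
  sc <- predict_score(m3, Xte)
  oracle <- apply(Xte, 1, function(x) {
    d <- colSums((t(train$X) - x)^2)
    mean(train$y[order(d)[1:3]] == 1L)
  })
  expect_equal(sc, oracle)
  # k = 1 self-match returns the stored point's class with score 1 or 0
  m1 <- fit_knn(train, 1)
  expect_equal(predict_score(m1, train$X), as.numeric(train$y == 1L))
  expect_error(fit_knn(train, 9), "cannot exceed")
})

test_that("PAM soft-thresholding and total-shrinkage behavior are correct", {
  st <- smotehd:::soft_threshold
  expect_equal(st(0.5, 0.2), 0.3)
  expect_equal(st(-0.1, 0.2), 0)
  expect_equal(st(-0.5, 0.2), -0.3)
  train <- make_null_train(n1 = 5, n2 = 15, p = 10, seed = 47)
  stats <- smotehd:::pam_stats(train)
  # total shrinkage leaves only the class priors: everything goes majority
  sc <- smotehd:::pam_score(stats, train$X, delta = 1e6)
  expect_equal(unname(sc), rep(5 / 20, 20), tolerance = 1e-12)
  # delta = 0 reproduces the unshrunken standardized-centroid rule
  sc0 <- smotehd:::pam_score(stats, train$X, delta = 0)
  ds <- stats$d
  expect_equal(smotehd:::soft_threshold(ds, 0), ds)
  # fitted model carries a CV-chosen delta from the grid
  m <- suppressWarnings(fit_pam(train, seed = 1))
  expect_true(m$delta %in% m$grid)
  expect_warning(fit_pam(train, seed = 1), "folds")
})

test_that("CART honors the stated depth, complexity and pruning settings", {
  train <- with_seed_local(48, labeled_dataset(
    matrix(c(rnorm(20, 0), rnorm(20, 6)), 40, 1), rep(c(1L, 2L), each = 20)))
  m <- fit_classifier(train, "CART", seed = 1)
  expect_equal(m$fit$control$maxdepth, 5)
  expect_equal(m$fit$control$cp, 0.01)
  # perfectly separable 1-D data: training accuracy 1
  expect_equal(as.integer(classify(m, train$X, seed = 1)), as.integer(train$y))
})

test_that("delegated classifiers return probability scores in [0, 1]", {
  sim <- simulate_dataset(sim_config(p = 12, n_train = 40, n_test = 10,
                                     k1 = 0.5, rho = 0, block_size = 4,
                                     p_de = 4, mu2 = 2, seed = 49))
  for (cl in c("RF", "SVM", "PLR-L1", "PLR-L2")) {
    m <- fit_classifier(sim$train, cl, seed = 7)
    sc <- predict_score(m, sim$test$X)
    expect_true(all(sc >= 0 & sc <= 1), info = cl)
    # strong signal: scores separate the classes (AUC well above chance)
    expect_gt(compute_metrics(sim$test$y, classify(m, sim$test$X, seed = 1),
                              sc)[["AUC"]], 0.8)
  }
})

test_that("thresholding is monotone and ties are resolved by a fair coin", {
  train <- labeled_dataset(
    rbind(c(-1, -1), c(1, 1), c(1, 1), c(3, 3)), c(1, 1, 2, 2))
  m <- fit_dlda(train)
  Xte <- with_seed_local(50, matrix(rnorm(100), 50, 2))
  n1_calls <- sapply(c(0.7, 0.5, 0.3), function(th) {
    sum(classify(m, Xte, threshold = th, seed = 1) == 1L)
  })
  expect_true(all(diff(n1_calls) >= 0))
  # score exactly at the threshold: Class-1 frequency 0.5 +/- 0.02 at 1e4 draws
  ties <- matrix(1, 10000, 2)  # every row scores exactly 0.5
  lab <- classify(m, ties, threshold = 0.5, seed = 2)
  expect_lt(abs(mean(lab == 1L) - 0.5), 0.02)
  expect_identical(as.integer(classify(m, ties, threshold = 0.5, seed = 2)),
                   as.integer(lab))
  # cut-off threshold equals the training class-1 fraction
  expect_equal(cutoff_threshold(make_null_train(8, 24, 5, 1)), 0.25)
})

test_that("variable-set mismatches are reported", {
  train <- make_null_train(n1 = 5, n2 = 10, p = 6, seed = 51)
  m <- fit_dlda(train)
  expect_error(predict_score(m, matrix(0, 1, 4)), "fitted on 6 variables")
  bad <- matrix(0, 1, 6)
  colnames(bad) <- paste0("W", 1:6)
  expect_error(predict_score(m, bad), "mismatch")
})
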