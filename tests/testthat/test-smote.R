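test_that("synthetic samples are the recorded interpolation of their parents", {
  train <- make_null_train(n1 = 10, n2 = 25, p = 15, seed = 11)
  aug <- smote_augment(train, smote_params(seed = 1))
  syn <- which(aug$origin == "synthetic")
  expect_length(syn, 15)
  for (i in syn) {
    x <- train$X[aug$parent_base[i], ]
    xr <- train$X[aug$parent_neighbor[i], ]
    u <- aug$weight[i]
    expect_equal(aug$data$X[i, ], x + u * (xr - x), tolerance = 1e-12)
    # convex hull: componentwise between the two parents
    expect_true(all(aug$data$X[i, ] >= pmin(x, xr) - 1e-12))
    expect_true(all(aug$data$X[i, ] <= pmax(x, xr) + 1e-12))
  }
  expect_true(all(aug$weight[syn] >= 0 & aug$weight[syn] <= 1))
  # parents are minority samples and neighbor differs from base
  expect_true(all(train$y[aug$parent_base[syn]] == 1L))
  expect_true(all(train$y[aug$parent_neighbor[syn]] == 1L))
  expect_true(all(aug$parent_base[syn] != aug$parent_neighbor[syn]))
  # original rows pass through untouched
  expect_identical(aug$data$X[seq_len(35), ], train$X)
})

test_that("endpoint weights reproduce the parents exactly", {
  x <- c(0, 0, 0); xr <- c(1, 2, -1)
  expect_equal(x + 0.5 * (xr - x), c(0.5, 1, -0.5))
  train <- make_null_train(n1 = 5, n2 = 10, p = 3, seed = 12)
  aug <- smote_augment(train, smote_params(seed = 3))
  syn <- which(aug$origin == "synthetic")
  s_at <- function(u) {
    x <- train$X[aug$parent_base[syn[1]], ]
    xr <- train$X[aug$parent_neighbor[syn[1]], ]
    x + u * (xr - x)
  }
  expect_equal(s_at(0), train$X[aug$parent_base[syn[1]], ])
  expect_equal(s_at(1), train$X[aug$parent_neighbor[syn[1]], ])
})

test_that("augmentation balances the classes; balanced input adds nothing", {
  train <- make_null_train(n1 = 7, n2 = 20, p = 10, seed = 13)
  aug <- smote_augment(train, smote_params(seed = 1))
  expect_equal(unname(class_counts(aug$data)), c(20, 20))
  bal <- make_null_train(n1 = 10, n2 = 10, p = 10, seed = 13)
  aug0 <- smote_augment(bal, smote_params(seed = 1))
  expect_identical(aug0$data$X, bal$X)
  expect_true(all(aug0$origin == "original"))
})

test_that("neighbors are drawn from the k effective nearest minority samples", {
  train <- make_null_train(n1 = 4, n2 = 12, p = 6, seed = 14)  # k_eff = 3
  aug <- smote_augment(train, smote_params(k_neighbors = 5, seed = 2))
  syn <- which(aug$origin == "synthetic")
  idx_min <- which(train$y == 1L)
  D <- as.matrix(dist(train$X[idx_min, ])); diag(D) <- Inf
  for (i in syn) {
    b <- match(aug$parent_base[i], idx_min)
    nb <- match(aug$parent_neighbor[i], idx_min)
    expect_true(nb %in% order(D[b, ])[1:3])
  }
})

test_that("degenerate geometry: identical minority points synthesize themselves", {
  X <- rbind(matrix(1, 3, 4), matrix(rnorm(40), 10, 4))
  train <- labeled_dataset(X, rep(c(1L, 2L), c(3, 10)))
  aug <- smote_augment(train, smote_params(seed = 5))
  syn <- which(aug$origin == "synthetic")
  expect_true(all(aug$data$X[syn, ] == 1))
})

test_that("a single minority sample is a hard error", {
  X <- matrix(rnorm(40), 10, 4)
  train <- labeled_dataset(X, c(1L, rep(2L, 9)))
  expect_error(smote_augment(train), "at least 2 minority")
})

test_that("identical inputs and seed give identical augmented sets", {
  train <- make_null_train(seed = 15)
  a <- smote_augment(train, smote_params(seed = 9))
  b <- smote_augment(train, smote_params(seed = 9))
  expect_identical(a, b)
  c <- smote_augment(train, smote_params(seed = 10))
  expect_false(identical(a$weight, c$weight))
})

test_that("undersampling keeps the minority and a subset of the majority", {
  train <- make_null_train(n1 = 8, n2 = 72, p = 5, seed = 16)
  out <- undersample(train, seed = 1)
  expect_equal(length(out$y), 16)
  expect_equal(unname(class_counts(out)), c(8, 8))
  # minority untouched
  expect_identical(out$X[out$y == 1L, ], train$X[train$y == 1L, ])
  # retained majority rows are original majority rows, across seeds
  key <- function(X) apply(X, 1, function(r) paste(r, collapse = ","))
  maj_keys <- key(train$X[train$y == 2L, ])
  for (s in 1:20) {
    o <- undersample(train, seed = s)
    expect_true(all(key(o$X[o$y == 2L, ]) %in% maj_keys))
  }
  bal <- make_null_train(n1 = 6, n2 = 6, p = 5, seed = 16)
  expect_identical(undersample(bal, seed = 1)$X, bal$X)
})

test_that("augmented sets serialize with provenance columns", {
  train <- make_null_train(n1 = 5, n2 = 9, p = 4, seed = 17)
  aug <- smote_augment(train, smote_params(seed = 1))
  path <- tempfile(fileext = ".csv")
  write_augmented(aug, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 18)
  expect_true(all(c("origin", "parent_base", "parent_neighbor", "weight")
                  %in% names(df)))
  unlink(path)
})
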