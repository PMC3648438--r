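test_that("training class counts follow k1 with round-half-up, test sets are balanced", {
  sim <- simulate_dataset(sim_config(p = 50, n_train = 80, n_test = 20,
                                     k1 = 0.45, rho = 0, seed = 1))
  expect_equal(unname(class_counts(sim$train)), c(36, 44))
  expect_equal(unname(class_counts(sim$test)), c(10, 10))

  low <- simulate_lowdim(p = 5, n_train = 40, k1 = 0.10, seed = 1)
  expect_equal(unname(class_counts(low$train)), c(4, 36))
  expect_equal(unname(class_counts(low$test)), c(20, 20))

  low200 <- simulate_lowdim(p = 5, n_train = 200, k1 = 0.10, seed = 1)
  expect_equal(unname(class_counts(low200$train))[1], 20)

  # odd test size differs by one at most
  odd <- simulate_dataset(sim_config(p = 10, n_train = 20, n_test = 21,
                                     k1 = 0.5, rho = 0, seed = 1))
  expect_lte(abs(diff(unname(class_counts(odd$test)))), 1)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(p = 100, n_train = 80, k1 = 0.001),
               "rounds a training class to 0")
  expect_error(sim_config(p = 100, p_de = 200), "cannot exceed")
  expect_error(sim_config(p = 100, block_size = 30), "divide")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(simulate_lowdim(p = 7), "5 or 10")
})

test_that("null Gaussian marginals have mean 0 and variance 1 (3 SE at n = 1e4)", {
  sim <- simulate_dataset(sim_config(p = 20, n_train = 10000, n_test = 2,
                                     k1 = 0.5, rho = 0.8, seed = 2))
  X <- sim$train$X
  n <- nrow(X)
  expect_lt(max(abs(colMeans(X))), 3 / sqrt(n))
  expect_lt(max(abs(apply(X, 2, var) - 1)), 3 * sqrt(2 / (n - 1)))
})

test_that("exponential variant has Exp(1) marginals and uniform class-2 shifts", {
  sim <- simulate_dataset(sim_config(p = 20, n_train = 10000, n_test = 2,
                                     k1 = 0.5, rho = 0.5, p_de = 5,
                                     distribution = "exponential", seed = 3))
  X1 <- sim$train$X[sim$train$y == 1L, , drop = FALSE]
  expect_lt(max(abs(colMeans(X1) - 1)), 4 / sqrt(nrow(X1)))
  expect_lt(max(abs(apply(X1, 2, var) - 1)), 0.15)
  # class 2 DE variables carry a shift inside (shift_low, shift_high)
  shift <- colMeans(sim$train$X[sim$train$y == 2L, 1:5]) - colMeans(X1[, 1:5])
  expect_true(all(shift > 1 - 0.1 & shift < 1.5 + 0.1))
  # non-DE variables unshifted
  rest <- colMeans(sim$train$X[sim$train$y == 2L, 6:20]) - colMeans(X1[, 6:20])
  expect_lt(max(abs(rest)), 0.1)
})

test_that("block-exchangeable correlation matches rho within then zero across blocks", {
  sim <- simulate_dataset(sim_config(p = 30, n_train = 10000, n_test = 2,
                                     k1 = 0.5, rho = 0.8, block_size = 10,
                                     seed = 4))
  C <- cor(sim$train$X)
  blk <- rep(1:3, each = 10)
  within <- C[outer(blk, blk, "==") & upper.tri(C)]
  across <- C[outer(blk, blk, "!=") & upper.tri(C)]
  expect_lt(abs(mean(within) - 0.8), 0.02)
  expect_lt(abs(mean(across)), 0.02)

  ind <- simulate_dataset(sim_config(p = 30, n_train = 10000, n_test = 2,
                                     k1 = 0.5, rho = 0, seed = 4))
  Ci <- cor(ind$train$X)
  expect_lt(mean(abs(Ci[upper.tri(Ci)])), 0.02)
})

test_that("alternative case shifts exactly the first p_de variables by mu2", {
  sim <- simulate_dataset(sim_config(p = 40, n_train = 4000, n_test = 2,
                                     k1 = 0.5, rho = 0, p_de = 10, mu2 = 1,
                                     seed = 5))
  d <- colMeans(sim$train$X[sim$train$y == 2L, ]) -
       colMeans(sim$train$X[sim$train$y == 1L, ])
  expect_lt(max(abs(d[1:10] - 1)), 0.15)
  expect_lt(max(abs(d[11:40])), 0.15)
})

test_that("identical config and seed reproduce datasets bitwise", {
  cfg <- sim_config(p = 20, n_train = 30, n_test = 10, k1 = 0.3, rho = 0.5,
                    seed = 77)
  a <- simulate_dataset(cfg); b <- simulate_dataset(cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(p = 20, n_train = 30, n_test = 10, k1 = 0.3, rho = 0.5,
                     seed = 78)
  expect_false(identical(simulate_dataset(cfg2)$train$X, a$train$X))
})

test_that("titration subsampling fixes the minority and grows the majority", {
  pool <- with_seed_local(6, labeled_dataset(
    matrix(rnorm(200 * 10), 200, 10), rep(c(1L, 2L), c(120, 80))))
  bal <- subsample_for_titration(pool, n_min = 5, k1 = 0.5, n_test = 20,
                                 seed = 1)
  expect_equal(unname(class_counts(bal$train)), c(5, 5))
  ext <- subsample_for_titration(pool, n_min = 5, k1 = 0.9, n_test = 20,
                                 seed = 1)
  expect_equal(unname(class_counts(ext$train)), c(45, 5))
  # training size strictly increasing in k1 for n_min = 10
  sizes <- sapply(seq(0.5, 0.9, 0.1), function(k1) {
    length(subsample_for_titration(pool, 10, k1, n_test = 20, seed = 1)$train$y)
  })
  expect_true(all(diff(sizes) > 0))
  # train and test are disjoint: all test rows absent from training rows
  key <- function(X) apply(X, 1, function(r) paste(r, collapse = ","))
  expect_length(intersect(key(ext$train$X), key(ext$test$X)), 0)
  expect_error(subsample_for_titration(pool, n_min = 90, k1 = 0.5),
               "minority")
})

test_that("datasets round-trip through CSV with a config sidecar", {
  sim <- simulate_dataset(sim_config(p = 6, block_size = 6, n_train = 12, n_test = 4,
                                     k1 = 0.5, rho = 0, seed = 8))
  path <- tempfile(fileext = ".csv")
  write_dataset(sim$train, path, config = list(seed = 8, p = 6))
  back <- read_dataset(path)
  expect_equal(back$X, sim$train$X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(back$y, sim$train$y)
  expect_equal(attr(back, "config")$p, 6)
  unlink(c(path, paste0(path, ".json")))
})
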