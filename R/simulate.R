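#' Simulation design configuration
#'
#' Parameterizes the data-generating designs used throughout the package:
#' `p` variables in blocks of `block_size` with within-block exchangeable
#' correlation `rho` (variables in different blocks independent), `n_train`
#' training samples of which a fraction `k1` belong to Class 1, and a
#' class-balanced test set of `n_test` samples. Under the null design
#' (`p_de = 0` or `mu2 = 0`) the class labels carry no information; under the
#' alternative the first `p_de` variables are shifted by `mu2` in Class 2.
#'
#' For `distribution = "exponential"` all variables are marginally Exp(1)
#' (generated through a Gaussian copula so the block structure is retained)
#' and the Class-2 shift of each differentially expressed variable is a fresh
#' draw from `U(shift_low, shift_high)` (one draw per DE variable per
#' simulated dataset).
#'
#' @param p number of variables.
#' @param n_train,n_test training and (balanced) test set sizes.
#' @param k1 fraction of Class-1 samples in the training set, in (0, 1).
#' @param rho within-block pairwise correlation in `[0, 1)`.
#' @param block_size variables per correlated block; must divide `p`.
#' @param p_de number of differentially expressed (shifted) variables.
#' @param mu2 Class-2 mean shift of the DE variables (Gaussian case).
#' @param distribution `"gaussian"` or `"exponential"`.
#' @param shift_low,shift_high bounds of the uniform Class-2 shift used in the
#'   exponential case.
#' @param seed optional integer seed making the generated datasets
#'   reproducible.
#' @return a `sim_config` list.
#' @examples
#' cfg <- sim_config(p = 100, n_train = 80, n_test = 20, k1 = 0.45, rho = 0.8)
#' sim <- simulate_dataset(cfg)
#' sim$train
#' @export
sim_config <- function(p = 1000, n_train = 80, n_test = 20, k1 = 0.5,
                       rho = 0.8, block_size = 10, p_de = 0, mu2 = 0,
                       distribution = c("gaussian", "exponential"),
                       shift_low = 1, shift_high = 1.5, seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(p >= 1, n_train >= 2, n_test >= 2, block_size >= 1)
  if (p %% block_size != 0) stop("'block_size' must divide 'p'")
  if (k1 <= 0 || k1 >= 1) stop("'k1' must lie strictly between 0 and 1")
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)")
  if (p_de > p) stop("'p_de' (", p_de, ") cannot exceed 'p' (", p, ")")
  n1 <- round_half_up(k1 * n_train)
  if (n1 < 1 || n_train - n1 < 1) {
    stop("k1 = ", k1, " rounds a training class to 0 samples (n_train = ",
         n_train, ")")
  }
  structure(
    list(p = p, n_train = n_train, n_test = n_test, k1 = k1, rho = rho,
         block_size = block_size, p_de = p_de, mu2 = mu2,
         distribution = distribution, shift_low = shift_low,
         shift_high = shift_high, seed = seed),
    class = "sim_config"
  )
}

# n x p matrix with block-exchangeable correlation rho: within a block
# x = sqrt(rho) * z_block + sqrt(1 - rho) * z_own gives pairwise corr rho,
# unit marginal variance, and independence across blocks.
block_correlated_normal <- function(n, p, rho, block_size) {
  Z <- matrix(stats::rnorm(n * p), n, p)
  if (rho == 0) return(Z)
  n_blocks <- p %/% block_size
  W <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
  block_of <- rep(seq_len(n_blocks), each = block_size)
  sqrt(rho) * W[, block_of, drop = FALSE] + sqrt(1 - rho) * Z
}

# raw data for one labeled set under a sim_config; `shifts` is the per-variable
# Class-2 shift vector (length p) shared between train and test of a replicate
simulate_block <- function(cfg, n1, n2, shifts) {
  n <- n1 + n2
  Z <- block_correlated_normal(n, cfg$p, cfg$rho, cfg$block_size)
  X <- if (cfg$distribution == "exponential") {
    stats::qexp(stats::pnorm(Z), rate = 1)
  } else Z
  y <- rep(c(1L, 2L), c(n1, n2))
  if (any(shifts != 0)) {
    X[y == 2L, ] <- sweep(X[y == 2L, , drop = FALSE], 2, shifts, "+")
  }
  list(X = X, y = y)
}

#' Simulate a training and test set under a design configuration
#'
#' Generates `n_train` training samples with Class-1 fraction as close to `k1`
#' as rounding (half up) allows, plus a class-balanced test set of `n_test`
#' samples, with the covariance and class-shift structure described in
#' [sim_config()]. The test set shares the replicate's Class-2 shift vector so
#' train and test are draws from the same population.
#'
#' @param config a [sim_config()].
#' @return list with elements `train` and `test`, both [labeled_dataset()]s.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n1 <- round_half_up(config$k1 * config$n_train)
    n2 <- config$n_train - n1
    shifts <- numeric(config$p)
    if (config$p_de > 0) {
      de <- seq_len(config$p_de)
      shifts[de] <- if (config$distribution == "exponential") {
        stats::runif(config$p_de, config$shift_low, config$shift_high)
      } else {
        config$mu2
      }
    }
    tr <- simulate_block(config, n1, n2, shifts)
    n1_test <- config$n_test %/% 2L
    te <- simulate_block(config, n1_test, config$n_test - n1_test, shifts)
    list(
      train = labeled_dataset(tr$X, tr$y, role = "train"),
      test  = labeled_dataset(te$X, te$y, role = "test")
    )
  })
}

#' Simulate a low-dimensional design
#'
#' Convenience wrapper for the low-dimensional study: `p = 5` or `10`
#' variables, all mutually correlated at `rho` (one exchangeable block),
#' `k1 = 0.10`, a balanced test set of 40 samples, and in the alternative case
#' (`alternative = TRUE`) a mean shift `mu2 = 1` applied to every variable.
#'
#' @param p number of variables, 5 or 10.
#' @param n_train training set size (40, 80 or 200 in the study design).
#' @param k1 Class-1 training fraction.
#' @param rho exchangeable correlation among all variables.
#' @param alternative if `TRUE` Class 2 is shifted by `mu2` on all variables.
#' @param mu2 Class-2 shift used when `alternative = TRUE`.
#' @param n_test balanced test set size.
#' @param seed optional integer seed.
#' @return list with `train` and `test` [labeled_dataset()]s.
#' @export
simulate_lowdim <- function(p = 5, n_train = 40, k1 = 0.10, rho = 0.8,
                            alternative = FALSE, mu2 = 1, n_test = 40,
                            seed = NULL) {
  if (!p %in% c(5L, 10L)) stop("low-dimensional designs use p = 5 or 10")
  cfg <- sim_config(
    p = p, n_train = n_train, n_test = n_test, k1 = k1, rho = rho,
    block_size = p, p_de = if (alternative) p else 0,
    mu2 = if (alternative) mu2 else 0, seed = seed
  )
  simulate_dataset(cfg)
}

#' Subsample a dataset into a fixed-minority, varying-majority training set
#'
#' Builds the class-imbalance titration design: the training set keeps exactly
#' `n_min` minority-class samples while the majority class grows with the
#' majority fraction `k1`, `n_maj = round(n_min * k1 / (1 - k1))`. A
#' class-balanced test set is drawn from the samples not used for training.
#'
#' @param dataset a [labeled_dataset()] to subsample from.
#' @param n_min minority-class training size (5 or 10 in the study design).
#' @param k1 majority-class training fraction, in `[0.5, 1)`.
#' @param n_test test set size; defaults to the largest balanced test set the
#'   leftover samples allow.
#' @param minority label of the minority class (default: the rarer class).
#' @param seed optional integer seed.
#' @return list with `train` and `test` [labeled_dataset()]s, disjoint sample
#'   sets.
#' @export
subsample_for_titration <- function(dataset, n_min, k1, n_test = NULL,
                                    minority = minority_class(dataset),
                                    seed = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (k1 < 0.5 || k1 >= 1) stop("'k1' is the majority fraction, in [0.5, 1)")
  majority <- if (minority == 2L) 1L else 2L
  n_maj <- round_half_up(n_min * k1 / (1 - k1))
  idx_min <- which(dataset$y == minority)
  idx_maj <- which(dataset$y == majority)
  with_seed(seed, {
    for (cls in c("minority", "majority")) {
      need <- if (cls == "minority") n_min else n_maj
      have <- if (cls == "minority") length(idx_min) else length(idx_maj)
      if (have < need) {
        stop(sprintf("%s class has %d samples, %d required for training",
                     cls, have, need))
      }
    }
    tr_min <- sample(idx_min, n_min)
    tr_maj <- sample(idx_maj, n_maj)
    rest_min <- setdiff(idx_min, tr_min)
    rest_maj <- setdiff(idx_maj, tr_maj)
    per_class <- if (is.null(n_test)) {
      min(length(rest_min), length(rest_maj))
    } else n_test %/% 2L
    if (per_class < 1 || length(rest_min) < per_class ||
        length(rest_maj) < per_class) {
      short <- if (length(rest_min) < per_class) "minority" else "majority"
      stop(sprintf("%s class cannot supply %d held-out test samples", short,
                   per_class))
    }
    te_min <- sample(rest_min, per_class)
    te_maj <- sample(rest_maj, per_class)
    tr <- c(tr_maj, tr_min)
    te <- c(te_maj, te_min)
    list(
      train = subset_samples(dataset, tr, role = "train"),
      test  = subset_samples(dataset, te, role = "test")
    )
  })
}
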