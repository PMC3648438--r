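#' Monte-Carlo check of the SMOTE moment properties
#'
#' Estimates the per-variable mean difference between synthetic and original
#' minority samples (theory: 0, SMOTE preserves the class mean) and the
#' variance ratio var(synthetic)/var(original) (theory: 2/3, because
#' `var((1-u)X + uX^R) = E[(1-u)^2 + u^2] var(X) = (2/3) var(X)` for
#' independent X, X^R and u ~ U(0,1)).
#'
#' Both claims concern the distribution of the SMOTE generator, not one
#' particular minority sample, so the estimator pools synthetic samples over
#' `n_datasets` independently drawn iid N(0,1) minority sets of `n_min`
#' samples each (a single-dataset estimate of the variance ratio is biased
#' downward at small `n_min` by the within-sample variance factor (n-1)/n and
#' by the preferential selection of central points as nearest neighbors).
#' Monte-Carlo standard errors are taken across the `p` independent
#' variables.
#'
#' @param p number of variables.
#' @param n_min minority-class size per dataset.
#' @param n_synth total number of synthetic samples (split evenly across
#'   datasets).
#' @param n_datasets number of independent minority draws pooled.
#' @param k_neighbors SMOTE neighbor count.
#' @param seed optional integer seed.
#' @return a `property_report` list with `mean_diff`, `mean_diff_se`,
#'   `var_ratio`, `var_ratio_se` and the run parameters.
#' @export
moment_check <- function(p = 500, n_min = 30, n_synth = 10000,
                         n_datasets = 20, k_neighbors = 5, seed = NULL) {
  stopifnot(n_synth >= n_datasets)
  per <- ceiling(n_synth / n_datasets)
  with_seed(seed, {
    # pool the synthetic and original draws of all datasets before taking
    # moments, so the estimate targets the generator's unconditional
    # distribution (between-dataset mean variability included)
    sS <- sS2 <- sX <- sX2 <- numeric(p)
    for (r in seq_len(n_datasets)) {
      X <- matrix(stats::rnorm(n_min * p), n_min, p)
      S <- smote_synthesize(X, per, k_neighbors)$S
      sS <- sS + colSums(S); sS2 <- sS2 + colSums(S^2)
      sX <- sX + colSums(X); sX2 <- sX2 + colSums(X^2)
    }
    nS <- per * n_datasets
    nX <- n_min * n_datasets
    vS <- (sS2 - sS^2 / nS) / (nS - 1)
    vX <- (sX2 - sX^2 / nX) / (nX - 1)
    diff_j <- sS / nS - sX / nX
    ratio_j <- vS / vX
    structure(
      list(mean_diff = mean(diff_j), mean_diff_se = stats::sd(diff_j) / sqrt(p),
           var_ratio = mean(vS) / mean(vX),
           var_ratio_se = stats::sd(ratio_j) / sqrt(p),
           p = p, n_min = n_min, n_synth = nS, n_datasets = n_datasets),
      class = "property_report"
    )
  })
}

#' Monte-Carlo check of the SMOTE correlation properties
#'
#' Verifies that SMOTE introduces correlation between samples but not between
#' variables, on iid N(0,1) minority data:
#' \describe{
#'   \item{`parent_corr`}{pooled correlation between synthetic samples and
#'     their base parent x, estimating the closed form
#'     `cor(S, X) = (1/2)/sqrt(2/3) ~ 0.612` (covariance `var(X)/2` over
#'     `sqrt(var(S) var(X))`). All (synthetic, parent) value pairs are pooled
#'     before correlating, which is the direct estimator of that population
#'     quantity.}
#'   \item{`parent_corr_pairwise`}{mean of the per-pair Pearson correlations
#'     across variables; slightly larger (~0.623) because the shared
#'     interpolation weight u enters each pair's correlation nonlinearly.}
#'   \item{`sibling_corr`}{mean correlation between synthetic samples sharing
#'     the same base parent.}
#'   \item{`nonparent_corr`}{mean correlation between synthetic samples and
#'     unrelated original samples (theory: 0).}
#'   \item{`cross_var_corr_synth` / `cross_var_corr_orig`}{mean absolute
#'     between-variable correlation computed over synthetic and over original
#'     samples; their difference should vanish within Monte-Carlo error.}
#' }
#'
#' @inheritParams moment_check
#' @param n_var_pairs number of random variable pairs sampled for the
#'   between-variable correlation summaries.
#' @return a `property_report` list.
#' @export
correlation_check <- function(p = 1000, n_min = 30, n_synth = 2000,
                              k_neighbors = 5, n_var_pairs = 2000,
                              seed = NULL) {
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_min * p), n_min, p)
    syn <- smote_synthesize(X, n_synth, k_neighbors)
    S <- syn$S
    ctr <- colMeans(X)
    Sc <- sweep(S, 2, ctr)
    Bc <- sweep(X[syn$base, , drop = FALSE], 2, ctr)
    parent_corr <- sum(Sc * Bc) / sqrt(sum(Sc^2) * sum(Bc^2))
    parent_pair <- mean(vapply(
      seq_len(n_synth), function(i) stats::cor(S[i, ], X[syn$base[i], ]), 0
    ))
    # synthetic vs an original sample that is neither parent
    other <- vapply(seq_len(n_synth), function(i) {
      pool <- setdiff(seq_len(n_min), c(syn$base[i], syn$neighbor[i]))
      pool[1L + (i %% length(pool))]
    }, 0L)
    nonparent_corr <- mean(vapply(
      seq_len(n_synth), function(i) stats::cor(S[i, ], X[other[i], ]), 0
    ))
    # siblings: pairs of synthetic samples with the same base parent
    sib <- split(seq_len(n_synth), syn$base)
    sib_pairs <- do.call(rbind, lapply(sib, function(ii) {
      if (length(ii) < 2L) return(NULL)
      cbind(ii[-length(ii)], ii[-1])
    }))
    sibling_corr <- if (is.null(sib_pairs)) NA_real_ else {
      mean(apply(sib_pairs, 1, function(pr) stats::cor(S[pr[1], ], S[pr[2], ])))
    }
    pairs <- cbind(sample.int(p, n_var_pairs, TRUE),
                   sample.int(p, n_var_pairs, TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    pairwise_abs_cor <- function(M) {
      Mc <- scale(M, center = TRUE, scale = FALSE)
      ss <- colSums(Mc^2)
      num <- colSums(Mc[, pairs[, 1], drop = FALSE] *
                     Mc[, pairs[, 2], drop = FALSE])
      mean(abs(num / sqrt(ss[pairs[, 1]] * ss[pairs[, 2]])))
    }
    cross_synth <- pairwise_abs_cor(S)
    cross_orig <- pairwise_abs_cor(X)
    structure(
      list(parent_corr = parent_corr, parent_corr_pairwise = parent_pair,
           sibling_corr = sibling_corr, nonparent_corr = nonparent_corr,
           cross_var_corr_synth = cross_synth,
           cross_var_corr_orig = cross_orig,
           p = p, n_min = n_min, n_synth = n_synth),
      class = "property_report"
    )
  })
}

#' Nearest-neighbor composition and distance geometry of SMOTE-augmented data
#'
#' Reproduces the distance-geometry experiment behind the k-NN reversal: under
#' a null design (all variables N(0,1), 80 training samples with a minority
#' fraction of 36/80, minority SMOTE-augmented to balance), test samples are
#' on average closer to the synthetic samples than to the original ones, and
#' once p is large enough the single nearest training neighbor of essentially
#' every test sample is synthetic. With unit variances the mean squared
#' distance from a test sample is `2p` to an original sample and
#' `(1 + 2/3) p = (5/3) p` to a synthetic one.
#'
#' @param p_grid variable counts to profile.
#' @param n_train training set size.
#' @param n_min minority-class training size (36/80 in the reference design).
#' @param n_test number of N(0,1) test samples per replicate.
#' @param n_rep number of replicates per p.
#' @param k_neighbors SMOTE neighbor count.
#' @param seed optional integer seed.
#' @return a `property_report` data.frame with one row per p: mean and
#'   Monte-Carlo SE (across replicates) of the squared test-original and
#'   test-synthetic distances, deciles of both distance distributions, and
#'   `nn_synth_fraction`, the fraction of test samples whose nearest neighbor
#'   in the full augmented training set is synthetic.
#' @export
nn_composition <- function(p_grid = c(1, 5, 10, 30, 100, 300, 1000),
                           n_train = 80, n_min = 36, n_test = 1000,
                           n_rep = 100, k_neighbors = 5, seed = NULL) {
  n_maj <- n_train - n_min
  if (n_min >= n_maj) stop("the design requires a minority class: n_min < n_train - n_min")
  with_seed(seed, {
    out <- lapply(p_grid, function(p) {
      msd_o <- msd_s <- frac <- numeric(n_rep)
      dec_o <- dec_s <- matrix(0, n_rep, 9)
      for (r in seq_len(n_rep)) {
        Xmin <- matrix(stats::rnorm(n_min * p), n_min, p)
        Xmaj <- matrix(stats::rnorm(n_maj * p), n_maj, p)
        S <- smote_synthesize(Xmin, n_maj - n_min, k_neighbors)$S
        Te <- matrix(stats::rnorm(n_test * p), n_test, p)
        d2o <- cross_dist2(Te, rbind(Xmin, Xmaj))
        d2s <- cross_dist2(Te, S)
        msd_o[r] <- mean(d2o); msd_s[r] <- mean(d2s)
        dec_o[r, ] <- stats::quantile(sqrt(d2o), probs = (1:9) / 10)
        dec_s[r, ] <- stats::quantile(sqrt(d2s), probs = (1:9) / 10)
        frac[r] <- mean(apply(d2s, 1, min) < apply(d2o, 1, min))
      }
      data.frame(
        p = p,
        msd_test_orig = mean(msd_o), msd_test_orig_se = stats::sd(msd_o) / sqrt(n_rep),
        msd_test_synth = mean(msd_s), msd_test_synth_se = stats::sd(msd_s) / sqrt(n_rep),
        nn_synth_fraction = mean(frac),
        nn_synth_fraction_se = stats::sd(frac) / sqrt(n_rep),
        dist_orig_median = mean(dec_o[, 5]), dist_synth_median = mean(dec_s[, 5])
      )
    })
    res <- do.call(rbind, out)
    attr(res, "n_rep") <- n_rep
    attr(res, "n_test") <- n_test
    class(res) <- c("property_report", "data.frame")
    res
  })
}

#' @export
print.property_report <- function(x, ...) {
  if (is.data.frame(x)) {
    print(as.data.frame(x), digits = 4)
  } else {
    vals <- x[vapply(x, is.numeric, TRUE)]
    print(round(unlist(vals), 4))
  }
  invisible(x)
}
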