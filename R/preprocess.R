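#' Row-center a matrix (sample normalization)
#'
#' Subtracts from every entry the mean of its sample (row) over all variables,
#' the sample-normalization step applied separately to training and test data
#' before variable selection or augmentation.
#'
#' @param X numeric matrix, samples in rows.
#' @return matrix with all row means 0.
#' @export
normalize_samples <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("at least one variable is required")
  X - rowMeans(X)
}

#' Column-center a matrix (variable normalization)
#'
#' Subtracts from every entry the mean of its variable (column) over all
#' samples.
#'
#' @param X numeric matrix, samples in rows.
#' @param center optional precomputed column means (e.g. training means to be
#'   applied to a held-out sample); defaults to the column means of `X`.
#' @return matrix with (training) column means removed.
#' @export
normalize_variables <- function(X, center = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  sweep(X, 2, center)
}

#' Pooled-variance two-sample t-statistics per variable
#'
#' For each variable computes
#' `t_j = (mean_1j - mean_2j) / sqrt(s2_pooled_j * (1/n1 + 1/n2))` with the
#' equal-variance pooled estimate
#' `s2_pooled_j = ((n1 - 1) s2_1j + (n2 - 1) s2_2j) / (n1 + n2 - 2)`.
#' Variables with zero pooled variance get `t = 0` (uninformative) rather
#' than +/-Inf, so constant variables are never selected.
#'
#' @param train a [labeled_dataset()] with at least 2 samples per class.
#' @return numeric vector of t-statistics, one per variable.
#' @export
pooled_t_statistics <- function(train) {
  stopifnot(inherits(train, "labeled_dataset"))
  cnt <- class_counts(train)
  if (any(cnt < 2L)) {
    stop("each class needs >= 2 samples for the pooled t-statistic")
  }
  X1 <- train$X[train$y == 1L, , drop = FALSE]
  X2 <- train$X[train$y == 2L, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- colSums((X1 - rep(m1, each = n1))^2) / (n1 - 1)
  v2 <- colSums((X2 - rep(m2, each = n2))^2) / (n2 - 1)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  unname(t)
}

#' Two-sided p-values for the pooled t-statistics
#'
#' Student-t p-values on `n1 + n2 - 2` degrees of freedom. After SMOTE
#' augmentation these are systematically too small (the synthetic samples are
#' not independent and shrink the variance), so they should be used for
#' ranking variables only, never as significance statements.
#'
#' @inheritParams pooled_t_statistics
#' @return numeric vector of two-sided p-values ("for ranking only").
#' @export
pooled_t_pvalues <- function(train) {
  t <- pooled_t_statistics(train)
  df <- length(train$y) - 2L
  2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
}

#' Select the top-G variables by absolute t-statistic
#'
#' Returns the indices of the `g` variables with the largest absolute
#' pooled-variance t-statistics, computed on the supplied training set only
#' (which may be SMOTE-augmented or undersampled, depending on the pipeline
#' order). Ties in |t| are broken by the smaller variable index for
#' determinism.
#'
#' @param train a [labeled_dataset()].
#' @param g number of variables to retain (the study default is 40).
#' @return integer vector of `g` variable indices, in decreasing |t| order.
#' @export
select_top_g <- function(train, g = 40) {
  p <- ncol(train$X)
  if (g < 1 || g > p) stop("'g' must lie in [1, ", p, "]")
  t <- pooled_t_statistics(train)
  order(-abs(t), seq_along(t))[seq_len(g)]
}
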