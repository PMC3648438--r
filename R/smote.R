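#' SMOTE parameters
#'
#' @param k_neighbors number of minority-class nearest neighbors considered
#'   for interpolation; the effective number is `min(k_neighbors, n_min - 1)`.
#' @param seed optional integer seed.
#' @return a `smote_params` list.
#' @export
smote_params <- function(k_neighbors = 5, seed = NULL) {
  stopifnot(k_neighbors >= 1)
  structure(list(k_neighbors = as.integer(k_neighbors), seed = seed),
            class = "smote_params")
}

# Core SMOTE kernel: generate `n_synth` synthetic samples from the minority
# matrix `Xmin`. For each synthetic sample the base x is taken by cycling
# deterministically through the minority samples in index order (equalizing
# per-base counts to +/-1), the neighbor x^R is drawn uniformly from the base's
# k effective Euclidean nearest minority neighbors (self excluded, distance
# ties broken by smallest index), and a single u ~ U(0,1) is applied to all
# variables: s = x + u * (x^R - x).
smote_synthesize <- function(Xmin, n_synth, k_neighbors = 5) {
  n_min <- nrow(Xmin)
  if (n_min < 2L) {
    stop("SMOTE requires at least 2 minority samples (got ", n_min,
         "): no nearest neighbor exists")
  }
  k_eff <- min(k_neighbors, n_min - 1L)
  if (n_synth == 0L) {
    return(list(S = Xmin[0, , drop = FALSE], base = integer(0),
                neighbor = integer(0), u = numeric(0)))
  }
  D <- as.matrix(stats::dist(Xmin))
  diag(D) <- Inf
  # order() is stable on ties -> smallest index wins
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k_eff)]))
  base <- rep(seq_len(n_min), length.out = n_synth)
  pick <- sample.int(k_eff, n_synth, replace = TRUE)
  neighbor <- nn[cbind(base, pick)]
  u <- stats::runif(n_synth)
  S <- Xmin[base, , drop = FALSE] +
    u * (Xmin[neighbor, , drop = FALSE] - Xmin[base, , drop = FALSE])
  list(S = S, base = base, neighbor = neighbor, u = u)
}

#' SMOTE-augment a training set to class balance
#'
#' Adds `n_majority - n_minority` synthetic minority samples, each a convex
#' combination `s = x + u * (x^R - x)` of a minority sample and one of its k
#' Euclidean nearest minority neighbors, with a single `u ~ U(0, 1)` shared by
#' all variables of a synthetic sample. Distances are computed on exactly the
#' columns present in `train`, so augmenting before or after variable
#' selection yields the two pipeline orders of the study design. Original
#' samples are left untouched; full provenance (parents and interpolation
#' weight) is recorded per synthetic sample.
#'
#' @param train a [labeled_dataset()] with at least 2 minority samples.
#' @param params a [smote_params()].
#' @return an object of class `smote_augmented`: list with
#'   \describe{
#'     \item{data}{[labeled_dataset()] holding original plus synthetic rows;}
#'     \item{origin}{`"original"` or `"synthetic"` per row;}
#'     \item{parent_base, parent_neighbor}{row indices (into `train`) of x and
#'       x^R (`NA` for original rows);}
#'     \item{weight}{the u draw (`NA` for original rows).}
#'   }
#' @examples
#' sim <- simulate_dataset(sim_config(p = 20, n_train = 20, k1 = 0.2, rho = 0,
#'                                    seed = 1))
#' aug <- smote_augment(sim$train, smote_params(seed = 1))
#' table(aug$data$y)
#' @export
smote_augment <- function(train, params = smote_params()) {
  stopifnot(inherits(train, "labeled_dataset"))
  cnt <- class_counts(train)
  mino <- minority_class(train)
  n_synth <- max(cnt) - min(cnt)
  idx_min <- which(train$y == mino)
  with_seed(params$seed, {
    syn <- smote_synthesize(train$X[idx_min, , drop = FALSE], n_synth,
                            params$k_neighbors)
    n_orig <- nrow(train$X)
    X <- rbind(train$X, syn$S)
    y <- c(train$y, rep(mino, n_synth))
    structure(
      list(
        data = labeled_dataset(X, y, role = "train"),
        origin = rep(c("original", "synthetic"), c(n_orig, n_synth)),
        parent_base = c(rep(NA_integer_, n_orig), idx_min[syn$base]),
        parent_neighbor = c(rep(NA_integer_, n_orig), idx_min[syn$neighbor]),
        weight = c(rep(NA_real_, n_orig), syn$u),
        minority = mino
      ),
      class = "smote_augmented"
    )
  })
}

#' @export
print.smote_augmented <- function(x, ...) {
  cat(sprintf("<smote_augmented> %d original + %d synthetic samples (class %d)\n",
              sum(x$origin == "original"), sum(x$origin == "synthetic"),
              x$minority))
  invisible(x)
}

#' Export an augmented training set with provenance columns
#'
#' Writes the same CSV/TSV dialect as [write_dataset()] plus `origin`,
#' `parent_base`, `parent_neighbor` and `weight` columns.
#'
#' @param aug a [smote_augment()] result.
#' @param path output file path (`.tsv` selects tab separation).
#' @export
write_augmented <- function(aug, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(
    class = aug$data$y, origin = aug$origin, parent_base = aug$parent_base,
    parent_neighbor = aug$parent_neighbor, weight = aug$weight,
    aug$data$X, check.names = FALSE
  )
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Undersample the majority class to balance
#'
#' Removes a uniformly chosen (without replacement) subset of majority-class
#' samples so that both classes have `n_minority` samples; minority samples
#' are untouched.
#'
#' @param train a [labeled_dataset()] with both classes present.
#' @param seed optional integer seed.
#' @return a [labeled_dataset()] of `2 * n_minority` samples (input order
#'   preserved among retained rows).
#' @export
undersample <- function(train, seed = NULL) {
  stopifnot(inherits(train, "labeled_dataset"))
  cnt <- class_counts(train)
  mino <- minority_class(train)
  majo <- if (mino == 2L) 1L else 2L
  n_min <- min(cnt)
  idx_maj <- which(train$y == majo)
  with_seed(seed, {
    keep_maj <- sort(sample(idx_maj, n_min))
    keep <- sort(c(which(train$y == mino), keep_maj))
    subset_samples(train, keep)
  })
}
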