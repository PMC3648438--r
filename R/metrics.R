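#' Performance measures for two-class prediction
#'
#' Computes the five measures used throughout the package: overall predictive
#' accuracy (PA), class-specific accuracies (PA1, PA2), the rank-based AUC and
#' the G-mean `sqrt(PA1 * PA2)`. The AUC is the Mann-Whitney concordance
#' between the Class-1 scores and the true labels, with ties credited 1/2;
#' because it is rank-based it is identical whichever class is declared
#' positive (the minority Class 2 is the conventional positive class in the
#' imbalanced designs studied here) and is unaffected by any choice of
#' classification threshold.
#'
#' @param y_true true labels in `{1, 2}`, both classes present.
#' @param y_pred predicted labels in `{1, 2}`.
#' @param scores Class-1 posterior scores aligned with `y_true`; required for
#'   the AUC.
#' @return a `metric_set`: named numeric vector with elements `PA`, `PA1`,
#'   `PA2`, `AUC`, `Gmean`.
#' @examples
#' compute_metrics(c(1, 1, 2, 2), c(1, 2, 2, 2), scores = c(.9, .4, .3, .1))
#' @export
compute_metrics <- function(y_true, y_pred, scores = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  n1 <- sum(y_true == 1L); n2 <- sum(y_true == 2L)
  if (n1 == 0L || n2 == 0L) {
    stop("both classes must be present in 'y_true' (AUC is undefined otherwise)")
  }
  pa1 <- mean(y_pred[y_true == 1L] == 1L)
  pa2 <- mean(y_pred[y_true == 2L] == 2L)
  pa <- (n1 * pa1 + n2 * pa2) / (n1 + n2)
  auc <- if (is.null(scores)) NA_real_ else rank_auc(y_true, scores)
  structure(c(PA = pa, PA1 = pa1, PA2 = pa2, AUC = auc,
              Gmean = sqrt(pa1 * pa2)),
            class = c("metric_set", "numeric"))
}

#' @export
print.metric_set <- function(x, ...) {
  print(round(unclass(x), 4), ...)
  invisible(x)
}

# Mann-Whitney AUC: P(score(class1) > score(class2)) + P(=)/2, via midranks
rank_auc <- function(y_true, scores) {
  stopifnot(length(scores) == length(y_true))
  r <- rank(scores)
  n1 <- sum(y_true == 1L); n2 <- sum(y_true == 2L)
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
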