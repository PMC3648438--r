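#' Pipeline configuration: normalization, selection, correction, classifier
#'
#' Describes one analysis pipeline of the study: how the data are normalized,
#' whether and when the top-G variables are selected, which class-imbalance
#' correction is applied, and which classifier is fitted.
#'
#' The correction `"none"` fits the classifier on the imbalanced training set
#' with the 0.5 threshold; `"cutoff"` fits the same model but thresholds at
#' the training Class-1 fraction k1; `"smote"` augments the minority class to
#' balance; `"undersample"` trims the majority class to balance.
#' `selection_order` controls whether the top-G variables are picked before or
#' after SMOTE augmentation (undersampling always precedes selection).
#'
#' @param classifier one of [smotehd_methods()].
#' @param correction `"none"`, `"smote"`, `"undersample"` or `"cutoff"`.
#' @param normalization `"samples"` (row centering, the headline setting),
#'   `"variables"` (column centering) or `"raw"`.
#' @param g number of variables to select, or `NULL` to use all (G = p).
#' @param selection_order `"after_smote"` (the headline setting: SMOTE first,
#'   then selection on the augmented set) or `"before_smote"`.
#' @param k_neighbors SMOTE neighbor count.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(classifier = "DLDA",
                            correction = c("none", "smote", "undersample",
                                           "cutoff"),
                            normalization = c("samples", "variables", "raw"),
                            g = NULL,
                            selection_order = c("after_smote", "before_smote"),
                            k_neighbors = 5) {
  correction <- match.arg(correction)
  normalization <- match.arg(normalization)
  selection_order <- match.arg(selection_order)
  classifier <- match.arg(classifier, smotehd_methods())
  structure(
    list(classifier = classifier, correction = correction,
         normalization = normalization, g = g,
         selection_order = selection_order, k_neighbors = k_neighbors),
    class = "pipeline_config"
  )
}

normalize_train <- function(train, normalization) {
  X <- switch(normalization,
    raw = train$X,
    samples = normalize_samples(train$X),
    variables = normalize_variables(train$X)
  )
  list(ds = labeled_dataset(X, train$y, role = "train"),
       train_centers = if (normalization == "variables") colMeans(train$X))
}

normalize_test <- function(X, normalization, train_centers = NULL) {
  switch(normalization,
    raw = as.matrix(X),
    samples = normalize_samples(X),
    # held-out samples are centered with training-derived column means when
    # supplied (the leave-one-out case); otherwise with their own means, the
    # separate-normalization convention of the independent-test-set protocol
    variables = normalize_variables(X, center = train_centers)
  )
}

# Resampling + selection in the configured order. Returns the final training
# set the classifier sees and the selected variable indices (into the
# normalized input columns).
prepare_training <- function(train, cfg, seed = NULL) {
  seeds <- if (is.null(seed)) list(NULL, NULL) else as.list(derive_seeds(seed, 2))
  vars <- seq_len(ncol(train$X))
  final <- train
  if (cfg$correction == "smote") {
    if (!is.null(cfg$g) && cfg$selection_order == "before_smote") {
      vars <- select_top_g(train, cfg$g)
      final <- smote_augment(
        labeled_dataset(train$X[, vars, drop = FALSE], train$y, "train"),
        smote_params(cfg$k_neighbors, seed = seeds[[1]])
      )$data
    } else {
      aug <- smote_augment(train,
                           smote_params(cfg$k_neighbors, seed = seeds[[1]]))$data
      if (!is.null(cfg$g)) {
        vars <- select_top_g(aug, cfg$g)
        aug <- labeled_dataset(aug$X[, vars, drop = FALSE], aug$y, "train")
      }
      final <- aug
    }
  } else if (cfg$correction == "undersample") {
    final <- undersample(train, seed = seeds[[1]])
    if (!is.null(cfg$g)) {
      vars <- select_top_g(final, cfg$g)
      final <- labeled_dataset(final$X[, vars, drop = FALSE], final$y, "train")
    }
  } else {  # none / cutoff
    if (!is.null(cfg$g)) {
      vars <- select_top_g(train, cfg$g)
      final <- labeled_dataset(train$X[, vars, drop = FALSE], train$y, "train")
    }
  }
  list(train = final, vars = vars, fit_seed = seeds[[2]])
}

#' Run one pipeline on a train/test split
#'
#' Normalizes training and test data separately, applies the configured
#' correction and variable selection to the training set only, fits the
#' classifier, classifies the test set (threshold 0.5, or the training k1
#' under the cut-off adjustment) and returns the performance measures.
#'
#' @param train,test [labeled_dataset()]s on the same variables.
#' @param cfg a [pipeline_config()].
#' @param seed optional integer seed covering resampling, fitting and tie
#'   randomness.
#' @return a [compute_metrics()] `metric_set`, with the held-out scores and
#'   predicted labels attached as attributes `"scores"` and `"labels"`.
#' @examples
#' sim <- simulate_dataset(sim_config(p = 50, n_train = 40, n_test = 20,
#'                                    k1 = 0.3, rho = 0, p_de = 10, mu2 = 2,
#'                                    seed = 7))
#' evaluate_on_test(sim$train, sim$test,
#'                  pipeline_config("DLDA", "smote", g = 10), seed = 7)
#' @export
evaluate_on_test <- function(train, test, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seeds <- if (is.null(seed)) list(NULL, NULL) else as.list(derive_seeds(seed, 2))
  norm <- normalize_train(train, cfg$normalization)
  Xte <- normalize_test(test$X, cfg$normalization)
  prep <- prepare_training(norm$ds, cfg, seed = seeds[[1]])
  model <- fit_classifier(prep$train, cfg$classifier, seed = prep$fit_seed)
  thr <- if (cfg$correction == "cutoff") cutoff_threshold(train) else 0.5
  lab <- classify(model, Xte[, prep$vars, drop = FALSE], threshold = thr,
                  seed = seeds[[2]])
  m <- compute_metrics(test$y, lab, scores = attr(lab, "scores"))
  attr(m, "scores") <- attr(lab, "scores")
  attr(m, "labels") <- as.integer(lab)
  m
}

#' Leave-one-out cross-validation over resampled training sets
#'
#' Runs `repeats` full LOOCV passes; within every fold the normalization,
#' resampling draw and variable selection are redone from scratch on the n-1
#' retained samples, so no information from the held-out sample can leak into
#' the model. Each repeat uses an independent resampling stream, reproducing
#' the protocol of training each classifier on repeatedly re-drawn
#' SMOTE-augmented or undersampled training sets. Under variable
#' normalization the held-out sample is centered with the fold's training
#' column means (row centering is self-contained).
#'
#' @param dataset a [labeled_dataset()] with >= 2 samples per class.
#' @param cfg a [pipeline_config()].
#' @param repeats number of LOOCV passes with fresh resampling draws.
#' @param seed optional master seed; child seeds are derived per repeat and
#'   fold.
#' @return a `loocv_result` list: `per_repeat` (one metrics row per repeat),
#'   `mean` and `sd` (per-measure aggregates), `config`.
#' @export
loocv_evaluate <- function(dataset, cfg, repeats = 50, seed = NULL) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(cfg, "pipeline_config"))
  n <- length(dataset$y)
  if (any(class_counts(dataset) < 2L)) {
    stop("LOOCV needs >= 2 samples per class, otherwise a fold loses a class")
  }
  rep_seeds <- if (is.null(seed)) rep(list(NULL), repeats)
               else as.list(derive_seeds(seed, repeats))
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_seeds <- if (is.null(rep_seeds[[r]])) rep(list(NULL), n)
                  else as.list(derive_seeds(rep_seeds[[r]], n))
    scores <- numeric(n); labels <- integer(n)
    for (i in seq_len(n)) {
      tr <- subset_samples(dataset, -i, role = "train")
      norm <- normalize_train(tr, cfg$normalization)
      Xi <- normalize_test(dataset$X[i, , drop = FALSE], cfg$normalization,
                           train_centers = norm$train_centers)
      fseeds <- if (is.null(fold_seeds[[i]])) list(NULL, NULL)
                else as.list(derive_seeds(fold_seeds[[i]], 2))
      prep <- prepare_training(norm$ds, cfg, seed = fseeds[[1]])
      model <- fit_classifier(prep$train, cfg$classifier,
                              seed = prep$fit_seed)
      thr <- if (cfg$correction == "cutoff") cutoff_threshold(tr) else 0.5
      lab <- classify(model, Xi[, prep$vars, drop = FALSE], threshold = thr,
                      seed = fseeds[[2]])
      labels[i] <- as.integer(lab)
      scores[i] <- attr(lab, "scores")
    }
    rows[[r]] <- c(repeat_id = r,
                   unclass(compute_metrics(dataset$y, labels, scores)))
  }
  per_repeat <- as.data.frame(do.call(rbind, rows))
  measures <- c("PA", "PA1", "PA2", "AUC", "Gmean")
  structure(
    list(per_repeat = per_repeat,
         mean = colMeans(per_repeat[measures]),
         sd = apply(per_repeat[measures], 2, stats::sd),
         config = cfg),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %s / %s, %d repeats\n", x$config$classifier,
              x$config$correction, nrow(x$per_repeat)))
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}
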