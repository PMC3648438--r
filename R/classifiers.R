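#' The eleven classifiers behind one posterior-score interface
#'
#' `fit_classifier()` dispatches on `method` and returns a fitted model whose
#' [predict_score()] method yields the estimated posterior probability of
#' Class 1, `p(c = 1 | x)`, for new samples. DLDA, DQDA, k-NN and PAM
#' (nearest shrunken centroids) are implemented from definition; CART, random
#' forest, SVM and penalized logistic regression are delegated to rpart,
#' randomForest, e1071 and glmnet with the study's stated parameters (CART:
#' pruning, maximum depth 5, complexity parameter 0.01; PLR: penalty weight by
#' cross-validated likelihood; remaining hyperparameters at the delegated
#' implementations' defaults).
#'
#' @param train a [labeled_dataset()].
#' @param method one of `"1-NN"`, `"3-NN"`, `"5-NN"`, `"DLDA"`, `"DQDA"`,
#'   `"CART"`, `"RF"`, `"SVM"`, `"PAM"`, `"PLR-L1"`, `"PLR-L2"`.
#' @param seed optional integer seed pinning any internal randomness
#'   (bootstrap draws, cross-validation folds).
#' @return a fitted model of class `smotehd_model`.
#' @examples
#' sim <- simulate_dataset(sim_config(p = 30, n_train = 40, k1 = 0.5, rho = 0,
#'                                    p_de = 5, mu2 = 2, seed = 1))
#' m <- fit_classifier(sim$train, "DLDA")
#' head(predict_score(m, sim$test$X))
#' @export
fit_classifier <- function(train, method, seed = NULL) {
  method <- match.arg(method, smotehd_methods())
  switch(method,
    "1-NN" = fit_knn(train, 1L),
    "3-NN" = fit_knn(train, 3L),
    "5-NN" = fit_knn(train, 5L),
    "DLDA" = fit_dlda(train),
    "DQDA" = fit_dqda(train),
    "PAM"  = fit_pam(train, seed = seed),
    "CART" = fit_cart(train, seed = seed),
    "RF"   = fit_rf(train, seed = seed),
    "SVM"  = fit_svm(train, seed = seed),
    "PLR-L1" = fit_plr(train, alpha = 1, seed = seed),
    "PLR-L2" = fit_plr(train, alpha = 0, seed = seed)
  )
}

#' @rdname fit_classifier
#' @export
smotehd_methods <- function() {
  c("1-NN", "3-NN", "5-NN", "DLDA", "DQDA", "CART", "RF", "SVM", "PAM",
    "PLR-L1", "PLR-L2")
}

new_model <- function(subclass, method, train, fields) {
  structure(
    c(list(method = method, vars = colnames(train$X)), fields),
    class = c(subclass, "smotehd_model")
  )
}

#' @export
print.smotehd_model <- function(x, ...) {
  cat(sprintf("<smotehd_model: %s> fitted on %d variables\n", x$method,
              length(x$vars)))
  invisible(x)
}

#' Posterior score of Class 1 for new samples
#'
#' @param model a fitted `smotehd_model`.
#' @param X numeric matrix of new samples (same variables as at fit time).
#' @return numeric vector of `p(c = 1 | x)` scores in `[0, 1]`.
#' @export
predict_score <- function(model, X) UseMethod("predict_score")

check_vars <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$vars)) {
    stop("model was fitted on ", length(model$vars), " variables but test ",
         "data has ", ncol(X))
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), model$vars)) {
    bad <- setdiff(colnames(X), model$vars)
    stop("variable set mismatch between model and test data",
         if (length(bad)) paste0(": unexpected ", toString(utils::head(bad, 3))))
  }
  X
}

class_stats <- function(train) {
  X1 <- train$X[train$y == 1L, , drop = FALSE]
  X2 <- train$X[train$y == 2L, , drop = FALSE]
  if (nrow(X1) < 2L || nrow(X2) < 2L) {
    stop("discriminant classifiers need >= 2 samples per class")
  }
  list(
    n1 = nrow(X1), n2 = nrow(X2),
    m1 = colMeans(X1), m2 = colMeans(X2),
    v1 = apply(X1, 2, stats::var), v2 = apply(X2, 2, stats::var)
  )
}

floor_variance <- function(v) {
  pmax(v, max(1e-8 * mean(v), 1e-12))
}

two_class_posterior <- function(ll1, ll2) {
  m <- pmax(ll1, ll2)
  e1 <- exp(ll1 - m); e2 <- exp(ll2 - m)
  e1 / (e1 + e2)
}

#' Diagonal linear discriminant analysis
#'
#' Gaussian classifier with a diagonal covariance shared by the two classes:
#' class means per variable and pooled per-variable variances. The score is
#' the two-class posterior from the diagonal Gaussian likelihoods with equal
#' priors, so the 0.5 threshold reproduces the minimum-distance rule
#' `d_c(x) = sum_j (x_j - mean_cj)^2 / s2_j`. Zero pooled variances are
#' floored at a small positive fraction of the mean pooled variance.
#'
#' @param train a [labeled_dataset()] with >= 2 samples per class.
#' @return a fitted `smotehd_model`.
#' @export
fit_dlda <- function(train) {
  st <- class_stats(train)
  s2 <- ((st$n1 - 1) * st$v1 + (st$n2 - 1) * st$v2) / (st$n1 + st$n2 - 2)
  new_model("smotehd_dlda", "DLDA", train,
            list(m1 = st$m1, m2 = st$m2, s2 = floor_variance(s2)))
}

#' @export
predict_score.smotehd_dlda <- function(model, X) {
  X <- check_vars(model, X)
  ll1 <- -0.5 * colSums((t(X) - model$m1)^2 / model$s2)
  ll2 <- -0.5 * colSums((t(X) - model$m2)^2 / model$s2)
  two_class_posterior(ll1, ll2)
}

#' Diagonal quadratic discriminant analysis
#'
#' As [fit_dlda()] but with class-specific per-variable variances, giving the
#' discriminant `d_c(x) = sum_j [(x_j - mean_cj)^2 / s2_cj + log s2_cj]`.
#' Because the class variances enter the rule, DQDA is sensitive to the
#' variance shrinkage that SMOTE induces in the minority class.
#'
#' @inheritParams fit_dlda
#' @return a fitted `smotehd_model`.
#' @export
fit_dqda <- function(train) {
  st <- class_stats(train)
  new_model("smotehd_dqda", "DQDA", train,
            list(m1 = st$m1, m2 = st$m2,
                 v1 = floor_variance(st$v1), v2 = floor_variance(st$v2)))
}

#' @export
predict_score.smotehd_dqda <- function(model, X) {
  X <- check_vars(model, X)
  ll1 <- -0.5 * (colSums((t(X) - model$m1)^2 / model$v1) + sum(log(model$v1)))
  ll2 <- -0.5 * (colSums((t(X) - model$m2)^2 / model$v2) + sum(log(model$v2)))
  two_class_posterior(ll1, ll2)
}

#' k-nearest-neighbor classifier
#'
#' The score of a new sample is the fraction of its k Euclidean nearest
#' training samples belonging to Class 1; distance ties are broken by the
#' smaller training-sample index. With k = 5 the score is a multiple of 0.2,
#' which is why the class-specific accuracies of the threshold-adjusted 5-NN
#' change regime at thresholds 1/5, 2/5, 3/5 and 4/5.
#'
#' @param train a [labeled_dataset()].
#' @param k number of neighbors (1, 3 or 5 in the study design).
#' @return a fitted `smotehd_model`.
#' @export
fit_knn <- function(train, k = 5L) {
  k <- as.integer(k)
  if (k > nrow(train$X)) stop("'k' cannot exceed the training set size")
  new_model("smotehd_knn", paste0(k, "-NN"), train,
            list(X = train$X, y = train$y, k = k))
}

#' @export
predict_score.smotehd_knn <- function(model, X) {
  X <- check_vars(model, X)
  D <- cross_dist2(X, model$X)
  apply(D, 1, function(d) {
    nn <- order(d)[seq_len(model$k)]  # stable order: smallest index on ties
    mean(model$y[nn] == 1L)
  })
}

#' Nearest shrunken centroids (PAM-style) classifier
#'
#' Standardized class-centroid contrasts
#' `d_cj = (mean_cj - mean_j) / (m_c (s_j + s0))` are soft-thresholded,
#' `d'_cj = sign(d_cj) max(|d_cj| - Delta, 0)`, and the shrunken centroids
#' `mean_j + m_c (s_j + s0) d'_cj` define the discriminant
#' `delta_c(x) = sum_j (x_j - mean'_cj)^2 / (s_j + s0)^2 - 2 log pi_c`
#' with class-proportion priors `pi_c` — the classifier's embedded
#' class-imbalance correction. `s_j` is the pooled within-class standard
#' deviation, `s0` its median, `m_c = sqrt(1/n_c - 1/n)`. The shrinkage
#' `Delta` is chosen by stratified internal cross-validation on the training
#' set over a grid of 10 values from 0 to `max |d_cj|` (ties in accuracy go
#' to the larger `Delta`); the fold count is `min(10, n_min)`, with a warning
#' when fewer than 10 folds are possible.
#'
#' @param train a [labeled_dataset()] with >= 2 samples per class.
#' @param n_delta grid size for the shrinkage search.
#' @param seed optional integer seed for the fold assignment.
#' @return a fitted `smotehd_model` (element `delta` holds the chosen value).
#' @export
fit_pam <- function(train, n_delta = 10L, seed = NULL) {
  cnt <- class_counts(train)
  if (any(cnt < 2L)) stop("PAM needs >= 2 samples per class")
  n_min <- min(cnt)
  nfold <- min(10L, n_min)
  if (nfold < 10L) {
    warning("reducing PAM cross-validation to ", nfold,
            " folds (minority class has ", n_min, " samples)")
  }
  stats0 <- pam_stats(train)
  grid <- seq(0, max(abs(stats0$d)), length.out = n_delta)
  with_seed(seed, {
    fold <- integer(length(train$y))
    for (cls in c(1L, 2L)) {
      idx <- sample(which(train$y == cls))
      fold[idx] <- rep_len(seq_len(nfold), length(idx))
    }
    acc <- numeric(length(grid))
    for (f in seq_len(nfold)) {
      tr <- subset_samples(train, fold != f)
      if (length(unique(tr$y)) < 2L) next
      st <- pam_stats(tr)
      Xte <- train$X[fold == f, , drop = FALSE]
      yte <- train$y[fold == f]
      for (g in seq_along(grid)) {
        sc <- pam_score(st, Xte, grid[g])
        pred <- ifelse(sc > 0.5, 1L, ifelse(sc < 0.5, 2L,
                                            sample(c(1L, 2L), length(sc), TRUE)))
        acc[g] <- acc[g] + sum(pred == yte)
      }
    }
    delta <- grid[max(which(acc == max(acc)))]  # ties -> more shrinkage
    new_model("smotehd_pam", "PAM", train,
              c(stats0, list(delta = delta, grid = grid)))
  })
}

pam_stats <- function(train) {
  X1 <- train$X[train$y == 1L, , drop = FALSE]
  X2 <- train$X[train$y == 2L, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2); n <- n1 + n2
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  mo <- (n1 * m1 + n2 * m2) / n
  df <- max(n - 2L, 1L)
  s <- sqrt((colSums((X1 - rep(m1, each = n1))^2) +
             colSums((X2 - rep(m2, each = n2))^2)) / df)
  s0 <- stats::median(s)
  mc <- sqrt(pmax(c(1 / n1, 1 / n2) - 1 / n, 0))
  d <- rbind((m1 - mo) / (mc[1] * (s + s0)),
             (m2 - mo) / (mc[2] * (s + s0)))
  list(mo = mo, s = s, s0 = s0, mc = mc, d = d, prior = c(n1, n2) / n)
}

soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

pam_score <- function(st, X, delta) {
  ds <- soft_threshold(st$d, delta)
  sw <- st$s + st$s0
  cen1 <- st$mo + st$mc[1] * sw * ds[1, ]
  cen2 <- st$mo + st$mc[2] * sw * ds[2, ]
  disc1 <- colSums((t(X) - cen1)^2 / sw^2) - 2 * log(st$prior[1])
  disc2 <- colSums((t(X) - cen2)^2 / sw^2) - 2 * log(st$prior[2])
  two_class_posterior(-disc1 / 2, -disc2 / 2)
}

#' @export
predict_score.smotehd_pam <- function(model, X) {
  X <- check_vars(model, X)
  pam_score(model, X, model$delta)
}

# --- delegated classifiers -------------------------------------------------

as_train_frame <- function(train) {
  df <- as.data.frame(train$X)
  names(df) <- make.names(colnames(train$X))
  df$.class <- factor(train$y, levels = c(1L, 2L))
  df
}

as_test_frame <- function(model, X) {
  df <- as.data.frame(X)
  names(df) <- make.names(model$vars)
  df
}

fit_cart <- function(train, seed = NULL) {
  with_seed(seed, {
    fit <- rpart::rpart(
      .class ~ ., data = as_train_frame(train), method = "class",
      control = rpart::rpart.control(maxdepth = 5, cp = 0.01)
    )
    cpt <- fit$cptable
    best <- cpt[which.min(cpt[, "xerror"]), "CP"]
    fit <- rpart::prune(fit, cp = best)
    new_model("smotehd_cart", "CART", train, list(fit = fit))
  })
}

#' @export
predict_score.smotehd_cart <- function(model, X) {
  X <- check_vars(model, X)
  unname(stats::predict(model$fit, as_test_frame(model, X),
                        type = "prob")[, "1"])
}

fit_rf <- function(train, seed = NULL) {
  with_seed(seed, {
    fit <- randomForest::randomForest(x = train$X,
                                      y = factor(train$y, levels = c(1L, 2L)))
    new_model("smotehd_rf", "RF", train, list(fit = fit))
  })
}

#' @export
predict_score.smotehd_rf <- function(model, X) {
  X <- check_vars(model, X)
  colnames(X) <- model$vars
  unname(stats::predict(model$fit, X, type = "prob")[, "1"])
}

fit_svm <- function(train, seed = NULL) {
  with_seed(seed, {
    fit <- tryCatch(
      e1071::svm(x = train$X, y = factor(train$y, levels = c(1L, 2L)),
                 probability = TRUE),
      error = function(e) stop("SVM fit failed: ", conditionMessage(e))
    )
    new_model("smotehd_svm", "SVM", train, list(fit = fit))
  })
}

#' @export
predict_score.smotehd_svm <- function(model, X) {
  X <- check_vars(model, X)
  colnames(X) <- model$vars
  pred <- stats::predict(model$fit, X, probability = TRUE)
  unname(attr(pred, "probabilities")[, "1"])
}

fit_plr <- function(train, alpha, seed = NULL) {
  cnt <- class_counts(train)
  nfold <- max(3L, min(10L, min(cnt)))
  with_seed(seed, {
    fold <- integer(length(train$y))
    for (cls in c(1L, 2L)) {
      idx <- sample(which(train$y == cls))
      fold[idx] <- rep_len(seq_len(nfold), length(idx))
    }
    y <- factor(train$y, levels = c(1L, 2L))
    cv <- tryCatch(
      glmnet::cv.glmnet(train$X, y, family = "binomial", alpha = alpha,
                        type.measure = "deviance", foldid = fold),
      error = function(e) {
        stop("penalized logistic fit failed to converge: ",
             conditionMessage(e))
      }
    )
    name <- if (alpha == 1) "PLR-L1" else "PLR-L2"
    new_model("smotehd_plr", name, train, list(fit = cv))
  })
}

#' @export
predict_score.smotehd_plr <- function(model, X) {
  X <- check_vars(model, X)
  colnames(X) <- model$vars
  # glmnet's binomial response is P(second level) = P(class 2)
  p2 <- stats::predict(model$fit, X, s = "lambda.min", type = "response")
  unname(1 - p2[, 1])
}

# --- classification rule ---------------------------------------------------

#' Classification threshold of the cut-off adjustment
#'
#' The cut-off adjustment replaces the uncorrected 0.5 threshold with the
#' training Class-1 fraction k1, so that a new sample goes to Class 1 only if
#' its posterior exceeds the prior imbalance.
#'
#' @param train the (original, pre-resampling) training [labeled_dataset()].
#' @return the training Class-1 fraction k1.
#' @export
cutoff_threshold <- function(train) {
  unname(class_fractions(train)[["1"]])
}

#' Classify new samples by thresholding the posterior score
#'
#' Assigns Class 1 when `p(c = 1 | x) > threshold`, Class 2 when below, and a
#' fair random class at exact equality (the tie rule of the threshold
#' adjustment).
#'
#' @param model a fitted `smotehd_model`.
#' @param X matrix of new samples on the model's variable set.
#' @param threshold classification threshold: 0.5 for the uncorrected rule or
#'   [cutoff_threshold()] of the training set for the adjusted rule.
#' @param seed optional integer seed for the tie draws.
#' @return integer vector of predicted labels in `{1, 2}`, with the scores
#'   attached as attribute `"scores"`.
#' @export
classify <- function(model, X, threshold = 0.5, seed = NULL) {
  score <- predict_score(model, X)
  with_seed(seed, {
    lab <- ifelse(score > threshold, 1L, 2L)
    tie <- score == threshold
    if (any(tie)) {
      lab[tie] <- sample(c(1L, 2L), sum(tie), replace = TRUE)
    }
    structure(lab, scores = score)
  })
}
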