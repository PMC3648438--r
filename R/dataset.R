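#' Labeled two-class dataset
#'
#' The universal container passed between all stages of the package: a numeric
#' samples-by-variables matrix together with a class label (1 or 2) per sample.
#'
#' @param X numeric matrix, samples in rows, variables in columns.
#' @param y integer-like vector of class labels in `{1, 2}`, one per row of `X`.
#' @param role `"train"` or `"test"`; training sets must contain both classes.
#' @return an object of class `labeled_dataset` with elements `X`, `y`, `role`.
#' @examples
#' ds <- labeled_dataset(matrix(rnorm(20), 10, 2), rep(1:2, each = 5))
#' class_counts(ds)
#' @export
labeled_dataset <- function(X, y, role = c("train", "test")) {
  role <- match.arg(role)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y)) {
    stop("'X' has ", nrow(X), " rows but 'y' has ", length(y), " labels")
  }
  if (anyNA(X)) stop("'X' contains missing values")
  if (anyNA(y) || !all(y %in% c(1L, 2L))) {
    stop("labels must be 1 or 2 with no missing values")
  }
  if (role == "train" && length(unique(y)) < 2L) {
    stop("a training set must contain samples from both classes")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  structure(list(X = X, y = y, role = role), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cnt <- class_counts(x)
  cat(sprintf(
    "<labeled_dataset [%s]> %d samples x %d variables (class 1: %d, class 2: %d)\n",
    x$role, nrow(x$X), ncol(x$X), cnt[["1"]], cnt[["2"]]
  ))
  invisible(x)
}

#' Class counts and fractions of a labeled dataset
#'
#' @param ds a [labeled_dataset()].
#' @return `class_counts()`: named integer vector `c("1" = n1, "2" = n2)`.
#' @export
class_counts <- function(ds) {
  c("1" = sum(ds$y == 1L), "2" = sum(ds$y == 2L))
}

#' @rdname class_counts
#' @return `class_fractions()`: named numeric vector `k_c = n_c / n`.
#' @export
class_fractions <- function(ds) {
  class_counts(ds) / length(ds$y)
}

#' @rdname class_counts
#' @return `minority_class()`: the label (1 or 2) of the smaller class; ties
#'   resolve to class 2, the minority class in the designs emulated here.
#' @export
minority_class <- function(ds) {
  cnt <- class_counts(ds)
  if (cnt[["2"]] <= cnt[["1"]]) 2L else 1L
}

#' Subset the samples of a labeled dataset
#'
#' @param ds a [labeled_dataset()].
#' @param i row (sample) indices or logical mask.
#' @param role optional new role for the subset.
#' @return a [labeled_dataset()] with the selected samples.
#' @export
subset_samples <- function(ds, i, role = ds$role) {
  labeled_dataset(ds$X[i, , drop = FALSE], ds$y[i], role = role)
}

#' Read and write labeled datasets as CSV/TSV
#'
#' The on-disk dialect is one row per sample with a `class` column holding 1/2
#' and all remaining columns numeric. `write_dataset()` optionally writes a
#' sidecar JSON (`<path>.json`) recording the generating configuration and
#' seed; `read_dataset()` picks the sidecar up if present.
#'
#' @param ds a [labeled_dataset()].
#' @param path file path; a `.tsv` extension selects tab separation.
#' @param config optional list (e.g. a [sim_config()]) stored in the sidecar.
#' @return `read_dataset()` returns a [labeled_dataset()]; any sidecar config
#'   is attached as attribute `"config"`.
#' @export
write_dataset <- function(ds, path, config = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(class = ds$y, ds$X, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(config, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_dataset
#' @param role role to assign to the dataset read from disk.
#' @param label_column name of the column holding class labels.
#' @export
read_dataset <- function(path, role = "train", label_column = "class") {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop("no '", label_column, "' column in ", path)
  }
  lab <- df[[label_column]]
  if (!all(lab %in% c(1, 2))) {
    lev <- sort(unique(lab))
    if (length(lev) != 2L) stop("label column must have exactly two levels")
    lab <- match(lab, lev)  # first level -> class 1, second -> class 2
  }
  X <- as.matrix(df[, setdiff(names(df), label_column), drop = FALSE])
  ds <- labeled_dataset(X, lab, role = role)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(ds, "config") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  ds
}
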