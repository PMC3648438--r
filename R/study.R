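#' Configuration of a simulation study
#'
#' Describes one of the study families: the low-dimensional design, the
#' high-dimensional designs over a grid of class-imbalance levels (null,
#' alternative, all-variables-DE, exponential), or the fixed-minority
#' titration. Every (replicate, k1) cell simulates one dataset that is shared
#' by all corrections and classifiers, so comparisons between corrections are
#' paired.
#'
#' @param design `"highdim_null"`, `"highdim_alt"`, `"highdim_allDE"`,
#'   `"highdim_exponential"` or `"lowdim"`.
#' @param k1_grid Class-1 training fractions to profile (default: 0.05, 0.1,
#'   ..., 0.9, 0.95).
#' @param corrections subset of `{"none", "smote", "undersample", "cutoff"}`.
#' @param classifiers subset of [smotehd_methods()].
#' @param g selected variable count, or `NULL` for G = p.
#' @param selection_order see [pipeline_config()].
#' @param normalization `NULL` picks the design's convention: sample
#'   normalization everywhere except the all-DE design, which uses raw data.
#' @param n_replicates simulated datasets per k1 (the reference study used
#'   1000; the desk-scale default is 50).
#' @param p,n_train,n_test,rho,mu2,p_de,block_size design parameters passed to
#'   [sim_config()]; `mu2`/`p_de` are only used by the alternative designs.
#' @param master_seed integer seed from which all per-replicate streams are
#'   derived.
#' @return a `study_config` list.
#' @export
study_config <- function(design = c("highdim_null", "highdim_alt",
                                    "highdim_allDE", "highdim_exponential",
                                    "lowdim"),
                         k1_grid = c(0.05, seq(0.1, 0.9, by = 0.1), 0.95),
                         corrections = c("none", "smote"),
                         classifiers = c("DLDA", "5-NN"),
                         g = 40, selection_order = "after_smote",
                         normalization = NULL, n_replicates = 50,
                         p = NULL, n_train = NULL, n_test = NULL, rho = 0.8,
                         mu2 = NULL, p_de = NULL, block_size = 10,
                         master_seed = 1) {
  design <- match.arg(design)
  classifiers <- match.arg(classifiers, smotehd_methods(), several.ok = TRUE)
  corrections <- match.arg(corrections,
                           c("none", "smote", "undersample", "cutoff"),
                           several.ok = TRUE)
  lowdim <- design == "lowdim"
  if (is.null(p)) p <- if (lowdim) 5 else 1000
  if (is.null(n_train)) n_train <- if (lowdim) 40 else 80
  if (is.null(n_test)) n_test <- if (lowdim) 40 else 20
  if (is.null(normalization)) {
    normalization <- if (design == "highdim_allDE") "raw" else "samples"
  }
  if (is.null(p_de)) {
    p_de <- switch(design, highdim_null = 0, lowdim = p,
                   highdim_allDE = p, 20)
  }
  if (is.null(mu2)) {
    mu2 <- switch(design, highdim_null = 0, highdim_allDE = 0.2, 1)
  }
  structure(
    list(design = design, k1_grid = k1_grid, corrections = corrections,
         classifiers = classifiers, g = g, selection_order = selection_order,
         normalization = normalization, n_replicates = n_replicates,
         p = p, n_train = n_train, n_test = n_test, rho = rho, mu2 = mu2,
         p_de = p_de,
         block_size = if (lowdim) p else block_size,
         distribution = if (design == "highdim_exponential") "exponential"
                        else "gaussian",
         master_seed = master_seed),
    class = "study_config"
  )
}

study_sim_config <- function(cfg, k1, seed) {
  sim_config(
    p = cfg$p, n_train = cfg$n_train, n_test = cfg$n_test, k1 = k1,
    rho = cfg$rho, block_size = cfg$block_size, p_de = cfg$p_de,
    mu2 = cfg$mu2, distribution = cfg$distribution, seed = seed
  )
}

#' Run a simulation study
#'
#' For every replicate and class-imbalance level, simulates one dataset under
#' the configured design and evaluates every (correction, classifier) cell on
#' that same dataset via [evaluate_on_test()]. Failures of individual cells
#' (e.g. a degenerate replicate breaking a delegated optimizer) are recorded
#' and skipped rather than aborting the study.
#'
#' @param cfg a [study_config()].
#' @return a `study_result`: list with `results` (long data.frame with columns
#'   design, replicate, k1, classifier, correction, metric, value), `failures`
#'   (data.frame of skipped cells) and `config`.
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  rep_seeds <- derive_seeds(cfg$master_seed, cfg$n_replicates)
  rows <- list(); fails <- list()
  measures <- c("PA", "PA1", "PA2", "AUC", "Gmean")
  for (r in seq_len(cfg$n_replicates)) {
    cell_seeds <- derive_seeds(rep_seeds[r], length(cfg$k1_grid) *
                                 (1L + length(cfg$corrections) *
                                    length(cfg$classifiers)))
    s <- 0L
    for (k1 in cfg$k1_grid) {
      s <- s + 1L
      sim <- simulate_dataset(study_sim_config(cfg, k1, cell_seeds[s]))
      for (corr in cfg$corrections) {
        for (cl in cfg$classifiers) {
          s <- s + 1L
          pc <- pipeline_config(classifier = cl, correction = corr,
                                normalization = cfg$normalization,
                                g = cfg$g,
                                selection_order = cfg$selection_order)
          m <- tryCatch(
            evaluate_on_test(sim$train, sim$test, pc, seed = cell_seeds[s]),
            error = function(e) e
          )
          if (inherits(m, "error")) {
            fails[[length(fails) + 1L]] <- data.frame(
              replicate = r, k1 = k1, classifier = cl, correction = corr,
              message = conditionMessage(m)
            )
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              design = cfg$design, replicate = r, k1 = k1, classifier = cl,
              correction = corr, metric = measures,
              value = unname(unclass(m)[measures])
            )
          }
        }
      }
    }
  }
  structure(
    list(results = do.call(rbind, rows),
         failures = if (length(fails)) do.call(rbind, fails) else NULL,
         config = cfg),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d rows", nrow(x$results)))
  if (!is.null(x$failures)) cat(sprintf(" (%d failed cells)", nrow(x$failures)))
  cat("\n")
  invisible(x)
}

#' Aggregate a study result into per-cell means and standard deviations
#'
#' @param result a [run_study()] or [run_titration()] result.
#' @return data.frame with one row per (design, k1, classifier, correction,
#'   metric) and columns `mean`, `sd`, `n_replicates`; exactly recomputable
#'   from `result$results`.
#' @export
aggregate_study <- function(result) {
  stopifnot(inherits(result, "study_result"))
  df <- result$results
  agg <- stats::aggregate(
    value ~ design + k1 + classifier + correction + metric, data = df,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v))
  )
  out <- cbind(agg[setdiff(names(agg), "value")], as.data.frame(agg$value))
  names(out)[names(out) == "n"] <- "n_replicates"
  out
}

#' Export study results as tidy CSV
#'
#' Writes the long per-replicate table and, alongside it
#' (`<path>_aggregate.csv`), the per-cell mean/sd aggregation.
#'
#' @param result a `study_result`.
#' @param path output CSV path for the long table.
#' @export
write_study_results <- function(result, path) {
  utils::write.csv(result$results, path, row.names = FALSE)
  utils::write.csv(aggregate_study(result),
                   sub("\\.csv$", "_aggregate.csv", path), row.names = FALSE)
  invisible(path)
}

#' Run the fixed-minority class-imbalance titration
#'
#' Emulates the design in which the training minority class is held at
#' `n_min` samples while the majority class grows with the majority fraction
#' k1 (0.50 to 0.90): per replicate a fresh dataset is simulated under the
#' alternative high-dimensional design, a titration split is drawn with
#' [subsample_for_titration()], and every (correction, classifier) cell is
#' evaluated on the balanced held-out test set.
#'
#' @param n_min minority training size (5 or 10 in the reference design).
#' @param k1_grid majority fractions to profile.
#' @param cfg a [study_config()] providing design, classifiers, corrections,
#'   selection and normalization settings (its `k1_grid` is ignored).
#' @param n_test balanced test-set size per replicate.
#' @param n_pool number of samples per class in each simulated pool.
#' @return a `study_result` (k1 is the majority fraction).
#' @export
run_titration <- function(n_min = 5, k1_grid = seq(0.5, 0.9, by = 0.1),
                          cfg = study_config("highdim_alt",
                                             n_replicates = 100),
                          n_test = 20, n_pool = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  max_maj <- round_half_up(n_min * max(k1_grid) / (1 - max(k1_grid)))
  if (is.null(n_pool)) n_pool <- max(max_maj, n_min) + n_test
  rep_seeds <- derive_seeds(cfg$master_seed, cfg$n_replicates)
  rows <- list(); fails <- list()
  measures <- c("PA", "PA1", "PA2", "AUC", "Gmean")
  for (r in seq_len(cfg$n_replicates)) {
    n_cells <- length(k1_grid) * (2L + length(cfg$corrections) *
                                    length(cfg$classifiers))
    cell_seeds <- derive_seeds(rep_seeds[r], n_cells)
    s <- 0L
    for (k1 in k1_grid) {
      s <- s + 2L
      pool_cfg <- sim_config(
        p = cfg$p, n_train = 2L * n_pool, n_test = 4L, k1 = 0.5,
        rho = cfg$rho, block_size = cfg$block_size, p_de = cfg$p_de,
        mu2 = cfg$mu2, distribution = cfg$distribution,
        seed = cell_seeds[s - 1L]
      )
      pool <- simulate_dataset(pool_cfg)$train
      split <- subsample_for_titration(pool, n_min = n_min, k1 = k1,
                                       n_test = n_test, minority = 2L,
                                       seed = cell_seeds[s])
      for (corr in cfg$corrections) {
        for (cl in cfg$classifiers) {
          s <- s + 1L
          pc <- pipeline_config(classifier = cl, correction = corr,
                                normalization = cfg$normalization,
                                g = cfg$g,
                                selection_order = cfg$selection_order)
          m <- tryCatch(
            evaluate_on_test(split$train, split$test, pc,
                             seed = cell_seeds[s]),
            error = function(e) e
          )
          if (inherits(m, "error")) {
            fails[[length(fails) + 1L]] <- data.frame(
              replicate = r, k1 = k1, classifier = cl, correction = corr,
              message = conditionMessage(m)
            )
          } else {
            rows[[length(rows) + 1L]] <- data.frame(
              design = "titration", replicate = r, k1 = k1, classifier = cl,
              correction = corr, metric = measures,
              value = unname(unclass(m)[measures])
            )
          }
        }
      }
    }
  }
  structure(
    list(results = do.call(rbind, rows),
         failures = if (length(fails)) do.call(rbind, fails) else NULL,
         config = cfg),
    class = "study_result"
  )
}
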