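#' Accuracy and F1 of a prediction vector
#'
#' Accuracy is the fraction of exact matches. F1 is the harmonic mean of
#' precision and recall for `positive_class` (used here to detect
#' majority-class overfitting on imbalanced cohorts; the positive class is
#' the minority by convention). When the positive class is never predicted
#' or never present, the undefined ratio is reported as 0 with a warning.
#'
#' @param predictions,truth integer vectors of equal length.
#' @param positive_class the class treated as positive for F1.
#' @return list with `accuracy` and `f1`.
#' @examples
#' evaluate(c(1, 2, 2, 2), c(1, 1, 2, 2), positive_class = 2)
#' @export
evaluate <- function(predictions, truth, positive_class = 2L) {
  if (length(predictions) != length(truth) || length(truth) < 1L) {
    stop("predictions and truth must have equal positive length")
  }
  accuracy <- mean(predictions == truth)
  tp <- sum(predictions == positive_class & truth == positive_class)
  fp <- sum(predictions == positive_class & truth != positive_class)
  fn <- sum(predictions != positive_class & truth == positive_class)
  if (tp + fp == 0L || tp + fn == 0L) {
    if (tp + fn == 0L) {
      log_msg(sprintf("positive class %d absent from truth; F1 set to 0",
                      positive_class), level = "warn")
    }
    f1 <- 0
  } else {
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }
  list(accuracy = accuracy, f1 = f1)
}

# minority class of a label vector (ties -> higher class id, i.e. "2")
minority_class <- function(labels) {
  tab <- table(labels)
  as.integer(names(tab)[max(which(tab == min(tab)))])
}

# stratified fraction subsample of a labeled dataset, seeded
stratified_subsample <- function(data, fraction, seed) {
  withr::with_seed(seed, {
    keep <- unlist(lapply(sort(unique(data$labels)), function(cl) {
      idx <- which(data$labels == cl)
      sort(sample(idx, max(2L, round(length(idx) * fraction))))
    }))
  })
  keep <- sort(keep)
  domain_dataset(data$features[keep, , drop = FALSE],
                 labels = data$labels[keep],
                 feature_names = colnames(data$features),
                 domain_tag = data$domain_tag)
}

# balanced per-class subsample (n_per_class from each class), seeded
balanced_subsample <- function(data, n_per_class, seed) {
  withr::with_seed(seed, {
    keep <- unlist(lapply(sort(unique(data$labels)), function(cl) {
      idx <- which(data$labels == cl)
      sort(sample(idx, min(n_per_class, length(idx))))
    }))
  })
  keep <- sort(keep)
  domain_dataset(data$features[keep, , drop = FALSE],
                 labels = data$labels[keep],
                 feature_names = colnames(data$features),
                 domain_tag = data$domain_tag)
}

#' Hyperparameter grid search on a fixed source/target pair
#'
#' Evaluates every `(k, lambda)` cell of the grid for the adaptive methods;
#' the parameter-free methods (`coral`, `no_adaptation_1nn`) ignore the grid
#' and report a single cell. Because the target carries no labels in
#' deployment, this is transparent grid reporting against held-back target
#' labels rather than cross-validation: each of `repeats` repetitions uses a
#' seeded stratified 80% subsample of the source (mirroring repeated data
#' splits), and per-cell mean and standard deviation over the repeats are
#' reported together with the best cell by mean accuracy. The default grid
#' is k in 2..10 crossed with lambda in {0.01, 0.1, 1, 10, 100} (45 cells).
#'
#' @param source labeled [domain_dataset()].
#' @param target_with_heldback_labels labeled [domain_dataset()]; labels are
#'   hidden from the method and used only for scoring.
#' @param k_values,lam_values grid values.
#' @param method method token, see [run_method()].
#' @param repeats seeded repetitions per cell.
#' @param base_seed repeat `r` uses seed `base_seed + r`.
#' @param config_template [run_config()] supplying the remaining settings.
#' @return an object of class `benchmark_result`; see [run_benchmark()].
#' @export
grid_search <- function(source, target_with_heldback_labels,
                        k_values = 2:10,
                        lam_values = c(0.01, 0.1, 1, 10, 100),
                        method = "ceda", repeats = 5L, base_seed = 1L,
                        config_template = run_config()) {
  method <- match.arg(method,
                      c("ceda", "jda", "coral", "no_adaptation_1nn"))
  target <- target_with_heldback_labels
  if (is.null(source$labels) || is.null(target$labels)) {
    stop("grid_search needs labels on both domains (target held back)")
  }
  grid <- if (method %in% c("ceda", "jda")) {
    expand.grid(k = k_values, lam = lam_values)
  } else {
    data.frame(k = NA_integer_, lam = NA_real_)
  }
  pos <- minority_class(source$labels)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(repeats)) {
      seed_r <- base_seed + r
      src_r <- stratified_subsample(source, 0.8, seed_r)
      cfg <- config_template
      if (!is.na(grid$k[g])) {
        cfg$k <- as.integer(grid$k[g])
        cfg$lam <- grid$lam[g]
      }
      cfg$seed <- seed_r
      preds <- run_method(method, src_r, strip_labels(target), cfg)
      ev <- evaluate(preds, target$labels, pos)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, k = grid$k[g], lam = grid$lam[g],
        repeat_index = r, seed = seed_r,
        accuracy = ev$accuracy, f1 = ev$f1)
    }
  }
  per_repeat <- do.call(rbind, rows)
  summarize_benchmark(per_repeat, group_cols = c("method", "k", "lam"))
}

# aggregate per-repeat rows into a benchmark_result
summarize_benchmark <- function(per_repeat, group_cols) {
  key <- do.call(paste, c(lapply(per_repeat[group_cols], as.character),
                          list(sep = "\r")))
  agg <- do.call(rbind, lapply(split(per_repeat, key), function(df) {
    out <- df[1, group_cols, drop = FALSE]
    out$mean_accuracy <- mean(df$accuracy)
    out$sd_accuracy <- sd(df$accuracy)
    out$mean_f1 <- mean(df$f1)
    out$sd_f1 <- sd(df$f1)
    out$repeats <- nrow(df)
    out
  }))
  agg$sd_accuracy[is.na(agg$sd_accuracy)] <- 0
  agg$sd_f1[is.na(agg$sd_f1)] <- 0
  rownames(agg) <- NULL
  best <- agg[order(-agg$mean_accuracy), , drop = FALSE][1, ]
  structure(list(per_repeat = per_repeat, summary = agg, best = best),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d cell(s), %d repeat rows\n",
              nrow(x$summary), nrow(x$per_repeat)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Run a full simulation benchmark suite
#'
#' For each scenario a-d of the chosen suite, generates fresh source/target
#' data per repeat ([make_experiment()] or [synth_fall_cohort()]), runs
#' every method with the target labels held back, and scores accuracy and
#' F1 against them. Repeat `r` uses seed `base_seed + r` for both data
#' generation and method config, so the whole table is reproducible from
#' `base_seed`.
#'
#' @param suite `"sample_size"`, `"overlap"`, `"noise"` or `"fall_cohort"`.
#' @param methods method tokens, see [run_method()].
#' @param repeats seeded repetitions per scenario.
#' @param base_seed base seed.
#' @param config_template [run_config()] with the hyperparameters to use.
#' @param balanced logical (fall_cohort only): balance classes by
#'   sub-sampling the majority down to the minority count before running.
#' @param out_csv optional path; the summary table is written there as CSV.
#' @return an object of class `benchmark_result` with columns
#'   `suite`, `scenario`, `method` in its summary.
#' @export
run_benchmark <- function(suite = c("overlap", "sample_size", "noise",
                                    "fall_cohort"),
                          methods = c("ceda", "jda", "coral",
                                      "no_adaptation_1nn"),
                          repeats = 20L, base_seed = 1L,
                          config_template = run_config(),
                          balanced = FALSE, out_csv = NULL) {
  suite <- match.arg(suite)
  methods <- match.arg(methods,
                       c("ceda", "jda", "coral", "no_adaptation_1nn"),
                       several.ok = TRUE)
  scenarios <- if (suite == "fall_cohort") "a" else c("a", "b", "c", "d")
  rows <- list()
  for (sc in scenarios) {
    for (r in seq_len(repeats)) {
      seed_r <- base_seed + r
      if (suite == "fall_cohort") {
        sim <- synth_fall_cohort(seed = seed_r)
        if (balanced) {
          n_min <- min(table(sim$source$labels))
          sim$source <- balanced_subsample(sim$source, n_min,
                                           seed = seed_r + 500L)
        }
      } else {
        sim <- make_experiment(suite, sc, seed = seed_r)
      }
      pos <- minority_class(sim$source$labels)
      cfg <- config_template
      cfg$seed <- seed_r
      for (m in methods) {
        preds <- run_method(m, sim$source, strip_labels(sim$target), cfg)
        ev <- evaluate(preds, sim$target$labels, pos)
        rows[[length(rows) + 1L]] <- data.frame(
          suite = suite, scenario = sc, method = m,
          repeat_index = r, seed = seed_r,
          accuracy = ev$accuracy, f1 = ev$f1)
      }
    }
  }
  per_repeat <- do.call(rbind, rows)
  res <- summarize_benchmark(per_repeat,
                             group_cols = c("suite", "scenario", "method"))
  if (!is.null(out_csv)) {
    write.csv(res$summary, out_csv, row.names = FALSE)
    log_msg("benchmark summary written to ", out_csv)
  }
  res
}
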