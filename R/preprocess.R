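#' Define feature groups
#'
#' Assigns every feature to exactly one group and records how many principal
#' components to keep per group. The motivating use is a gait-feature table
#' split into 28 "linear" descriptors (step time, velocity, ...) reduced to
#' 10 components and 22 "nonlinear" dynamics measures (recurrence
#' quantification, entropy, ...) reduced to 12, combined into 22 components.
#'
#' @param group_assignments character/factor vector, one group id per
#'   feature, in feature order.
#' @param components_per_group named integer vector, components to keep for
#'   each group id; each entry must not exceed the group's size.
#' @return an object of class `feature_groups`.
#' @export
feature_groups <- function(group_assignments, components_per_group) {
  group_assignments <- as.character(group_assignments)
  ids <- unique(group_assignments)
  if (!all(ids %in% names(components_per_group))) {
    stop("components_per_group must name every group")
  }
  for (g in ids) {
    sz <- sum(group_assignments == g)
    m <- components_per_group[[g]]
    if (m < 1L || m > sz) {
      stop(sprintf("group '%s': %d components requested from %d features",
                   g, m, sz))
    }
  }
  structure(list(group_assignments = group_assignments,
                 components_per_group = components_per_group[ids]),
            class = "feature_groups")
}

#' Standard gait-feature grouping
#'
#' The 28 linear + 22 nonlinear split with 10 + 12 retained components,
#' matching the feature names produced by [synth_fall_cohort()].
#'
#' @return a [feature_groups()] object for 50 features.
#' @export
fall_feature_groups <- function() {
  feature_groups(
    rep(c("linear", "nonlinear"), c(28L, 22L)),
    c(linear = 10L, nonlinear = 12L)
  )
}

#' Group-wise principal component reduction
#'
#' Fits a separate PCA within each feature group on the pooled rows of all
#' supplied datasets (reference plus others; labels are never used, so both
#' domains end up in one shared component space), keeps the requested number
#' of components per group, and concatenates the per-group scores. Per-group
#' loadings are orthonormal and components are ordered by decreasing
#' explained variance; component signs follow the largest-loading-positive
#' convention so results are deterministic. Groups with deficient rank are
#' truncated to their rank with a warning. Components are not rescaled to
#' unit variance.
#'
#' @param reference a [domain_dataset()] (typically the source domain).
#' @param others list of further [domain_dataset()] objects sharing the
#'   feature space (typically the target domain).
#' @param groups a [feature_groups()] covering all features.
#' @return list with `reference` and `others` (transformed datasets),
#'   `loadings` and `centers` (per group) and `explained_variance`.
#' @export
groupwise_pca <- function(reference, others = list(), groups) {
  stopifnot(inherits(reference, "domain_dataset"),
            inherits(groups, "feature_groups"))
  if (inherits(others, "domain_dataset")) others <- list(others)
  all_ds <- c(list(reference), others)
  d <- n_features(reference)
  if (length(groups$group_assignments) != d) {
    stop("group assignments do not cover the feature space")
  }
  for (ds in all_ds) {
    if (n_features(ds) != d) stop("datasets share no common feature space")
  }
  pooled <- do.call(rbind, lapply(all_ds, function(ds) ds$features))

  loadings <- list()
  centers <- list()
  expl <- list()
  score_blocks <- lapply(all_ds, function(ds) NULL)
  out_names <- character(0)
  for (g in names(groups$components_per_group)) {
    cols <- which(groups$group_assignments == g)
    m_req <- groups$components_per_group[[g]]
    pc <- prcomp(pooled[, cols, drop = FALSE], center = TRUE, scale. = FALSE)
    rank_g <- sum(pc$sdev > pc$sdev[1] * 1e-10)
    m <- min(m_req, rank_g)
    if (m < m_req) {
      log_msg(sprintf(
        "group '%s' has rank %d < %d requested components; truncated",
        g, rank_g, m_req), level = "warn")
    }
    rot <- fix_signs(pc$rotation[, seq_len(m), drop = FALSE])
    loadings[[g]] <- rot
    centers[[g]] <- pc$center
    expl[[g]] <- pc$sdev[seq_len(m)]^2
    for (i in seq_along(all_ds)) {
      sc <- sweep(all_ds[[i]]$features[, cols, drop = FALSE],
                  2, pc$center, `-`) %*% rot
      score_blocks[[i]] <- cbind(score_blocks[[i]], sc)
    }
    out_names <- c(out_names, paste0(g, "_PC", seq_len(m)))
  }
  transformed <- lapply(seq_along(all_ds), function(i) {
    set_features(all_ds[[i]], score_blocks[[i]], feature_names = out_names)
  })
  list(reference = transformed[[1]],
       others = transformed[-1],
       loadings = loadings, centers = centers,
       explained_variance = expl)
}

#' Mutual-information feature filtering
#'
#' Scores every feature by its estimated mutual information with the class
#' label and keeps the `top_k` highest. Mutual information is zero if and
#' only if feature and label are independent, with higher values meaning
#' stronger dependence. Each continuous feature is discretized into
#' `n_bins` equal-frequency (quantile) bins, and the plug-in estimate
#' `sum p(x, y) log(p(x, y) / (p(x) p(y)))` is computed in nats; quantile
#' binning makes the score invariant to strictly monotone rescalings of a
#' feature (up to ties). Score ties break toward the lower feature index.
#'
#' @param data labeled [domain_dataset()].
#' @param top_k number of features to keep.
#' @param n_bins number of quantile bins per feature (default 10).
#' @return an object of class `selection_report` with `selected_indices`
#'   (ordered by descending score), `scores` (all features, nats) and
#'   `method`.
#' @export
mutual_info_select <- function(data, top_k, n_bins = 10L) {
  stopifnot(inherits(data, "domain_dataset"))
  if (is.null(data$labels)) stop("mutual information needs labels")
  d <- n_features(data)
  if (top_k < 1L || top_k > d) {
    stop(sprintf("top_k must be in [1, %d]", d))
  }
  scores <- vapply(seq_len(d), function(j) {
    mi_binned(data$features[, j], data$labels, n_bins)
  }, numeric(1))
  ord <- order(-scores, seq_len(d))
  structure(
    list(selected_indices = ord[seq_len(top_k)], scores = scores,
         feature_names = colnames(data$features),
         method = sprintf("mutual_information_quantile_%dbins", n_bins)),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %s: kept %d of %d features\n",
              x$method, length(x$selected_indices), length(x$scores)))
  invisible(x)
}

# plug-in MI (nats) between a quantile-binned continuous x and discrete y
mi_binned <- function(x, y, n_bins) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(0)  # constant feature
  xb <- cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- table(xb, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Write a selection report to CSV
#'
#' One row per feature with its score and rank; selected features flagged.
#'
#' @param report a `selection_report` from [mutual_info_select()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  d <- length(report$scores)
  nms <- report$feature_names
  if (is.null(nms)) nms <- paste0("f", seq_len(d))
  df <- data.frame(
    feature = nms,
    score = report$scores,
    rank = rank(-report$scores, ties.method = "first"),
    selected = seq_len(d) %in% report$selected_indices
  )
  df <- df[order(df$rank), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Pooled z-scoring across a stack of datasets
#'
#' Fits per-feature mean and standard deviation over the pooled rows of all
#' supplied datasets and standardizes each dataset with the shared record.
#' Features with zero pooled variance are dropped with a warning; it is an
#' error for every feature to be constant.
#'
#' @param reference_stack list of [domain_dataset()] objects with matching
#'   features.
#' @return list with `datasets` (transformed, same order), `center`,
#'   `scale` and `dropped_features` (indices).
#' @export
zscore_fit_apply <- function(reference_stack) {
  if (inherits(reference_stack, "domain_dataset")) {
    reference_stack <- list(reference_stack)
  }
  stopifnot(length(reference_stack) >= 1L)
  d <- n_features(reference_stack[[1]])
  pooled <- do.call(rbind, lapply(reference_stack, function(x) x$features))
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, sd)
  drop <- unname(which(!is.finite(scl) | scl <= .Machine$double.eps))
  if (length(drop) == d) stop("all features have zero pooled variance")
  if (length(drop)) {
    log_msg(sprintf("dropping %d zero-variance feature(s): %s",
                    length(drop), paste(drop, collapse = ", ")),
            level = "warn")
  }
  keep <- setdiff(seq_len(d), drop)
  datasets <- lapply(reference_stack, function(ds) {
    m <- sweep(sweep(ds$features[, keep, drop = FALSE], 2, ctr[keep], `-`),
               2, scl[keep], `/`)
    nms <- colnames(ds$features)
    set_features(ds, m, feature_names = if (!is.null(nms)) nms[keep])
  })
  list(datasets = datasets, center = ctr[keep], scale = scl[keep],
       dropped_features = drop)
}
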