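#' Iterative joint distribution adaptation
#'
#' Starting from supplied target pseudo-labels, alternates: build the
#' marginal + conditional MMD matrices from the current pseudo-labels, solve
#' the adaptation eigenproblem ([solve_jda_eigenproblem()]) for the d x k
#' matrix `A`, embed all samples as `Z = A' X`, train 1NN on the embedded
#' source with its true labels, and re-predict the target pseudo-labels.
#' The loop stops early once the pseudo-labels are unchanged between two
#' consecutive iterations (so at least two iterations run unless
#' `max_iters = 1`).
#'
#' Internally samples live as columns (`X` is d x n, source block first);
#' the interface uses samples-as-rows [domain_dataset()] objects.
#'
#' @param source labeled [domain_dataset()] (already aligned if used inside
#'   the full pipeline).
#' @param target unlabeled [domain_dataset()], same feature dimension.
#' @param config a [run_config()]; `normalize = TRUE` z-scores each feature
#'   over the pooled source+target stack before adaptation.
#' @param initial_pseudo_labels integer vector of length `nrow(target)`;
#'   values must come from the source label set.
#' @return an object of class `adaptation_result`: `matrix_a` (d x k),
#'   `embedding_z` (k x (ns+nt)), `eigenvalues` (ascending), `pseudo_labels`
#'   (final), `iterations_run`, and `history` (data frame with per-iteration
#'   pseudo-label change counts and the marginal MMD value of the embedding).
#' @export
jda_iterate <- function(source, target, config, initial_pseudo_labels) {
  stopifnot(inherits(source, "domain_dataset"),
            inherits(target, "domain_dataset"),
            inherits(config, "run_config"))
  if (is.null(source$labels)) stop("source must be labeled")
  if (config$max_iters < 1L) stop("max_iters must be >= 1 here")
  if (n_features(source) != n_features(target)) {
    stop("source and target feature dimensions disagree")
  }
  ns <- n_samples(source)
  nt <- n_samples(target)
  check_config_for_data(config, ns, nt, n_features(source))
  classes <- sort(unique(source$labels))
  pseudo <- as.integer(initial_pseudo_labels)
  if (length(pseudo) != nt) stop("initial pseudo-labels length mismatch")
  if (!all(pseudo %in% classes)) {
    stop("initial pseudo-labels outside the source label set")
  }

  stacked <- rbind(source$features, target$features)
  if (config$normalize) {
    zs <- zscore_matrix(stacked)
    stacked <- zs$scaled
  }
  x <- t(stacked)  # d x n, source block first
  m0 <- build_marginal_mmd(ns, nt)
  xm0xt <- x %*% m0 %*% t(x)  # fixed across iterations

  history <- data.frame(iteration = integer(0), n_changed = integer(0),
                        marginal_mmd = numeric(0))
  sol <- NULL
  z <- NULL
  for (t_iter in seq_len(config$max_iters)) {
    mset <- build_mmd_set(source$labels, pseudo, classes)
    sol <- solve_jda_eigenproblem(x, mset$m_sum, config$lam, config$k)
    z <- crossprod(sol$matrix_a, x)  # k x n
    new_pseudo <- knn1_predict(t(z[, seq_len(ns), drop = FALSE]),
                               source$labels,
                               t(z[, ns + seq_len(nt), drop = FALSE]))
    n_changed <- sum(new_pseudo != pseudo)
    mmd_val <- sum(diag(crossprod(sol$matrix_a,
                                  xm0xt %*% sol$matrix_a)))
    history <- rbind(history,
                     data.frame(iteration = t_iter, n_changed = n_changed,
                                marginal_mmd = mmd_val))
    converged <- t_iter > 1L && n_changed == 0L
    pseudo <- new_pseudo
    if (converged) break
  }

  structure(
    list(matrix_a = sol$matrix_a, embedding_z = z,
         eigenvalues = sol$eigenvalues, pseudo_labels = pseudo,
         iterations_run = nrow(history), history = history,
         ns = ns, nt = nt, normalize = config$normalize),
    class = "adaptation_result"
  )
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf(
    "<adaptation_result> k=%d, %d+%d samples, %d iteration(s), final marginal MMD %.4g\n",
    length(x$eigenvalues), x$ns, x$nt, x$iterations_run,
    x$history$marginal_mmd[nrow(x$history)]))
  invisible(x)
}

# z-score columns of a matrix; constant columns are left centered (sd -> 1)
zscore_matrix <- function(m) {
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  degenerate <- !is.finite(scl) | scl <= .Machine$double.eps
  if (any(degenerate)) {
    log_msg(sprintf("%d constant feature(s) left unscaled during z-scoring",
                    sum(degenerate)), level = "warn")
    scl[degenerate] <- 1
  }
  list(scaled = sweep(sweep(m, 2, ctr, `-`), 2, scl, `/`),
       center = ctr, scale = scl)
}
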