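#' Adaptation run configuration
#'
#' Bundles the hyperparameters shared by the adaptation routines: the number
#' of subspace bases `k`, the regularization parameter `lambda` of the
#' generalized eigenproblem, the pseudo-label refinement iteration budget,
#' the covariance regularization used by the correlation-alignment step, and
#' the normalization switch. A single `seed` field is the only entry point
#' for randomness so that every run is reproducible.
#'
#' @param k positive integer, number of subspace bases (embedding dimension).
#'   Must not exceed the feature dimension of the data it is applied to.
#' @param lam positive real, eigenproblem regularization lambda.
#' @param max_iters nonnegative integer, pseudo-label refinement iterations.
#'   `0` is accepted by [run_ceda()] only and means "correlation alignment
#'   plus 1NN, no joint distribution adaptation".
#' @param seed integer seed governing any randomness downstream.
#' @param normalize logical; z-score features over the pooled source+target
#'   stack before adaptation (default `TRUE`: without it scale disparities
#'   dominate the discrepancy terms).
#' @param coral_reg nonnegative real added to the covariance diagonals in the
#'   correlation-alignment step; default 1 keeps the step well-posed when
#'   there are fewer samples than features.
#' @param coral_center logical; mean-align the correlation-alignment step
#'   (see the `center` flag of [fit_coral()]). Default `TRUE` for the
#'   pipeline: the uncentered map `X A` displaces the source mean by the
#'   arbitrary amount `mu_s (A - I)`, which degrades the initial
#'   pseudo-labels whenever the shift has a first-order component; centering
#'   and re-basing at the target mean removes that artifact.
#' @param classifier classifier token; only `"1nn"` is supported.
#' @return an object of class `run_config`.
#' @export
run_config <- function(k = 2L, lam = 1, max_iters = 10L, seed = 1L,
                       normalize = TRUE, coral_reg = 1,
                       coral_center = TRUE, classifier = "1nn") {
  check_scalar_number(k, "k", lower = 1)
  check_scalar_number(lam, "lam", lower = 0, strict = TRUE)
  check_scalar_number(max_iters, "max_iters", lower = 0)
  check_scalar_number(coral_reg, "coral_reg", lower = 0)
  if (!identical(classifier, "1nn")) {
    stop("only the '1nn' classifier is supported")
  }
  structure(
    list(k = as.integer(k), lam = as.numeric(lam),
         max_iters = as.integer(max_iters), seed = as.integer(seed),
         normalize = isTRUE(normalize), coral_reg = as.numeric(coral_reg),
         coral_center = isTRUE(coral_center), classifier = "1nn"),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> k=%d lam=%g max_iters=%d seed=%d normalize=%s coral_reg=%g\n",
    x$k, x$lam, x$max_iters, x$seed, x$normalize, x$coral_reg))
  invisible(x)
}

# validate a config against concrete data dimensions
check_config_for_data <- function(config, ns, nt, d) {
  stopifnot(inherits(config, "run_config"))
  if (config$k > d) {
    stop(sprintf("k = %d exceeds the feature dimension d = %d", config$k, d))
  }
  if (config$k >= ns + nt) {
    stop("k must be smaller than the total number of samples")
  }
  invisible(config)
}
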