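#' Regularized sample covariance
#'
#' Sample covariance of a samples-by-features matrix (divisor `n - 1`; the
#' zero matrix for a single sample) with `reg_strength` added to the
#' diagonal. The result is exactly symmetric.
#'
#' @param features numeric n x d matrix, rows are samples.
#' @param reg_strength nonnegative real added to the diagonal.
#' @return d x d symmetric matrix.
#' @export
estimate_covariance <- function(features, reg_strength = 0) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("features contain non-finite values")
  check_scalar_number(reg_strength, "reg_strength", lower = 0)
  d <- ncol(features)
  if (nrow(features) < 2L) {
    cv <- matrix(0, d, d)
  } else {
    cv <- cov(features)
  }
  sym(unname(cv)) + diag(reg_strength, d)
}

#' Fit a correlation-alignment transform
#'
#' Second-order alignment of the source domain to the target: the returned
#' d x d matrix `A` whitens the source correlation structure and re-colors it
#' with the target's, `A = Cs^(-1/2) Ct^(1/2)` with `Cs`, `Ct` the
#' regularized covariances and symmetric principal matrix square roots.
#' Applying `A` (see [apply_coral()]) maps source samples into the target
#' covariance geometry; means are not touched (the alignment is second-order
#' only).
#'
#' @param source,target [domain_dataset()] objects with equal feature count.
#' @param reg_strength nonnegative ridge added to both covariance diagonals;
#'   the default 1 keeps both matrices invertible when n < d.
#' @param center logical, default `FALSE` (pure second-order alignment, the
#'   transform acts on the raw coordinates). With `center = TRUE` the
#'   re-coloring acts on mean-centered source coordinates and the result is
#'   re-based at the target mean, so first-order (mean) shift is aligned as
#'   well; useful when the domain shift has a large mean component, which
#'   covariance alignment alone cannot address (and, applied to uncentered
#'   data, the linear map displaces the source mean arbitrarily).
#' @return an object of class `coral_transform` with elements `matrix_a`,
#'   `reg_strength`, `center`, `source_mean`, `target_mean`, `source_cov`,
#'   `target_cov` (both regularized) and `condition_number` of `matrix_a`.
#' @examples
#' s <- domain_dataset(matrix(rnorm(100), 50, 2), domain_tag = "source")
#' t <- domain_dataset(matrix(rnorm(100, sd = 2), 50, 2), domain_tag = "target")
#' ct <- fit_coral(s, t, reg_strength = 0)
#' @export
fit_coral <- function(source, target, reg_strength = 1, center = FALSE) {
  stopifnot(inherits(source, "domain_dataset"),
            inherits(target, "domain_dataset"))
  if (n_features(source) != n_features(target)) {
    stop("source and target must have the same number of features")
  }
  cs <- estimate_covariance(source$features, reg_strength)
  ct <- estimate_covariance(target$features, reg_strength)
  cs_isqrt <- sym_mat_power(cs, -0.5)
  ct_sqrt <- sym_mat_power(ct, 0.5)
  a <- cs_isqrt %*% ct_sqrt
  sv <- svd(a, nu = 0, nv = 0)$d
  structure(
    list(matrix_a = a, reg_strength = reg_strength, center = isTRUE(center),
         source_mean = colMeans(source$features),
         target_mean = colMeans(target$features),
         source_cov = cs, target_cov = ct,
         condition_number = max(sv) / min(sv)),
    class = "coral_transform"
  )
}

#' @export
print.coral_transform <- function(x, ...) {
  cat(sprintf("<coral_transform> d=%d reg=%g cond(A)=%.3g\n",
              nrow(x$matrix_a), x$reg_strength, x$condition_number))
  invisible(x)
}

#' Apply a correlation-alignment transform
#'
#' For a transform fitted with `center = FALSE` (the default) this is the
#' plain linear map `X A`. With `center = TRUE` the source mean is removed
#' first and the target mean added after: `(X - mu_s) A + mu_t`.
#'
#' @param transform a `coral_transform` from [fit_coral()].
#' @param features numeric n x d matrix, d matching the transform.
#' @return the transformed n x d matrix.
#' @export
apply_coral <- function(transform, features) {
  stopifnot(inherits(transform, "coral_transform"))
  features <- as.matrix(features)
  if (ncol(features) != nrow(transform$matrix_a)) {
    stop("feature dimension does not match the transform")
  }
  if (transform$center) {
    sweep(sweep(features, 2, transform$source_mean, `-`) %*%
            transform$matrix_a,
          2, transform$target_mean, `+`)
  } else {
    features %*% transform$matrix_a
  }
}
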