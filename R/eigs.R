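#' Solve the adaptation eigenproblem
#'
#' Finds the adaptation matrix `A` as the `k` generalized eigenvectors with
#' smallest eigenvalues of
#' `(X M X' + lambda I) a = phi X H X' a`,
#' where `X` is the d x n stacked feature matrix (samples as columns, source
#' block first), `M` the summed marginal+conditional MMD matrix and `H` the
#' centering matrix. Minimizing the MMD quadratic form subject to unit
#' projected variance is exactly this pencil.
#'
#' Both sides are symmetrized before solving; since the left side `S` is
#' positive definite for `lambda > 0`, the pencil is reduced to the ordinary
#' symmetric problem `S^(-1/2) B S^(-1/2) v = theta v` whose k largest
#' `theta` give the k smallest `phi = 1/theta` with `a = S^(-1/2) v`.
#' Eigenvalues are returned ascending; eigenvector signs are fixed by making
#' each column's largest-magnitude entry positive, and ties resolve by solver
#' output order, so repeated runs are bit-identical.
#'
#' @param stacked_features d x n matrix, columns are samples.
#' @param mmd_sum n x n summed MMD matrix for the current pseudo-labels.
#' @param lam positive regularization lambda.
#' @param k number of subspace bases, `k <= d`.
#' @return list with `matrix_a` (d x k) and `eigenvalues` (ascending,
#'   length k).
#' @export
solve_jda_eigenproblem <- function(stacked_features, mmd_sum, lam, k) {
  x <- as.matrix(stacked_features)
  d <- nrow(x)
  n <- ncol(x)
  check_scalar_number(lam, "lam", lower = 0, strict = TRUE)
  check_scalar_number(k, "k", lower = 1)
  if (k > d) stop(sprintf("k = %d exceeds feature dimension d = %d", k, d))
  if (!all(dim(mmd_sum) == c(n, n))) stop("mmd_sum dimension mismatch")

  s <- sym(x %*% mmd_sum %*% t(x)) + diag(lam, d)
  b <- sym(tcrossprod(x %*% centering_matrix(n), x))

  es <- eigen(s, symmetric = TRUE)
  if (min(es$values) <= 0) {
    stop("left-hand side not positive definite; check lambda and the MMD sum")
  }
  s_isqrt <- es$vectors %*% (1 / sqrt(es$values) * t(es$vectors))
  w <- sym(s_isqrt %*% b %*% s_isqrt)
  ew <- eigen(w, symmetric = TRUE)
  theta <- ew$values[seq_len(k)]
  if (any(theta <= max(ew$values[1], 0) * 1e-12) || any(theta <= 0)) {
    stop(sprintf(
      "centered data rank is below k = %d; reduce k or add features", k))
  }
  a <- fix_signs(s_isqrt %*% ew$vectors[, seq_len(k), drop = FALSE])
  list(matrix_a = a, eigenvalues = 1 / theta)
}
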