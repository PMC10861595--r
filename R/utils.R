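#' Structured log line
#'
#' Writes a tagged message to stderr. Used by the pipeline stages to report
#' parameters, dropped features, empty pseudo-label classes and similar
#' non-fatal events without polluting output files.
#'
#' @param ... pieces pasted into the message.
#' @param level one of "info", "warn".
#' @keywords internal
log_msg <- function(..., level = "info") {
  message(sprintf("[ceda:%s] %s", level, paste0(...)))
}

# symmetrize a square matrix (kills floating-point asymmetry)
sym <- function(m) (m + t(m)) / 2

#' Symmetric matrix power via eigendecomposition
#'
#' Computes `m^power` for a symmetric positive semi-definite matrix using the
#' spectral decomposition. Negative eigenvalues (floating-point noise) are
#' clipped at zero before the power is taken; negative powers require strict
#' positive definiteness.
#'
#' @param m symmetric matrix.
#' @param power real exponent (1/2 and -1/2 are the uses here).
#' @return symmetric matrix of the same dimension.
#' @keywords internal
sym_mat_power <- function(m, power) {
  e <- eigen(sym(m), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (power < 0 && min(vals) <= max(vals) * .Machine$double.eps * 100) {
    stop("matrix is not positive definite; increase reg_strength")
  }
  out <- e$vectors %*% (vals^power * t(e$vectors))
  sym(out)
}

# deterministic eigenvector sign convention: largest-magnitude entry positive
fix_signs <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 1)
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

check_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name))
  }
  if (strict && x <= lower) stop(sprintf("`%s` must be > %s", name, lower))
  if (!strict && x < lower) stop(sprintf("`%s` must be >= %s", name, lower))
  invisible(x)
}
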