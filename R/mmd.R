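#' Marginal MMD matrix
#'
#' The (ns+nt) x (ns+nt) block matrix `M0` whose quadratic form
#' `tr(A' X M0 X' A)` is the squared empirical maximum mean discrepancy
#' between the projected source and target marginals. With samples ordered
#' source block first, entries are `1/(ns*ns)` within the source block,
#' `1/(nt*nt)` within the target block and `-1/(ns*nt)` across; equivalently
#' the rank-1 outer product `v v'` with `v_i = 1/ns` (source) or `-1/nt`
#' (target). Symmetric, positive semi-definite, entries summing to zero.
#'
#' @param ns,nt positive source/target sample counts.
#' @return (ns+nt) x (ns+nt) matrix.
#' @export
build_marginal_mmd <- function(ns, nt) {
  check_scalar_number(ns, "ns", lower = 1)
  check_scalar_number(nt, "nt", lower = 1)
  v <- c(rep(1 / ns, ns), rep(-1 / nt, nt))
  tcrossprod(v)
}

#' Conditional MMD matrices
#'
#' One matrix per class `c`, measuring the discrepancy between the source
#' samples truly labeled `c` and the target samples pseudo-labeled `c`:
#' entries `1/(ns_c*ns_c)` for two source samples of class `c`,
#' `1/(nt_c*nt_c)` for two target samples of class `c`, `-1/(ns_c*nt_c)` for
#' cross pairs, and 0 otherwise. A class absent from either block yields the
#' zero matrix (with a logged warning) rather than an error: pseudo-label
#' refinement may transiently empty a class.
#'
#' @param source_labels integer source labels (length ns).
#' @param target_pseudo_labels integer target pseudo-labels (length nt).
#' @param classes integer vector of admissible classes; defaults to the
#'   sorted union of the two label vectors.
#' @return named list of (ns+nt) x (ns+nt) matrices, one per class.
#' @export
build_conditional_mmd <- function(source_labels, target_pseudo_labels,
                                  classes = NULL) {
  source_labels <- as.integer(source_labels)
  target_pseudo_labels <- as.integer(target_pseudo_labels)
  if (is.null(classes)) {
    classes <- sort(unique(c(source_labels, target_pseudo_labels)))
  }
  if (!all(source_labels %in% classes) ||
      !all(target_pseudo_labels %in% classes)) {
    stop("labels outside the declared class set")
  }
  ns <- length(source_labels)
  nt <- length(target_pseudo_labels)
  out <- vector("list", length(classes))
  names(out) <- as.character(classes)
  for (i in seq_along(classes)) {
    cl <- classes[i]
    ns_c <- sum(source_labels == cl)
    nt_c <- sum(target_pseudo_labels == cl)
    if (ns_c == 0L || nt_c == 0L) {
      log_msg(sprintf(
        "class %d empty in %s block; conditional MMD term zeroed",
        cl, if (ns_c == 0L) "source" else "target"), level = "warn")
      out[[i]] <- matrix(0, ns + nt, ns + nt)
      next
    }
    v <- numeric(ns + nt)
    v[which(source_labels == cl)] <- 1 / ns_c
    v[ns + which(target_pseudo_labels == cl)] <- -1 / nt_c
    out[[i]] <- tcrossprod(v)
  }
  out
}

#' MMD matrix set for one refinement iteration
#'
#' Convenience bundle of the marginal matrix, the per-class conditional
#' matrices and their sum, together with the per-class counts.
#'
#' @inheritParams build_conditional_mmd
#' @return an object of class `mmd_matrix_set` with elements `m0`,
#'   `mc_list`, `m_sum`, `ns`, `nt`, `class_counts`.
#' @export
build_mmd_set <- function(source_labels, target_pseudo_labels,
                          classes = NULL) {
  ns <- length(source_labels)
  nt <- length(target_pseudo_labels)
  m0 <- build_marginal_mmd(ns, nt)
  mc <- build_conditional_mmd(source_labels, target_pseudo_labels, classes)
  m_sum <- Reduce(`+`, mc, m0)
  cls <- as.integer(names(mc))
  counts <- data.frame(
    class = cls,
    ns_c = vapply(cls, function(cl) sum(source_labels == cl), integer(1)),
    nt_c = vapply(cls, function(cl) sum(target_pseudo_labels == cl),
                  integer(1))
  )
  structure(list(m0 = m0, mc_list = mc, m_sum = m_sum, ns = ns, nt = nt,
                 class_counts = counts),
            class = "mmd_matrix_set")
}

#' Centering matrix
#'
#' `H = I - (1/n) 11'`: symmetric, idempotent, rows summing to zero. Appears
#' on the variance-preserving side of the adaptation eigenproblem.
#'
#' @param n positive integer.
#' @return n x n matrix.
#' @export
centering_matrix <- function(n) {
  check_scalar_number(n, "n", lower = 1)
  diag(n) - matrix(1 / n, n, n)
}
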