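#' 1-nearest-neighbour classification
#'
#' Assigns each query point the label of its nearest training point under
#' Euclidean distance. Ties are broken deterministically by the lowest
#' training-point index. This is the transfer classifier used throughout the
#' adaptation pipeline (chosen, as is standard in shallow domain-adaptation
#' comparisons, because it has no tuning parameters of its own).
#'
#' @param train_points numeric n x k matrix of training coordinates.
#' @param train_labels integer vector of length n.
#' @param query_points numeric m x k matrix of query coordinates.
#' @return integer vector of m predicted labels.
#' @examples
#' knn1_predict(rbind(c(0, 0), c(2, 0)), c(1L, 2L), rbind(c(0.4, 0)))
#' @export
knn1_predict <- function(train_points, train_labels, query_points) {
  train_points <- as.matrix(train_points)
  query_points <- as.matrix(query_points)
  if (nrow(train_points) < 1L) stop("empty training set")
  if (ncol(train_points) != ncol(query_points)) {
    stop("train and query dimensions disagree")
  }
  if (length(train_labels) != nrow(train_points)) {
    stop("train_labels length must match the training points")
  }
  # squared distances: ||q||^2 + ||t||^2 - 2 q.t ; m x n
  d2 <- outer(rowSums(query_points^2), rowSums(train_points^2), `+`) -
    2 * tcrossprod(query_points, train_points)
  idx <- max.col(-d2, ties.method = "first")
  as.integer(train_labels)[idx]
}
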