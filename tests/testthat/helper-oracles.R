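# independent brute-force oracles used across the suite

# two-pass sample covariance, explicit loops
brute_covariance <- function(x) {
  n <- nrow(x); d <- ncol(x)
  mu <- colMeans(x)
  out <- matrix(0, d, d)
  if (n < 2) return(out)
  for (i in seq_len(n)) {
    dev <- x[i, ] - mu
    out <- out + tcrossprod(dev)
  }
  out / (n - 1)
}

# all-pairs 1NN with explicit double loop and lowest-index tie-break
brute_knn1 <- function(train, labels, query) {
  out <- integer(nrow(query))
  for (i in seq_len(nrow(query))) {
    best <- Inf; best_j <- NA_integer_
    for (j in seq_len(nrow(train))) {
      dist <- sqrt(sum((query[i, ] - train[j, ])^2))
      if (dist < best) { best <- dist; best_j <- j }
    }
    out[i] <- labels[best_j]
  }
  out
}

# entrywise MMD matrix from the piecewise definition
brute_marginal_mmd <- function(ns, nt) {
  n <- ns + nt
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- if (i <= ns && j <= ns) 1 / (ns * ns)
               else if (i > ns && j > ns) 1 / (nt * nt)
               else -1 / (ns * nt)
  }
  m
}

brute_conditional_mmd <- function(src_lab, tgt_lab, cl) {
  ns <- length(src_lab); nt <- length(tgt_lab); n <- ns + nt
  ns_c <- sum(src_lab == cl); nt_c <- sum(tgt_lab == cl)
  m <- matrix(0, n, n)
  if (ns_c == 0 || nt_c == 0) return(m)
  memb <- c(src_lab == cl, tgt_lab == cl)
  side <- rep(c("s", "t"), c(ns, nt))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!memb[i] || !memb[j]) next
    m[i, j] <- if (side[i] == "s" && side[j] == "s") 1 / (ns_c * ns_c)
               else if (side[i] == "t" && side[j] == "t") 1 / (nt_c * nt_c)
               else -1 / (ns_c * nt_c)
  }
  m
}

# largest principal angle (radians) between the column spaces of two bases
max_principal_angle <- function(a, b) {
  qa <- qr.Q(qr(a)); qb <- qr.Q(qr(b))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(sv))))
}

rel_frobenius <- function(a, b) norm(a - b, "F") / norm(b, "F")

# simple 2-class Gaussian pair with a mild covariance shift
make_gaussian_pair <- function(seed, n = 40L, d = 3L, sep = 4) {
  withr::with_seed(seed, {
    mu <- rep(0, d)
    xs <- rbind(MASS::mvrnorm(n, mu, diag(d)),
                MASS::mvrnorm(n, mu + sep, diag(d)))
    xt <- rbind(MASS::mvrnorm(n, mu + 0.3, 1.5 * diag(d)),
                MASS::mvrnorm(n, mu + sep + 0.3, 1.5 * diag(d)))
    list(source = domain_dataset(xs, labels = rep(1:2, each = n),
                                 domain_tag = "source"),
         target = domain_dataset(xt, labels = rep(1:2, each = n),
                                 domain_tag = "target"))
  })
}
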