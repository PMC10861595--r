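# build a stacked d x n matrix plus MMD sum for eigenproblem tests
eigen_fixture <- function(seed, d = 6, ns = 20, nt = 25) {
  withr::with_seed(seed, {
    x <- t(matrix(rnorm((ns + nt) * d), ns + nt, d))
    src <- c(1L, 2L, sample(1:2, ns - 2, TRUE))
    tgt <- c(1L, 2L, sample(1:2, nt - 2, TRUE))
  })
  list(x = x, m = build_mmd_set(src, tgt)$m_sum, ns = ns, nt = nt)
}

test_that("returned columns satisfy the generalized eigen residual bound", {
  for (seed in 1:6) {
    fx <- eigen_fixture(seed)
    k <- 3
    sol <- solve_jda_eigenproblem(fx$x, fx$m, lam = 0.5, k = k)
    n <- ncol(fx$x)
    s <- fx$x %*% fx$m %*% t(fx$x) + diag(0.5, nrow(fx$x))
    b <- fx$x %*% centering_matrix(n) %*% t(fx$x)
    expect_equal(sort(sol$eigenvalues), sol$eigenvalues)  # ascending
    for (j in seq_len(k)) {
      a <- sol$matrix_a[, j]
      lhs <- s %*% a
      expect_lt(sqrt(sum((lhs - sol$eigenvalues[j] * b %*% a)^2)),
                1e-8 * sqrt(sum(lhs^2)))
    }
  }
})

test_that("with a zero MMD matrix the solution spans the leading principal components", {
  fx <- eigen_fixture(12, d = 8, ns = 30, nt = 30)
  k <- 3
  sol <- solve_jda_eigenproblem(fx$x, matrix(0, ncol(fx$x), ncol(fx$x)),
                                lam = 2, k = k)
  pcs <- prcomp(t(fx$x), center = TRUE)$rotation[, seq_len(k)]
  expect_lt(max_principal_angle(sol$matrix_a, pcs), 1e-6)
})

test_that("the eigensolve is deterministic and k is validated", {
  fx <- eigen_fixture(5)
  s1 <- solve_jda_eigenproblem(fx$x, fx$m, 1, 4)
  s2 <- solve_jda_eigenproblem(fx$x, fx$m, 1, 4)
  expect_identical(s1$eigenvalues, s2$eigenvalues)
  expect_identical(s1$matrix_a, s2$matrix_a)
  expect_error(solve_jda_eigenproblem(fx$x, fx$m, 1, nrow(fx$x) + 1),
               "exceeds")
})

test_that("with dominant regularization eigenvalues scale linearly in lambda", {
  fx <- eigen_fixture(8)
  e1 <- solve_jda_eigenproblem(fx$x, fx$m, 1e8, 3)$eigenvalues
  e2 <- solve_jda_eigenproblem(fx$x, fx$m, 2e8, 3)$eigenvalues
  expect_equal(e2 / e1, rep(2, 3), tolerance = 0.01)
})

test_that("refinement loop contracts: iteration count and early stopping", {
  pair <- make_gaussian_pair(14, n = 25, d = 3, sep = 6)
  tgt <- strip_labels(pair$target)
  init <- knn1_predict(pair$source$features, pair$source$labels,
                       tgt$features)

  one <- jda_iterate(pair$source, tgt, run_config(k = 2, max_iters = 1),
                     init)
  expect_identical(one$iterations_run, 1L)
  expect_identical(nrow(one$history), 1L)

  # well-separated identical domains: pseudo-labels are perfect after the
  # first pass and the loop stops right after confirming stability
  src <- pair$source
  same <- strip_labels(src)
  res <- jda_iterate(src, same, run_config(k = 2, max_iters = 10),
                     knn1_predict(src$features, src$labels, same$features))
  expect_identical(res$pseudo_labels, src$labels)
  expect_identical(res$iterations_run, 2L)
  expect_identical(res$history$n_changed[2], 0L)
})

test_that("embedding equals the projection of the stacked features", {
  pair <- make_gaussian_pair(15, n = 20, d = 4)
  tgt <- strip_labels(pair$target)
  cfg <- run_config(k = 2, max_iters = 2, normalize = FALSE)
  init <- knn1_predict(pair$source$features, pair$source$labels,
                       tgt$features)
  res <- jda_iterate(pair$source, tgt, cfg, init)
  x <- t(rbind(pair$source$features, tgt$features))
  expect_equal(res$embedding_z, crossprod(res$matrix_a, x),
               tolerance = 1e-10)
  expect_identical(length(res$eigenvalues), 2L)
  expect_true(all(res$pseudo_labels %in% pair$source$labels))
})

test_that("reordering target samples permutes the pseudo-labels identically", {
  pair <- make_gaussian_pair(16, n = 20, d = 3)
  tgt <- strip_labels(pair$target)
  cfg <- run_config(k = 2, max_iters = 3, normalize = FALSE)
  init <- knn1_predict(pair$source$features, pair$source$labels,
                       tgt$features)
  res <- jda_iterate(pair$source, tgt, cfg, init)
  withr::with_seed(1, perm <- sample(nrow(tgt$features)))
  tgt_p <- domain_dataset(tgt$features[perm, ], domain_tag = "target")
  res_p <- jda_iterate(pair$source, tgt_p, cfg, init[perm])
  expect_identical(res_p$pseudo_labels, res$pseudo_labels[perm])
})

test_that("projection found by the eigensolve beats a random projection at reducing marginal MMD", {
  # on the fixed-parameter overlap scenario (a): the adaptation subspace
  # should carry a smaller marginal-MMD quadratic form than a random
  # projection of identical column scale in most seeded runs
  wins <- 0L
  n_runs <- 20L
  for (r in seq_len(n_runs)) {
    sim <- make_experiment("overlap", "a", seed = 400 + r)
    tgt <- strip_labels(sim$target)
    cfg <- run_config(k = 2, lam = 1, max_iters = 3, normalize = FALSE)
    init <- knn1_predict(sim$source$features, sim$source$labels,
                         tgt$features)
    res <- jda_iterate(sim$source, tgt, cfg, init)
    x <- t(rbind(sim$source$features, tgt$features))
    m0 <- build_marginal_mmd(nrow(sim$source$features),
                             nrow(tgt$features))
    quad <- function(a) sum(diag(crossprod(a, x %*% m0 %*% t(x) %*% a)))
    withr::with_seed(4000 + r, {
      rnd <- matrix(rnorm(length(res$matrix_a)), nrow(res$matrix_a))
    })
    # match column norms so the comparison is scale-free
    rnd <- sweep(rnd, 2, sqrt(colSums(rnd^2)), `/`)
    rnd <- sweep(rnd, 2, sqrt(colSums(res$matrix_a^2)), `*`)
    if (quad(res$matrix_a) < quad(rnd)) wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})

test_that("a class vanishing from the pseudo-labels is tolerated", {
  pair <- make_gaussian_pair(18, n = 15, d = 3)
  tgt <- strip_labels(pair$target)
  init <- rep(1L, nrow(tgt$features))  # class 2 absent
  expect_message(
    res <- jda_iterate(pair$source, tgt,
                       run_config(k = 2, max_iters = 2), init),
    "class 2 empty")
  expect_s3_class(res, "adaptation_result")
})
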