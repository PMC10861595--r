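test_that("random covariance has the drawn eigenvalues and respects the range", {
  for (dim in c(1, 3, 8)) {
    sig <- random_covariance(dim, c(2, 5), seed = 80 + dim)
    expect_equal(sig, t(sig))
    ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= 2 - 1e-8 & ev <= 5 + 1e-8))
    # same seed reproduces; eigenvalues equal the drawn diagonal multiset
    withr::with_seed(80 + dim, dvals <- runif(dim, 2, 5))
    expect_equal(sort(ev), sort(dvals), tolerance = 1e-8)
  }
  expect_error(random_covariance(3, c(0, 1)), "diag_range")
  expect_error(random_covariance(3, c(5, 2)), "diag_range")
})

test_that("sample_domain draws the configured counts, labels and moments", {
  cfg <- scenario_config(
    source = list(list(mean = c(0, 0), sigma = diag(2), n = 5000L),
                  list(mean = c(3, -1), sigma = diag(2), n = 5000L)),
    target = list(list(mean = c(1, 1), sigma = diag(2), n = 1L),
                  list(mean = c(4, 4), sigma = diag(2), n = 1L)),
    seed = 81L)
  src <- sample_domain(cfg, "source")
  expect_identical(nrow(src$features), 10000L)
  expect_identical(sort(unique(src$labels)), 1:2)
  m1 <- colMeans(src$features[src$labels == 1L, ])
  expect_true(all(abs(m1 - c(0, 0)) < 0.06))  # 4 sd / sqrt(n)
  # degenerate n = 1 per class: C rows with labels 1..C
  tgt <- sample_domain(cfg, "target")
  expect_identical(nrow(tgt$features), 2L)
  expect_identical(tgt$labels, 1:2)
  # bit-identical under the same seed
  expect_identical(sample_domain(cfg, "source")$features, src$features)
})

test_that("uniform noise respects its support and mean", {
  pair <- make_gaussian_pair(82, n = 50, d = 100)
  ds <- pair$source
  expect_identical(add_uniform_noise(ds, 0, 0, seed = 1), ds)
  noisy <- add_uniform_noise(ds, -3, 3, seed = 5)
  eps <- noisy$features - ds$features
  expect_true(all(abs(eps) <= 3))
  expect_lt(abs(mean(eps)), 0.1)  # 1e4 cells
  expect_identical(noisy$labels, ds$labels)
  expect_error(add_uniform_noise(ds, 2, 1), "a <= b")
})

test_that("overlap scenarios reproduce the fixed printed parameters", {
  sim <- make_experiment("overlap", "a", seed = 83)
  expect_identical(nrow(sim$source$features), 200L)  # 100 per class
  s1 <- sim$source$features[sim$source$labels == 1L, ]
  expect_true(all(abs(colMeans(s1) - c(2.5, 7.5)) <
                    4 * sqrt(c(3, 1) / 100)))
  expect_lt(rel_frobenius(estimate_covariance(s1), diag(c(3, 1))), 0.35)
  t2 <- sim$target$features[sim$target$labels == 2L, ]
  expect_true(all(abs(colMeans(t2) - c(13, 0)) < 4 * sqrt(c(6, 1) / 100)))

  sim_d <- make_experiment("overlap", "d", seed = 83)
  t1 <- sim_d$target$features[sim_d$target$labels == 1L, ]
  expect_true(all(abs(colMeans(t1) - c(2.5, 6)) < 4 * sqrt(c(8, 2) / 100)))
})

test_that("sample-size scenarios scale the per-class counts", {
  for (sc in c("a", "d")) {
    sim <- make_experiment("sample_size", sc, seed = 84)
    n_expect <- c(a = 50L, d = 500L)[[sc]]
    expect_identical(sum(sim$source$labels == 1L), n_expect)
    expect_identical(sum(sim$target$labels == 2L), n_expect)
    d <- ncol(sim$source$features)
    expect_true(d >= 2 && d <= 20)
    expect_identical(ncol(sim$target$features), d)
  }
})

test_that("noise scenarios add bounded perturbations on top of the same draw", {
  sim <- make_experiment("noise", "d", seed = 85)
  clean_tgt <- sample_domain(sim$params, "target")
  eps <- sim$target$features - clean_tgt$features
  expect_true(all(abs(eps) <= 4))
  expect_gt(max(abs(eps)), 1)      # noise really was added
  expect_identical(sim$params$noise_range, c(-4, 4))
})

test_that("the printed target parameters order scenarios a-c by class overlap", {
  # numeric Bayes-error oracle: optimal rule from the true Gaussian
  # densities, evaluated by quadrature on a fine grid
  bayes_error <- function(p) {
    g <- expand.grid(x = seq(-15, 25, length.out = 220),
                     y = seq(-12, 16, length.out = 220))
    dens <- function(cl) {
      s <- diag(p[[cl]]$sigma)
      stats::dnorm(g$x, p[[cl]]$mean[1], sqrt(s[1])) *
        stats::dnorm(g$y, p[[cl]]$mean[2], sqrt(s[2]))
    }
    d1 <- dens(1); d2 <- dens(2)
    cell <- diff(range(g$x)) / 219 * diff(range(g$y)) / 219
    sum(pmin(d1, d2)) / 2 * cell   # equal priors
  }
  errs <- vapply(c("a", "b", "c"), function(sc) {
    bayes_error(ceda:::overlap_parameters(sc)$target)
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("the synthetic cohort fixture matches the documented shape", {
  sim <- synth_fall_cohort(seed = 86)
  expect_identical(dim(sim$source$features), c(171L, 50L))
  expect_identical(dim(sim$target$features), c(49L, 50L))
  expect_identical(colnames(sim$source$features)[c(1, 29)],
                   c("lin_01", "nl_01"))
  # imbalanced binary labels, class 2 the minority
  tab <- table(sim$source$labels)
  expect_lt(tab[["2"]], tab[["1"]])
  # determinism
  sim2 <- synth_fall_cohort(seed = 86)
  expect_identical(sim2$source$features, sim$source$features)
  expect_identical(sim2$target$features, sim$target$features)
})

test_that("cohort correlations are block-structured and shared across domains", {
  sim <- synth_fall_cohort(seed = 87)
  corr <- sim$params$correlation
  lin <- seq_len(sim$params$n_linear)
  nl <- sim$params$n_linear + seq_len(sim$params$n_nonlinear)
  off_diag_mean <- function(m) mean(abs(m[upper.tri(m)]))
  expect_gt(off_diag_mean(corr[lin, lin]), mean(abs(corr[lin, nl])))
  # both domains use covariances proportional to one correlation matrix
  s1 <- sim$params$source[[1]]$sigma
  t1 <- sim$params$target[[1]]$sigma
  expect_equal(stats::cov2cor(s1), stats::cov2cor(t1), tolerance = 1e-12)
  # empirical check on a large draw from the generating parameters
  withr::with_seed(88, big <- MASS::mvrnorm(2000, rep(0, 50), s1))
  emp <- stats::cor(big)
  expect_gt(off_diag_mean(emp[lin, lin]), off_diag_mean(emp[lin, nl]))
  expect_error(synth_fall_cohort(minority_fraction = 0.8), "minority")
})
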