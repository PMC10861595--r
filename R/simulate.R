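#' Random covariance with prescribed eigenvalue range
#'
#' Draws diagonal values uniformly from `diag_range`, then conjugates by a
#' random orthogonal matrix to introduce off-diagonal structure:
#' `Sigma = Q diag(d1..d_dim) Q'`. The eigenvalues of the result equal the
#' drawn diagonal values, so they lie inside `diag_range`.
#'
#' @param dim dimension.
#' @param diag_range length-2 vector `c(low, high)`, `0 < low <= high`.
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (so callers can embed the draw in a larger seeded block).
#' @return dim x dim symmetric positive-definite matrix.
#' @export
random_covariance <- function(dim, diag_range, seed = NULL) {
  check_scalar_number(dim, "dim", lower = 1)
  if (length(diag_range) != 2L || diag_range[1] <= 0 ||
      diag_range[1] > diag_range[2]) {
    stop("diag_range must be c(low, high) with 0 < low <= high")
  }
  draw <- function() {
    dvals <- runif(dim, diag_range[1], diag_range[2])
    qrres <- qr(matrix(rnorm(dim * dim), dim, dim))
    q <- qr.Q(qrres)
    q <- q %*% diag(sign(diag(qr.R(qrres))), dim)
    sym(q %*% (dvals * t(q)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Scenario configuration for a two-domain Gaussian simulation
#'
#' Full parameterization of one simulated experiment: per domain and class a
#' mean vector, covariance and sample count, plus an additive-noise range and
#' the seed all randomness flows from.
#'
#' @param source,target lists of per-class parameter lists, each with
#'   elements `mean`, `sigma`, `n`.
#' @param noise_range length-2 vector `c(a, b)` of the uniform additive
#'   noise; `c(0, 0)` means none.
#' @param seed integer seed.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(source, target, noise_range = c(0, 0),
                            seed = 1L) {
  for (dom in list(source, target)) {
    for (cl in dom) {
      stopifnot(is.numeric(cl$mean), is.matrix(cl$sigma), cl$n >= 1)
      if (!isTRUE(all.equal(cl$sigma, t(cl$sigma))) ||
          min(eigen(sym(cl$sigma), symmetric = TRUE,
                    only.values = TRUE)$values) <= 0) {
        stop("class covariance must be symmetric positive definite")
      }
    }
  }
  if (noise_range[1] > noise_range[2]) stop("noise range must have a <= b")
  structure(list(source = source, target = target,
                 noise_range = as.numeric(noise_range),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Sample one domain of a scenario
#'
#' Draws `n_c` multivariate Gaussian samples per class with that class's
#' `(mean, sigma)` and attaches labels `1..C` (class order as configured).
#' The draw is deterministic given the scenario seed; source and target use
#' distinct derived streams. Additive noise is NOT applied here (see
#' [add_uniform_noise()]).
#'
#' @param config a [scenario_config()].
#' @param domain `"source"` or `"target"`.
#' @return a labeled [domain_dataset()].
#' @export
sample_domain <- function(config, domain = c("source", "target")) {
  stopifnot(inherits(config, "scenario_config"))
  domain <- match.arg(domain)
  spec <- config[[domain]]
  offset <- if (domain == "source") 0L else 1L
  withr::with_seed(config$seed * 2L + offset, {
    feats <- NULL
    labels <- integer(0)
    for (ci in seq_along(spec)) {
      cl <- spec[[ci]]
      x <- MASS::mvrnorm(cl$n, mu = cl$mean, Sigma = cl$sigma)
      if (cl$n == 1L) x <- matrix(x, nrow = 1)
      feats <- rbind(feats, x)
      labels <- c(labels, rep(ci, cl$n))
    }
    domain_dataset(feats, labels = labels, domain_tag = domain)
  })
}

#' Add independent uniform noise to every feature cell
#'
#' Perturbs each cell by an independent Uniform(a, b) draw; labels are
#' untouched. `a = b = 0` returns the data unchanged.
#'
#' @param data a [domain_dataset()].
#' @param a,b noise range endpoints, `a <= b`.
#' @param seed integer seed for the draw.
#' @return the perturbed [domain_dataset()].
#' @export
add_uniform_noise <- function(data, a, b, seed = 1L) {
  stopifnot(inherits(data, "domain_dataset"))
  if (a > b) stop("noise range must have a <= b")
  if (a == b && a == 0) return(data)
  withr::with_seed(seed, {
    eps <- matrix(runif(length(data$features), a, b),
                  nrow = nrow(data$features))
    set_features(data, data$features + eps,
                 feature_names = colnames(data$features))
  })
}

# fixed parameters of the class-overlap experiment (2-D, printed values)
overlap_parameters <- function(scenario) {
  src <- list(
    list(mean = c(2.5, 7.5), sigma = diag(c(3, 1))),
    list(mean = c(7, 4),     sigma = diag(c(2, 1)))
  )
  tgt <- switch(scenario,
    a = list(list(mean = c(3, 6),   sigma = diag(c(8, 2))),
             list(mean = c(13, 0),  sigma = diag(c(6, 1)))),
    b = list(list(mean = c(3, 6),   sigma = diag(c(8, 2))),
             list(mean = c(8, 1),   sigma = diag(c(6, 1)))),
    c = list(list(mean = c(3, 6),   sigma = diag(c(8, 2))),
             list(mean = c(8, 2),   sigma = diag(c(6, 2)))),
    d = list(list(mean = c(2.5, 6), sigma = diag(c(8, 2))),
             list(mean = c(7, 4),   sigma = diag(c(6, 2)))),
    stop("unknown overlap scenario"))
  list(source = src, target = tgt)
}

# randomized parameters shared by the sample-size and noise experiments:
# each domain draws its own class means from the same per-class ranges
# (class 1 low, class 2 high, so class geometry is preserved while the
# domains genuinely shift), and its own covariance with domain-specific
# eigenvalue ranges
random_shift_parameters <- function(seed,
                                    mean1_range = c(2, 5),
                                    mean2_range = c(4, 9),
                                    source_diag_range = c(1, 3),
                                    target_diag_range = c(4, 6),
                                    dim_range = c(2L, 20L)) {
  withr::with_seed(seed, {
    dim <- sample(seq(dim_range[1], dim_range[2]), 1L)
    ranges <- list(mean1_range, mean2_range)
    draw_domain <- function(diag_range) {
      lapply(1:2, function(ci) {
        list(mean = runif(dim, ranges[[ci]][1], ranges[[ci]][2]),
             sigma = random_covariance(dim, diag_range))
      })
    }
    src <- draw_domain(source_diag_range)
    tgt <- draw_domain(target_diag_range)
    list(source = src, target = tgt, dim = dim)
  })
}

#' Generate one scenario of the simulation suite
#'
#' Reproduces the three simulated robustness experiments:
#' \describe{
#'   \item{`sample_size`}{randomized Gaussian parameters (class-1 means
#'     Uniform(2, 5), class-2 Uniform(4, 9) per dimension; covariance
#'     eigenvalues Uniform(1, 3) for the source and Uniform(4, 6) for the
#'     target via [random_covariance()]; dimension uniform on 2..20) with
#'     50, 100, 200, 500 samples per class for scenarios a-d.}
#'   \item{`overlap`}{the fixed printed 2-D parameters — source class 1
#'     mean (2.5, 7.5), covariance diag(3, 1); class 2 mean (7, 4),
#'     covariance diag(2, 1) — against four target settings of increasing
#'     class overlap, 100 samples per class.}
#'   \item{`noise`}{randomized parameters as in `sample_size`, 100 samples
#'     per class, plus additive Uniform(-s, s) noise with s = 1, 2, 3, 4 for
#'     scenarios a-d, applied to both domains.}
#' }
#' Simulation labels are 1/2 (the binary 0/1 responses remapped).
#'
#' @param name experiment token: `"sample_size"`, `"overlap"` or `"noise"`.
#' @param scenario scenario token `"a"`..`"d"`.
#' @param seed integer seed; all parameter draws and sampling derive from it.
#' @param samples_per_class optional override of the per-class sample count.
#' @return list with labeled `source` and `target` [domain_dataset()]s and
#'   `params` (the generating configuration).
#' @export
make_experiment <- function(name = c("sample_size", "overlap", "noise"),
                            scenario = c("a", "b", "c", "d"),
                            seed = 1L, samples_per_class = NULL) {
  name <- match.arg(name)
  scenario <- match.arg(scenario)
  noise_range <- c(0, 0)
  if (name == "overlap") {
    par <- overlap_parameters(scenario)
    n_per_class <- samples_per_class %||% 100L
  } else {
    par <- random_shift_parameters(seed)
    if (name == "sample_size") {
      n_per_class <- samples_per_class %||%
        c(a = 50L, b = 100L, c = 200L, d = 500L)[[scenario]]
    } else {
      n_per_class <- samples_per_class %||% 100L
      s <- c(a = 1, b = 2, c = 3, d = 4)[[scenario]]
      noise_range <- c(-s, s)
    }
  }
  add_n <- function(dom) lapply(dom, function(cl) c(cl, list(n = n_per_class)))
  config <- scenario_config(add_n(par$source), add_n(par$target),
                            noise_range = noise_range, seed = seed)
  source <- sample_domain(config, "source")
  target <- sample_domain(config, "target")
  if (any(noise_range != 0)) {
    source <- add_uniform_noise(source, noise_range[1], noise_range[2],
                                seed = seed * 2L + 7001L)
    target <- add_uniform_noise(target, noise_range[1], noise_range[2],
                                seed = seed * 2L + 7002L)
  }
  list(source = source, target = target, params = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic two-cohort gait-feature fixture
#'
#' Emulates the shape of a two-cohort wearable-sensor fall-risk dataset: a
#' larger labeled cohort (default 171 community-dwelling older adults) and a
#' smaller one (default 49 osteoporosis patients), 50 features arranged as a
#' correlated block of 28 "linear" gait descriptors and a block of 22
#' "nonlinear" dynamics measures, with binary imbalanced labels
#' (non-faller = 1, faller = 2, the minority). The within-block correlation
#' structure (AR(1), coefficient 0.6; blocks independent) is identical in
#' the two cohorts; the domain shift is a per-feature mean offset plus a
#' common variance inflation in the target. This is a synthetic stand-in for
#' private clinical data — it reproduces sizes, grouping and imbalance, not
#' real gait physiology.
#'
#' @param n_source,n_target cohort sizes.
#' @param n_features feature count, split ~28:22 between the groups.
#' @param minority_fraction fraction of fallers (class 2), in (0, 0.5].
#' @param seed integer seed.
#' @return list with labeled `source` and `target` [domain_dataset()]s and
#'   `params` (generating means and covariances, including the shared
#'   correlation matrix).
#' @export
synth_fall_cohort <- function(n_source = 171L, n_target = 49L,
                              n_features = 50L, minority_fraction = 0.3,
                              seed = 1L) {
  if (minority_fraction <= 0 || minority_fraction > 0.5) {
    stop("minority_fraction must be in (0, 0.5]")
  }
  n_lin <- max(1L, round(n_features * 28 / 50))
  n_nl <- n_features - n_lin
  ar1 <- function(p, rho) rho^abs(outer(seq_len(p), seq_len(p), `-`))
  corr <- matrix(0, n_features, n_features)
  corr[seq_len(n_lin), seq_len(n_lin)] <- ar1(n_lin, 0.6)
  if (n_nl > 0) {
    idx <- n_lin + seq_len(n_nl)
    corr[idx, idx] <- ar1(n_nl, 0.6)
  }
  withr::with_seed(seed, {
    delta <- rnorm(n_features, 0, 0.7)        # class-2 mean shift
    shift <- runif(n_features, 0.3, 0.8)      # target-domain mean offset
  })
  target_scale <- 1.5
  mk_domain <- function(n, dom) {
    n2 <- max(1L, round(n * minority_fraction))
    n1 <- n - n2
    base <- if (dom == "source") rep(0, n_features) else shift
    sc2 <- if (dom == "source") 1 else target_scale^2
    lapply(1:2, function(ci) {
      list(mean = base + if (ci == 2L) delta else 0,
           sigma = sc2 * corr, n = if (ci == 1L) n1 else n2)
    })
  }
  config <- scenario_config(mk_domain(n_source, "source"),
                            mk_domain(n_target, "target"), seed = seed)
  nms <- c(sprintf("lin_%02d", seq_len(n_lin)),
           if (n_nl > 0) sprintf("nl_%02d", seq_len(n_nl)))
  tag_names <- function(ds) {
    set_features(ds, ds$features, feature_names = nms)
  }
  list(source = tag_names(sample_domain(config, "source")),
       target = tag_names(sample_domain(config, "target")),
       params = c(config, list(correlation = corr, n_linear = n_lin,
                               n_nonlinear = n_nl)))
}
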