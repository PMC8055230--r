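test_that("binomial log pmf matches closed forms and normalizes", {
  expect_equal(binomial_logpmf(0, 0, 0.3), 0)
  expect_equal(binomial_logpmf(5, 10, 0.5), log(choose(10, 5)) - 10 * log(2))
  expect_equal(binomial_logpmf(2, 5, 0), -Inf)
  set.seed(2)
  for (i in 1:20) {
    R <- sample(0:40, 1); theta <- runif(1)
    expect_equal(sum(exp(binomial_logpmf(0:R, R, theta))), 1,
                 tolerance = 1e-12)
  }
})

test_that("beta-binomial log pmf: uniform special case and normalization", {
  expect_equal(betabinomial_logpmf(0, 0, 0.5, 2), 0)
  # v = 2, theta = 0.5 gives Beta(1,1) mixing: discrete uniform on 0..R
  for (R in c(1, 7, 23)) {
    expect_equal(betabinomial_logpmf(0:R, R, 0.5, 2),
                 rep(-log(R + 1), R + 1))
  }
  set.seed(3)
  for (i in 1:20) {
    R <- sample(1:40, 1); theta <- runif(1, 0.01, 0.99)
    v <- rgamma(1, 2, 0.1) + 0.1
    expect_equal(sum(exp(betabinomial_logpmf(0:R, R, theta, v))), 1,
                 tolerance = 1e-10)
  }
  expect_error(betabinomial_logpmf(1, 2, 0, 5), "strictly inside")
})

test_that("beta-binomial converges to the binomial as precision grows", {
  # R and theta kept where the genuine over-dispersion gap at v = 1e8
  # (~ R^2 theta / (2 v (1-theta))) stays below the tolerance
  grid <- expand.grid(r = c(0, 3, 10), R = c(10, 50), theta = c(0.1, 0.5, 0.8))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], expect_equal(
      betabinomial_logpmf(r, R, theta, 1e8),
      binomial_logpmf(r, R, theta),
      tolerance = 1e-4
    ))
  }
})

test_that("beta-binomial is over-dispersed relative to the binomial", {
  for (theta in c(0.2, 0.5, 0.8)) {
    for (v in c(2, 10, 100)) {
      R <- 30
      var_bb <- R * theta * (1 - theta) * (R + v) / (v + 1)  # moment formula
      var_bin <- R * theta * (1 - theta)
      expect_gt(var_bb, var_bin)
      # empirical check of the moment formula against the pmf itself
      p <- exp(betabinomial_logpmf(0:R, R, theta, v))
      mu <- sum((0:R) * p)
      expect_equal(sum((0:R - mu)^2 * p), var_bb, tolerance = 1e-8)
    }
  }
})

test_that("sequencing-error adjustment is a symmetric shrinkage toward 1/2", {
  expect_equal(error_adjusted_theta(0.37, 0), 0.37)
  expect_equal(error_adjusted_theta(0, 0.01), 0.01)
  expect_equal(error_adjusted_theta(1, 0.01), 0.99)
  expect_equal(error_adjusted_theta(0.5, 0.2), 0.5)
  expect_error(error_adjusted_theta(0.5, 0.6), "0.5")
})

test_that("mixture log-likelihood equals a brute-force enumeration oracle", {
  tbl <- as_mutation_table(toy_table(n = 3, m = 2, depth = 40))
  phi <- matrix(c(0.8, 0.7, 0.3, 0.2), 2, 2)
  w <- c(0.6, 0.4)
  v <- c(20, 35)
  got <- mixture_loglik(tbl, phi, w, family = "betabinomial", precision = v)

  # explicit double loop, no vectorization
  arr <- clonetrend:::table_arrays(resolve_multiplicity(tbl))
  oracle <- 0
  for (i in 1:3) {
    li <- 0
    for (k in 1:2) {
      lik_k <- 1
      for (j in 1:2) {
        zeta <- clonal_vaf_coefficient(arr$purity[j], arr$cn[i, j],
                                       arr$multiplicity[i, j])
        th <- min(max(zeta * phi[j, k], 1e-9), 1 - 1e-9)
        lik_k <- lik_k * exp(betabinomial_logpmf(arr$alt[i, j],
                                                 arr$total[i, j], th, v[j]))
      }
      li <- li + w[k] * lik_k
    }
    oracle <- oracle + log(li)
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  # binomial family against the same oracle structure
  got_bin <- mixture_loglik(tbl, phi, w, family = "binomial")
  oracle_bin <- 0
  for (i in 1:3) {
    li <- 0
    for (k in 1:2) {
      lik_k <- 1
      for (j in 1:2) {
        zeta <- clonal_vaf_coefficient(arr$purity[j], arr$cn[i, j],
                                       arr$multiplicity[i, j])
        th <- min(max(zeta * phi[j, k], 1e-9), 1 - 1e-9)
        lik_k <- lik_k * stats::dbinom(arr$alt[i, j], arr$total[i, j], th)
      }
      li <- li + w[k] * lik_k
    }
    oracle_bin <- oracle_bin + log(li)
  }
  expect_equal(got_bin, oracle_bin, tolerance = 1e-12)
})

test_that("mixture log-likelihood is invariant to joint cluster permutation
           and degenerates correctly at K = 1", {
  tbl <- as_mutation_table(toy_table(n = 4, m = 3, depth = 60))
  set.seed(9)
  phi <- matrix(runif(9, 0.1, 0.9), 3, 3)
  w <- c(0.5, 0.3, 0.2)
  base <- mixture_loglik(tbl, phi, w, precision = 30)
  perm <- c(3, 1, 2)
  expect_equal(mixture_loglik(tbl, phi[, perm], w[perm], precision = 30),
               base, tolerance = 1e-12)
  # K = 1 reduces to the plain sum of observation log pmfs
  phi1 <- matrix(c(0.5, 0.6, 0.7), 3, 1)
  arr <- clonetrend:::table_arrays(resolve_multiplicity(tbl))
  zeta <- matrix(clonal_vaf_coefficient(rep(arr$purity, each = arr$n),
                                        arr$cn, arr$multiplicity),
                 arr$n, arr$m)
  theta <- zeta * matrix(phi1[, 1], arr$n, arr$m, byrow = TRUE)
  direct <- sum(betabinomial_logpmf(arr$alt, arr$total, theta,
                                    rep(30, each = arr$n)))
  expect_equal(mixture_loglik(tbl, phi1, 1, precision = 30), direct,
               tolerance = 1e-10)
})

test_that("precision prior transform used by the engine matches 1/(1+v) uniform", {
  # p(v) = (1+v)^-2 integrates to 1 on (0, Inf)
  total <- stats::integrate(function(v) (1 + v)^-2, 0, Inf)
  expect_equal(total$value, 1, tolerance = 1e-8)
  # and the implied distribution of 1/(1+v) under that density is uniform:
  # P(1/(1+v) <= q) = P(v >= 1/q - 1) = q
  for (q in c(0.1, 0.5, 0.9)) {
    p <- stats::integrate(function(v) (1 + v)^-2, 1 / q - 1, Inf)$value
    expect_equal(p, q, tolerance = 1e-8)
  }
})
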