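test_that("stick-breaking produces exact simplices with residual closure", {
  expect_equal(stick_breaking(0.5, k = 1), 1)
  expect_equal(stick_breaking(c(0.5, 0.5, 0.5)), c(0.5, 0.25, 0.25))
  set.seed(3)
  for (i in 1:50) {
    k <- sample(2:25, 1)
    u <- runif(k)
    w <- stick_breaking(u, k = k)
    expect_equal(sum(w), 1, tolerance = 1e-15)
    expect_true(all(w >= 0))
    # recursive product formula for the non-closing elements
    if (k >= 3) expect_equal(w[2], u[2] * (1 - u[1]))
  }
  expect_error(stick_breaking(c(0.5, 1.2, 0.1)), "inside")
})

test_that("concentration prior is proper with the stated density", {
  expect_equal(alpha_log_prior(1), -2 * log(2))
  expect_equal(exp(alpha_log_prior(1e-12)), 1, tolerance = 1e-9)
  total <- stats::integrate(function(a) exp(alpha_log_prior(a)), 0, Inf)
  expect_equal(total$value, 1, tolerance = 1e-6)
})

test_that("the four kernels match their closed forms and limits", {
  kinds <- c("Exp", "Mat32", "Mat52", "ExpQ")
  for (kind in kinds) {
    expect_equal(kernel_g(kind, 2.3, 0), 1)
    expect_equal(kernel_g(kind, 1.7, 0.4), kernel_g(kind, 1.7, -0.4))
    expect_equal(kernel_g(kind, 1e-9, 0.9), 1, tolerance = 1e-6)
    g <- kernel_g(kind, 2, seq(0, 3, by = 0.1))
    expect_true(all(diff(g) < 0))
  }
  expect_equal(kernel_g("Exp", 1, 1), exp(-1))
  expect_equal(kernel_g("Mat32", 1.5, 0.5),
               (1 + sqrt(3) * 0.75) * exp(-sqrt(3) * 0.75))
  expect_equal(kernel_g("Mat52", 2, 0.5),
               (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)))
  expect_equal(kernel_g("ExpQ", 3, 0.5), exp(-3 * 0.25 / 2))
  # smoothness ordering at small lags: 1 - g vanishes like |dt| for Exp
  # and like dt^2 for ExpQ
  dt <- 1e-3
  expect_equal((1 - kernel_g("Exp", 1, dt)) / dt, 1, tolerance = 1e-3)
  expect_equal((1 - kernel_g("ExpQ", 1, dt)) / dt^2, 0.5, tolerance = 1e-3)
})

test_that("kernel tau-derivatives match numerical differentiation", {
  for (kind in c("Exp", "Mat32", "Mat52", "ExpQ")) {
    for (tau in c(0.3, 1, 4)) {
      dt <- c(0, 0.1, 0.5, 1)
      num <- (kernel_g(kind, tau + 1e-6, dt) -
                kernel_g(kind, tau - 1e-6, dt)) / 2e-6
      expect_equal(clonetrend:::kernel_g_dtau(kind, tau, dt), num,
                   tolerance = 1e-6)
    }
  }
})

test_that("single-output covariance builder is elementwise correct and PD", {
  expect_equal(gp_covariance(0.5, "Exp", 1, h2 = 2.5, jitter = 0),
               matrix(2.5, 1, 1))
  k2 <- gp_covariance(c(0, 1), "Exp", 1, 1, jitter = 0)
  expect_equal(k2, matrix(c(1, exp(-1), exp(-1), 1), 2))
  set.seed(7)
  for (i in 1:100) {
    times <- sort(runif(sample(2:8, 1)))
    kind <- sample(c("Exp", "Mat32", "Mat52", "ExpQ"), 1)
    covm <- gp_covariance(times, kind, rgamma(1, 1), rgamma(1, 1),
                          jitter = 1e-6)
    expect_silent(chol(covm))
  }
})

test_that("multi-output covariance variants collapse into each other", {
  times <- c(0, 0.3, 1)
  h2 <- c(0.5, 1.2, 2)
  gp1 <- gp_covariance_multi(times, "GP1", "Mat32", h2, tau = 1.5)
  gp2 <- gp_covariance_multi(times, "GP2", "Mat32", h2, tau = 1.5,
                             corr = diag(3))
  expect_equal(gp1, gp2)                   # identity correlation = diagonal
  gp3 <- gp_covariance_multi(times, "GP3", "Mat32", rep(1.2, 3),
                             tau = rep(1.5, 3))
  gp1_same <- gp_covariance_multi(times, "GP1", "Mat32", rep(1.2, 3),
                                  tau = 1.5)
  expect_equal(gp3, gp1_same)              # equal taus/h2: block = separable
  # GP1 with equal amplitudes replicates the GP0 covariance per cluster
  gp0 <- gp_covariance(times, "Mat32", 1.5, 1.2)
  expect_equal(gp1_same[1:3, 1:3], gp0)
  expect_equal(gp1_same[4:6, 4:6], gp0)
  expect_true(all(gp1_same[1:3, 4:6] == 0))
  expect_error(
    gp_covariance_multi(times, "GP2", "Exp", h2, 1,
                        corr = matrix(c(1, 2, 2, 1), 2)),
    "semi-definite"
  )
})

test_that("covariance builders stay near-PSD over random parameter draws", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(2:5, 1); k <- sample(2:4, 1)
    times <- sort(runif(m)); kind <- sample(c("Exp", "ExpQ"), 1)
    variant <- sample(c("GP1", "GP3"), 1)
    tau <- if (variant == "GP3") rgamma(k, 1) else rgamma(1, 1)
    covm <- gp_covariance_multi(times, variant, kind, rgamma(k, 1) + 0.01,
                                tau, jitter = 0)
    ev <- eigen(covm, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("trajectory log prior equals the dense multivariate-normal oracle", {
  set.seed(21)
  times <- c(0, 0.4, 1)
  for (i in 1:20) {
    psi <- matrix(rnorm(9), 3, 3)
    cov0 <- gp_covariance(times, "Mat52", rgamma(1, 1), rgamma(1, 1))
    lp0 <- trajectory_log_prior(psi, cov0, "GP0")
    oracle0 <- sum(vapply(1:3, function(j)
      oracle_mvn_logpdf(psi[, j], cov0), numeric(1)))
    expect_equal(lp0, oracle0, tolerance = 1e-9)

    covm <- gp_covariance_multi(times, "GP3", "Exp", rgamma(3, 1) + 0.1,
                                rgamma(3, 1) + 0.1)
    expect_equal(trajectory_log_prior(psi, covm, "GP3"),
                 oracle_mvn_logpdf(as.vector(psi), covm),
                 tolerance = 1e-9)
  }
  # GP0 with M = 1 and unit amplitude reduces to standard normals
  expect_equal(
    trajectory_log_prior(matrix(c(0.3, -1), 1, 2),
                         gp_covariance(0, "Exp", 1, 1, jitter = 0), "GP0"),
    sum(stats::dnorm(c(0.3, -1), log = TRUE))
  )
  # all-zero trajectories leave only the normalizing constant
  covm <- gp_covariance_multi(c(0, 1), "GP1", "Exp", c(1, 2), 1)
  expect_equal(trajectory_log_prior(matrix(0, 2, 2), covm, "GP1"),
               -0.5 * determinant(covm)$modulus[1] - 2 * log(2 * pi))
})

test_that("LKJ Cholesky construction yields valid correlation matrices", {
  set.seed(4)
  for (k in c(2, 3, 6)) {
    y <- rnorm(k * (k - 1) / 2)
    L <- clonetrend:::lkj_chol_from_y(y, k)
    C <- L %*% t(L)
    expect_equal(diag(C), rep(1, k))
    expect_true(all(eigen(C, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("LKJ prior on the unconstrained scale is normalized and matches
           the closed-form bivariate density", {
  # K = 2: integral over y of exp(log prior) must be 1
  total <- stats::integrate(function(y)
    vapply(y, function(yy)
      exp(clonetrend:::lkj_log_prior_y(yy, 2, eta = 2)), numeric(1)),
    -Inf, Inf)
  expect_equal(total$value, 1, tolerance = 1e-6)
  # implied density of r = tanh(y) must be (3/4)(1 - r^2), the LKJ(2) law
  r <- c(-0.8, -0.2, 0.5, 0.9)
  y <- atanh(r)
  dens_y <- exp(vapply(y, function(yy)
    clonetrend:::lkj_log_prior_y(yy, 2, eta = 2), numeric(1)))
  dens_r <- dens_y / (1 - r^2)            # back through the tanh jacobian
  expect_equal(dens_r, 0.75 * (1 - r^2), tolerance = 1e-12)
})
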