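test_that("membership probabilities match a brute-force Bayes computation", {
  ctx <- get_small_fit()
  fit <- ctx$fit
  mem <- membership_probabilities(fit)
  expect_equal(unname(rowSums(mem)), rep(1, nrow(mem)),
               tolerance = 1e-12)

  # independent dense recomputation: explicit loops over draws, mutations,
  # clusters and samples
  arr <- clonetrend:::table_arrays(fit$data)
  k <- fit$spec$truncation
  s_use <- dim(fit$draws$phi)[1L]
  probs <- array(0, c(arr$n, k, s_use))
  for (s in seq_len(s_use)) {
    for (i in seq_len(arr$n)) {
      lp <- numeric(k)
      for (kk in seq_len(k)) {
        acc <- log(max(fit$draws$weights[s, kk], 1e-300))
        for (j in seq_len(arr$m)) {
          zeta <- clonal_vaf_coefficient(arr$purity[j], arr$cn[i, j],
                                         arr$multiplicity[i, j])
          th <- min(max(zeta * fit$draws$phi[s, j, kk], 1e-9), 1 - 1e-9)
          acc <- acc + betabinomial_logpmf(arr$alt[i, j], arr$total[i, j],
                                          th, fit$draws$precision[s, j])
        }
        lp[kk] <- acc
      }
      probs[i, , s] <- exp(lp - logsumexp_test(lp))
    }
  }
  oracle <- apply(probs, c(1, 2), median)
  oracle <- oracle / rowSums(oracle)
  expect_equal(unname(mem), oracle, tolerance = 1e-10)
})

test_that("hard assignment takes the argmax with the stated tie rule", {
  m <- rbind(c(0.7, 0.3), c(0.5, 0.5), c(0.2, 0.8))
  rownames(m) <- c("a", "b", "c")
  expect_equal(unname(hard_assignment(m, weights = c(0.6, 0.4))),
               c(1L, 1L, 2L))
  # tie goes to the heavier cluster even when it is the second column
  expect_equal(unname(hard_assignment(rbind(c(0.5, 0.5)),
                                      weights = c(0.3, 0.7))), 2L)
  # labels follow a joint permutation of columns and weights
  perm <- c(2, 1)
  relabeled <- hard_assignment(m[, perm], weights = c(0.4, 0.6))
  expect_equal(unname(perm[relabeled]), unname(hard_assignment(m,
               weights = c(0.6, 0.4))))
})

test_that("pruning keeps exactly the supported clusters", {
  ctx <- get_small_fit()
  kept <- prune_clusters(ctx$fit, min_weight = 0.02)
  expect_equal(length(kept), 2L)   # simulation has two true clusters
  # with min_weight = 0 every cluster with any assignment is kept
  mem <- membership_probabilities(ctx$fit)
  labels <- hard_assignment(mem)
  kept0 <- prune_clusters(ctx$fit, min_weight = 0, membership = mem)
  expect_true(all(unique(labels) %in% kept0))
  # report weights renormalize to one
  rep <- cluster_report(ctx$fit, grid = NULL)
  expect_equal(sum(rep$weights), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(rep$membership)),
               rep(1, nrow(rep$membership)), tolerance = 1e-12)
})

test_that("GP conditional interpolates exactly at sample times", {
  times <- c(0, 0.4, 1)
  for (kind in c("Exp", "Mat32", "Mat52", "ExpQ")) {
    cond <- clonetrend:::gp_conditional(times, times, kind, 1.3,
                                        jitter = 1e-9)
    expect_equal(cond$A, diag(3), tolerance = 1e-6)
    expect_lt(max(abs(cond$T)), 1e-6)
  }
})

test_that("trajectory reconstruction matches sampled CCFs at sample times
           and flattens in the long time-scale limit", {
  ctx <- get_small_fit()
  fit <- ctx$fit
  samples <- sample_info(fit$data)
  traj <- predict_trajectories(fit, grid = samples$time, ndraws = 300)
  expect_equal(attr(traj, "type"), "gp")
  kept <- prune_clusters(fit)
  td <- tidy(fit)
  for (k in kept) {
    got <- traj$ccf[traj$cluster == k]
    at_fit <- td$ccf[td$cluster == k]
    expect_equal(got, at_fit, tolerance = 0.05)
  }
  # tau -> 0 limit: correlation ~ 1 everywhere, curve flat at the average
  flat_cond <- clonetrend:::gp_conditional(c(0, 1), c(0.25, 0.5, 0.75),
                                           "Exp", 1e-9, jitter = 1e-9)
  expect_equal(as.vector(flat_cond$A %*% c(2, 2)), rep(2, 3),
               tolerance = 1e-4)

  # band width at sample times does not exceed the midpoint width (ExpQ)
  sim2 <- simulate_clones(n_mutations = 16, n_samples = 2, n_clusters = 1,
                          depth_mean = 400, seed = 31)
  fit2 <- suppressWarnings(clone_fit(sim2$data, "GP0-ExpQ", truncation = 4,
                                     max_iters = 1200, draws = 300,
                                     final_elbo_draws = 100, seed = 3))
  kept2 <- prune_clusters(fit2)[1]
  tr2 <- predict_trajectories(fit2, grid = c(0, 0.5, 1), ndraws = 300)
  tr2 <- tr2[tr2$cluster == kept2, ]
  width <- tr2$ccf_hi - tr2$ccf_lo
  expect_lte(width[1], width[2] + 0.02)
  expect_lte(width[3], width[2] + 0.02)
})

test_that("Flat trajectories are linear interpolations between samples", {
  sim <- simulate_clones(n_mutations = 14, n_samples = 3, n_clusters = 1,
                         depth_mean = 300, seed = 17)
  fit <- suppressWarnings(clone_fit(sim$data, "Flat", truncation = 4,
                                    max_iters = 1000, draws = 200,
                                    final_elbo_draws = 100, seed = 1))
  traj <- predict_trajectories(fit, grid = seq(0, 1, by = 0.25),
                               ndraws = 200)
  expect_equal(attr(traj, "type"), "interpolated")
  expect_warning(predict_trajectories(fit, grid = c(0, 1.2), ndraws = 10),
                 "xtrapolat")
})

test_that("posterior predictive VAF density is normalized and matches
           forward simulation", {
  ctx <- get_small_fit()
  fit <- ctx$fit
  samples <- sample_info(fit$data)
  sid <- samples$sample_id[1]
  pred <- posterior_predictive_vaf(fit, sid,
                                   vaf_grid = seq(0, 1, length.out = 801))
  area <- sum(diff(pred$vaf) * (pred$density[-1] + pred$density[-801]) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  expect_error(posterior_predictive_vaf(fit, "nope"), "Unknown sample_id")

  # forward-simulation oracle: draw VAFs from the fitted model at the same
  # depth/zeta context and compare via the KS statistic on the CDF
  arr <- clonetrend:::table_arrays(fit$data)
  j <- 1L
  depth <- round(median(arr$total[, j]))
  zeta_j <- median(fit$zeta[, j])
  set.seed(41)
  sims <- replicate(4000, {
    s <- sample(nrow(fit$draws$weights), 1)
    k <- sample(fit$spec$truncation, 1, prob = fit$draws$weights[s, ])
    th <- min(max(zeta_j * fit$draws$phi[s, j, k], 1e-9), 1 - 1e-9)
    v <- fit$draws$precision[s, j]
    p <- rbeta(1, v * th, v * (1 - th))
    rbinom(1, depth, p) / depth
  })
  cdf_pred <- cumsum(pred$density) * (pred$vaf[2] - pred$vaf[1])
  cdf_emp <- stats::ecdf(sims)(pred$vaf)
  expect_lt(max(abs(cdf_pred - cdf_emp)), 0.05)
})

test_that("fit reports round-trip through the written files", {
  ctx <- get_small_fit()
  fit <- ctx$fit
  out <- withr::local_tempdir()
  report <- cluster_report(fit, grid = seq(0, 1, length.out = 21))
  paths <- write_fit_report(fit, report, out)
  expect_true(all(file.exists(paths)))

  asg <- readr::read_csv(paths[["assignments"]], show_col_types = FALSE)
  expect_equal(nrow(asg), length(unique(fit$data$mutation_id)))
  expect_equal(asg$cluster,
               unname(report$hard_labels[asg$mutation_id]))
  traj <- readr::read_csv(paths[["trajectories"]], show_col_types = FALSE)
  expect_equal(nrow(traj), 21L * length(report$kept_clusters))
  meta <- jsonlite::read_json(paths[["metadata"]])
  expect_equal(meta$seed, fit$seed)
  expect_equal(meta$model, fit$spec$name)
  expect_equal(meta$truncation, fit$spec$truncation)
})

test_that("tidy, glance and augment return consistent tibbles", {
  ctx <- get_small_fit()
  fit <- ctx$fit
  td <- tidy(fit)
  gl <- glance(fit)
  au <- augment(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(sort(unique(td$cluster)), prune_clusters(fit))
  expect_equal(gl$n_clusters, length(prune_clusters(fit)))
  expect_equal(gl$model, "GP0-Mat32")
  expect_true(all(c(".cluster", ".membership") %in% names(au)))
  expect_equal(nrow(au), nrow(fit$data))
  expect_true(all(au$.membership > 0.5))
})

test_that("plot builders return valid ggplot objects", {
  ctx <- get_small_fit()
  fit <- ctx$fit
  sid <- sample_info(fit$data)$sample_id[1]
  for (p in list(ggplot2::autoplot(fit), plot_vaf_clusters(fit),
                 plot_elbo(fit), plot_predictive(fit, sid))) {
    expect_s3_class(p, "ggplot")
    expect_silent(invisible(ggplot2::ggplot_build(p)))
  }
})
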