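#' Fit a clonal-deconvolution model by variational inference
#'
#' Clusters the mutations of a longitudinal mutation table by cancer-cell
#' fraction with a truncated Dirichlet-process mixture, places the chosen
#' prior on the per-cluster logit-CCF trajectories (uniform per sample for
#' `Flat`; a Gaussian process over normalized time for `GP0`-`GP3`), and
#' maximizes a Monte-Carlo estimate of the evidence lower bound (ELBO) over
#' a mean-field Gaussian variational family on unconstrained transforms,
#' using the reparameterization gradient and an Adam optimizer. Cluster
#' assignments are marginalized out of the likelihood, so the objective is
#' differentiable. The fit is deterministic given `seed`.
#'
#' @param data A `mutation_tbl` (see [as_mutation_table()]) or a data frame
#'   coercible to one. Unset multiplicities are resolved with
#'   [resolve_multiplicity()].
#' @param model Model name from [clone_models()], e.g. `"GP0-Mat32"`.
#' @param truncation,obs_family,shared_dispersion,error_rate,lkj_eta Model
#'   options forwarded to [model_spec()].
#' @param restarts Number of optimization restarts (default 1). Restart
#'   `r` initializes the trajectories from k-means with roughly
#'   `K / 2^(r-1)` distinct centers, giving a ladder from fully split to
#'   strongly agglomerated starting points; the restart with the highest
#'   final ELBO is kept. Useful when the mixture may be stuck splitting a
#'   true cluster.
#' @param max_iters Maximum optimizer iterations (default 20000).
#' @param learning_rate Adam learning rate (default 0.02).
#' @param mc_samples Monte-Carlo samples per gradient step (default 1).
#' @param draws Posterior draws to store from the fitted variational
#'   distribution (default 1000).
#' @param convergence_window,convergence_rel_tol Convergence is declared
#'   when the relative change between consecutive window-means of the ELBO
#'   trace falls below the tolerance.
#' @param final_elbo_draws Fresh Monte-Carlo draws used to evaluate the
#'   reported final ELBO and its standard error (default 500), because the
#'   per-iteration trace is noisy.
#' @param jitter Relative diagonal jitter for GP covariances.
#' @param seed Integer seed controlling initialization, gradient noise and
#'   stored draws.
#' @param verbose Print the ELBO every 500 iterations.
#' @return A `clone_fit` object: a list with the model `spec`, the resolved
#'   input `data`, the variational solution, the per-iteration `elbo_trace`,
#'   `final_elbo` (+/- `final_elbo_se`), a `converged` flag and posterior
#'   `draws` (weights, CCF trajectories `phi`, concentration `alpha`,
#'   kernel hyper-parameters, GP2 correlations and beta-binomial
#'   precisions), with clusters relabeled by decreasing posterior mean
#'   weight.
#' @seealso [tidy.clone_fit()], [glance.clone_fit()], [cluster_report()],
#'   [compare_models()]
#' @export
clone_fit <- function(data, model = "GP0-Mat32",
                      truncation = 20L,
                      obs_family = c("betabinomial", "binomial"),
                      shared_dispersion = FALSE,
                      error_rate = NULL,
                      lkj_eta = 2,
                      restarts = 1L,
                      max_iters = 20000L,
                      learning_rate = 0.02,
                      mc_samples = 1L,
                      draws = 1000L,
                      convergence_window = 500L,
                      convergence_rel_tol = 1e-4,
                      final_elbo_draws = 500L,
                      jitter = 1e-6,
                      seed = 1L,
                      verbose = FALSE) {
  obs_family <- match.arg(obs_family)
  spec <- model_spec(model, truncation = truncation, family = obs_family,
                     shared_dispersion = shared_dispersion,
                     error_rate = error_rate, lkj_eta = lkj_eta)
  tbl <- resolve_multiplicity(data)
  arrays <- table_arrays(tbl)
  if (spec$prior_family != "Flat" && arrays$m < 2) {
    abort("GP families need at least two samples; use the Flat model.")
  }
  cfg <- list(max_iters = as.integer(max_iters),
              learning_rate = learning_rate,
              mc_samples = as.integer(mc_samples),
              draws = as.integer(draws),
              convergence_window = as.integer(convergence_window),
              convergence_rel_tol = convergence_rel_tol,
              final_elbo_draws = as.integer(final_elbo_draws),
              restarts = as.integer(restarts),
              jitter = jitter, seed = as.integer(seed),
              verbose = isTRUE(verbose))
  stopifnot(cfg$max_iters > 0, cfg$learning_rate > 0, cfg$mc_samples > 0,
            cfg$draws > 0, cfg$convergence_window > 0,
            cfg$convergence_rel_tol > 0)
  problem <- build_problem(arrays, spec, jitter = jitter)

  p_tot <- problem$layout$total
  ladder <- pmax(2L, ceiling(spec$truncation / 2^(seq_len(restarts) - 1L)))
  fit <- with_seed(seed, {
    runs <- lapply(ladder, function(k_init) {
      sol <- run_advi(problem, cfg, k_init = k_init)
      sigma <- exp(sol$omega)
      # smoothed terminal ELBO from fresh draws at the optimum
      ent <- sum(sol$omega) + 0.5 * p_tot * log(2 * pi * exp(1))
      elbo_draws <- vapply(seq_len(cfg$final_elbo_draws), function(s) {
        z <- sol$mu + sigma * rnorm(p_tot)
        problem$logp_grad(z, want_grad = FALSE)$value + ent
      }, numeric(1))
      list(sol = sol, elbo_draws = elbo_draws)
    })
    best <- which.max(vapply(runs, function(r) mean(r$elbo_draws),
                             numeric(1)))
    sol <- runs[[best]]$sol
    sigma <- exp(sol$omega)
    zdraws <- lapply(seq_len(cfg$draws), function(s) {
      constrain_draw(sol$mu + sigma * rnorm(p_tot), problem$layout, spec)
    })
    list(sol = sol, elbo_draws = runs[[best]]$elbo_draws, zdraws = zdraws,
         restart_elbos = vapply(runs, function(r) mean(r$elbo_draws),
                                numeric(1)))
  })

  draws_list <- collate_draws(fit$zdraws, spec)
  draws_list <- relabel_draws(draws_list, spec)

  if (!fit$sol$converged) {
    warn(paste0("Maximum iterations (", cfg$max_iters,
                ") reached without meeting the convergence tolerance."))
  }
  structure(list(
    spec = spec,
    data = tbl,
    config = cfg,
    mu = fit$sol$mu,
    omega = fit$sol$omega,
    layout = problem$layout,
    zeta = problem$zeta,
    elbo_trace = fit$sol$trace,
    converged = fit$sol$converged,
    iterations = fit$sol$iterations,
    final_elbo = mean(fit$elbo_draws),
    final_elbo_se = sd(fit$elbo_draws) / sqrt(length(fit$elbo_draws)),
    restart_elbos = fit$restart_elbos,
    draws = draws_list,
    seed = cfg$seed
  ), class = "clone_fit")
}

# stack per-draw constrained parameter lists into arrays
collate_draws <- function(zdraws, spec) {
  s <- length(zdraws)
  k <- length(zdraws[[1L]]$weights)
  m <- nrow(zdraws[[1L]]$phi)
  out <- list(
    weights = t(vapply(zdraws, `[[`, numeric(k), "weights")),
    phi = aperm(vapply(zdraws, `[[`, matrix(0, m, k), "phi"), c(3, 1, 2)),
    alpha = vapply(zdraws, `[[`, numeric(1), "alpha")
  )
  if (!is.null(zdraws[[1L]]$h2)) {
    nh <- length(zdraws[[1L]]$h2)
    nt <- length(zdraws[[1L]]$tau)
    out$h2 <- matrix(vapply(zdraws, `[[`, numeric(nh), "h2"),
                     s, nh, byrow = TRUE)
    out$tau <- matrix(vapply(zdraws, `[[`, numeric(nt), "tau"),
                      s, nt, byrow = TRUE)
  }
  if (!is.null(zdraws[[1L]]$corr)) {
    out$corr <- aperm(vapply(zdraws, `[[`, matrix(0, k, k), "corr"),
                      c(3, 1, 2))
  }
  if (!is.null(zdraws[[1L]]$precision)) {
    out$precision <- matrix(vapply(zdraws, `[[`, numeric(m), "precision"),
                            s, m, byrow = TRUE)
  }
  out
}

# order clusters by decreasing posterior mean weight (mean-field draws do
# not label-switch across draws, so one global permutation suffices)
relabel_draws <- function(draws, spec) {
  perm <- order(colMeans(draws$weights), decreasing = TRUE)
  draws$weights <- draws$weights[, perm, drop = FALSE]
  draws$phi <- draws$phi[, , perm, drop = FALSE]
  percluster <- spec$prior_family %in% c("GP1", "GP2", "GP3")
  if (!is.null(draws$h2) && percluster) {
    draws$h2 <- draws$h2[, perm, drop = FALSE]
  }
  if (!is.null(draws$tau) && spec$prior_family == "GP3") {
    draws$tau <- draws$tau[, perm, drop = FALSE]
  }
  if (!is.null(draws$corr)) {
    draws$corr <- draws$corr[, perm, perm, drop = FALSE]
  }
  draws
}

#' @export
print.clone_fit <- function(x, ...) {
  cat("<clone_fit> model", x$spec$name, "\n")
  cat(sprintf("  mutations: %d  samples: %d  truncation K: %d\n",
              length(unique(x$data$mutation_id)),
              nrow(sample_info(x$data)), x$spec$truncation))
  cat(sprintf("  final ELBO: %.2f (MC se %.2f), %d iterations%s\n",
              x$final_elbo, x$final_elbo_se, x$iterations,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Energy/entropy decomposition of the ELBO
#'
#' Re-evaluates the fitted variational distribution with fresh Monte-Carlo
#' draws and reports the decomposition `ELBO = entropy - energy`, where the
#' energy is the negative expected joint log-density under the variational
#' distribution and the entropy is that of the mean-field Gaussian
#' (analytic).
#'
#' @param fit A `clone_fit`.
#' @param ndraws Number of fresh Monte-Carlo draws.
#' @param seed Seed for the evaluation draws.
#' @return A list with `energy`, `entropy`, `elbo` and the Monte-Carlo
#'   standard error `mc_se` of the energy.
#' @export
elbo_components <- function(fit, ndraws = 500L, seed = 1L) {
  problem <- build_problem(table_arrays(fit$data), fit$spec,
                           jitter = fit$config$jitter)
  sigma <- exp(fit$omega)
  p_tot <- fit$layout$total
  lps <- with_seed(seed, {
    vapply(seq_len(ndraws), function(s) {
      z <- fit$mu + sigma * rnorm(p_tot)
      problem$logp_grad(z, want_grad = FALSE)$value
    }, numeric(1))
  })
  entropy <- sum(fit$omega) + 0.5 * p_tot * log(2 * pi * exp(1))
  energy <- -mean(lps)
  list(energy = energy, entropy = entropy, elbo = entropy - energy,
       mc_se = sd(lps) / sqrt(ndraws))
}

#' Rank fitted models by their final ELBO
#'
#' The maximized ELBO approximates the log model evidence, so a higher
#' value indicates a better model; its internal complexity penalty guards
#' against over-fitting. Monte-Carlo standard errors are reported so that
#' near-ties are visible.
#'
#' @param fits A list of `clone_fit` objects fitted to the same data.
#' @return A tibble with `model`, `elbo`, `elbo_se` and `rank` (1 = best),
#'   sorted by decreasing ELBO.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "clone_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "clone_fit")))
  ref <- fits[[1L]]$data
  for (f in fits[-1L]) {
    same <- identical(ref$mutation_id, f$data$mutation_id) &&
      identical(ref$alt_reads, f$data$alt_reads) &&
      identical(ref$total_reads, f$data$total_reads) &&
      identical(ref$sample_id, f$data$sample_id)
    if (!same) abort("All fits must be on the same mutation table.")
  }
  out <- tibble::tibble(
    model = vapply(fits, function(f) f$spec$name, character(1)),
    elbo = vapply(fits, function(f) f$final_elbo, numeric(1)),
    elbo_se = vapply(fits, function(f) f$final_elbo_se, numeric(1))
  ) |>
    dplyr::arrange(dplyr::desc(.data$elbo)) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy per-cluster summary of a fitted model
#'
#' @param x A `clone_fit`.
#' @param min_weight Pruning threshold passed to [prune_clusters()].
#' @param ... Unused.
#' @return A tibble with one row per kept cluster and sample: cluster id,
#'   posterior median weight, assigned mutation count, sample id, time and
#'   the posterior median CCF with a 95% credible interval.
#' @method tidy clone_fit
#' @export
tidy.clone_fit <- function(x, min_weight = 0.02, ...) {
  rep <- cluster_report(x, min_weight = min_weight, grid = NULL)
  samples <- sample_info(x$data)
  purrr::map_dfr(seq_along(rep$kept_clusters), function(i) {
    k <- rep$kept_clusters[i]
    phi_k <- matrix(x$draws$phi[, , k], dim(x$draws$phi)[1L])   # S x M
    tibble::tibble(
      cluster = k,
      weight = rep$weights_raw[i],
      n_mutations = sum(rep$hard_labels == k),
      sample_id = samples$sample_id,
      time = samples$time,
      ccf = apply(phi_k, 2, median),
      ccf_lo = apply(phi_k, 2, quantile, 0.025),
      ccf_hi = apply(phi_k, 2, quantile, 0.975)
    )
  })
}

#' One-row model summary
#'
#' @param x A `clone_fit`.
#' @param min_weight Pruning threshold for the cluster count.
#' @param ... Unused.
#' @return A tibble with the model name, number of mutations and samples,
#'   kept cluster count, final ELBO (+/- MC standard error), iteration
#'   count and convergence flag.
#' @method glance clone_fit
#' @export
glance.clone_fit <- function(x, min_weight = 0.02, ...) {
  kept <- prune_clusters(x, min_weight = min_weight)
  tibble::tibble(
    model = x$spec$name,
    n_mutations = length(unique(x$data$mutation_id)),
    n_samples = nrow(sample_info(x$data)),
    n_clusters = length(kept),
    elbo = x$final_elbo,
    elbo_se = x$final_elbo_se,
    iterations = x$iterations,
    converged = x$converged
  )
}

#' Per-mutation cluster assignments
#'
#' @param x A `clone_fit`.
#' @param ... Unused.
#' @return The input mutation table augmented with `.cluster` (hard label)
#'   and `.membership` (probability of the assigned cluster).
#' @method augment clone_fit
#' @export
augment.clone_fit <- function(x, ...) {
  mem <- membership_probabilities(x)
  labels <- hard_assignment(mem)
  tbl <- tibble::as_tibble(x$data)
  idx <- match(tbl$mutation_id, rownames(mem))
  tbl$.cluster <- labels[idx]
  tbl$.membership <- mem[cbind(idx, labels[idx])]
  tbl
}
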