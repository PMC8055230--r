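#' Simulate a longitudinal mutation table with known clonal structure
#'
#' Generative recipe: (1) cluster weights from a symmetric Dirichlet;
#' (2) `n_clusters` latent logit-CCF trajectories drawn from the
#' Gaussian-process prior at the design times (or i.i.d. uniform CCFs per
#' sample when `prior = "flat"`), optionally rejection-sampled until every
#' pair of trajectories differs by at least `min_separation` in mean
#' absolute CCF; (3) mutations assigned to clusters by the weights;
#' (4) per (mutation, sample): local copy number from `cn_probs`,
#' multiplicity uniform on `1..D`, purity shared per sample from
#' `purity_range`, total depth negative-binomial, and alt reads from the
#' observation family at \eqn{\theta = \zeta \cdot \phi}.
#'
#' The defaults emulate a targeted-sequencing longitudinal series: six
#' equally spaced samples, fifty mutations in three clusters, mean depth
#' 500 with negative-binomial size 10, purity in `[0.6, 1]`, mostly diploid
#' loci, and mildly over-dispersed beta-binomial counts (`precision`
#' 500).
#'
#' @param n_mutations,n_samples,n_clusters Dataset dimensions (N, M, true
#'   K).
#' @param prior `"gp"` (trajectories from the GP prior) or `"flat"`
#'   (i.i.d. uniform per-sample CCFs).
#' @param kernel,h2,tau Trajectory GP kernel and hyper-parameters.
#' @param times Raw collection times; default equally spaced. With
#'   `time_design = "random"`, times are uniform draws (sorted, endpoints
#'   kept).
#' @param time_design `"equal"` or `"random"`.
#' @param depth_mean,depth_size Negative-binomial total-read model (mean
#'   and size/overdispersion); depths are floored at 10 reads.
#' @param purity_range Per-sample purity is drawn uniformly in this range.
#' @param cn_probs Named probability vector over local total copy numbers.
#' @param family Observation family for alt counts: `"betabinomial"` or
#'   `"binomial"`.
#' @param precision Beta-binomial precision used for simulation.
#' @param weights_conc Symmetric Dirichlet concentration for the cluster
#'   weights.
#' @param min_separation Minimum pairwise mean absolute CCF difference
#'   between cluster trajectories (rejection sampling; 0 disables).
#' @param emit_multiplicity Include the true multiplicity in the emitted
#'   table (default `TRUE`), mirroring the modelling assumption that local
#'   copy state is estimated upstream and treated as fixed. With `FALSE`
#'   the column is left unset and the integer estimation rule of
#'   [resolve_multiplicity()] is exercised instead; note that rule is
#'   exact only for clonal mutations, so multi-copy subclonal mutations
#'   may be misconverted.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A `clone_sim` list with `data` (a `mutation_tbl`) and `truth`
#'   (labels, `phi` M x K matrix, weights, purity, multiplicity and copy
#'   number matrices, precision, times).
#' @export
simulate_clones <- function(n_mutations = 50L, n_samples = 6L,
                            n_clusters = 3L,
                            prior = c("gp", "flat"),
                            kernel = "Mat32", h2 = 1, tau = 1,
                            times = NULL,
                            time_design = c("equal", "random"),
                            depth_mean = 500, depth_size = 10,
                            purity_range = c(0.6, 1),
                            cn_probs = c(`1` = 0.1, `2` = 0.7,
                                         `3` = 0.15, `4` = 0.05),
                            family = c("betabinomial", "binomial"),
                            precision = 500,
                            weights_conc = 2,
                            min_separation = 0,
                            emit_multiplicity = TRUE,
                            seed = 1L) {
  prior <- match.arg(prior)
  time_design <- match.arg(time_design)
  family <- match.arg(family)
  if (n_clusters > n_mutations) {
    abort("`n_clusters` cannot exceed `n_mutations`.")
  }
  if (n_samples < 1) abort("`n_samples` must be >= 1.")
  n <- as.integer(n_mutations); m <- as.integer(n_samples)
  k <- as.integer(n_clusters)

  with_seed(seed, {
    t_raw <- if (!is.null(times)) {
      if (length(times) != m) abort("`times` length must equal n_samples.")
      times
    } else if (time_design == "equal" || m <= 2) {
      seq(0, 1, length.out = max(m, 1L))
    } else {
      sort(c(0, runif(m - 2L), 1))
    }
    tt <- normalize_times(t_raw)

    # cluster weights and trajectories
    gam <- rgamma(k, shape = weights_conc, rate = 1)
    w <- gam / sum(gam)
    draw_phi <- function() {
      if (prior == "flat" || m == 1L) {
        matrix(runif(m * k), m, k)
      } else {
        cov <- gp_covariance(tt, kernel, tau, h2)
        ch <- chol(cov)
        plogis(t(ch) %*% matrix(rnorm(m * k), m, k))
      }
    }
    phi <- draw_phi()
    if (min_separation > 0 && k > 1) {
      ok <- function(p) {
        d <- as.matrix(stats::dist(t(p), method = "manhattan")) / m
        min(d[upper.tri(d)]) >= min_separation
      }
      tries <- 0L
      while (!ok(phi)) {
        tries <- tries + 1L
        if (tries > 5000L) {
          abort("Could not achieve `min_separation`; lower it.")
        }
        phi <- draw_phi()
      }
    }

    labels <- sample.int(k, n, replace = TRUE, prob = w)
    purity <- runif(m, purity_range[1L], purity_range[2L])
    cn_levels <- as.integer(names(cn_probs))
    cn_mut <- sample(cn_levels, n, replace = TRUE, prob = cn_probs)
    cn <- matrix(cn_mut, n, m)          # no sub-clonal CNV: constant in time
    mult_mut <- vapply(cn_mut, function(d) sample.int(d, 1L), integer(1))
    mult <- matrix(mult_mut, n, m)

    depth <- matrix(pmax(rnbinom(n * m, size = depth_size, mu = depth_mean),
                         10L), n, m)
    zeta <- matrix(clonal_vaf_coefficient(rep(purity, each = n), cn, mult),
                   n, m)
    theta <- zeta * matrix(phi[cbind(rep(seq_len(m), each = n),
                                     rep(labels, m))], n, m)
    theta <- clip01(theta)
    alt <- if (family == "binomial") {
      matrix(rbinom(n * m, size = depth, prob = theta), n, m)
    } else {
      p <- matrix(rbeta(n * m, precision * theta, precision * (1 - theta)),
                  n, m)
      matrix(rbinom(n * m, size = depth, prob = clip01(p)), n, m)
    }

    mut_ids <- sprintf("m%03d", seq_len(n))
    sample_ids <- sprintf("s%02d", seq_len(m))
    df <- tibble::tibble(
      mutation_id = rep(mut_ids, m),
      sample_id = rep(sample_ids, each = n),
      alt_reads = as.vector(alt),
      total_reads = as.vector(depth),
      total_cn = as.vector(cn),
      purity = rep(purity, each = n),
      time_raw = rep(t_raw, each = n)
    )
    if (emit_multiplicity) df$multiplicity <- as.vector(mult)
    truth <- list(
      labels = setNames(labels, mut_ids),
      phi = phi, weights = w, purity = purity,
      multiplicity = mult_mut, copy_number = cn_mut,
      precision = if (family == "betabinomial") precision else Inf,
      times = tt, kernel = kernel, h2 = h2, tau = tau, prior = prior
    )
    structure(list(data = as_mutation_table(df), truth = truth),
              class = "clone_sim")
  })
}

#' @export
print.clone_sim <- function(x, ...) {
  cat("<clone_sim>",
      length(unique(x$data$mutation_id)), "mutations x",
      nrow(sample_info(x$data)), "samples,",
      length(x$truth$weights), "true clusters\n")
  invisible(x)
}

#' Simulation benchmark over a grid of dataset shapes
#'
#' For each combination of samples (M), mutations (N) and true clusters
#' (K) and each replicate: simulates a dataset, fits each requested model,
#' and scores the hard clustering against the simulated truth with
#' ARI/AMI/FMI alongside the final ELBO. Individual fit failures are
#' recorded as rows with `status != "ok"` and the grid continues.
#'
#' @param n_samples,n_mutations,n_clusters Vectors of grid levels.
#' @param replicates Replicates per grid cell.
#' @param models Character vector of model names to fit.
#' @param sim_args Named list of extra arguments for [simulate_clones()].
#' @param fit_args Named list of extra arguments for [clone_fit()].
#' @param min_weight Pruning threshold used when counting clusters.
#' @param seed Base seed; each (cell, replicate) derives its own.
#' @return A tidy tibble with one row per (cell, replicate, model):
#'   configuration columns, `status`, `ari`, `ami`, `fmi`, `elbo`,
#'   `elbo_se`, `n_clusters_found`.
#' @export
benchmark_grid <- function(n_samples = c(3L, 6L, 12L),
                           n_mutations = c(25L, 50L, 100L),
                           n_clusters = c(2L, 4L, 8L),
                           replicates = 1L,
                           models = c("Flat", "GP0-Mat32"),
                           sim_args = list(),
                           fit_args = list(),
                           min_weight = 0.02,
                           seed = 1L) {
  grid <- tidyr::expand_grid(
    n_samples = n_samples, n_mutations = n_mutations,
    n_clusters = n_clusters, replicate = seq_len(replicates)
  )
  purrr::pmap_dfr(grid, function(n_samples, n_mutations, n_clusters,
                                 replicate) {
    cell_seed <- (seed + 7919L * n_samples + 104729L * n_mutations +
                    1299709L * n_clusters + 15485863L * replicate) %%
      .Machine$integer.max
    sim <- do.call(simulate_clones, c(list(
      n_mutations = n_mutations, n_samples = n_samples,
      n_clusters = n_clusters, seed = cell_seed
    ), sim_args))
    purrr::map_dfr(models, function(model) {
      base <- tibble::tibble(
        n_samples = n_samples, n_mutations = n_mutations,
        n_clusters = n_clusters, replicate = replicate,
        model = model, seed = cell_seed
      )
      res <- tryCatch({
        fit <- suppressWarnings(do.call(clone_fit, c(list(
          data = sim$data, model = model, seed = cell_seed
        ), fit_args)))
        mem <- membership_probabilities(fit)
        labels <- hard_assignment(mem)
        truth <- sim$truth$labels[rownames(mem)]
        kept <- prune_clusters(fit, min_weight = min_weight,
                               membership = mem)
        dplyr::mutate(base, status = "ok",
                      ari = adjusted_rand_index(labels, truth),
                      ami = adjusted_mutual_information(labels, truth),
                      fmi = fowlkes_mallows(labels, truth),
                      elbo = fit$final_elbo, elbo_se = fit$final_elbo_se,
                      n_clusters_found = length(kept))
      }, error = function(e) {
        dplyr::mutate(base, status = conditionMessage(e),
                      ari = NA_real_, ami = NA_real_, fmi = NA_real_,
                      elbo = NA_real_, elbo_se = NA_real_,
                      n_clusters_found = NA_integer_)
      })
      res
    })
  })
}
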