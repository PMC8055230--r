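#' Posterior cluster-membership probabilities
#'
#' For each stored posterior draw, the probability that mutation `i` belongs
#' to cluster `k` is proportional to
#' \eqn{w_k \prod_j p(r_{ij} \mid R_{ij}, f(\phi_{jk}))} (Bayes rule on the
#' marginalized assignment); the per-draw matrices are summarized by their
#' elementwise median and renormalized so rows sum to 1.
#'
#' @param fit A `clone_fit`.
#' @param ndraws Number of stored draws to use (default: all).
#' @return An `N x K` matrix of probabilities with mutation ids as row
#'   names; rows sum to 1.
#' @export
membership_probabilities <- function(fit, ndraws = NULL) {
  arrays <- table_arrays(fit$data)
  n <- arrays$n; m <- arrays$m
  k <- fit$spec$truncation
  s_all <- nrow(fit$draws$weights)
  s_use <- if (is.null(ndraws)) s_all else min(ndraws, s_all)
  jt <- rep(seq_len(m), k)
  r_t <- arrays$alt[, jt, drop = FALSE]
  R_t <- arrays$total[, jt, drop = FALSE]
  zeta_t <- fit$zeta[, jt, drop = FALSE]
  group <- matrix(0, m * k, k)
  group[cbind(seq_len(m * k), rep(seq_len(k), each = m))] <- 1
  betabin <- fit$spec$family == "betabinomial"
  eps_err <- fit$spec$error_rate
  clip <- 1e-9

  acc <- array(0, c(n, k, s_use))
  for (s in seq_len(s_use)) {
    phi <- matrix(fit$draws$phi[s, , ], m, k)
    theta <- sweep(zeta_t, 2L, as.vector(phi), "*")
    if (!is.null(eps_err)) theta <- error_adjusted_theta(theta, eps_err)
    theta <- clip01(theta, clip)
    if (betabin) {
      v_t <- matrix(fit$draws$precision[s, jt], n, m * k, byrow = TRUE)
      a <- v_t * theta; b <- v_t * (1 - theta)
      ll_t <- lbeta(r_t + a, R_t - r_t + b) - lbeta(a, b)
    } else {
      ll_t <- r_t * log(theta) + (R_t - r_t) * log1p(-theta)
    }
    lp <- sweep(ll_t %*% group, 2L, log(pmax(fit$draws$weights[s, ], 1e-300)),
                "+")
    acc[, , s] <- exp(lp - row_logsumexp(lp))
  }
  med <- apply(acc, c(1, 2), median)
  med <- med / rowSums(med)
  rownames(med) <- arrays$mutations
  colnames(med) <- paste0("cluster_", seq_len(k))
  med
}

#' Hard cluster assignment from membership probabilities
#'
#' Assigns each mutation to the cluster with the highest (median) membership
#' probability. Exact ties are broken toward the cluster with the larger
#' mixture weight; by default columns are assumed ordered by decreasing
#' weight (as produced by [clone_fit()]), so the first maximum wins.
#'
#' @param membership `N x K` probability matrix (rows sum to 1).
#' @param weights Optional cluster weights used for tie-breaking.
#' @return Integer vector of cluster indices, named by mutation when the
#'   matrix has row names.
#' @export
hard_assignment <- function(membership, weights = NULL) {
  membership <- as.matrix(membership)
  if (is.null(weights)) weights <- rev(seq_len(ncol(membership)))
  labels <- apply(membership, 1L, function(p) {
    cand <- which(p == max(p))
    cand[which.max(weights[cand])]
  })
  as.integer(labels) |> setNames(rownames(membership))
}

#' Prune negligible mixture components
#'
#' The truncated Dirichlet process typically leaves most of its `K`
#' components empty; a cluster is kept when its posterior median weight
#' reaches `min_weight` or when at least one mutation is hard-assigned to
#' it.
#'
#' @param fit A `clone_fit`.
#' @param min_weight Weight threshold (default 0.02).
#' @param membership Optional precomputed membership matrix (to avoid
#'   recomputation).
#' @return Sorted integer vector of kept cluster indices.
#' @export
prune_clusters <- function(fit, min_weight = 0.02, membership = NULL) {
  w_med <- apply(fit$draws$weights, 2L, median)
  if (is.null(membership)) membership <- membership_probabilities(fit)
  labels <- hard_assignment(membership, w_med)
  sort(union(which(w_med >= min_weight), unique(labels)))
}

safe_chol <- function(x) {
  j <- 1e-8 * max(diag(x), 1e-12)
  chol(x + j * diag(nrow(x)))
}

#' Continuous CCF trajectory reconstruction
#'
#' For Gaussian-process families, draws each cluster's latent logit-CCF
#' function on a dense time grid from the GP conditional given its values
#' at the sample times (zero prior mean), per posterior draw, and maps
#' through the inverse logit; the separable multi-output families condition
#' with the shared temporal kernel and retain the between-cluster
#' covariance. For the `Flat` model, which is not informative between
#' sample times, draws are connected by straight segments (interpolation,
#' not inference; the `type` attribute is `"interpolated"`).
#'
#' @param fit A `clone_fit`.
#' @param grid Time points in `[0, 1]` (values outside trigger an
#'   extrapolation warning but are still computed).
#' @param ndraws Posterior draws to propagate (default 500).
#' @param level Credible level for the bands (default 0.95).
#' @param seed Seed for the conditional draws, so summaries are
#'   deterministic given the stored posterior draws.
#' @return A tibble with `cluster`, `time`, `ccf` (posterior median), and
#'   `ccf_lo`/`ccf_hi` band columns; attribute `type` is `"gp"` or
#'   `"interpolated"`.
#' @export
predict_trajectories <- function(fit, grid = seq(0, 1, length.out = 101),
                                 ndraws = 500L, level = 0.95, seed = 1L) {
  if (any(grid < 0 | grid > 1)) {
    warn("Grid extends outside [0, 1]: extrapolating beyond the samples.")
  }
  arrays <- table_arrays(fit$data)
  times <- arrays$times
  k <- fit$spec$truncation
  s_all <- dim(fit$draws$phi)[1L]
  s_use <- min(ndraws, s_all)
  ng <- length(grid)
  fam <- fit$spec$prior_family
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  jit <- fit$config$jitter

  curves <- array(NA_real_, c(s_use, ng, k))
  curves <- with_seed(seed, {
  if (fam == "Flat") {
    for (s in seq_len(s_use)) {
      psi <- qlogis(matrix(fit$draws$phi[s, , ], length(times), k))
      for (j in seq_len(k)) {
        curves[s, , j] <- if (length(times) == 1L) {
          rep(psi[1L, j], ng)
        } else {
          approx(times, psi[, j], xout = grid, rule = 2)$y
        }
      }
    }
  } else {
    kind <- fit$spec$kernel
    for (s in seq_len(s_use)) {
      psi <- qlogis(matrix(fit$draws$phi[s, , ], length(times), k))
      h2 <- fit$draws$h2[s, ]
      tau <- fit$draws$tau[s, ]
      if (fam == "GP3") {
        for (j in seq_len(k)) {
          cond <- gp_conditional(times, grid, kind, tau[j], jit)
          mean_j <- cond$A %*% psi[, j]
          Tc <- h2[j] * cond$T
          curves[s, , j] <- mean_j +
            t(safe_chol(Tc)) %*% rnorm(ng)
        }
      } else {
        cond <- gp_conditional(times, grid, kind, tau[1L], jit)
        mean_mat <- cond$A %*% psi               # ng x k
        sigma <- if (fam == "GP0") {
          diag(h2[1L], k)
        } else if (fam == "GP1") {
          diag(h2, nrow = k)
        } else {
          C <- matrix(fit$draws$corr[s, , ], k, k)
          diag(sqrt(h2), nrow = k) %*% C %*% diag(sqrt(h2), nrow = k)
        }
        LT <- t(safe_chol(cond$T))
        LS <- t(safe_chol(sigma))
        curves[s, , ] <- mean_mat +
          LT %*% matrix(rnorm(ng * k), ng, k) %*% t(LS)
      }
    }
  }
  curves
  })
  phi_curves <- plogis(curves)
  out <- purrr::map_dfr(seq_len(k), function(j) {
    tibble::tibble(
      cluster = j,
      time = grid,
      ccf = apply(phi_curves[, , j, drop = FALSE], 2L, median),
      ccf_lo = apply(phi_curves[, , j, drop = FALSE], 2L, quantile, qs[1L]),
      ccf_hi = apply(phi_curves[, , j, drop = FALSE], 2L, quantile, qs[2L])
    )
  })
  attr(out, "type") <- if (fam == "Flat") "interpolated" else "gp"
  out
}

# temporal GP conditional operator: A maps psi at sample times to the
# conditional mean on the grid; T is the unit-amplitude conditional
# covariance (shared across clusters for separable kernels)
gp_conditional <- function(times, grid, kind, tau, jitter = 1e-6) {
  m <- length(times)
  G <- kernel_g(kind, tau, abs(outer(times, times, "-"))) + jitter * diag(m)
  gs <- kernel_g(kind, tau, abs(outer(grid, times, "-")))
  gg <- kernel_g(kind, tau, abs(outer(grid, grid, "-")))
  A <- gs %*% chol2inv(chol(G))
  list(A = A, T = gg - A %*% t(gs))
}

#' Posterior predictive density of observed VAF in one sample
#'
#' Mixture, over clusters and posterior draws, of the observation density
#' of the VAF at the sample's median read depth and median clonal
#' coefficient \eqn{\zeta}. The discrete read-count pmf is extended to
#' non-integer counts through the gamma function so the returned curve is
#' smooth; it integrates to 1 (trapezoid rule) up to discretization error.
#'
#' @param fit A `clone_fit`.
#' @param sample_id Sample to evaluate.
#' @param vaf_grid Grid of VAF values in `[0, 1]`.
#' @param ndraws Posterior draws to average over (default 200).
#' @return A tibble with `vaf` and `density` columns.
#' @export
posterior_predictive_vaf <- function(fit, sample_id,
                                     vaf_grid = seq(0, 1, length.out = 401),
                                     ndraws = 200L) {
  samples <- sample_info(fit$data)
  j <- match(sample_id, samples$sample_id)
  if (is.na(j)) abort(paste0("Unknown sample_id `", sample_id, "`."))
  arrays <- table_arrays(fit$data)
  depth <- round(median(arrays$total[, j]))
  zeta_j <- median(fit$zeta[, j])
  s_use <- min(ndraws, nrow(fit$draws$weights))
  k <- fit$spec$truncation
  betabin <- fit$spec$family == "betabinomial"
  eps_err <- fit$spec$error_rate

  r <- vaf_grid * depth
  lnorm <- lgamma(depth + 1) - lgamma(r + 1) - lgamma(depth - r + 1)
  dens <- numeric(length(vaf_grid))
  for (s in seq_len(s_use)) {
    w <- fit$draws$weights[s, ]
    phi_j <- fit$draws$phi[s, j, ]
    theta <- clip01(zeta_j * phi_j)
    if (!is.null(eps_err)) theta <- error_adjusted_theta(theta, eps_err)
    for (kk in seq_len(k)) {
      if (w[kk] < 1e-12) next
      lpdf <- if (betabin) {
        v <- fit$draws$precision[s, j]
        a <- v * theta[kk]; b <- v * (1 - theta[kk])
        lnorm + lbeta(r + a, depth - r + b) - lbeta(a, b)
      } else {
        lnorm + r * log(theta[kk]) + (depth - r) * log1p(-theta[kk])
      }
      dens <- dens + w[kk] * exp(lpdf) * depth
    }
  }
  tibble::tibble(vaf = vaf_grid, density = dens / s_use)
}

#' Full post-processing report of a fitted model
#'
#' Bundles pruning, soft/hard assignment and trajectory reconstruction.
#' Cluster weights are reported both as posterior medians of the mixture
#' weights (renormalized over kept clusters) and as empirical hard
#' assignment fractions.
#'
#' @param fit A `clone_fit`.
#' @param min_weight Pruning threshold; see [prune_clusters()].
#' @param grid Dense time grid for [predict_trajectories()]; `NULL` skips
#'   trajectory reconstruction.
#' @param predictive Also compute [posterior_predictive_vaf()] per sample.
#' @return A `cluster_report` list: `kept_clusters`, `weights_raw`
#'   (posterior median weights), `weights` (renormalized over kept),
#'   `assign_frac`, `membership` (rows renormalized over kept clusters),
#'   `hard_labels`, `trajectories`, `predictive`.
#' @export
cluster_report <- function(fit, min_weight = 0.02,
                           grid = seq(0, 1, length.out = 101),
                           predictive = FALSE) {
  membership <- membership_probabilities(fit)
  w_med <- apply(fit$draws$weights, 2L, median)
  labels <- hard_assignment(membership, w_med)
  kept <- prune_clusters(fit, min_weight = min_weight,
                         membership = membership)
  mem_kept <- membership[, kept, drop = FALSE]
  mem_kept <- mem_kept / rowSums(mem_kept)
  n <- nrow(membership)
  traj <- if (is.null(grid)) NULL else {
    tr <- predict_trajectories(fit, grid = grid)
    tr[tr$cluster %in% kept, ]
  }
  pred <- if (predictive) {
    ids <- sample_info(fit$data)$sample_id
    setNames(lapply(ids, function(sid) {
      posterior_predictive_vaf(fit, sid)
    }), ids)
  } else NULL
  structure(list(
    kept_clusters = kept,
    weights_raw = w_med[kept],
    weights = w_med[kept] / sum(w_med[kept]),
    assign_frac = vapply(kept, function(kk) mean(labels == kk), numeric(1)),
    membership = mem_kept,
    hard_labels = labels,
    trajectories = traj,
    predictive = pred
  ), class = "cluster_report")
}

#' Write fit results to disk
#'
#' Writes three artifacts into `out_dir`: `assignments.csv` (per-mutation
#' hard label and membership probabilities over kept clusters),
#' `trajectories.csv` (per-cluster CCF median and band on the dense grid)
#' and `run_metadata.json` (model, seed, final ELBO, iterations, package
#' version).
#'
#' @param fit A `clone_fit`.
#' @param report A `cluster_report`; computed with defaults when `NULL`.
#' @param out_dir Output directory, created if missing.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fit_report <- function(fit, report = NULL, out_dir) {
  if (is.null(report)) report <- cluster_report(fit)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(paste0("Cannot create `", out_dir, "`."))
  assign_path <- file.path(out_dir, "assignments.csv")
  traj_path <- file.path(out_dir, "trajectories.csv")
  meta_path <- file.path(out_dir, "run_metadata.json")

  assignments <- tibble::tibble(
    mutation_id = rownames(report$membership),
    cluster = as.integer(report$hard_labels[rownames(report$membership)])
  )
  probs <- tibble::as_tibble(report$membership)
  names(probs) <- paste0("p_cluster_", report$kept_clusters)
  readr::write_csv(dplyr::bind_cols(assignments, probs), assign_path,
                   progress = FALSE)

  traj <- report$trajectories
  if (is.null(traj)) {
    traj <- tibble::tibble(cluster = integer(), time = numeric(),
                           ccf = numeric(), ccf_lo = numeric(),
                           ccf_hi = numeric())
  }
  readr::write_csv(traj, traj_path, progress = FALSE)

  meta <- list(
    model = fit$spec$name,
    prior_family = fit$spec$prior_family,
    kernel = fit$spec$kernel,
    truncation = fit$spec$truncation,
    observation_family = fit$spec$family,
    shared_dispersion = fit$spec$shared_dispersion,
    error_rate = fit$spec$error_rate,
    lkj_eta = fit$spec$lkj_eta,
    seed = fit$seed,
    final_elbo = fit$final_elbo,
    final_elbo_se = fit$final_elbo_se,
    iterations = fit$iterations,
    converged = fit$converged,
    kept_clusters = report$kept_clusters,
    package_version = as.character(utils::packageVersion("clonetrend"))
  )
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(assignments = assign_path, trajectories = traj_path,
              metadata = meta_path))
}
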