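#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_point
#'   geom_histogram labs theme_minimal scale_y_continuous
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot reconstructed cluster CCF trajectories
#'
#' Posterior median CCF of each kept cluster as a function of normalized
#' time with its credible band; sample collection times are marked by the
#' points. For `Flat` fits the lines are straight interpolations between
#' samples and carry no information between them.
#'
#' @param fit A `clone_fit`.
#' @param min_weight Pruning threshold.
#' @param grid Dense time grid.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(fit, min_weight = 0.02,
                              grid = seq(0, 1, length.out = 101)) {
  traj <- predict_trajectories(fit, grid = grid)
  kept <- prune_clusters(fit, min_weight = min_weight)
  traj <- traj[traj$cluster %in% kept, ]
  traj$cluster <- factor(traj$cluster)
  samples <- sample_info(fit$data)
  at_samples <- tidy(fit, min_weight = min_weight)
  at_samples$cluster <- factor(at_samples$cluster)
  ggplot(traj, aes(x = .data$time, y = .data$ccf,
                   colour = .data$cluster, fill = .data$cluster)) +
    geom_ribbon(aes(ymin = .data$ccf_lo, ymax = .data$ccf_hi),
                alpha = 0.2, colour = NA) +
    geom_line() +
    geom_point(data = at_samples) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "normalized time", y = "cancer cell fraction",
         title = paste0(fit$spec$name, " cluster trajectories"),
         subtitle = if (attr(traj, "type") == "interpolated")
           "Flat model: straight interpolation between samples" else NULL) +
    theme_minimal()
}

#' @rdname plot_trajectories
#' @param object A `clone_fit` (autoplot interface).
#' @param ... Forwarded to [plot_trajectories()].
#' @method autoplot clone_fit
#' @export
autoplot.clone_fit <- function(object, ...) plot_trajectories(object, ...)

#' Observed VAFs by sample, coloured by hard cluster assignment
#'
#' @param fit A `clone_fit`.
#' @return A ggplot object.
#' @export
plot_vaf_clusters <- function(fit) {
  aug <- augment(fit)
  aug$vaf <- aug$alt_reads / aug$total_reads
  aug$.cluster <- factor(aug$.cluster)
  ggplot(aug, aes(x = .data$time, y = .data$vaf, colour = .data$.cluster,
                  group = .data$mutation_id)) +
    geom_line(alpha = 0.3) +
    geom_point() +
    labs(x = "normalized time", y = "observed VAF", colour = "cluster") +
    theme_minimal()
}

#' ELBO optimization trace
#'
#' @param fit A `clone_fit`.
#' @param window Moving-average window for the smoothed overlay.
#' @return A ggplot object.
#' @export
plot_elbo <- function(fit, window = 100L) {
  tr <- tibble::tibble(iteration = seq_along(fit$elbo_trace),
                       elbo = fit$elbo_trace)
  tr$smooth <- stats::filter(tr$elbo, rep(1 / window, window), sides = 1)
  ggplot(tr, aes(x = .data$iteration, y = .data$elbo)) +
    geom_line(alpha = 0.3) +
    geom_line(aes(y = .data$smooth), na.rm = TRUE, colour = "red") +
    labs(x = "iteration", y = "ELBO estimate") +
    theme_minimal()
}

#' Posterior predictive VAF density over the observed histogram
#'
#' @param fit A `clone_fit`.
#' @param sample_id Sample to show; defaults to the first.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_predictive <- function(fit, sample_id = NULL, bins = 30L) {
  samples <- sample_info(fit$data)
  sample_id <- sample_id %||% samples$sample_id[1L]
  obs <- tibble::as_tibble(fit$data) |>
    dplyr::filter(.data$sample_id == !!sample_id) |>
    dplyr::mutate(vaf = .data$alt_reads / .data$total_reads)
  pred <- posterior_predictive_vaf(fit, sample_id)
  ggplot(obs, aes(x = .data$vaf)) +
    geom_histogram(aes(y = ggplot2::after_stat(density)), bins = bins,
                   fill = "grey80", colour = "grey50") +
    geom_line(data = pred, aes(x = .data$vaf, y = .data$density),
              colour = "red") +
    labs(x = "observed VAF", y = "density",
         title = paste("Posterior predictive VAF,", sample_id)) +
    theme_minimal()
}
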