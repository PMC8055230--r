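model_families <- c("Flat", "GP0", "GP1", "GP2", "GP3")

#' Registry of candidate model configurations
#'
#' Enumerates the full model space: the `Flat` baseline (uniform priors on
#' per-sample cluster CCFs, ignoring sample timing) plus each
#' Gaussian-process prior family (`GP0`-`GP3`) crossed with each of the four
#' kernels (`Exp`, `Mat32`, `Mat52`, `ExpQ`) — 17 configurations in total.
#'
#' @return A tibble with columns `name` (e.g. `"GP0-Mat32"`), `family` and
#'   `kernel` (`NA` for `Flat`), in a stable order.
#' @export
clone_models <- function() {
  gp <- tidyr::expand_grid(
    family = model_families[-1],
    kernel = kernel_kinds
  )
  dplyr::bind_rows(
    tibble::tibble(family = "Flat", kernel = NA_character_),
    gp
  ) |>
    dplyr::mutate(
      name = ifelse(is.na(.data$kernel), .data$family,
                    paste(.data$family, .data$kernel, sep = "-")),
      .before = 1L
    )
}

#' Build a model specification
#'
#' @param name Model name from [clone_models()], e.g. `"Flat"` or
#'   `"GP0-Mat32"`.
#' @param truncation Mixture truncation level `K` (default 20): the number
#'   of components retained from the stick-breaking representation of the
#'   Dirichlet process.
#' @param family Observation family: `"betabinomial"` (default) or
#'   `"binomial"`.
#' @param shared_dispersion Share a single beta-binomial precision across
#'   samples instead of one per sample.
#' @param error_rate Optional fixed sequencing error rate (see
#'   [error_adjusted_theta()]); `NULL` disables the adjustment.
#' @param lkj_eta LKJ concentration for the `GP2` between-cluster
#'   correlation prior (default 2, favouring near-identity correlation).
#' @return A `model_spec` list.
#' @export
model_spec <- function(name, truncation = 20L,
                       family = c("betabinomial", "binomial"),
                       shared_dispersion = FALSE, error_rate = NULL,
                       lkj_eta = 2) {
  registry <- clone_models()
  hit <- registry[registry$name == name, ]
  if (nrow(hit) != 1L) {
    abort(paste0("Unknown model `", name, "`. Valid models: ",
                 paste(registry$name, collapse = ", ")))
  }
  family <- match.arg(family)
  if (truncation < 2) abort("`truncation` must be at least 2.")
  if (!is.null(error_rate) && (error_rate < 0 || error_rate >= 0.5)) {
    abort("`error_rate` must lie in [0, 0.5).")
  }
  structure(list(
    name = name,
    prior_family = hit$family,
    kernel = hit$kernel,
    truncation = as.integer(truncation),
    family = family,
    shared_dispersion = isTRUE(shared_dispersion),
    error_rate = error_rate,
    lkj_eta = lkj_eta
  ), class = "model_spec")
}

#' Free-parameter count of a fitted model configuration
#'
#' With `L` clusters carrying non-zero weight and `M` samples, the `Flat`
#' model has \eqn{n_p = L + M L} free parameters (weights plus per-sample
#' cluster CCFs), counting one location per latent scalar. The
#' Gaussian-process families add their kernel hyper-parameters:
#' `GP0` \eqn{n_p + 2}, `GP1` \eqn{n_p + L + 1},
#' `GP2` \eqn{n_p + L + 1 + L(L-1)/2}, `GP3` \eqn{n_p + 2L}.
#'
#' @param family Prior family name (or a full model name such as
#'   `"GP1-Exp"`, whose kernel suffix is ignored).
#' @param n_clusters Number of clusters with non-zero weights, `L`.
#' @param n_samples Number of samples, `M`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(family, n_clusters, n_samples) {
  family <- strsplit(family, "-", fixed = TRUE)[[1L]][1L]
  family <- match.arg(family, model_families)
  L <- as.integer(n_clusters); M <- as.integer(n_samples)
  if (L < 1 || M < 1) abort("`n_clusters` and `n_samples` must be >= 1.")
  np <- L + M * L
  as.integer(switch(family,
    Flat = np,
    GP0 = np + 2L,
    GP1 = np + L + 1L,
    GP2 = np + L + 1L + L * (L - 1L) / 2L,
    GP3 = np + 2L * L
  ))
}
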