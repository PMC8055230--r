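#' Binomial log probability mass of alternative read counts
#'
#' @param r Alternative read count(s), `0 <= r <= R`.
#' @param R Total read count(s).
#' @param theta Expected VAF in `[0, 1]`.
#' @return Log pmf, vectorized; `theta = 0` with `r > 0` gives `-Inf`.
#' @export
binomial_logpmf <- function(r, R, theta) {
  stopifnot(all(r >= 0), all(r <= R))
  stats::dbinom(r, R, theta, log = TRUE)
}

#' Beta-binomial log probability mass of alternative read counts
#'
#' Read counts are modelled as \eqn{r \sim BBin(R, v\theta, v(1-\theta))},
#' an over-dispersed binomial whose mean matches `R * theta` and whose
#' precision `v` controls the extra-binomial variance; as
#' \eqn{v \to \infty} it converges to the binomial model.
#'
#' @inheritParams binomial_logpmf
#' @param v Positive precision parameter.
#' @return Log pmf, vectorized.
#' @export
betabinomial_logpmf <- function(r, R, theta, v) {
  stopifnot(all(r >= 0), all(r <= R))
  if (any(v <= 0)) abort("`v` must be positive.")
  if (any(theta <= 0 | theta >= 1)) {
    abort("`theta` must lie strictly inside (0, 1); clip boundary values.")
  }
  dims <- dim(r) %||% dim(R) %||% dim(theta)
  n <- max(length(r), length(R), length(theta), length(v))
  r <- rep_len(as.vector(r), n); R <- rep_len(as.vector(R), n)
  theta <- rep_len(as.vector(theta), n); v <- rep_len(as.vector(v), n)
  a <- v * theta
  b <- v * (1 - theta)
  out <- lchoose(R, r) + lbeta(r + a, R - r + b) - lbeta(a, b)
  # At very large shapes the lgamma differences above lose absolute
  # precision; switch to a series expansion of log Gamma(x+n) - log
  # Gamma(x) = n log x + S1/x - S2/(2 x^2) + O(n^4/x^3), exact enough for
  # the binomial limit.
  big <- pmin(a, b) > 1e6
  if (any(big)) {
    lgr <- function(x, k) {
      s1 <- k * (k - 1) / 2
      s2 <- (k - 1) * k * (2 * k - 1) / 6
      k * log(x) + s1 / x - s2 / (2 * x^2)
    }
    out[big] <- lchoose(R[big], r[big]) + lgr(a[big], r[big]) +
      lgr(b[big], R[big] - r[big]) - lgr(v[big], R[big])
  }
  if (!is.null(dims) && length(out) == prod(dims)) dim(out) <- dims
  out
}

#' Sequencing-error adjustment of the expected VAF
#'
#' Symmetric misread mixing: a true variant read is observed as reference
#' with probability `eps` and vice versa, so the expected observed VAF
#' becomes \eqn{\epsilon(1-\theta) + (1-\epsilon)\theta}, mapping `[0, 1]`
#' into `[eps, 1-eps]`. This is an optional stand-in form for an explicit
#' sequencing-error observation model; it is the identity when `eps = 0`.
#'
#' @param theta Expected VAF(s).
#' @param eps Error rate in `[0, 0.5)`.
#' @return Adjusted VAF(s).
#' @export
error_adjusted_theta <- function(theta, eps) {
  if (any(eps < 0 | eps >= 0.5)) abort("`eps` must lie in [0, 0.5).")
  eps + (1 - 2 * eps) * theta
}

# observation log-pmf dispatcher on N x M matrices for one cluster column
obs_logpmf_matrix <- function(r, R, theta, family, v = NULL) {
  if (family == "binomial") {
    binomial_logpmf(r, R, theta)
  } else {
    betabinomial_logpmf(r, R, theta, rep(v, each = nrow(r)))
  }
}

#' Marginalized mixture log-likelihood of a mutation table
#'
#' Sums, over mutations, the log of the weight-mixture of per-cluster
#' likelihoods, with the discrete cluster assignment marginalized out:
#' \deqn{\sum_i \log \sum_k w_k \exp\Big(\sum_j \log p(r_{ij} \mid R_{ij},
#'   f(\phi_{jk}))\Big)}
#' where \eqn{f} maps CCF to expected VAF through each locus' clonal
#' coefficient \eqn{\zeta_{ij}} (and optionally a sequencing-error
#' adjustment). Computed with log-sum-exp stabilization.
#'
#' @param tbl A `mutation_tbl`; unset multiplicities are resolved first.
#' @param phi `M x K` matrix of per-sample cluster CCFs in `(0, 1)`.
#' @param weights Simplex of `K` mixture weights.
#' @param family `"betabinomial"` (default) or `"binomial"`.
#' @param precision Per-sample beta-binomial precision vector (length `M`
#'   or 1, recycled); required for the beta-binomial family.
#' @param error_rate Optional sequencing error rate; `NULL` to disable.
#' @param theta_clip Expected VAFs are clipped to
#'   `[theta_clip, 1 - theta_clip]` before evaluation.
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(tbl, phi, weights,
                           family = c("betabinomial", "binomial"),
                           precision = NULL, error_rate = NULL,
                           theta_clip = 1e-9) {
  family <- match.arg(family)
  arr <- table_arrays(resolve_multiplicity(tbl))
  phi <- as.matrix(phi)
  if (nrow(phi) != arr$m) abort("`phi` must have one row per sample.")
  k <- ncol(phi)
  if (length(weights) != k) abort("`weights` length must match ncol(phi).")
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0)) {
    abort("`weights` must be a simplex.")
  }
  if (family == "betabinomial") {
    if (is.null(precision)) abort("Beta-binomial requires `precision`.")
    precision <- rep(precision, length.out = arr$m)
  }
  zeta <- matrix(clonal_vaf_coefficient(
    rep(arr$purity, each = arr$n), arr$cn, arr$multiplicity
  ), arr$n, arr$m)
  ll <- matrix(0, arr$n, k)
  for (j in seq_len(k)) {
    theta <- zeta * matrix(phi[, j], arr$n, arr$m, byrow = TRUE)
    if (!is.null(error_rate)) theta <- error_adjusted_theta(theta, error_rate)
    theta <- clip01(theta, theta_clip)
    ll[, j] <- rowSums(obs_logpmf_matrix(arr$alt, arr$total, theta,
                                         family, precision))
  }
  sum(row_logsumexp(sweep(ll, 2L, log(weights), "+")))
}
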