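#' Truncated stick-breaking weights
#'
#' Maps stick fractions \eqn{u_1,\dots,u_K} to Dirichlet-process mixture
#' weights \eqn{w_1 = u_1}, \eqn{w_k = u_k \prod_{l<k}(1-u_l)}. The
#' truncation is closed by treating the last fraction as 1, so the final
#' weight absorbs the residual mass \eqn{\prod_{l<K}(1-u_l)} and the result
#' is an exact simplex.
#'
#' @param sticks Numeric vector of stick fractions in `(0, 1)`; the last
#'   element is ignored (treated as 1). A vector of length `K - 1` is also
#'   accepted and produces `K` weights.
#' @param k Number of weights to produce; defaults to `length(sticks)` when
#'   `sticks` already includes the final (ignored) fraction, otherwise
#'   `length(sticks) + 1`.
#' @return Numeric simplex of length `k`.
#' @export
stick_breaking <- function(sticks, k = NULL) {
  if (length(sticks) == 0 && is.null(k)) abort("Empty stick vector.")
  if (is.null(k)) k <- length(sticks)
  if (k == 1L) return(1)
  u <- sticks[seq_len(k - 1L)]
  if (anyNA(u) || any(u <= 0 | u >= 1)) {
    abort("Stick fractions must lie strictly inside (0, 1).")
  }
  log_remain <- c(0, cumsum(log1p(-u)))          # log prod_{l<k} (1-u_l)
  w <- exp(log_remain[seq_len(k - 1L)]) * u
  c(w, max(1 - sum(w), 0))
}

#' Log prior density of the Dirichlet-process concentration parameter
#'
#' The prior \eqn{p(\alpha) = (1+\alpha)^{-2}} arises from a uniform prior
#' on \eqn{1/(1+\alpha)}; it is proper on \eqn{(0,\infty)}, similar to a
#' standard exponential but heavier tailed.
#'
#' @param alpha Positive concentration value(s).
#' @return Log density, vectorized.
#' @export
alpha_log_prior <- function(alpha) {
  if (any(alpha <= 0)) abort("`alpha` must be positive.")
  -2 * log1p(alpha)
}

kernel_kinds <- c("Exp", "Mat32", "Mat52", "ExpQ")

#' Stationary temporal correlation kernels
#'
#' Evaluates the unit-amplitude correlation \eqn{g_\tau(\Delta t)} for the
#' four supported kernels, ordered by increasing smoothness:
#' \itemize{
#'   \item `Exp`: \eqn{\exp(-\tau |dt|)}
#'   \item `Mat32`: \eqn{(1 + \sqrt{3}\tau|dt|)\exp(-\sqrt{3}\tau|dt|)}
#'   \item `Mat52`: \eqn{(1 + \sqrt{5}\tau|dt| + 5\tau^2 dt^2/3)
#'     \exp(-\sqrt{5}\tau|dt|)}
#'   \item `ExpQ`: \eqn{\exp(-\tau\, dt^2/2)}
#' }
#' `tau` is an inverse (squared, for `ExpQ`) time-scale on the normalized
#' time axis.
#'
#' @param kind One of `"Exp"`, `"Mat32"`, `"Mat52"`, `"ExpQ"`.
#' @param tau Positive inverse time-scale parameter.
#' @param dt Time difference(s); only `|dt|` matters.
#' @return Correlation value(s) in `(0, 1]`.
#' @export
kernel_g <- function(kind = c("Exp", "Mat32", "Mat52", "ExpQ"), tau, dt) {
  kind <- match.arg(kind)
  if (any(tau <= 0)) abort("`tau` must be positive.")
  d <- abs(dt)
  switch(kind,
    Exp   = exp(-tau * d),
    Mat32 = (1 + sqrt(3) * tau * d) * exp(-sqrt(3) * tau * d),
    Mat52 = (1 + sqrt(5) * tau * d + 5 * tau^2 * d^2 / 3) *
            exp(-sqrt(5) * tau * d),
    ExpQ  = exp(-tau * d^2 / 2)
  )
}

# d g / d tau, needed for kernel hyper-parameter gradients
kernel_g_dtau <- function(kind, tau, dt) {
  d <- abs(dt)
  switch(kind,
    Exp   = -d * exp(-tau * d),
    Mat32 = -3 * tau * d^2 * exp(-sqrt(3) * tau * d),
    Mat52 = -(5 / 3) * tau * d^2 * (1 + sqrt(5) * tau * d) *
            exp(-sqrt(5) * tau * d),
    ExpQ  = -(d^2 / 2) * exp(-tau * d^2 / 2)
  )
}

#' Gaussian-process covariance matrix over sample times (single output)
#'
#' Builds the `M x M` covariance \eqn{h^2 g_\tau(t_j, t_{j'})} of a
#' logit-CCF trajectory at the sampling times, with a relative jitter
#' (`jitter * h2`) on the diagonal for numerical stability of the Cholesky
#' factorization.
#'
#' @param times Normalized sample times in `[0, 1]`.
#' @param kind Kernel kind; see [kernel_g()].
#' @param tau Inverse time-scale.
#' @param h2 Amplitude (marginal variance) \eqn{h^2}.
#' @param jitter Relative diagonal jitter; default `1e-6`.
#' @return Symmetric positive-definite matrix of size `length(times)`.
#' @export
gp_covariance <- function(times, kind, tau, h2 = 1, jitter = 1e-6) {
  if (h2 <= 0) abort("`h2` must be positive.")
  dt <- abs(outer(times, times, "-"))
  h2 * (kernel_g(kind, tau, dt) + jitter * diag(length(times)))
}

#' Multi-output covariance over time points and clusters
#'
#' Covariance of `vec(Psi)` for the matrix of logit-CCF values
#' `Psi` (`M` times x `K` clusters, columns stacked):
#' \itemize{
#'   \item `GP1`: separable \eqn{\Sigma_K \otimes G_M} with
#'     \eqn{\Sigma_K = diag(h_1^2,\dots,h_K^2)} and one shared kernel
#'     \eqn{G_M = g_\tau}.
#'   \item `GP2`: as `GP1` but \eqn{\Sigma_K = D C D}, `D = diag(h_k)`,
#'     with a full correlation matrix `C` between clusters.
#'   \item `GP3`: block-diagonal, block `k` equal to
#'     \eqn{h_k^2 g_{\tau_k}} with cluster-specific time-scales.
#' }
#'
#' @param times Normalized sample times (length `M`).
#' @param variant `"GP1"`, `"GP2"` or `"GP3"`.
#' @param kind Kernel kind.
#' @param h2 Vector of per-cluster amplitudes \eqn{h_k^2} (length `K`).
#' @param tau Shared inverse time-scale (`GP1`/`GP2`) or per-cluster vector
#'   (`GP3`).
#' @param corr `K x K` correlation matrix (`GP2` only; default identity).
#' @param jitter Relative diagonal jitter applied to the temporal factor.
#' @return `MK x MK` symmetric positive-definite covariance matrix.
#' @export
gp_covariance_multi <- function(times, variant = c("GP1", "GP2", "GP3"),
                                kind, h2, tau, corr = NULL, jitter = 1e-6) {
  variant <- match.arg(variant)
  m <- length(times)
  k <- length(h2)
  if (any(h2 <= 0)) abort("`h2` must be positive.")
  if (variant == "GP3") {
    if (length(tau) != k) abort("GP3 needs one `tau` per cluster.")
    blocks <- lapply(seq_len(k), function(j) {
      gp_covariance(times, kind, tau[j], h2[j], jitter)
    })
    out <- matrix(0, m * k, m * k)
    for (j in seq_len(k)) {
      idx <- (j - 1L) * m + seq_len(m)
      out[idx, idx] <- blocks[[j]]
    }
    return(out)
  }
  if (length(tau) != 1L) abort(paste0(variant, " shares one `tau`."))
  g <- kernel_g(kind, tau, abs(outer(times, times, "-"))) +
    jitter * diag(m)
  sigma <- if (variant == "GP1" || is.null(corr)) {
    diag(h2, nrow = k)
  } else {
    if (!isSymmetric(unname(corr)) || any(abs(diag(corr) - 1) > 1e-8)) {
      abort("`corr` must be a symmetric correlation matrix.")
    }
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) abort("`corr` must be positive semi-definite.")
    diag(sqrt(h2), nrow = k) %*% corr %*% diag(sqrt(h2), nrow = k)
  }
  kronecker(sigma, g)
}

#' Log prior density of logit-CCF trajectories
#'
#' Zero-mean multivariate normal log density of the latent matrix `Psi`
#' under the family's covariance: for `GP0` the `M x M` covariance is shared
#' by all `K` independent columns; for `GP1`-`GP3` the full `MK x MK`
#' covariance applies to `vec(Psi)` (columns stacked).
#'
#' @param psi `M x K` matrix of logit-CCF values.
#' @param cov Covariance matrix from [gp_covariance()] (`M x M`, GP0) or
#'   [gp_covariance_multi()] (`MK x MK`).
#' @param variant `"GP0"`, `"GP1"`, `"GP2"` or `"GP3"`.
#' @return Scalar log density.
#' @export
trajectory_log_prior <- function(psi, cov, variant = "GP0") {
  psi <- as.matrix(psi)
  m <- nrow(psi); k <- ncol(psi)
  if (variant == "GP0") {
    if (!all(dim(cov) == c(m, m))) abort("GP0 expects an M x M covariance.")
    ch <- chol(cov)
    quad <- sum(backsolve(ch, psi, transpose = TRUE)^2)
    -0.5 * quad - k * sum(log(diag(ch))) - m * k / 2 * log(2 * pi)
  } else {
    if (!all(dim(cov) == c(m * k, m * k))) {
      abort("Multi-output families expect an MK x MK covariance.")
    }
    x <- as.vector(psi)
    ch <- chol(cov)
    quad <- sum(backsolve(ch, x, transpose = TRUE)^2)
    -0.5 * quad - sum(log(diag(ch))) - m * k / 2 * log(2 * pi)
  }
}

# ---- LKJ correlation prior via canonical partial correlations -------------
#
# The K x K correlation matrix is parameterized through the lower Cholesky
# factor L built from partial correlations z_ij = tanh(y_ij): row i has
# L[i,j] = z_ij * prod_{l<j} sqrt(1 - z_il^2) and diagonal
# L[i,i] = prod_{l<i} sqrt(1 - z_il^2). Under the LKJ(eta) distribution the
# z_ij in column j are independent with (z+1)/2 ~ Beta(b_j, b_j),
# b_j = eta + (K - 1 - j)/2 — which gives a fully normalized prior density
# directly on the unconstrained y scale.

lkj_chol_from_y <- function(y, k) {
  z <- tanh(y)
  L <- diag(k)
  pos <- 0L
  for (i in seq_len(k)[-1]) {
    w <- 1
    for (j in seq_len(i - 1L)) {
      pos <- pos + 1L
      L[i, j] <- z[pos] * w
      w <- w * sqrt(1 - z[pos]^2)
    }
    L[i, i] <- w
  }
  L
}

lkj_col_index <- function(k) {
  unlist(lapply(seq_len(k)[-1], function(i) seq_len(i - 1L)))
}

# log p(y) for the LKJ(eta) prior expressed on the unconstrained scale
lkj_log_prior_y <- function(y, k, eta = 2) {
  if (k < 2) return(0)
  z <- tanh(y)
  b <- eta + (k - 1 - lkj_col_index(k)) / 2
  sum(b * log1p(-z^2) - ((2 * b - 1) * log(2) + lbeta(b, b)))
}

lkj_log_prior_y_grad <- function(y, k, eta = 2) {
  if (k < 2) return(numeric(0))
  b <- eta + (k - 1 - lkj_col_index(k)) / 2
  -2 * b * tanh(y)
}

# Backpropagate a gradient wrt L (lower triangular, including diagonal)
# to the unconstrained y vector. gL is a K x K matrix; entries above the
# diagonal are ignored.
lkj_chol_backprop <- function(y, k, gL) {
  z <- tanh(y)
  gy <- numeric(length(y))
  pos <- 0L
  for (i in seq_len(k)[-1]) {
    nj <- i - 1L
    zi <- z[pos + seq_len(nj)]
    w <- cumprod(c(1, sqrt(1 - zi^2)))    # w[j] = prod_{l<j} sqrt(1-z^2)
    Lrow <- c(zi * w[seq_len(nj)], w[nj + 1L])
    gRow <- c(gL[i, seq_len(nj)], gL[i, i])
    # dF/dz_m = g_m w_m - z_m/(1-z_m^2) * sum_{j>m} g_j L_j
    tail_sums <- rev(cumsum(rev(gRow * Lrow)))  # sum_{j>=m} g_j L_j
    gz <- gRow[seq_len(nj)] * w[seq_len(nj)] -
      zi / (1 - zi^2) * tail_sums[seq_len(nj) + 1L]
    gy[pos + seq_len(nj)] <- gz * (1 - zi^2)    # tanh jacobian
    pos <- pos + nj
  }
  gy
}
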