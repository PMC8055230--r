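# Deterministic toy mutation table: two well-separated CCF groups, no RNG.
toy_table <- function(n = 6L, m = 3L, depth = 100L, purity = 0.8) {
  ccf <- ifelse(seq_len(n) <= n / 2, 0.85, 0.25)
  zeta <- purity / (2 * (1 - purity) + 2 * purity)
  grid <- expand.grid(i = seq_len(n), j = seq_len(m))
  tibble::tibble(
    mutation_id = sprintf("m%02d", grid$i),
    sample_id = sprintf("s%d", grid$j),
    alt_reads = round(depth * zeta * ccf[grid$i]),
    total_reads = depth,
    total_cn = 2L,
    multiplicity = 1L,
    purity = purity,
    time_raw = (grid$j - 1) * 10
  )
}

# Pair-counting oracles for partition agreement (explicit enumeration of
# all item pairs; independent of the contingency-table implementations).
pair_counts <- function(a, b) {
  n <- length(a)
  ss <- sd_ <- ds <- dd <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) ss <- ss + 1L
      else if (sa && !sb) sd_ <- sd_ + 1L
      else if (!sa && sb) ds <- ds + 1L
      else dd <- dd + 1L
    }
  }
  c(ss = ss, sd = sd_, ds = ds, dd = dd)
}

oracle_ari <- function(a, b) {
  pc <- pair_counts(a, b)
  n2 <- sum(pc)
  idx <- pc[["ss"]]
  exp_idx <- (pc[["ss"]] + pc[["sd"]]) * (pc[["ss"]] + pc[["ds"]]) / n2
  max_idx <- ((pc[["ss"]] + pc[["sd"]]) + (pc[["ss"]] + pc[["ds"]])) / 2
  if (max_idx == exp_idx) return(1)
  (idx - exp_idx) / (max_idx - exp_idx)
}

oracle_fmi <- function(a, b) {
  pc <- pair_counts(a, b)
  pa <- pc[["ss"]] + pc[["sd"]]
  pb <- pc[["ss"]] + pc[["ds"]]
  if (pa == 0 || pb == 0) return(1)
  pc[["ss"]] / sqrt(pa * pb)
}

# Mutual information of two labelings (plain definition, no adjustment)
plain_mi <- function(a, b) {
  ct <- table(a, b); n <- sum(ct)
  p <- ct / n
  ra <- rowSums(ct) / n; cb <- colSums(ct) / n
  keep <- p > 0
  sum(p[keep] * log(p[keep] / outer(ra, cb)[keep]))
}

# Expected MI under the permutation model by explicit enumeration of all
# permutations of item order (feasible for n <= 7).
oracle_expected_mi <- function(a, b) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  mean(vapply(perms(seq_along(b)), function(p) plain_mi(a, b[p]),
              numeric(1)))
}

# All partitions of n items into at most `maxb` blocks, as restricted
# growth strings.
partitions_upto <- function(n, maxb = 3L) {
  out <- list(1L)
  for (item in seq_len(n)[-1L]) {
    nxt <- list()
    for (p in out) {
      top <- max(p)
      for (lab in seq_len(min(top + 1L, maxb))) {
        nxt[[length(nxt) + 1L]] <- c(p, lab)
      }
    }
    out <- nxt
  }
  out
}

# Dense multivariate-normal log density (textbook formula with solve();
# independent of the Cholesky path used in the package).
oracle_mvn_logpdf <- function(x, covm) {
  d <- length(x)
  -0.5 * (t(x) %*% solve(covm, x))[1] -
    0.5 * determinant(covm, logarithm = TRUE)$modulus[1] -
    d / 2 * log(2 * pi)
}

# Small cached fit used by several postprocess tests (built once per run).
small_fit_cache <- new.env(parent = emptyenv())
get_small_fit <- function() {
  if (is.null(small_fit_cache$fit)) {
    sim <- simulate_clones(n_mutations = 60, n_samples = 4, n_clusters = 2,
                           depth_mean = 1000, min_separation = 0.35,
                           seed = 5)
    small_fit_cache$sim <- sim
    small_fit_cache$fit <- suppressWarnings(clone_fit(
      sim$data, "GP0-Mat32", truncation = 8, max_iters = 5000,
      draws = 400, final_elbo_draws = 200, seed = 2
    ))
  }
  list(sim = small_fit_cache$sim, fit = small_fit_cache$fit)
}

logsumexp_test <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
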