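# Variational-inference engine: joint log-density of every model family and
# its analytic gradient on the unconstrained parameter scale, plus the
# stochastic-gradient (reparameterization) ELBO optimizer.
#
# Unconstrained parameterization:
#   psi       M x K   logit-CCF trajectories (identity transform)
#   sticks    K - 1   logit of stick fractions u_k
#   log_alpha 1       log DP concentration
#   log_h2    0/1/K   log kernel amplitudes h^2
#   log_tau   0/1/K   log inverse time-scales tau
#   corr_y    K(K-1)/2  tanh^-1 canonical partial correlations (GP2)
#   log_v     0/1/M   log beta-binomial precisions
# Priors (with the change-of-variable Jacobians folded in): u_k ~ Beta(1,a),
# alpha ~ (1+alpha)^-2, h2 ~ Gamma(1,1), tau ~ Gamma(1,1), 1/(1+v) ~ U(0,1),
# C ~ LKJ(eta); Flat uses phi_jk ~ U(0,1) i.e. a standard logistic on psi.

problem_layout <- function(n, m, k, spec) {
  blocks <- list(psi = m * k, sticks = k - 1L, log_alpha = 1L)
  fam <- spec$prior_family
  if (fam %in% c("GP0")) {
    blocks$log_h2 <- 1L; blocks$log_tau <- 1L
  } else if (fam %in% c("GP1", "GP2")) {
    blocks$log_h2 <- k; blocks$log_tau <- 1L
    if (fam == "GP2") blocks$corr_y <- k * (k - 1L) / 2L
  } else if (fam == "GP3") {
    blocks$log_h2 <- k; blocks$log_tau <- k
  }
  if (spec$family == "betabinomial") {
    blocks$log_v <- if (spec$shared_dispersion) 1L else m
  }
  sizes <- unlist(blocks)
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  names(offsets) <- names(sizes)
  list(sizes = sizes, offsets = offsets, total = sum(sizes),
       n = n, m = m, k = k)
}

layout_block <- function(layout, z, name) {
  if (!name %in% names(layout$sizes)) return(NULL)
  z[layout$offsets[[name]] + seq_len(layout$sizes[[name]])]
}

layout_block_of_index <- function(layout, idx) {
  ends <- cumsum(layout$sizes)
  names(ends)[which(idx <= ends)[1L]]
}

build_problem <- function(arrays, spec, jitter = 1e-6, theta_clip = 1e-9) {
  n <- arrays$n; m <- arrays$m; k <- spec$truncation
  layout <- problem_layout(n, m, k, spec)
  zeta <- matrix(clonal_vaf_coefficient(
    rep(arrays$purity, each = n), arrays$cn, arrays$multiplicity
  ), n, m)
  if (anyNA(zeta)) abort("Unresolved multiplicities; run resolve_multiplicity().")

  # column j' = (k-1)*m + j of the tiled N x (M K) matrices refers to
  # sample j under cluster k
  jt <- rep(seq_len(m), k)
  r_t <- arrays$alt[, jt, drop = FALSE]
  R_t <- arrays$total[, jt, drop = FALSE]
  zeta_t <- zeta[, jt, drop = FALSE]
  lch_t <- lchoose(R_t, r_t)
  group <- matrix(0, m * k, k)        # sums tiled columns into clusters
  group[cbind(seq_len(m * k), rep(seq_len(k), each = m))] <- 1
  eps_err <- spec$error_rate
  betabin <- spec$family == "betabinomial"
  dmat <- abs(outer(arrays$times, arrays$times, "-"))
  eta <- spec$lkj_eta

  logp_grad <- function(z, want_grad = TRUE) {
    g <- if (want_grad) numeric(layout$total) else NULL
    gset <- function(name, val) {
      idx <- layout$offsets[[name]] + seq_len(layout$sizes[[name]])
      g[idx] <<- g[idx] + val
    }
    psi <- matrix(layout_block(layout, z, "psi"), m, k)
    s <- layout_block(layout, z, "sticks")
    la <- layout_block(layout, z, "log_alpha")
    alpha <- exp(la)
    phi <- plogis(psi)

    # ---- mixture weights ----
    u <- plogis(s)
    w <- stick_breaking(u, k = k)
    logw <- log(pmax(w, 1e-300))

    # ---- observation likelihood, marginalized over assignments ----
    if (betabin) {
      v_raw <- exp(layout_block(layout, z, "log_v"))
      v <- rep(v_raw, length.out = m)
      v_t <- matrix(v[jt], n, m * k, byrow = TRUE)
    }
    theta_raw <- sweep(zeta_t, 2L, as.vector(phi), "*")
    if (!is.null(eps_err)) theta_raw <- eps_err + (1 - 2 * eps_err) * theta_raw
    inside <- theta_raw > theta_clip & theta_raw < 1 - theta_clip
    theta <- pmin(pmax(theta_raw, theta_clip), 1 - theta_clip)
    if (betabin) {
      a <- v_t * theta; b <- v_t * (1 - theta)
      ll_t <- lch_t + lbeta(r_t + a, R_t - r_t + b) - lbeta(a, b)
    } else {
      ll_t <- lch_t + r_t * log(theta) + (R_t - r_t) * log1p(-theta)
    }
    LL <- ll_t %*% group                       # N x K
    lse_in <- sweep(LL, 2L, logw, "+")
    ci <- row_logsumexp(lse_in)
    loglik <- sum(ci)
    val <- loglik

    if (want_grad) {
      gamma <- exp(lse_in - ci)                # N x K responsibilities
      gamma_t <- gamma[, rep(seq_len(k), each = m), drop = FALSE]
      if (betabin) {
        dg_ra <- digamma(r_t + a); dg_rb <- digamma(R_t - r_t + b)
        dg_a <- digamma(a); dg_b <- digamma(b)
        T_t <- v_t * (dg_ra - dg_rb - dg_a + dg_b)
      } else {
        T_t <- r_t / theta - (R_t - r_t) / (1 - theta)
      }
      dtheta_dphi <- zeta_t * if (is.null(eps_err)) 1 else (1 - 2 * eps_err)
      gphi_vec <- colSums(gamma_t * T_t * dtheta_dphi * inside)
      gphi <- matrix(gphi_vec, m, k)
      gpsi <- gphi * phi * (1 - phi)           # likelihood part

      if (betabin) {
        dll_dv <- theta * (dg_ra - dg_a) + (1 - theta) * (dg_rb - dg_b) -
          digamma(R_t + v_t) + digamma(v_t)
        gv_cols <- colSums(gamma_t * dll_dv)   # length m*k
        gv <- rowSums(matrix(gv_cols, m, k))   # per sample, d/dv
        # prior 1/(1+v) ~ U(0,1) => p(v) = (1+v)^-2, plus log jacobian
        if (spec$shared_dispersion) {
          vj <- v_raw
          gset("log_v", sum(gv) * vj - 2 * vj / (1 + vj) + 1)
        } else {
          gset("log_v", gv * v - 2 * v / (1 + v) + 1)
        }
      }

      # sticks and concentration (priors u_k ~ Beta(1, alpha) + jacobians)
      gk <- colSums(gamma)
      tail_g <- rev(cumsum(rev(gk)))           # sum_{l >= k} g_l
      gs <- gk[seq_len(k - 1L)] * (1 - u) - u * tail_g[-1L] +
        (1 - u) - alpha * u
      gset("sticks", gs)
      gset("log_alpha",
           sum(1 + alpha * log1p(-u)) - 2 * alpha / (1 + alpha) + 1)
    }
    if (betabin) {
      vj <- if (spec$shared_dispersion) v_raw else v
      val <- val - 2 * sum(log1p(vj)) + sum(log(vj))
    }
    val <- val + (k - 1L) * log(alpha) + alpha * sum(log1p(-u)) +
      sum(log(u) ) - 2 * log1p(alpha) + la

    # ---- trajectory prior ----
    fam <- spec$prior_family
    if (fam == "Flat") {
      val <- val + sum(dlogis_log(psi))
      if (want_grad) gpsi <- gpsi + (1 - 2 * phi)
    } else if (fam == "GP0") {
      h2 <- exp(layout_block(layout, z, "log_h2"))
      tau <- exp(layout_block(layout, z, "log_tau"))
      G <- kernel_g(spec$kernel, tau, dmat)
      Kmat <- h2 * (G + jitter * diag(m))
      ch <- chol(Kmat)
      Kinv <- chol2inv(ch)
      A <- Kinv %*% psi
      val <- val - 0.5 * sum(psi * A) - k * sum(log(diag(ch))) -
        m * k / 2 * log(2 * pi) +
        sum(log(h2) - h2) + sum(log(tau) - tau)
      if (want_grad) {
        gpsi <- gpsi - A
        B <- A %*% t(A) - k * Kinv
        gset("log_h2", 0.5 * sum(B * Kmat) + 1 - h2)
        dG <- kernel_g_dtau(spec$kernel, tau, dmat)
        gset("log_tau", 0.5 * sum(B * (h2 * tau * dG)) + 1 - tau)
      }
    } else if (fam %in% c("GP1", "GP2")) {
      lh <- layout_block(layout, z, "log_h2")
      h2 <- exp(lh); hs <- exp(lh / 2)
      tau <- exp(layout_block(layout, z, "log_tau"))
      G <- kernel_g(spec$kernel, tau, dmat) + jitter * diag(m)
      chG <- chol(G); Ginv <- chol2inv(chG)
      W <- Ginv %*% psi
      Sq <- crossprod(psi, W)                  # Psi' G^-1 Psi
      if (fam == "GP1") {
        Sinv <- diag(1 / h2, nrow = k)
        ldetS <- sum(lh)
      } else {
        y <- layout_block(layout, z, "corr_y")
        L <- lkj_chol_from_y(y, k)
        Ls <- hs * L                           # chol factor of Sigma = DCD
        Linv <- forwardsolve(Ls, diag(k))
        Sinv <- crossprod(Linv)
        ldetS <- 2 * sum(log(diag(Ls)))
      }
      val <- val - 0.5 * sum(Sinv * Sq) - m / 2 * ldetS -
        k * sum(log(diag(chG))) - m * k / 2 * log(2 * pi) +
        sum(log(h2) - h2) + sum(log(tau) - tau)
      if (fam == "GP2") val <- val + lkj_log_prior_y(y, k, eta)
      if (want_grad) {
        gpsi <- gpsi - W %*% Sinv
        S_g <- 0.5 * (Sinv %*% Sq %*% Sinv - m * Sinv)
        if (fam == "GP1") {
          gset("log_h2", diag(S_g) * h2 + 1 - h2)
        } else {
          SDC <- S_g %*% (hs * L %*% t(L))     # S_g D C, D = diag(hs)
          gset("log_h2", diag(SDC) * hs + 1 - h2)
          G_C <- (hs %o% hs) * S_g             # D S_g D
          gL <- 2 * G_C %*% L
          gset("corr_y", lkj_chol_backprop(y, k, gL) +
                         lkj_log_prior_y_grad(y, k, eta))
        }
        dvaldG <- 0.5 * (W %*% Sinv %*% t(W)) - k / 2 * Ginv
        dG <- kernel_g_dtau(spec$kernel, tau, dmat)
        gset("log_tau", sum(dvaldG * (tau * dG)) + 1 - tau)
      }
    } else if (fam == "GP3") {
      h2 <- exp(layout_block(layout, z, "log_h2"))
      tau <- exp(layout_block(layout, z, "log_tau"))
      g_lh <- numeric(k); g_lt <- numeric(k)
      for (j in seq_len(k)) {
        G <- kernel_g(spec$kernel, tau[j], dmat)
        Kmat <- h2[j] * (G + jitter * diag(m))
        ch <- chol(Kmat); Kinv <- chol2inv(ch)
        aj <- Kinv %*% psi[, j]
        val <- val - 0.5 * sum(psi[, j] * aj) - sum(log(diag(ch))) -
          m / 2 * log(2 * pi)
        if (want_grad) {
          gpsi[, j] <- gpsi[, j] - aj
          B <- aj %*% t(aj) - Kinv
          g_lh[j] <- 0.5 * sum(B * Kmat)
          dG <- kernel_g_dtau(spec$kernel, tau[j], dmat)
          g_lt[j] <- 0.5 * sum(B * (h2[j] * tau[j] * dG))
        }
      }
      val <- val + sum(log(h2) - h2) + sum(log(tau) - tau)
      if (want_grad) {
        gset("log_h2", g_lh + 1 - h2)
        gset("log_tau", g_lt + 1 - tau)
      }
    }
    if (want_grad) gset("psi", as.vector(gpsi))
    list(value = val, grad = g)
  }

  list(layout = layout, zeta = zeta, arrays = arrays, spec = spec,
       logp_grad = logp_grad, jitter = jitter, theta_clip = theta_clip)
}

# K-means based initialization of the variational means for psi. With
# k_init < K only the first k_init components start at distinct centers;
# the rest start at the depth-weighted pooled trajectory, which gives
# restarts a ladder of progressively more agglomerated starting points.
init_mu <- function(problem, k_init = NULL) {
  layout <- problem$layout
  arrays <- problem$arrays
  k <- layout$k
  if (is.null(k_init)) k_init <- k
  k_init <- max(2L, min(k_init, k))
  mu <- numeric(layout$total)
  ccf <- pmin(pmax(arrays$alt / arrays$total / problem$zeta, 0.01), 0.99)
  # tiny deterministic jitter keeps kmeans happy on degenerate tables
  ccfj <- ccf + matrix(rnorm(length(ccf), 0, 1e-3), nrow(ccf))
  centers <- if (arrays$n >= k_init) {
    km <- tryCatch(
      suppressWarnings(
        stats::kmeans(ccfj, centers = k_init, nstart = 5, iter.max = 50)
      ),
      error = function(e) NULL
    )
    if (is.null(km)) {
      matrix(runif(k_init * arrays$m, 0.05, 0.95), k_init, arrays$m)
    } else {
      km$centers
    }
  } else {
    rbind(ccfj, matrix(runif((k_init - arrays$n) * arrays$m, 0.05, 0.95),
                       max(k_init - arrays$n, 0), arrays$m))
  }
  if (nrow(centers) < k) {
    pooled <- colSums(ccf * arrays$total) / colSums(arrays$total)
    centers <- rbind(centers,
                     matrix(pooled, k - nrow(centers), arrays$m,
                            byrow = TRUE))
  }
  psi0 <- t(qlogis(pmin(pmax(centers, 0.01), 0.99)))  # M x K
  mu[layout$offsets[["psi"]] + seq_len(layout$sizes[["psi"]])] <-
    as.vector(psi0)
  # near-uniform initial weights: u_k = 1 / (K - k + 1)
  u0 <- 1 / (k - seq_len(k - 1L) + 1)
  mu[layout$offsets[["sticks"]] + seq_len(k - 1L)] <- qlogis(u0)
  if ("log_v" %in% names(layout$sizes)) {
    mu[layout$offsets[["log_v"]] + seq_len(layout$sizes[["log_v"]])] <-
      log(50)
  }
  mu
}

run_advi <- function(problem, cfg, k_init = NULL) {
  layout <- problem$layout
  p_tot <- layout$total
  mu <- init_mu(problem, k_init)
  omega <- rep(-2, p_tot)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  m1 <- numeric(2 * p_tot); m2 <- numeric(2 * p_tot)
  trace <- numeric(cfg$max_iters)
  ent_const <- 0.5 * p_tot * log(2 * pi * exp(1))
  converged <- FALSE
  iters <- cfg$max_iters
  win <- cfg$convergence_window

  for (it in seq_len(cfg$max_iters)) {
    sigma <- exp(omega)
    g_mu <- numeric(p_tot); g_om <- numeric(p_tot); lp <- 0
    for (s in seq_len(cfg$mc_samples)) {
      eps <- rnorm(p_tot)
      z <- mu + sigma * eps
      res <- problem$logp_grad(z)
      if (!is.finite(res$value) || any(!is.finite(res$grad))) {
        bad <- if (any(!is.finite(res$grad))) {
          layout_block_of_index(layout, which(!is.finite(res$grad))[1L])
        } else "joint density"
        abort(paste0("Non-finite ELBO gradient in parameter block `",
                     bad, "` at iteration ", it, "."))
      }
      g_mu <- g_mu + res$grad
      g_om <- g_om + res$grad * sigma * eps
      lp <- lp + res$value
    }
    g_mu <- g_mu / cfg$mc_samples
    g_om <- g_om / cfg$mc_samples + 1      # + d entropy / d omega
    trace[it] <- lp / cfg$mc_samples + sum(omega) + ent_const

    grad <- c(g_mu, g_om)
    m1 <- b1 * m1 + (1 - b1) * grad
    m2 <- b2 * m2 + (1 - b2) * grad^2
    step <- cfg$learning_rate * (m1 / (1 - b1^it)) /
      (sqrt(m2 / (1 - b2^it)) + adam_eps)
    mu <- mu + step[seq_len(p_tot)]
    omega <- pmin(omega + step[p_tot + seq_len(p_tot)], 5)

    if (isTRUE(cfg$verbose) && it %% 500L == 0L) {
      message(sprintf("iter %6d  ELBO %.2f", it, trace[it]))
    }

    if (it %% win == 0 && it >= 2 * win) {
      recent <- mean(trace[(it - win + 1):it])
      prev <- mean(trace[(it - 2 * win + 1):(it - win)])
      if (abs(recent - prev) / (abs(prev) + 1e-12) <
          cfg$convergence_rel_tol) {
        converged <- TRUE; iters <- it
        break
      }
    }
  }
  list(mu = mu, omega = omega, trace = trace[seq_len(iters)],
       converged = converged, iterations = iters)
}

# Transform one unconstrained draw into the constrained parameter list
constrain_draw <- function(z, layout, spec) {
  k <- layout$k; m <- layout$m
  u <- plogis(layout_block(layout, z, "sticks"))
  out <- list(
    weights = stick_breaking(u, k = k),
    phi = plogis(matrix(layout_block(layout, z, "psi"), m, k)),
    alpha = exp(layout_block(layout, z, "log_alpha"))
  )
  if ("log_h2" %in% names(layout$sizes)) {
    out$h2 <- exp(layout_block(layout, z, "log_h2"))
    out$tau <- exp(layout_block(layout, z, "log_tau"))
  }
  if ("corr_y" %in% names(layout$sizes)) {
    L <- lkj_chol_from_y(layout_block(layout, z, "corr_y"), k)
    out$corr <- L %*% t(L)
  }
  if ("log_v" %in% names(layout$sizes)) {
    out$precision <- rep(exp(layout_block(layout, z, "log_v")),
                         length.out = m)
  }
  out
}
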