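# Mean-field coordinate-ascent updates and the evidence lower bound.
#
# Every sub-update below is the exact optimizer of the ELBO with all other
# variational factors held fixed, so a full sweep can never decrease the
# objective (up to floating-point error).  The sweep order is fixed for
# reproducibility: zeta (local bounds) -> W per view -> Z per group ->
# alpha_w -> alpha_z -> theta_w -> theta_z -> tau.

LOG2PI <- log(2 * pi)

xlogx <- function(p) ifelse(p <= 0, 0, p * log(p))

theta_tilde <- function(th) digamma(th$a) - digamma(th$b)  # E[log th] - E[log(1-th)]

# Moments of the spike-and-slab weight posterior.  q(w_dk) is a mixture of a
# point mass at zero (prob 1-g) and N(mu, s2) (prob g); the slab variable
# w-hat has conditional variance s0 = 1/E[alpha] under the spike.
w_moments <- function(W) {
  E2 <- W$g * (W$mu^2 + W$s2)
  list(E = W$g * W$mu,
       E2 = E2,
       Ehat2 = E2 + sweep(1 - W$g, 2L, W$s0, "*"))
}

z_moments <- function(Z) {
  if (!is.null(Z$g)) return(w_moments(Z))
  E2 <- Z$mu^2 + Z$s2
  list(E = Z$mu, E2 = E2, Ehat2 = E2)
}

all_moments <- function(state) {
  list(w = lapply(state$W, w_moments),
       z = lapply(state$Z, z_moments))
}

# Per-entry precision T and (pseudo-)data Yt for one block.  Gaussian views
# use E[tau] per feature; non-Gaussian views are converted into Gaussian
# pseudo-observations by their local quadratic bound.
get_TY <- function(state, pp, g, m, rows = NULL) {
  Y <- pp$Y0[[g]][[m]]
  M <- pp$mask[[g]][[m]]
  if (!is.null(rows)) {
    Y <- Y[rows, , drop = FALSE]
    M <- M[rows, , drop = FALSE]
  }
  lik <- pp$lik[[m]]
  if (lik == "gaussian") {
    tau <- state$tau[[g]][[m]]
    Etau <- tau$a / tau$b
    list(T = M * rep(Etau, each = nrow(M)), Yt = Y)
  } else if (lik == "bernoulli") {
    z <- state$zeta[[g]][[m]]
    if (!is.null(rows)) z <- z[rows, , drop = FALSE]
    lam <- lambda_jj(z)
    list(T = M * (2 * lam), Yt = (Y - 0.5) / (2 * lam))
  } else {
    z <- state$zeta[[g]][[m]]
    if (!is.null(rows)) z <- z[rows, , drop = FALSE]
    L <- 0.25 + POISSON_CURVATURE * Y
    list(T = M * L, Yt = z + poisson_dloglik(Y, z) / L)
  }
}

# predictor variance: Var[sum_k z_k w_k] entrywise
pred_var <- function(zm, wm) {
  V <- zm$E2 %*% t(wm$E2) - (zm$E^2) %*% t(wm$E^2)
  pmax(V, 0)
}

update_zeta <- function(state, pp, mom, rows = NULL) {
  for (g in seq_len(pp$G)) {
    r <- if (is.null(rows)) NULL else rows[[g]]
    for (m in seq_len(pp$M)) {
      if (pp$lik[[m]] == "gaussian") next
      zm <- mom$z[[g]]
      if (!is.null(r)) zm <- lapply(zm, function(x) x[r, , drop = FALSE])
      Pred <- zm$E %*% t(mom$w[[m]]$E)
      new_zeta <- if (pp$lik[[m]] == "bernoulli") {
        zeta_bernoulli(Pred^2 + pred_var(zm, mom$w[[m]]))
      } else {
        Pred
      }
      if (is.null(r)) {
        state$zeta[[g]][[m]] <- new_zeta
      } else {
        state$zeta[[g]][[m]][r, ] <- new_zeta
      }
    }
  }
  state
}

# One coordinate update of q(W_m) for all views, factor columns swept in
# order with residuals kept current.  For each element the joint
# spike-and-slab optimum is: s1 = 1/(E[alpha_k] + A), mu1 = s1 * B,
# logit(g) = E[log th/(1-th)] + 0.5 log(E[alpha_k] s1) + mu1^2 / (2 s1).
update_W <- function(state, pp, TY, mom) {
  K <- state$K
  for (m in seq_len(pp$M)) {
    W <- state$W[[m]]
    Ea <- state$alpha_w[[m]]$a / state$alpha_w[[m]]$b
    tt <- theta_tilde(state$theta_w[[m]])
    EW <- W$g * W$mu
    A <- Am <- 0
    for (g in seq_len(pp$G)) {
      A <- A + crossprod(TY[[g]][[m]]$T, mom$z[[g]]$E2)
      Am <- Am + crossprod(TY[[g]][[m]]$T, mom$z[[g]]$E^2)  # restores the own-column term
    }
    R <- lapply(seq_len(pp$G), function(g)
      TY[[g]][[m]]$Yt - mom$z[[g]]$E %*% t(EW))
    for (k in seq_len(K)) {
      Bk <- Am[, k] * EW[, k]
      for (g in seq_len(pp$G)) {
        Bk <- Bk + crossprod(TY[[g]][[m]]$T * R[[g]], mom$z[[g]]$E[, k])
      }
      s1 <- 1 / (Ea[k] + A[, k])
      mu1 <- s1 * Bk
      gam <- sigmoid(tt[k] + 0.5 * log(Ea[k] * s1) + 0.5 * mu1^2 / s1)
      neww <- gam * mu1
      dw <- neww - EW[, k]
      for (g in seq_len(pp$G)) {
        R[[g]] <- R[[g]] - tcrossprod(mom$z[[g]]$E[, k], dw)
      }
      EW[, k] <- neww
      W$mu[, k] <- mu1
      W$s2[, k] <- s1
      W$g[, k] <- gam
      W$s0[k] <- 1 / Ea[k]
    }
    state$W[[m]] <- W
    mom$w[[m]] <- w_moments(W)
  }
  list(state = state, mom = mom)
}

update_Z <- function(state, pp, TY, mom, rows = NULL) {
  K <- state$K
  spike <- isTRUE(state$opts$spike_factors)
  for (g in seq_len(pp$G)) {
    r <- if (is.null(rows)) seq_len(pp$N[g]) else rows[[g]]
    Z <- state$Z[[g]]
    prior_prec <- if (isTRUE(state$opts$ard_factors)) {
      state$alpha_z[[g]]$a / state$alpha_z[[g]]$b
    } else {
      rep(1, K)
    }
    if (spike) tt <- theta_tilde(state$theta_z[[g]])
    EZ <- if (spike) (Z$g * Z$mu)[r, , drop = FALSE] else Z$mu[r, , drop = FALSE]
    TYg <- TY[[g]]  # caller passes batch-row blocks when `rows` is given
    A <- Am <- 0
    for (m in seq_len(pp$M)) {
      A <- A + TYg[[m]]$T %*% mom$w[[m]]$E2
      Am <- Am + TYg[[m]]$T %*% (mom$w[[m]]$E^2)
    }
    R <- lapply(seq_len(pp$M), function(m)
      TYg[[m]]$Yt - EZ %*% t(mom$w[[m]]$E))
    for (k in seq_len(K)) {
      Bk <- Am[, k] * EZ[, k]
      for (m in seq_len(pp$M)) {
        Bk <- Bk + (TYg[[m]]$T * R[[m]]) %*% mom$w[[m]]$E[, k]
      }
      s2 <- 1 / (prior_prec[k] + A[, k])
      mu <- s2 * Bk
      if (spike) {
        gam <- sigmoid(tt[k] + 0.5 * log(prior_prec[k] * s2) + 0.5 * mu^2 / s2)
        newz <- gam * mu
        Z$g[r, k] <- gam
        Z$s0[k] <- 1 / prior_prec[k]
      } else {
        newz <- mu
      }
      dz <- newz - EZ[, k]
      for (m in seq_len(pp$M)) {
        R[[m]] <- R[[m]] - tcrossprod(dz, mom$w[[m]]$E[, k])
      }
      EZ[, k] <- newz
      Z$mu[r, k] <- mu
      Z$s2[r, k] <- s2
    }
    state$Z[[g]] <- Z
    mom$z[[g]] <- z_moments(Z)
  }
  list(state = state, mom = mom)
}

update_alpha_w <- function(state, pp, mom) {
  pr <- state$opts$priors
  for (m in seq_len(pp$M)) {
    state$alpha_w[[m]]$a <- rep(pr$alpha_a + pp$D[m] / 2, state$K)
    state$alpha_w[[m]]$b <- pr$alpha_b + 0.5 * colSums(mom$w[[m]]$Ehat2)
  }
  state
}

update_alpha_z <- function(state, pp, mom) {
  if (!isTRUE(state$opts$ard_factors)) return(state)
  pr <- state$opts$priors
  for (g in seq_len(pp$G)) {
    state$alpha_z[[g]]$a <- rep(pr$alpha_a + pp$N[g] / 2, state$K)
    state$alpha_z[[g]]$b <- pr$alpha_b + 0.5 * colSums(mom$z[[g]]$Ehat2)
  }
  state
}

update_theta_w <- function(state, pp) {
  pr <- state$opts$priors
  for (m in seq_len(pp$M)) {
    sg <- colSums(state$W[[m]]$g)
    state$theta_w[[m]]$a <- pr$theta_a + sg
    state$theta_w[[m]]$b <- pr$theta_b + pp$D[m] - sg
  }
  state
}

update_theta_z <- function(state, pp) {
  if (!isTRUE(state$opts$spike_factors)) return(state)
  pr <- state$opts$priors
  for (g in seq_len(pp$G)) {
    sg <- colSums(state$Z[[g]]$g)
    state$theta_z[[g]]$a <- pr$theta_a + sg
    state$theta_z[[g]]$b <- pr$theta_b + pp$N[g] - sg
  }
  state
}

update_tau <- function(state, pp, mom) {
  pr <- state$opts$priors
  for (g in seq_len(pp$G)) for (m in seq_len(pp$M)) {
    if (pp$lik[[m]] != "gaussian") next
    Pred <- mom$z[[g]]$E %*% t(mom$w[[m]]$E)
    V <- pred_var(mom$z[[g]], mom$w[[m]])
    SS <- colSums(pp$mask[[g]][[m]] * ((pp$Y0[[g]][[m]] - Pred)^2 + V))
    state$tau[[g]][[m]]$a <- pr$tau_a + pp$nobs[[g]][[m]] / 2
    state$tau[[g]][[m]]$b <- pr$tau_b + SS / 2
  }
  state
}

# One full coordinate-ascent sweep.
vi_iteration <- function(state, pp) {
  mom <- all_moments(state)
  state <- update_zeta(state, pp, mom)
  TY <- lapply(seq_len(pp$G), function(g)
    lapply(seq_len(pp$M), function(m) get_TY(state, pp, g, m)))
  res <- update_W(state, pp, TY, mom)
  res <- update_Z(res$state, pp, TY, res$mom)
  state <- res$state
  mom <- res$mom
  state <- update_alpha_w(state, pp, mom)
  state <- update_alpha_z(state, pp, mom)
  state <- update_theta_w(state, pp)
  state <- update_theta_z(state, pp)
  state <- update_tau(state, pp, mom)
  check_finite_state(state)
  state
}

check_finite_state <- function(state) {
  for (m in seq_along(state$W)) {
    if (!all(is.finite(state$W[[m]]$mu)) || !all(is.finite(state$W[[m]]$s2))) {
      stop("non-finite value in the weight update for view ", m)
    }
  }
  for (g in seq_along(state$Z)) {
    if (!all(is.finite(state$Z[[g]]$mu)) || !all(is.finite(state$Z[[g]]$s2))) {
      stop("non-finite value in the factor update for group ", g)
    }
  }
  invisible(TRUE)
}

gamma_elbo_term <- function(a, b, a0, b0) {
  Ex <- a / b
  Elx <- digamma(a) - log(b)
  lp <- a0 * log(b0) - lgamma(a0) + (a0 - 1) * Elx - b0 * Ex
  lq <- a * log(b) - lgamma(a) + (a - 1) * Elx - a
  sum(lp - lq)
}

beta_elbo_term <- function(a, b, a0, b0) {
  El1 <- digamma(a) - digamma(a + b)
  El0 <- digamma(b) - digamma(a + b)
  lp <- (a0 - 1) * El1 + (b0 - 1) * El0 - lbeta(a0, b0)
  lq <- (a - 1) * El1 + (b - 1) * El0 - lbeta(a, b)
  sum(lp - lq)
}

# ELBO contribution of one spike-and-slab matrix (weights, or factors when
# the factor-side spike is enabled): E[log p(w-hat | alpha)] +
# E[log p(s | theta)] + entropy of q(s, w-hat).
spikeslab_elbo_term <- function(W, Ea, Ela, theta) {
  El1 <- digamma(theta$a) - digamma(theta$a + theta$b)
  El0 <- digamma(theta$b) - digamma(theta$a + theta$b)
  D <- nrow(W$mu)
  Ehat2 <- W$g * (W$mu^2 + W$s2) + sweep(1 - W$g, 2L, W$s0, "*")
  lp_w <- sum(D * 0.5 * Ela) - 0.5 * D * length(Ea) * LOG2PI -
    0.5 * sum(Ea * colSums(Ehat2))
  cg <- colSums(W$g)
  lp_s <- sum(cg * El1 + (D - cg) * El0)
  H_s <- -sum(xlogx(W$g) + xlogx(1 - W$g))
  H_w <- 0.5 * sum(W$g * (log(2 * pi * W$s2) + 1)) +
    0.5 * sum(colSums(1 - W$g) * (log(2 * pi * W$s0) + 1))
  lp_w + lp_s + H_s + H_w
}

gaussian_factor_elbo_term <- function(Z, alpha) {
  if (is.null(alpha)) {
    Ea <- rep(1, ncol(Z$mu))
    Ela <- rep(0, ncol(Z$mu))
  } else {
    Ea <- alpha$a / alpha$b
    Ela <- digamma(alpha$a) - log(alpha$b)
  }
  N <- nrow(Z$mu)
  lp <- sum(N * 0.5 * Ela) - 0.5 * N * length(Ea) * LOG2PI -
    0.5 * sum(Ea * colSums(Z$mu^2 + Z$s2))
  H <- 0.5 * sum(log(2 * pi * Z$s2) + 1)
  lp + H
}

# Evidence lower bound of the current state on the full data set.  For
# non-Gaussian views the likelihood term is the local-bound surrogate.
compute_elbo <- function(state, pp) {
  mom <- all_moments(state)
  pr <- state$opts$priors
  total <- 0
  for (g in seq_len(pp$G)) for (m in seq_len(pp$M)) {
    Pred <- mom$z[[g]]$E %*% t(mom$w[[m]]$E)
    V <- pred_var(mom$z[[g]], mom$w[[m]])
    Y <- pp$Y0[[g]][[m]]
    Msk <- pp$mask[[g]][[m]]
    lik <- pp$lik[[m]]
    if (lik == "gaussian") {
      tau <- state$tau[[g]][[m]]
      total <- total + gaussian_loglik(Y, Msk, Pred, V, tau$a / tau$b,
                                       digamma(tau$a) - log(tau$b))
    } else if (lik == "bernoulli") {
      bb <- bernoulli_bound(Y, Pred, V, state$zeta[[g]][[m]])
      total <- total + sum(bb[Msk == 1])
    } else {
      bb <- poisson_bound(Y, Pred, V, state$zeta[[g]][[m]])
      total <- total + sum(bb[Msk == 1])
    }
  }
  for (m in seq_len(pp$M)) {
    aw <- state$alpha_w[[m]]
    total <- total + spikeslab_elbo_term(state$W[[m]], aw$a / aw$b,
                                         digamma(aw$a) - log(aw$b),
                                         state$theta_w[[m]])
    total <- total + gamma_elbo_term(state$alpha_w[[m]]$a, state$alpha_w[[m]]$b,
                                     pr$alpha_a, pr$alpha_b)
    total <- total + beta_elbo_term(state$theta_w[[m]]$a, state$theta_w[[m]]$b,
                                    pr$theta_a, pr$theta_b)
  }
  for (g in seq_len(pp$G)) {
    if (isTRUE(state$opts$spike_factors)) {
      if (isTRUE(state$opts$ard_factors)) {
        az <- state$alpha_z[[g]]
        Ea <- az$a / az$b
        Ela <- digamma(az$a) - log(az$b)
      } else {
        Ea <- rep(1, state$K)   # fixed unit-precision slab
        Ela <- rep(0, state$K)
      }
      total <- total + spikeslab_elbo_term(state$Z[[g]], Ea, Ela, state$theta_z[[g]])
      total <- total + beta_elbo_term(state$theta_z[[g]]$a, state$theta_z[[g]]$b,
                                      pr$theta_a, pr$theta_b)
    } else {
      total <- total + gaussian_factor_elbo_term(state$Z[[g]],
        if (isTRUE(state$opts$ard_factors)) state$alpha_z[[g]] else NULL)
    }
    if (isTRUE(state$opts$ard_factors)) {
      total <- total + gamma_elbo_term(state$alpha_z[[g]]$a, state$alpha_z[[g]]$b,
                                       pr$alpha_a, pr$alpha_b)
    }
  }
  for (g in seq_len(pp$G)) for (m in seq_len(pp$M)) {
    if (pp$lik[[m]] != "gaussian") next
    total <- total + gamma_elbo_term(state$tau[[g]][[m]]$a, state$tau[[g]][[m]]$b,
                                     pr$tau_a, pr$tau_b)
  }
  total
}
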