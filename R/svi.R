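# Stochastic variational inference: stratified mini-batches over samples,
# exact local updates on the batch, and natural-parameter interpolation of
# the global posteriors with the decaying step size rho(t).

#' Step-size schedule for stochastic inference
#'
#' Returns `rho(t) = lr_start / (1 + forgetting_rate * t)^(3/4)`, the
#' learning rate applied to the natural-gradient interpolation at update
#' step `t` (counted per mini-batch, starting at 0).  `forgetting_rate = 0`
#' gives a constant rate; larger values decay faster.
#'
#' @param t Update step index (>= 0, vectorized).
#' @param lr_start Starting learning rate (default 1.0).
#' @param forgetting_rate Decay parameter (default 0.25).
#' @export
svi_learning_rate <- function(t, lr_start = 1.0, forgetting_rate = 0.25) {
  stopifnot(lr_start > 0, forgetting_rate >= 0, all(t >= 0))
  lr_start * (1 + forgetting_rate * t)^(-3 / 4)
}

# Partition each group's samples into ceiling(1/fraction) batches of
# near-equal size (within one sample), reshuffled deterministically from
# `seed`.  Every batch is stratified: it contains samples from all groups
# in proportion to group size.
make_batch_plan <- function(N, fraction, seed) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  B <- as.integer(ceiling(1 / fraction))
  per_group <- vector("list", length(N))
  for (g in seq_along(N)) {
    if (N[g] < B) {
      stop(sprintf("batch fraction %.3f yields an empty batch for a group of size %d",
                   fraction, N[g]))
    }
    perm <- local({
      set.seed((seed + 7919L * g) %% .Machine$integer.max)
      sample.int(N[g])
    })
    sizes <- rep(N[g] %/% B, B)
    extra <- N[g] %% B
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    per_group[[g]] <- split(perm, rep(seq_len(B), times = sizes))
  }
  lapply(seq_len(B), function(b) lapply(per_group, `[[`, b))
}

# One stochastic update from one mini-batch.  Local variables (factor rows
# and local bound parameters of the batch samples) get their exact VI
# update; global natural statistics are moved a step rho towards the
# full-data optimum estimated from the batch, with batch sums scaled by
# N_g / |batch_g| per group.
svi_step <- function(state, pp, batch, rho) {
  if (rho <= 0 || rho > 1) stop("`rho` must be in (0, 1]")
  K <- state$K
  scale <- pp$N / vapply(batch, length, 1L)
  mom <- all_moments(state)

  # local bound parameters for the batch rows
  state <- update_zeta(state, pp, mom, rows = batch)

  TYb <- lapply(seq_len(pp$G), function(g)
    lapply(seq_len(pp$M), function(m) get_TY(state, pp, g, m, rows = batch[[g]])))
  zb <- lapply(seq_len(pp$G), function(g)
    lapply(mom$z[[g]], function(x) x[batch[[g]], , drop = FALSE]))

  # --- weights: interpolate natural statistics, then recompute q(W) ---
  for (m in seq_len(pp$M)) {
    W <- state$W[[m]]
    nat <- state$Wnat[[m]]
    Ea <- state$alpha_w[[m]]$a / state$alpha_w[[m]]$b
    tt <- theta_tilde(state$theta_w[[m]])
    EW <- W$g * W$mu
    Ab <- Abm <- 0
    for (g in seq_len(pp$G)) {
      Ab <- Ab + scale[g] * crossprod(TYb[[g]][[m]]$T, zb[[g]]$E2)
      Abm <- Abm + scale[g] * crossprod(TYb[[g]][[m]]$T, zb[[g]]$E^2)
    }
    R <- lapply(seq_len(pp$G), function(g)
      TYb[[g]][[m]]$Yt - zb[[g]]$E %*% t(EW))
    for (k in seq_len(K)) {
      Bk <- Abm[, k] * EW[, k]
      for (g in seq_len(pp$G)) {
        Bk <- Bk + scale[g] * crossprod(TYb[[g]][[m]]$T * R[[g]], zb[[g]]$E[, k])
      }
      nat$A[, k] <- (1 - rho) * nat$A[, k] + rho * Ab[, k]
      nat$B[, k] <- (1 - rho) * nat$B[, k] + rho * Bk
      s1 <- 1 / (Ea[k] + nat$A[, k])
      mu1 <- s1 * nat$B[, k]
      gam <- sigmoid(tt[k] + 0.5 * log(Ea[k] * s1) + 0.5 * mu1^2 / s1)
      neww <- gam * mu1
      dw <- neww - EW[, k]
      for (g in seq_len(pp$G)) {
        R[[g]] <- R[[g]] - tcrossprod(zb[[g]]$E[, k], dw)
      }
      EW[, k] <- neww
      W$mu[, k] <- mu1
      W$s2[, k] <- s1
      W$g[, k] <- gam
      W$s0[k] <- 1 / Ea[k]
    }
    state$W[[m]] <- W
    state$Wnat[[m]] <- nat
    mom$w[[m]] <- w_moments(W)
  }

  # --- factors: exact update restricted to batch rows ---
  res <- update_Z(state, pp, TYb, mom, rows = batch)
  state <- res$state
  mom <- res$mom

  pr <- state$opts$priors
  interp <- function(old, hat) (1 - rho) * old + rho * hat

  for (m in seq_len(pp$M)) {
    state$alpha_w[[m]]$a <- interp(state$alpha_w[[m]]$a, rep(pr$alpha_a + pp$D[m] / 2, K))
    state$alpha_w[[m]]$b <- interp(state$alpha_w[[m]]$b,
                                   pr$alpha_b + 0.5 * colSums(mom$w[[m]]$Ehat2))
    sg <- colSums(state$W[[m]]$g)
    state$theta_w[[m]]$a <- interp(state$theta_w[[m]]$a, pr$theta_a + sg)
    state$theta_w[[m]]$b <- interp(state$theta_w[[m]]$b, pr$theta_b + pp$D[m] - sg)
  }
  if (isTRUE(state$opts$ard_factors)) {
    for (g in seq_len(pp$G)) {
      zhat2 <- mom$z[[g]]$Ehat2[batch[[g]], , drop = FALSE]
      state$alpha_z[[g]]$a <- interp(state$alpha_z[[g]]$a, rep(pr$alpha_a + pp$N[g] / 2, K))
      state$alpha_z[[g]]$b <- interp(state$alpha_z[[g]]$b,
                                     pr$alpha_b + 0.5 * scale[g] * colSums(zhat2))
    }
  }
  if (isTRUE(state$opts$spike_factors)) {
    for (g in seq_len(pp$G)) {
      sgz <- scale[g] * colSums(state$Z[[g]]$g[batch[[g]], , drop = FALSE])
      state$theta_z[[g]]$a <- interp(state$theta_z[[g]]$a, pr$theta_a + sgz)
      state$theta_z[[g]]$b <- interp(state$theta_z[[g]]$b, pr$theta_b + pp$N[g] - sgz)
    }
  }
  for (g in seq_len(pp$G)) for (m in seq_len(pp$M)) {
    if (pp$lik[[m]] != "gaussian") next
    r <- batch[[g]]
    Predb <- mom$z[[g]]$E[r, , drop = FALSE] %*% t(mom$w[[m]]$E)
    zbm <- lapply(mom$z[[g]], function(x) x[r, , drop = FALSE])
    Vb <- pred_var(zbm, mom$w[[m]])
    Mb <- pp$mask[[g]][[m]][r, , drop = FALSE]
    Yb <- pp$Y0[[g]][[m]][r, , drop = FALSE]
    SSb <- colSums(Mb * ((Yb - Predb)^2 + Vb))
    state$tau[[g]][[m]]$a <- interp(state$tau[[g]][[m]]$a,
                                    pr$tau_a + scale[g] * colSums(Mb) / 2)
    state$tau[[g]][[m]]$b <- interp(state$tau[[g]][[m]]$b,
                                    pr$tau_b + scale[g] * SSb / 2)
  }
  check_finite_state(state)
  state
}

# One epoch: a freshly shuffled batch plan, one svi_step per batch; the
# step counter t (and hence rho) advances per batch.
svi_epoch <- function(state, pp, epoch) {
  ctl <- state$opts
  plan <- make_batch_plan(pp$N, ctl$batch_fraction,
                          seed = ctl$seed + 131L * epoch)
  for (b in seq_along(plan)) {
    rho <- svi_learning_rate(state$tstep, ctl$lr_start, ctl$forgetting_rate)
    rho <- min(rho, 1)
    state <- svi_step(state, pp, plan[[b]], rho)
    state$tstep <- state$tstep + 1L
  }
  state
}
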