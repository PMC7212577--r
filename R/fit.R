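#' Training options for [sgfa()]
#'
#' @param tol Convergence tolerance on the change in the evidence lower
#'   bound (ELBO) between consecutive iterations; training stops when
#'   `|ELBO_i - ELBO_{i-1}| < tol` (default `1e-4`).
#' @param convergence `"absolute"` applies `tol` to the raw ELBO
#'   difference; `"relative"` divides the difference by `|ELBO_{i-1}|`
#'   first (useful because the absolute rule is scale dependent).
#' @param maxit Maximum number of iterations (full sweeps, or epochs in
#'   stochastic mode).
#' @param mode `"vi"` for deterministic mean-field coordinate ascent,
#'   `"svi"` for stochastic variational inference with mini-batches and
#'   natural-parameter interpolation.
#' @param batch_fraction Mini-batch size as a fraction of each group
#'   (stochastic mode; default 0.5).
#' @param lr_start Starting learning rate `tau` of the step-size schedule
#'   `rho(t) = tau / (1 + kappa t)^{3/4}` (default 1.0).
#' @param forgetting_rate Decay parameter `kappa` of the schedule
#'   (default 0.25).
#' @param seed Integer seed controlling mini-batch shuffling (the default
#'   deterministic initialization uses no randomness).
#' @param alpha_a,alpha_b Gamma prior on the ARD precisions (broad,
#'   uninformative default `1e-5`).
#' @param tau_a,tau_b Gamma prior on the noise precisions.
#' @param theta_a,theta_b Beta prior on the spike-and-slab inclusion
#'   levels (uniform default).
#' @param ard_factors Apply ARD precisions per (factor, group) on the
#'   factor side (the multi-group regularization).  With a single group
#'   and `ard_factors = FALSE, spike_factors = FALSE` the prior structure
#'   reduces to weight-side-only regularization.
#' @param spike_factors Also apply spike-and-slab sparsity to individual
#'   factor values (off by default).
#' @param drop_inactive Drop factors that collapse to an effective zero
#'   (`max |E[z]| < 1e-10`) during training.
#' @param verbose Print the ELBO per iteration.
#' @return A named list of validated options.
#' @export
sgfa_control <- function(tol = 1e-4, convergence = c("absolute", "relative"),
                         maxit = 200L, mode = c("vi", "svi"),
                         batch_fraction = 0.5, lr_start = 1.0,
                         forgetting_rate = 0.25, seed = 42L,
                         alpha_a = 1e-5, alpha_b = 1e-5,
                         tau_a = 1e-5, tau_b = 1e-5,
                         theta_a = 1, theta_b = 1,
                         ard_factors = TRUE, spike_factors = FALSE,
                         drop_inactive = TRUE, verbose = FALSE) {
  convergence <- match.arg(convergence)
  mode <- match.arg(mode)
  stopifnot(tol > 0, maxit >= 1,
            batch_fraction > 0, batch_fraction <= 1,
            lr_start > 0, forgetting_rate >= 0,
            alpha_a > 0, alpha_b > 0, tau_a > 0, tau_b > 0,
            theta_a > 0, theta_b > 0)
  list(tol = tol, convergence = convergence, maxit = as.integer(maxit),
       mode = mode, batch_fraction = batch_fraction, lr_start = lr_start,
       forgetting_rate = forgetting_rate, seed = as.integer(seed),
       priors = list(alpha_a = alpha_a, alpha_b = alpha_b,
                     tau_a = tau_a, tau_b = tau_b,
                     theta_a = theta_a, theta_b = theta_b),
       ard_factors = isTRUE(ard_factors), spike_factors = isTRUE(spike_factors),
       drop_inactive = isTRUE(drop_inactive), verbose = isTRUE(verbose))
}

make_pp <- function(ds) {
  G <- length(ds$groups)
  M <- length(ds$views)
  Y0 <- mask <- nobs <- stats::setNames(vector("list", G), ds$groups)
  for (g in seq_len(G)) {
    Y0[[g]] <- mask[[g]] <- nobs[[g]] <- stats::setNames(vector("list", M), ds$views)
    for (m in seq_len(M)) {
      Msk <- ds$masks[[ds$groups[g]]][[ds$views[m]]]
      B <- ds$blocks[[ds$groups[g]]][[ds$views[m]]]
      Y0[[g]][[m]] <- B * Msk  # values at unobserved positions never leak in
      mask[[g]][[m]] <- Msk * 1
      nobs[[g]][[m]] <- colSums(Msk)
    }
  }
  list(G = G, M = M,
       N = vapply(ds$samples, length, 1L),
       D = vapply(ds$features, length, 1L),
       lik = unname(ds$likelihoods[ds$views]),
       groups = ds$groups, views = ds$views,
       Y0 = Y0, mask = mask, nobs = nobs)
}

# Deterministic initialization: factors start at the principal component
# scores of the feature-wise concatenated, group-wise stacked data (missing
# entries contribute zero); the sign of each component is made canonical via
# its right singular vector so the result is invariant to row permutations.
init_state <- function(pp, K, control) {
  X <- do.call(rbind, lapply(seq_len(pp$G), function(g) {
    do.call(cbind, lapply(seq_len(pp$M), function(m) {
      B <- pp$Y0[[g]][[m]]
      M <- pp$mask[[g]][[m]]
      nob <- colSums(M)
      mu <- ifelse(nob > 0, colSums(B * M) / pmax(nob, 1), 0)
      Bc <- sweep(B, 2L, mu, "-")
      Bc[M == 0] <- 0
      Bc
    }))
  }))
  Kmax <- min(nrow(X), ncol(X))
  if (K > Kmax) {
    warning(sprintf("K = %d exceeds the feasible rank %d; reduced", K, Kmax))
    K <- Kmax
  }
  sv <- svd(X, nu = K, nv = K)
  for (k in seq_len(K)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$u[, k] <- -sv$u[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  scores <- sv$u * rep(sv$d[seq_len(K)], each = nrow(X))
  offsets <- cumsum(c(0L, pp$N))
  pr <- control$priors

  state <- list(K = K, opts = control, tstep = 0L)
  state$Z <- lapply(seq_len(pp$G), function(g) {
    mu <- scores[(offsets[g] + 1):offsets[g + 1L], , drop = FALSE]
    z <- list(mu = mu, s2 = matrix(1, pp$N[g], K))
    if (control$spike_factors) {
      z$g <- matrix(0.5, pp$N[g], K)
      z$s0 <- rep(1, K)
    }
    z
  })
  state$W <- lapply(seq_len(pp$M), function(m) {
    list(mu = matrix(0, pp$D[m], K), s2 = matrix(1, pp$D[m], K),
         g = matrix(0.5, pp$D[m], K), s0 = rep(pr$alpha_b / pr$alpha_a, K))
  })
  state$alpha_w <- lapply(seq_len(pp$M), function(m)
    list(a = rep(pr$alpha_a, K), b = rep(pr$alpha_b, K)))
  state$theta_w <- lapply(seq_len(pp$M), function(m)
    list(a = rep(pr$theta_a, K), b = rep(pr$theta_b, K)))
  if (control$ard_factors) {
    state$alpha_z <- lapply(seq_len(pp$G), function(g)
      list(a = rep(pr$alpha_a, K), b = rep(pr$alpha_b, K)))
  }
  if (control$spike_factors) {
    state$theta_z <- lapply(seq_len(pp$G), function(g)
      list(a = rep(pr$theta_a, K), b = rep(pr$theta_b, K)))
  }
  state$tau <- lapply(seq_len(pp$G), function(g) {
    lapply(seq_len(pp$M), function(m) {
      if (pp$lik[[m]] == "gaussian") {
        list(a = rep(pr$tau_a, pp$D[m]), b = rep(pr$tau_b, pp$D[m]))
      } else NULL
    })
  })
  state$zeta <- lapply(seq_len(pp$G), function(g) {
    lapply(seq_len(pp$M), function(m) {
      if (pp$lik[[m]] != "gaussian") matrix(1, pp$N[g], pp$D[m]) else NULL
    })
  })
  state$Wnat <- lapply(seq_len(pp$M), function(m)
    list(A = matrix(0, pp$D[m], K), B = matrix(0, pp$D[m], K)))
  state
}

subset_factors <- function(state, idx) {
  state$K <- length(idx)
  state$W <- lapply(state$W, function(W) {
    list(mu = W$mu[, idx, drop = FALSE], s2 = W$s2[, idx, drop = FALSE],
         g = W$g[, idx, drop = FALSE], s0 = W$s0[idx])
  })
  state$Z <- lapply(state$Z, function(Z) {
    z <- list(mu = Z$mu[, idx, drop = FALSE], s2 = Z$s2[, idx, drop = FALSE])
    if (!is.null(Z$g)) {
      z$g <- Z$g[, idx, drop = FALSE]
      z$s0 <- Z$s0[idx]
    }
    z
  })
  sub_ab <- function(x) list(a = x$a[idx], b = x$b[idx])
  state$alpha_w <- lapply(state$alpha_w, sub_ab)
  state$theta_w <- lapply(state$theta_w, sub_ab)
  if (!is.null(state$alpha_z)) state$alpha_z <- lapply(state$alpha_z, sub_ab)
  if (!is.null(state$theta_z)) state$theta_z <- lapply(state$theta_z, sub_ab)
  state$Wnat <- lapply(state$Wnat, function(n)
    list(A = n$A[, idx, drop = FALSE], B = n$B[, idx, drop = FALSE]))
  state
}

# effective-zero rule used during training
active_factors <- function(state) {
  mx <- rep(0, state$K)
  for (g in seq_along(state$Z)) {
    EZ <- if (!is.null(state$Z[[g]]$g)) state$Z[[g]]$g * state$Z[[g]]$mu else state$Z[[g]]$mu
    mx <- pmax(mx, apply(abs(EZ), 2L, max))
  }
  mx >= 1e-10
}

#' Fit a sparse Bayesian group factor analysis model
#'
#' Infers `K` latent factors from a multi-group, multi-view data set by
#' mean-field variational inference.  Factors are initialized at the
#' principal components of the concatenated data (no randomness in the
#' default path); ARD priors then switch factors off per view and per
#' group, so `K` only needs to be an upper bound on the number of factors.
#' Convergence is declared when the change in the evidence lower bound
#' falls below `control$tol`.
#'
#' Gaussian views are centered per group before fitting (intercepts are
#' regressed out) unless `center = FALSE`; the removed means are kept so
#' that [predict()] can restore them.  Missing entries are handled by
#' restricting all sufficient statistics to observed positions; nothing is
#' imputed during inference.
#'
#' @param data An [sgfa_data] object, a long-format `data.frame`, or a
#'   nested list of matrices `data[[group]][[view]]`.
#' @param K Starting (maximum) number of factors.
#' @param likelihoods Per-view likelihoods, see [sgfa_data()].
#' @param center Center Gaussian views per group (default `TRUE`).
#' @param min_r2 If positive, prune factors explaining less than this
#'   fraction of variance in every (group, view) block after training
#'   (the conventional filter is 0.01, i.e. 1%).
#' @param control Training options from [sgfa_control()].
#' @param ... Convenience overrides for single [sgfa_control()] arguments.
#' @return An object of class `"sgfa"` with components `state`
#'   (variational posteriors), `trace` (per-iteration ELBO and active
#'   factor count), `r2` (variance decomposition), `data` (the centered
#'   input), `K`, `elbo`, `converged`.
#' @examples
#' sim <- sgfa_simulate(G = 1, M = 1, K = 2, N = 60, D = 40,
#'                      noise_var = 0.25, seed = 1)
#' fit <- sgfa(sim$data, K = 3, maxit = 30, verbose = FALSE)
#' fit
#' @export
sgfa <- function(data, K = 10, likelihoods = NULL, center = TRUE,
                 min_r2 = 0, control = sgfa_control(), ...) {
  extra <- list(...)
  if (length(extra)) {
    control <- do.call(sgfa_control, utils::modifyList(
      control[setdiff(names(control), "priors")] |>
        c(control$priors), extra))
  }
  if (!inherits(data, "sgfa_data")) data <- sgfa_data(data, likelihoods)
  gauss <- names(data$likelihoods)[data$likelihoods == "gaussian"]
  if (center && length(gauss) && !all(data$centered[gauss])) {
    data <- center_per_group(data)
  }
  pp <- make_pp(data)
  if (K < 1) stop("K must be >= 1")
  state <- init_state(pp, K, control)

  trace_elbo <- numeric(0)
  trace_active <- integer(0)
  elbo_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(control$maxit)) {
    state <- if (control$mode == "vi") {
      vi_iteration(state, pp)
    } else {
      svi_epoch(state, pp, epoch = it)
    }
    if (control$drop_inactive) {
      act <- active_factors(state)
      if (!all(act) && any(act)) state <- subset_factors(state, which(act))
    }
    e <- compute_elbo(state, pp)
    if (!is.finite(e)) {
      stop(sprintf("ELBO became non-finite at iteration %d; trace: %s", it,
                   paste(signif(trace_elbo, 8), collapse = ", ")))
    }
    trace_elbo <- c(trace_elbo, e)
    trace_active <- c(trace_active, state$K)
    if (control$verbose) {
      message(sprintf("iter %3d  ELBO %.6f  (K = %d)", it, e, state$K))
    }
    delta <- abs(e - elbo_prev)
    if (control$convergence == "relative") delta <- delta / abs(elbo_prev)
    if (it > 1L && is.finite(delta) && delta < control$tol) {
      converged <- TRUE
      elbo_prev <- e
      break
    }
    elbo_prev <- e
  }

  fit <- structure(list(
    state = state,
    trace = data.frame(iteration = seq_along(trace_elbo), elbo = trace_elbo,
                       active_factors = trace_active),
    data = data,
    K = state$K,
    control = control,
    elbo = trace_elbo[length(trace_elbo)],
    converged = converged,
    mode = control$mode,
    call = match.call()
  ), class = "sgfa")
  fit$r2 <- variance_explained(fit)
  if (min_r2 > 0) fit <- prune_factors(fit, min_r2)
  fit
}

#' Remove factors below a variance-explained threshold
#'
#' Drops every factor whose variance explained (R-squared) is below
#' `min_r2` in *all* (group, view) blocks, and renumbers the remaining
#' factors in decreasing order of total variance explained.  The
#' conventional post-training filter keeps factors explaining at least 1%
#' of variance somewhere (`min_r2 = 0.01`).
#'
#' @param object A fitted `"sgfa"` model.
#' @param min_r2 Threshold on the fraction-scale R-squared (`>= 0`).
#' @return The model with pruned, reordered factors and refreshed `r2`.
#' @export
prune_factors <- function(object, min_r2 = 0.01) {
  stopifnot(inherits(object, "sgfa"), min_r2 >= 0)
  raw <- object$r2$raw
  keep <- which(apply(raw, 1L, function(x) any(x >= min_r2, na.rm = TRUE)) |
                  rep(min_r2 == 0, dim(raw)[1L]))
  if (length(keep) == 0L) {
    warning("all factors pruned; returning an empty model (K = 0)")
    object$state <- subset_factors(object$state, integer(0))
    object$K <- 0L
    object$r2 <- variance_explained(object)
    return(object)
  }
  tot <- apply(pmax(raw[keep, , , drop = FALSE], 0), 1L, sum, na.rm = TRUE)
  keep <- keep[order(-tot)]
  object$state <- subset_factors(object$state, keep)
  object$K <- length(keep)
  object$r2 <- variance_explained(object)
  object
}
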