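#' Simulate data from the generative model
#'
#' Draws a multi-group, multi-view data set from the group factor analysis
#' generative model, for validation and parameter-recovery experiments.
#' Factor values are zero-mean normal with per-(factor, group) scales
#' (`activity_groups`), weights are spike-and-slab with inclusion
#' probability `theta_w` and per-(factor, view) slab scales
#' (`activity_views`).  Setting an activity scale to zero switches a
#' factor off in that group or view, which is the designed "differential
#' activity" pattern the model is meant to recover.  Gaussian blocks add
#' noise of variance `noise_var`; Bernoulli blocks draw from
#' `sigmoid(Z W')`; Poisson blocks from `Poisson(softplus(Z W'))`.
#' A `missing` fraction of entries is masked uniformly at random
#' (completely at random, independent of values).
#'
#' Draws for different groups and views come from independently derived
#' random streams, so e.g. changing the size of view 2 does not perturb
#' view 1's values.
#'
#' @param G,M,K Numbers of groups, views and factors.
#' @param N,D Samples per group and features per view (recycled to length
#'   `G` / `M`).
#' @param likelihoods Per-view likelihood (recycled).
#' @param activity_groups K x G matrix of factor scales per group
#'   (default: all 1).
#' @param activity_views K x M matrix of weight slab scales per view.
#' @param theta_w Weight inclusion probability, scalar or K x M matrix
#'   (default 1: dense weights).
#' @param noise_var Gaussian noise variance per view.
#' @param missing Fraction of entries masked at random, in `[0, 1)`.
#' @param seed Root seed; identical seeds give identical output.
#' @return A list with `data` (an [sgfa_data] object) and `truth`
#'   (`Z` per group, `W` per view, the activity matrices and noise
#'   variances).
#' @examples
#' sim <- sgfa_simulate(G = 2, M = 2, K = 3, N = 50, D = 40, seed = 1)
#' sim$data
#' @export
sgfa_simulate <- function(G = 3, M = 2, K = 5,
                          N = 500, D = 1000,
                          likelihoods = "gaussian",
                          activity_groups = NULL, activity_views = NULL,
                          theta_w = 1, noise_var = 1,
                          missing = 0, seed = 1) {
  stopifnot(G >= 1, M >= 1, K >= 1, missing >= 0, missing < 1)
  N <- rep_len(N, G)
  D <- rep_len(D, M)
  likelihoods <- rep_len(likelihoods, M)
  noise_var <- rep_len(noise_var, M)
  if (is.null(activity_groups)) activity_groups <- matrix(1, K, G)
  if (is.null(activity_views)) activity_views <- matrix(1, K, M)
  if (length(theta_w) == 1L) theta_w <- matrix(theta_w, K, M)
  stopifnot(all(dim(activity_groups) == c(K, G)),
            all(dim(activity_views) == c(K, M)),
            all(dim(theta_w) == c(K, M)),
            all(activity_groups >= 0), all(activity_views >= 0),
            all(theta_w >= 0 & theta_w <= 1), all(noise_var >= 0))
  for (m in seq_len(M)) {
    if (likelihoods[m] == "gaussian" && noise_var[m] == 0 &&
        all(activity_views[, m] * max(activity_groups) == 0)) {
      stop(sprintf("view %d would be a constant block (all activity zero, no noise)", m))
    }
  }

  seed <- as.integer(seed)
  dseed <- function(off) (seed * 97L + off) %% .Machine$integer.max

  W <- lapply(seq_len(M), function(m) {
    set.seed(dseed(1000L + m))
    s <- matrix(rbinom(D[m] * K, 1L, rep(theta_w[, m], each = D[m])), D[m], K)
    w <- matrix(rnorm(D[m] * K, sd = rep(activity_views[, m], each = D[m])), D[m], K)
    out <- s * w
    dimnames(out) <- list(paste0("view", m, "_f", seq_len(D[m])),
                          paste0("Factor", seq_len(K)))
    out
  })
  Z <- lapply(seq_len(G), function(g) {
    set.seed(dseed(2000L + g))
    z <- matrix(rnorm(N[g] * K, sd = rep(activity_groups[, g], each = N[g])), N[g], K)
    dimnames(z) <- list(paste0("group", g, "_s", seq_len(N[g])),
                        paste0("Factor", seq_len(K)))
    z
  })

  blocks <- stats::setNames(vector("list", G), paste0("group", seq_len(G)))
  for (g in seq_len(G)) {
    blocks[[g]] <- stats::setNames(vector("list", M), paste0("view", seq_len(M)))
    for (m in seq_len(M)) {
      X <- Z[[g]] %*% t(W[[m]])
      set.seed(dseed(3000L + 100L * g + m))
      Y <- switch(likelihoods[m],
        gaussian = X + matrix(rnorm(length(X), sd = sqrt(noise_var[m])), nrow(X)),
        bernoulli = matrix(rbinom(length(X), 1L, sigmoid(X)), nrow(X)),
        poisson = matrix(rpois(length(X), softplus(X)), nrow(X)),
        stop("unknown likelihood: ", likelihoods[m])
      )
      if (missing > 0) {
        set.seed(dseed(4000L + 100L * g + m))
        Y[runif(length(Y)) < missing] <- NA
      }
      dimnames(Y) <- list(rownames(Z[[g]]), rownames(W[[m]]))
      blocks[[g]][[m]] <- Y
    }
  }
  data <- sgfa_data(blocks, likelihoods = stats::setNames(likelihoods,
                                                          paste0("view", seq_len(M))))
  truth <- list(Z = Z, W = W,
                activity_groups = activity_groups,
                activity_views = activity_views,
                theta_w = theta_w, noise_var = noise_var,
                likelihoods = likelihoods)
  list(data = data, truth = truth)
}

# Greedy one-to-one matching of inferred to true factors by maximal
# absolute correlation of the (group-concatenated) factor values.
match_factors <- function(Z_true, Z_est) {
  Kt <- ncol(Z_true)
  Ke <- ncol(Z_est)
  C <- abs(suppressWarnings(cor(Z_true, Z_est)))
  C[!is.finite(C)] <- 0
  match <- rep(NA_integer_, Kt)
  for (i in seq_len(min(Kt, Ke))) {
    j <- which(C == max(C), arr.ind = TRUE)[1L, ]
    match[j[1L]] <- j[2L]
    C[j[1L], ] <- -Inf
    C[, j[2L]] <- -Inf
  }
  match
}

#' Score recovery of a designed factor activity pattern
#'
#' Compares the binarized inferred factor activity -- variance explained
#' at least `threshold` in a (group) or (view) -- against the true
#' activity pattern used to simulate the data.  Inferred factors are
#' matched one-to-one to true factors by greedy maximal absolute
#' correlation of the factor values; true factors without a match (fewer
#' inferred than true factors) count all their cells as mismatches.
#'
#' @param truth The `truth` component of [sgfa_simulate()] output.
#' @param fit A fitted `"sgfa"` model on the simulated data.
#' @param threshold Fraction-of-variance activity threshold (the
#'   conventional filter is 0.01).
#' @return Fraction in `[0, 1]` of correctly recovered (factor, group)
#'   and (factor, view) activity cells.
#' @export
activity_recovery_score <- function(truth, fit, threshold = 0.01) {
  stopifnot(inherits(fit, "sgfa"))
  r2 <- fit$r2$raw
  G <- dim(r2)[2L]
  M <- dim(r2)[3L]
  Kt <- ncol(truth$Z[[1L]])
  true_g <- truth$activity_groups > 0
  true_m <- truth$activity_views > 0

  Z_true <- do.call(rbind, truth$Z)
  EZ <- do.call(rbind, lapply(fit$state$Z, function(Z)
    if (!is.null(Z$g)) Z$g * Z$mu else Z$mu))
  matched <- if (fit$K > 0) match_factors(Z_true, EZ) else rep(NA_integer_, Kt)

  correct <- 0L
  for (k in seq_len(Kt)) {
    j <- matched[k]
    if (is.na(j)) next  # unmatched true factor: all cells mismatch
    inf_g <- vapply(seq_len(G), function(g) max(r2[j, g, ]) >= threshold, TRUE)
    inf_m <- vapply(seq_len(M), function(m) max(r2[j, , m]) >= threshold, TRUE)
    correct <- correct + sum(inf_g == true_g[k, ]) + sum(inf_m == true_m[k, ])
  }
  correct / (Kt * (G + M))
}
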