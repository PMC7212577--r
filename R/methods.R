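# S3 methods for fitted models.

#' @export
print.sgfa <- function(x, ...) {
  cat("Sparse Bayesian group factor analysis fit\n")
  cat(sprintf("  %d factor(s), %d group(s), %d view(s)\n",
              x$K, length(x$data$groups), length(x$data$views)))
  cat(sprintf("  inference: %s, %d iteration(s), %s\n",
              toupper(x$mode), nrow(x$trace),
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  final ELBO: %.4f\n", x$elbo))
  invisible(x)
}

#' @export
summary.sgfa <- function(object, ...) {
  print(object)
  cat("\nTotal variance explained per (group, view):\n")
  print(round(object$r2$total, 3))
  if (object$K) {
    cat("\nVariance explained per factor (max over blocks):\n")
    print(round(apply(object$r2$r2, 1L, max, na.rm = TRUE), 3))
  }
  invisible(list(K = object$K, elbo = object$elbo, r2 = object$r2))
}

#' Posterior mean weights
#'
#' @param object A fitted `"sgfa"` model.
#' @param ... Unused.
#' @return A list of features x factors weight matrices, one per view.
#' @export
coef.sgfa <- function(object, ...) {
  out <- lapply(seq_along(object$data$views), function(m) {
    W <- object$state$W[[m]]
    EW <- W$g * W$mu
    dimnames(EW) <- list(object$data$features[[m]],
                         if (object$K) paste0("Factor", seq_len(object$K)))
    EW
  })
  stats::setNames(out, object$data$views)
}

#' Model-based reconstruction and imputation
#'
#' Returns the posterior-mean reconstruction `E[Z_g] E[W_m]^T` of every
#' block, mapped through the view's link: Gaussian views get their
#' per-group feature means added back, Bernoulli views return success
#' probabilities in `[0, 1]`, Poisson views return softplus rates.  The
#' reconstruction is defined at unobserved positions as well, which makes
#' it the model's imputation output ("denoising").
#'
#' @param object A fitted `"sgfa"` model.
#' @param type `"response"` (link scale, intercepts restored) or `"link"`
#'   (raw linear predictor).
#' @param ... Unused.
#' @return Nested list of matrices `[[group]][[view]]`.
#' @export
predict.sgfa <- function(object, type = c("response", "link"), ...) {
  type <- match.arg(type)
  mom <- all_moments(object$state)
  ds <- object$data
  out <- stats::setNames(vector("list", length(ds$groups)), ds$groups)
  for (g in seq_along(ds$groups)) {
    out[[g]] <- stats::setNames(vector("list", length(ds$views)), ds$views)
    for (m in seq_along(ds$views)) {
      P <- mom$z[[g]]$E %*% t(mom$w[[m]]$E)
      dimnames(P) <- list(ds$samples[[g]], ds$features[[m]])
      if (type == "response") {
        lik <- ds$likelihoods[[ds$views[m]]]
        if (lik == "gaussian") {
          mu <- ds$feature_means[[ds$groups[g]]][[ds$views[m]]]
          if (!is.null(mu)) P <- sweep(P, 2L, mu, "+")
        } else if (lik == "bernoulli") {
          P <- sigmoid(P)
        } else {
          P <- softplus(P)
        }
      }
      out[[g]][[m]] <- P
    }
  }
  out
}

#' @export
fitted.sgfa <- function(object, ...) predict(object, type = "response")

#' Residuals at observed positions
#'
#' Observed value minus model reconstruction (response scale); `NA` at
#' unobserved positions.
#'
#' @param object A fitted `"sgfa"` model.
#' @param ... Unused.
#' @export
residuals.sgfa <- function(object, ...) {
  fit <- predict(object, type = "response")
  ds <- object$data
  for (g in seq_along(ds$groups)) for (m in seq_along(ds$views)) {
    B <- ds$blocks[[g]][[m]]
    Msk <- ds$masks[[g]][[m]]
    lik <- ds$likelihoods[[ds$views[m]]]
    if (lik == "gaussian") {
      mu <- ds$feature_means[[ds$groups[g]]][[ds$views[m]]]
      if (!is.null(mu)) B <- sweep(B, 2L, mu, "+")  # de-center to response scale
    }
    R <- B - fit[[g]][[m]]
    R[!Msk] <- NA_real_
    fit[[g]][[m]] <- R
  }
  fit
}

#' Variance-explained heatmap
#'
#' Displays the fraction of variance explained per factor (rows) in each
#' (group, view) block (columns).
#'
#' @param x A fitted `"sgfa"` model.
#' @param ... Passed to [graphics::image()].
#' @export
plot.sgfa <- function(x, ...) {
  r2 <- x$r2$r2
  if (!dim(r2)[1L]) {
    warning("no factors to plot")
    return(invisible(x))
  }
  K <- dim(r2)[1L]
  combos <- expand.grid(group = dimnames(r2)[[2L]], view = dimnames(r2)[[3L]],
                        stringsAsFactors = FALSE)
  M <- matrix(NA_real_, K, nrow(combos))
  for (j in seq_len(nrow(combos))) {
    M[, j] <- r2[, combos$group[j], combos$view[j]]
  }
  op <- graphics::par(mar = c(6, 5, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(nrow(combos)), seq_len(K), t(M[K:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  xlab = "", ylab = "", axes = FALSE,
                  main = "Variance explained", ...)
  graphics::axis(1, at = seq_len(nrow(combos)),
                 labels = paste(combos$group, combos$view, sep = " / "), las = 2)
  graphics::axis(2, at = seq_len(K), labels = rev(rownames(r2)), las = 1)
  invisible(x)
}

#' Draw data sets from a fitted model
#'
#' Simulates new observations from the generative model at the posterior
#' means: Gaussian views add noise with variance `1 / E[tau]`, Bernoulli
#' views draw from the predicted success probabilities, Poisson views
#' from the predicted rates.  Observed/missing patterns are inherited.
#'
#' @param object A fitted `"sgfa"` model.
#' @param nsim Number of replicate data sets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` nested block lists.
#' @export
simulate.sgfa <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  link <- predict(object, type = "response")
  ds <- object$data
  replicate(nsim, {
    out <- link
    for (g in seq_along(ds$groups)) for (m in seq_along(ds$views)) {
      lik <- ds$likelihoods[[ds$views[m]]]
      P <- link[[g]][[m]]
      out[[g]][[m]] <- if (lik == "gaussian") {
        sds <- sqrt(object$state$tau[[g]][[m]]$b / object$state$tau[[g]][[m]]$a)
        P + matrix(rnorm(length(P), sd = rep(sds, each = nrow(P))), nrow(P))
      } else if (lik == "bernoulli") {
        matrix(rbinom(length(P), 1L, P), nrow(P), dimnames = dimnames(P))
      } else {
        matrix(rpois(length(P), P), nrow(P), dimnames = dimnames(P))
      }
    }
    out
  }, simplify = FALSE)
}

#' Evidence lower bound of a fitted model
#'
#' @param object A fitted `"sgfa"` model.
#' @param recompute Recompute the ELBO from the stored posteriors and data
#'   instead of returning the value recorded at the end of training.
#' @export
elbo <- function(object, recompute = FALSE) {
  stopifnot(inherits(object, "sgfa"))
  if (!recompute) return(object$elbo)
  if (is.null(object$data) || is.null(object$data$blocks)) {
    stop("cannot recompute the ELBO: this model was saved without its data")
  }
  compute_elbo(object$state, make_pp(object$data))
}

#' @export
logLik.sgfa <- function(object, ...) {
  structure(object$elbo, df = NA_integer_, class = "logLik")
}
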