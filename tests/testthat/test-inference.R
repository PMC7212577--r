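test_that("initialization is deterministic and recovers a rank-1 structure exactly", {
  sim <- sgfa_simulate(G = 1, M = 1, K = 1, N = 30, D = 20,
                       noise_var = 0, seed = 2)
  ds <- center_per_group(sim$data)
  pp <- sgfa:::make_pp(ds)
  ctl <- sgfa_control()
  s1 <- sgfa:::init_state(pp, 1, ctl)
  s2 <- sgfa:::init_state(pp, 1, ctl)
  expect_identical(s1, s2)  # bit-identical re-runs
  expect_equal(abs(cor(s1$Z[[1]]$mu[, 1], sim$truth$Z[[1]][, 1])), 1,
               tolerance = 1e-8)
})

test_that("initialization handles degenerate inputs", {
  tab <- toy_long()
  tab$value <- 0
  pp <- sgfa:::make_pp(sgfa_data(tab))
  st <- sgfa:::init_state(pp, 1, sgfa_control())
  expect_true(all(st$Z[[1]]$mu == 0))
  expect_warning(sgfa:::init_state(pp, 5, sgfa_control()), "feasible rank")
})

test_that("the ELBO never decreases across VI sweeps (mixed likelihoods, missing data)", {
  configs <- list(
    list(lik = "gaussian", miss = 0.1),
    list(lik = c("gaussian", "bernoulli"), miss = 0.3),
    list(lik = c("bernoulli", "poisson"), miss = 0.2),
    list(lik = "poisson", miss = 0.25)
  )
  for (i in seq_along(configs)) {
    cf <- configs[[i]]
    sim <- sgfa_simulate(G = 2, M = length(cf$lik), K = 2, N = 25, D = 15,
                         likelihoods = cf$lik, noise_var = 0.5,
                         missing = cf$miss, seed = 40 + i)
    fit <- sgfa(sim$data, K = 3, control = quick_ctl(maxit = 20, tol = 1e-12))
    e <- fit$trace$elbo
    expect_true(all(diff(e) >= -1e-8 * abs(e[-length(e)])),
                label = paste("monotone ELBO for", paste(cf$lik, collapse = "+")))
  }
})

test_that("a converged state is a fixed point; perturbations recover monotonically", {
  sim <- sgfa_simulate(G = 1, M = 1, K = 2, N = 40, D = 25,
                       noise_var = 0.5, seed = 50)
  fit <- sgfa(sim$data, K = 2, control = quick_ctl(maxit = 200, tol = 1e-12))
  pp <- sgfa:::make_pp(fit$data)
  e0 <- sgfa:::compute_elbo(fit$state, pp)
  st <- sgfa:::vi_iteration(fit$state, pp)
  e1 <- sgfa:::compute_elbo(st, pp)
  expect_lt(abs(e1 - e0), 1e-6 * abs(e0))

  # perturb a posterior away from the optimum: the next sweeps climb back
  set.seed(1)
  st$W[[1]]$mu <- st$W[[1]]$mu + rnorm(length(st$W[[1]]$mu), sd = 0.2)
  ep <- sgfa:::compute_elbo(st, pp)
  expect_lt(ep, e0)
  for (i in 1:5) st <- sgfa:::vi_iteration(st, pp)
  e2 <- sgfa:::compute_elbo(st, pp)
  expect_gt(e2, ep)
})

test_that("values at masked positions never influence the fit", {
  sc <- toy_fit()
  d2 <- sc$sim$data
  set.seed(8)
  for (g in d2$groups) for (v in d2$views) {
    M <- d2$masks[[g]][[v]]
    d2$blocks[[g]][[v]][!M] <- rnorm(sum(!M), sd = 50)
  }
  f2 <- sgfa(d2, K = 2, control = quick_ctl())
  expect_identical(sc$fit$trace$elbo, f2$trace$elbo)
  expect_identical(sc$fit$state$Z, f2$state$Z)
  expect_identical(sc$fit$state$W, f2$state$W)
})

test_that("fits are deterministic given identical options", {
  sim <- sgfa_simulate(G = 1, M = 1, K = 2, N = 25, D = 15, seed = 60)
  f1 <- sgfa(sim$data, K = 2, control = quick_ctl(maxit = 10))
  f2 <- sgfa(sim$data, K = 2, control = quick_ctl(maxit = 10))
  expect_identical(f1$trace, f2$trace)
})

test_that("permuting samples within a group permutes factor rows and nothing else", {
  sc <- toy_fit()
  d <- sc$sim$data
  set.seed(3)
  perm <- sample(length(d$samples$group1))
  d2 <- d
  for (v in d$views) {
    d2$blocks$group1[[v]] <- d$blocks$group1[[v]][perm, ]
    d2$masks$group1[[v]] <- d$masks$group1[[v]][perm, ]
  }
  d2$samples$group1 <- d$samples$group1[perm]
  f2 <- sgfa(d2, K = 2, control = quick_ctl())
  expect_equal(f2$state$Z[[1]]$mu, sc$fit$state$Z[[1]]$mu[perm, ], tolerance = 1e-10)
  expect_equal(f2$state$W, sc$fit$state$W, tolerance = 1e-10)
  expect_equal(f2$state$Z[[2]], sc$fit$state$Z[[2]], tolerance = 1e-10)
})

test_that("the ELBO is invariant to a joint sign flip of one factor", {
  sc <- toy_fit()
  pp <- sgfa:::make_pp(sc$fit$data)
  st <- sc$fit$state
  for (g in seq_along(st$Z)) st$Z[[g]]$mu[, 1] <- -st$Z[[g]]$mu[, 1]
  for (m in seq_along(st$W)) st$W[[m]]$mu[, 1] <- -st$W[[m]]$mu[, 1]
  expect_equal(sgfa:::compute_elbo(st, pp),
               sgfa:::compute_elbo(sc$fit$state, pp), tolerance = 1e-12)
})

test_that("ELBO equals a Monte-Carlo estimate of E_q[log p - log q] on a tiny model", {
  sim <- sgfa_simulate(G = 1, M = 1, K = 1, N = 2, D = 2, noise_var = 0.5, seed = 8)
  pp <- sgfa:::make_pp(sim$data)
  ctl <- sgfa_control()
  state <- sgfa:::init_state(pp, 1, ctl)
  for (i in 1:5) state <- sgfa:::vi_iteration(state, pp)
  analytic <- sgfa:::compute_elbo(state, pp)

  pr <- ctl$priors
  W <- state$W[[1]]; Z <- state$Z[[1]]
  aw <- state$alpha_w[[1]]; az <- state$alpha_z[[1]]
  thw <- state$theta_w[[1]]; tau <- state$tau[[1]][[1]]
  Y <- pp$Y0[[1]][[1]]
  set.seed(42)
  nmc <- 1e5
  draws <- vapply(seq_len(nmc), function(i) {
    alpha <- rgamma(1, aw$a[1], aw$b[1])
    alphaz <- rgamma(1, az$a[1], az$b[1])
    theta <- rbeta(1, thw$a[1], thw$b[1])
    tauv <- rgamma(2, tau$a, tau$b)
    s <- rbinom(2, 1, W$g[, 1])
    what <- ifelse(s == 1, rnorm(2, W$mu[, 1], sqrt(W$s2[, 1])),
                   rnorm(2, 0, sqrt(W$s0[1])))
    z <- rnorm(2, Z$mu[, 1], sqrt(Z$s2[, 1]))
    lp <- sum(dnorm(Y, z %*% t(s * what), rep(sqrt(1 / tauv), each = 2), log = TRUE)) +
      sum(dnorm(what, 0, sqrt(1 / alpha), log = TRUE)) +
      sum(dbinom(s, 1, theta, log = TRUE)) +
      sum(dnorm(z, 0, sqrt(1 / alphaz), log = TRUE)) +
      dgamma(alpha, pr$alpha_a, pr$alpha_b, log = TRUE) +
      dgamma(alphaz, pr$alpha_a, pr$alpha_b, log = TRUE) +
      dbeta(theta, pr$theta_a, pr$theta_b, log = TRUE) +
      sum(dgamma(tauv, pr$tau_a, pr$tau_b, log = TRUE))
    lq <- dgamma(alpha, aw$a[1], aw$b[1], log = TRUE) +
      dgamma(alphaz, az$a[1], az$b[1], log = TRUE) +
      dbeta(theta, thw$a[1], thw$b[1], log = TRUE) +
      sum(dgamma(tauv, tau$a, tau$b, log = TRUE)) +
      sum(dbinom(s, 1, W$g[, 1], log = TRUE)) +
      sum(ifelse(s == 1, dnorm(what, W$mu[, 1], sqrt(W$s2[, 1]), log = TRUE),
                 dnorm(what, 0, sqrt(W$s0[1]), log = TRUE))) +
      sum(dnorm(z, Z$mu[, 1], sqrt(Z$s2[, 1]), log = TRUE))
    lp - lq
  }, 0)
  se <- sd(draws) / sqrt(nmc)
  expect_lt(abs(mean(draws) - analytic), 3 * se)
})

test_that("an ELBO with no observations reduces to minus the KL to the priors", {
  tab <- toy_long()
  tab$value <- NA_real_
  ds <- suppressWarnings(sgfa_data(tab))
  pp <- sgfa:::make_pp(ds)
  ctl <- sgfa_control()
  st <- sgfa:::init_state(pp, 1, ctl)
  # make the posteriors equal the priors where possible: KL contributions vanish
  st$Z[[1]]$mu[] <- 0; st$Z[[1]]$s2[] <- 1
  e <- sgfa:::compute_elbo(st, pp)
  pr <- ctl$priors
  # remaining terms: spike-and-slab weights at (g=0.5, prior slab) + factor prior
  manual <- sgfa:::spikeslab_elbo_term(st$W[[1]], pr$alpha_a / pr$alpha_b,
                                       digamma(pr$alpha_a) - log(pr$alpha_b),
                                       st$theta_w[[1]]) +
    sgfa:::gaussian_factor_elbo_term(st$Z[[1]], st$alpha_z[[1]])
  expect_equal(e, manual, tolerance = 1e-10)
})

test_that("single-group fits with factor regularization disabled expose no factor-side priors", {
  sim <- sgfa_simulate(G = 1, M = 2, K = 2, N = 30, D = 15, seed = 70)
  fit <- sgfa(sim$data, K = 2,
              control = quick_ctl(ard_factors = FALSE, spike_factors = FALSE))
  # prior structure reduces to weight-side-only regularization
  expect_null(fit$state$alpha_z)
  expect_null(fit$state$theta_z)
  expect_null(fit$state$Z[[1]]$g)
  e <- fit$trace$elbo
  expect_true(all(diff(e) >= -1e-8 * abs(e[-length(e)])))
})

test_that("prune_factors applies the variance filter and reorders by total R2", {
  sim <- sgfa_simulate(G = 1, M = 1, K = 2, N = 60, D = 40,
                       activity_groups = matrix(c(2, 0.7), 2, 1),
                       noise_var = 0.3, seed = 80)
  fit <- sgfa(sim$data, K = 4, control = quick_ctl())
  # min_r2 = 0 removes nothing
  expect_equal(prune_factors(fit, 0)$K, fit$K)
  pruned <- prune_factors(fit, 0.01)
  expect_equal(pruned$K, 2L)
  tot <- apply(pruned$r2$r2, 1, sum)
  expect_true(all(diff(tot) <= 0))  # descending order
  # an absurd threshold prunes everything, with a warning
  expect_warning(empty <- prune_factors(fit, 0.99), "all factors pruned")
  expect_equal(empty$K, 0L)
})

test_that("inactive factors collapse during training on rank-1 data", {
  sim <- sgfa_simulate(G = 1, M = 1, K = 1, N = 80, D = 50,
                       noise_var = 0.25, seed = 90)
  fit <- sgfa(sim$data, K = 5, min_r2 = 0.01,
              control = quick_ctl(maxit = 60))
  expect_equal(fit$K, 1L)
})
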