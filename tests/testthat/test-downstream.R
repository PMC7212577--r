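test_that("variance explained matches a brute-force evaluation of 1 - SS_res/SS_tot", {
  sc <- toy_fit()
  fit <- sc$fit
  pp <- sgfa:::make_pp(fit$data)
  mom <- sgfa:::all_moments(fit$state)
  for (g in 1:2) for (m in 1:2) {
    Y <- pp$Y0[[g]][[m]]
    Msk <- pp$mask[[g]][[m]] == 1
    for (k in seq_len(fit$K)) {
      rec <- tcrossprod(mom$z[[g]]$E[, k], mom$w[[m]]$E[, k])
      oracle <- 1 - sum((Y - rec)[Msk]^2) / sum(Y[Msk]^2)
      expect_equal(fit$r2$raw[k, g, m], oracle, tolerance = 1e-12)
    }
    full <- mom$z[[g]]$E %*% t(mom$w[[m]]$E)
    oracle_tot <- 1 - sum((Y - full)[Msk]^2) / sum(Y[Msk]^2)
    expect_equal(fit$r2$total[g, m], oracle_tot, tolerance = 1e-12)
  }
})

test_that("variance explained has the analytic limits", {
  sc <- toy_fit()
  fit <- sc$fit
  # zero residual: doctor a state that reproduces the data exactly
  st <- fit$state
  pp <- sgfa:::make_pp(fit$data)
  Y <- pp$Y0[[1]][[1]]
  sv <- svd(Y)
  r <- length(sv$d)
  doctored <- fit
  doctored$state$K <- r
  doctored$state$Z <- list(list(mu = sv$u %*% diag(sv$d), s2 = matrix(1e-12, nrow(Y), r)),
                           fit$state$Z[[2]])
  doctored$state$W <- lapply(1:2, function(m)
    list(mu = if (m == 1) sv$v else matrix(0, ncol(pp$Y0[[1]][[2]]), r),
         s2 = matrix(1e-12, if (m == 1) ncol(Y) else ncol(pp$Y0[[1]][[2]]), r),
         g = matrix(1, if (m == 1) ncol(Y) else ncol(pp$Y0[[1]][[2]]), r),
         s0 = rep(1e-12, r)))
  # align remaining structures on K
  doctored$state$Z[[2]] <- list(mu = matrix(0, pp$N[2], r), s2 = matrix(1, pp$N[2], r))
  doctored$state$zeta <- fit$state$zeta
  r2d <- variance_explained(doctored)
  expect_equal(r2d$total[1, 1], 1, tolerance = 1e-9)  # perfect reconstruction
  # all weights zero for every factor in view 2 -> per-factor R2 is 0 there
  expect_true(all(r2d$raw[, 1, 2] == 0))
})

test_that("total R2 is invariant to joint rescaling and sign flips", {
  sc <- toy_fit()
  fit <- sc$fit
  scaled <- fit
  c0 <- 3.7
  for (g in seq_along(scaled$state$Z)) scaled$state$Z[[g]]$mu <- scaled$state$Z[[g]]$mu * c0
  for (m in seq_along(scaled$state$W)) scaled$state$W[[m]]$mu <- scaled$state$W[[m]]$mu / c0
  # make second moments consistent with the rescaled means (variances negligible)
  for (g in seq_along(scaled$state$Z)) scaled$state$Z[[g]]$s2 <- scaled$state$Z[[g]]$s2 * c0^2
  for (m in seq_along(scaled$state$W)) scaled$state$W[[m]]$s2 <- scaled$state$W[[m]]$s2 / c0^2
  expect_equal(variance_explained(scaled)$total, fit$r2$total, tolerance = 1e-10)

  flipped <- fit
  for (g in seq_along(flipped$state$Z)) flipped$state$Z[[g]]$mu[, 1] <- -flipped$state$Z[[g]]$mu[, 1]
  for (m in seq_along(flipped$state$W)) flipped$state$W[[m]]$mu[, 1] <- -flipped$state$W[[m]]$mu[, 1]
  expect_equal(variance_explained(flipped)$raw, fit$r2$raw, tolerance = 1e-12)
})

test_that("top_weights ranks by absolute value with stable ties and clamping", {
  sc <- toy_fit()
  fit <- sc$fit
  fit$state$W[[1]]$g[] <- 1
  fit$state$W[[1]]$mu[, 1] <- 0
  fit$state$W[[1]]$mu[1:3, 1] <- c(0.1, -0.9, 0.5)
  tw <- top_weights(fit, view = 1, factor = 1, n = 2)
  expect_equal(tw$weight, c(-0.9, 0.5))
  expect_equal(tw$feature, fit$data$features[[1]][c(2, 3)])
  # equal weights: original feature order
  fit$state$W[[1]]$mu[, 1] <- 0.4
  expect_equal(top_weights(fit, 1, 1, n = 3)$feature, fit$data$features[[1]][1:3])
  # n > D returns everything
  expect_equal(nrow(top_weights(fit, 1, 1, n = 1e6)), length(fit$data$features[[1]]))
  expect_error(top_weights(fit, "nope", 1), "unknown view")
  expect_error(top_weights(fit, 1, 99), "unknown factor")
})

test_that("enrichment matches hand-rolled Welch t and Benjamini-Hochberg oracles", {
  sc <- toy_fit()
  fit <- sc$fit
  feats <- fit$data$features[[1]]
  set.seed(33)
  sets <- list(A = sample(feats, 6), B = sample(feats, 8), C = sample(feats, 5))
  res <- run_enrichment(fit, sets, view = 1, factors = 1)
  w <- abs(coef(fit)[[1]][, 1])
  for (i in seq_along(sets)) {
    fg <- w[feats %in% sets[[i]]]
    bg <- w[!feats %in% sets[[i]]]
    # Welch statistic from first principles
    tstat <- (mean(fg) - mean(bg)) / sqrt(var(fg) / length(fg) + var(bg) / length(bg))
    expect_equal(res$t[i], tstat, tolerance = 1e-10)
  }
  # brute-force BH on the returned raw p-values
  p <- res$p
  n <- length(p)
  ord <- order(p)
  adj <- rev(cummin(rev(p[ord] * n / seq_len(n))))[order(ord)]
  expect_equal(res$p_adj, pmin(adj, 1), tolerance = 1e-12)
})

test_that("BH adjustment of {0.01, 0.02, 0.03, 0.04} over 4 sets gives 0.04 everywhere", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
})

test_that("enrichment flags a designed positive control and skips tiny sets", {
  sim <- sgfa_simulate(G = 1, M = 1, K = 1, N = 150, D = 200,
                       noise_var = 0.25, seed = 44)
  fit <- sgfa(sim$data, K = 1, control = quick_ctl())
  w <- abs(coef(fit)[[1]][, 1])
  feats <- fit$data$features[[1]]
  sets <- list(top = feats[order(-w)][1:50],
               rnd = feats[seq(3, 150, by = 3)],
               tiny = feats[1])
  expect_warning(res <- run_enrichment(fit, sets, view = 1, factors = 1),
                 "fewer than 2")
  expect_true(res$significant[res$set == "top"])
  expect_false("tiny" %in% res$set)
})

test_that("enrichment is calibrated under exchangeable weights", {
  sc <- toy_fit()
  fit <- sc$fit
  feats <- fit$data$features[[1]]
  set.seed(55)
  sets <- lapply(1:5, function(i) sample(feats, 7))
  names(sets) <- paste0("s", 1:5)
  flagged <- 0L
  total <- 0L
  for (r in 1:200) {
    fit$state$W[[1]]$mu[, 1] <- rnorm(length(feats))
    fit$state$W[[1]]$g[] <- 1
    res <- run_enrichment(fit, sets, view = 1, factors = 1)
    flagged <- flagged + sum(res$significant)
    total <- total + nrow(res)
  }
  expect_lte(flagged / total, 0.02)
})

test_that("reconstruction is exact in the noiseless limit and respects link ranges", {
  sim <- sgfa_simulate(G = 1, M = 1, K = 2, N = 40, D = 25,
                       noise_var = 0, missing = 0, seed = 66)
  fit <- sgfa(sim$data, K = 2, control = quick_ctl(maxit = 100, tol = 1e-12))
  rec <- predict(fit)[[1]][[1]]
  truthY <- sim$truth$Z[[1]] %*% t(sim$truth$W[[1]])
  expect_lt(max(abs(rec - truthY)), 1e-6)

  simb <- sgfa_simulate(G = 1, M = 1, K = 2, N = 30, D = 20,
                        likelihoods = "bernoulli", seed = 67)
  fitb <- sgfa(simb$data, K = 2, control = quick_ctl())
  recb <- predict(fitb)[[1]][[1]]
  expect_true(all(recb >= 0 & recb <= 1))
})

test_that("imputation at masked entries beats column-mean imputation", {
  sim <- sgfa_simulate(G = 1, M = 1, K = 3, N = 100, D = 60,
                       noise_var = 0.5, missing = 0.2, seed = 21)
  fit <- sgfa(sim$data, K = 4, control = quick_ctl(maxit = 40))
  truthY <- sim$truth$Z[[1]] %*% t(sim$truth$W[[1]])
  M <- sim$data$masks[[1]][[1]]
  imp <- predict(fit)[[1]][[1]]
  B <- sim$data$blocks[[1]][[1]]
  B[!M] <- NA
  cm <- matrix(colMeans(B, na.rm = TRUE), nrow(B), ncol(B), byrow = TRUE)
  expect_lt(sqrt(mean((imp[!M] - truthY[!M])^2)),
            sqrt(mean((cm[!M] - truthY[!M])^2)))
})

test_that("factor scores export with sample and group labels", {
  sc <- toy_fit()
  fs <- factor_scores(sc$fit)
  expect_named(fs, c("sample", "group", paste0("Factor", seq_len(sc$fit$K))))
  expect_equal(nrow(fs), sum(vapply(sc$sim$data$samples, length, 1L)))
  path <- tempfile(fileext = ".tsv")
  write_factors(sc$fit, path)
  back <- read.delim(path)
  expect_equal(back$Factor1, fs$Factor1, tolerance = 1e-6)
})

test_that("gmt parsing returns named member lists", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), path)
  gs <- read_gmt(path)
  expect_named(gs, c("setA", "setB"))
  expect_equal(gs$setA, c("g1", "g2", "g3"))
})
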