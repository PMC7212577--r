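# Shared fixtures, built in code.

quick_ctl <- function(...) {
  args <- utils::modifyList(
    list(maxit = 30, tol = 1e-7, convergence = "relative"), list(...))
  do.call(sgfa_control, args)
}

# small long-format table: 2 samples, 1 group, 3 features, 1 view, 5 rows
toy_long <- function() {
  data.frame(
    sample = c("s1", "s1", "s2", "s2", "s2"),
    group = "g1",
    feature = c("f1", "f2", "f1", "f2", "f3"),
    view = "rna",
    value = c(1, 2, 3, 4, 5),
    stringsAsFactors = FALSE
  )
}

# fitted model on a small two-group, two-view simulation
toy_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- sgfa_simulate(G = 2, M = 2, K = 2, N = 30, D = 20,
                           noise_var = 0.5, missing = 0.15, seed = 11)
      cache <<- list(sim = sim, fit = sgfa(sim$data, K = 2, control = quick_ctl()))
    }
    cache
  }
})
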