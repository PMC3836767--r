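# Independent oracles and shared fixtures.
#
# The tail oracles sum the probability mass function term by term and
# never touch the survival functions used by the implementation.

oracle_tail_pois <- function(lambda, k, terms = 2000L) {
  # P(X > k) by direct summation of the pmf above k
  sum(dpois(seq.int(k + 1L, k + terms), lambda))
}

oracle_tail_nbinom <- function(r, p, k, terms = 20000L) {
  sum(dnbinom(seq.int(k + 1L, k + terms), size = r, prob = p))
}

oracle_threshold <- function(tail_fun, alpha) {
  k <- 0L
  while (tail_fun(k) > alpha) k <- k + 1L
  k
}

# moment summaries without touching compute_moments internals
ms_of <- function(mean, variance) {
  structure(list(mean = mean, variance = variance,
                 ratio = if (mean > 0) variance / mean else NA_real_,
                 n = 48L),
            class = "moment_summary")
}

# a simulated 48-sample panel and its fitted models, shared across
# test files (built once per test run)
fixture_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_models(simulate_normal_panel(panel_spec(seed = 42L)))
    cache
  }
})

fixture_process <- function() default_panel_process(panel_spec(seed = 42L))

# Poisson model with given lambda, built through the public fitting path
new_model_pois <- function(lambda, alpha = 2e-5) {
  fit_poisson(ms_of(lambda, lambda), floor = (lambda == 1L), alpha = alpha)
}
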