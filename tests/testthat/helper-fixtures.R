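# shared fixtures and numerical helpers

# central finite-difference gradient of scalar f at x (matrix or vector)
num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# small hand-built cohort: 2 episodes, 2 variables
toy_cohort <- function() {
  obs <- tibble::tibble(
    episode_id = c("a", "a", "a", "b", "b"),
    variable_id = c(1L, 1L, 2L, 1L, 2L),
    time_hours = c(0.5, 3.0, 1.25, 2.0, 23.0),
    value = c(1.0, -0.5, 2.0, 0.0, 1.5)
  )
  qry <- tibble::tibble(
    episode_id = c("a", "b"), variable_id = c(1L, 2L),
    query_time_hours = c(30, 25), target_value = c(0.2, NA)
  )
  imts_cohort(obs, qry, n_variables = 2L)
}

# fast simulated cohort for model-level tests
quick_sim <- function(n_episodes = 20L, seed = 11L, ...) {
  simulate_imts_cohort(cohort_config(n_episodes = n_episodes, seed = seed, ...))
}

expect_row_stochastic <- function(a, tol = 1e-6) {
  expect_true(all(a >= -tol))
  expect_equal(unname(rowSums(a)), rep(1, nrow(a)), tolerance = tol)
}
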