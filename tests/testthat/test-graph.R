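# Lomb-Scargle spectral features and the dynamic graph stage.

test_that("Lomb-Scargle power matches a direct evaluation of its definition", {
  set.seed(4)
  t <- sort(runif(100, 0, 24))
  y <- 1.3 * sin(2 * pi * 0.25 * t + 0.7) + 0.3 * rnorm(100)
  freqs <- seq(0.05, 0.5, by = 0.05)
  got <- lomb_scargle_power(t, y, freqs)
  # independent oracle written straight from the periodogram definition
  oracle <- sapply(freqs, function(f) {
    w <- 2 * pi * f
    yc <- y - mean(y)
    tau <- atan(sum(sin(2 * w * t)) / sum(cos(2 * w * t))) / (2 * w)
    # atan vs atan2 can differ by pi/(2w); both are valid tau solutions, so
    # evaluate the defining quadratic form instead at the returned tau
    a <- sum(yc * cos(w * (t - tau)))^2 / sum(cos(w * (t - tau))^2)
    b <- sum(yc * sin(w * (t - tau)))^2 / sum(sin(w * (t - tau))^2)
    (a + b) / (2 * mean(yc^2))
  })
  expect_equal(got, oracle, tolerance = 1e-8)
})

test_that("the periodogram recovers a planted frequency from irregular samples", {
  set.seed(5)
  t <- sort(runif(100, 0, 24))
  f0 <- 0.25
  y <- sin(2 * pi * f0 * t + 1.1) # noiseless
  freqs <- seq(0.05, 0.5, by = 0.05) # f0 on the grid
  p <- lomb_scargle_power(t, y, freqs)
  expect_equal(freqs[which.max(p)], f0)
  # constant signal has no power anywhere
  expect_equal(lomb_scargle_power(t, rep(2, 100), freqs), rep(0, 10))
})

test_that("degenerate support windows yield a flagged zero feature", {
  spec <- patch_spec(c(1, 2, 4, 8, 24), 24)
  obs <- tibble::tibble(variable_id = 1L, time_hours = c(1, 2), value = c(0, 1))
  f <- lomb_scargle_features(obs, 1L, 5L, spec, seq(0.1, 1, by = 0.1))
  expect_equal(as.vector(f), rep(0, 10))
  expect_true(attr(f, "degenerate"))
  obs3 <- tibble::tibble(variable_id = 1L, time_hours = c(1, 2, 7, 13, 20),
                         value = c(0, 1, -1, 2, 0.5))
  f3 <- lomb_scargle_features(obs3, 1L, 5L, spec, seq(0.1, 1, by = 0.1))
  expect_false(attr(f3, "degenerate"))
  expect_true(any(f3 > 0))
})

test_that("probe grid spans (0, f_max] with the Nyquist-style cap", {
  co <- quick_sim(5L, seed = 2L)$cohort
  fr <- probe_frequencies(co, n = 10L, cap = 2)
  expect_length(fr, 10L)
  expect_true(all(fr > 0) && max(fr) <= 2)
  expect_equal(diff(fr), rep(fr[1], 9), tolerance = 1e-10) # evenly spaced
})

test_that("interval graphs are row-stochastic and uniform under identical features", {
  set.seed(6)
  n <- 5L
  gp <- graph_params(d_comb = 7L, d_g = 3L, d_input_tf = 4L, seed = 3L)
  m <- matrix(rnorm(n * 4), n, 4)
  f <- matrix(abs(rnorm(n * 3)), n, 3)
  g <- build_interval_graph(m, f, gp)
  expect_row_stochastic(g$adjacency)
  # identical rows force the uniform graph
  m1 <- matrix(rep(m[1, ], each = n), n, 4)
  f1 <- matrix(rep(f[1, ], each = n), n, 3)
  gu <- build_interval_graph(m1, f1, gp)
  expect_equal(gu$adjacency, matrix(1 / n, n, n), tolerance = 1e-12)
})

test_that("graph construction matches a scalar hand computation at N = 3", {
  gp <- list(w_source = matrix(c(0.2, -0.1, 0.4, 0.3), 2, 2),
             w_target = matrix(c(-0.3, 0.5, 0.1, 0.2), 2, 2),
             w_gnn = diag(2))
  feats <- matrix(c(1, 0.5, -1, 0.2, 0.4, -0.6), 3, 2)
  g <- build_interval_graph(feats[, 1, drop = FALSE], feats[, 2, drop = FALSE],
                            list(w_source = gp$w_source, w_target = gp$w_target,
                                 w_gnn = gp$w_gnn))
  es <- feats %*% gp$w_source
  et <- feats %*% gp$w_target
  s <- pmax(es %*% t(et), 0)
  a <- t(apply(s, 1L, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(g$adjacency, a, tolerance = 1e-6)
  # normalization identity entry by entry
  ahat <- a + diag(3)
  d <- rowSums(ahat)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(g$normalized[i, j], ahat[i, j] / sqrt(d[i] * d[j]),
                 tolerance = 1e-12)
  }
})

test_that("GCN aggregation handles the degenerate identity graph and is equivariant", {
  set.seed(7)
  n <- 4L
  m <- matrix(rnorm(n * 3), n, 3)
  w <- matrix(rnorm(9), 3, 3)
  gp <- list(w_gnn = w)
  idg <- structure(list(adjacency = matrix(0, n, n),
                        adjacency_selfloop = diag(n), normalized = diag(n),
                        interval = 1L), class = "imts_interval_graph")
  expect_equal(gcn_aggregate(idg, m, gp),
               (function(x) x * pnorm(x))(m %*% w), tolerance = 1e-12)
  # permuting variables permutes outputs identically
  gpfull <- graph_params(3L, 2L, 3L, seed = 9L)
  gpfull$w_gnn <- w
  g1 <- build_interval_graph(m, NULL, gpfull)
  out1 <- gcn_aggregate(g1, m, gpfull)
  perm <- c(3L, 1L, 4L, 2L)
  g2 <- build_interval_graph(m[perm, ], NULL, gpfull)
  out2 <- gcn_aggregate(g2, m[perm, ], gpfull)
  expect_equal(out2, out1[perm, ], tolerance = 1e-10)
})

test_that("episode aggregation averages interval graphs entry-wise", {
  a1 <- matrix(c(0.5, 0.5, 0.2, 0.8), 2, 2, byrow = TRUE)
  a2 <- matrix(c(0.9, 0.1, 0.6, 0.4), 2, 2, byrow = TRUE)
  ag <- aggregate_episode_graph(list(a1, a2))
  expect_equal(unclass(ag), (a1 + a2) / 2, ignore_attr = TRUE)
  expect_row_stochastic(ag)
  same <- aggregate_episode_graph(list(a1, a1, a1))
  expect_equal(unclass(same), a1, ignore_attr = TRUE)
  expect_error(aggregate_episode_graph(list()), "no interval graphs")
})

test_that("binarization keeps the top fraction with deterministic ties", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[3, 4] <- 0.8; w[2, 1] <- 0.7
  b <- binarize_top_fraction(w, 0.1) # ceiling(0.1 * 12) = 2 edges
  expect_equal(sum(b), 2L)
  expect_equal(b[1, 2] + b[3, 4], 2L)
  expect_equal(diag(b), rep(0L, 4))
  # all-equal weights: lexicographically first off-diagonal cells win
  beq <- binarize_top_fraction(matrix(1, 4, 4), 0.1)
  expect_equal(which(beq == 1L), c(5L, 9L)) # (1,2) then (1,3): row-major tie order
  # invariance under monotone rescaling
  set.seed(8)
  r <- matrix(runif(16), 4, 4)
  expect_identical(binarize_top_fraction(r, 0.25),
                   binarize_top_fraction(exp(3 * r), 0.25))
})

test_that("stability metrics behave on hand-built masks and weights", {
  expect_equal(jaccard_similarity(diag(3), diag(3)), 1)
  a <- matrix(c(0, 1, 0, 0), 2, 2); b <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(jaccard_similarity(a, b), 0)
  m1 <- matrix(0, 3, 3); m1[1, 2] <- 1; m1[2, 3] <- 1 # {e1, e2}
  m2 <- matrix(0, 3, 3); m2[2, 3] <- 1; m2[3, 1] <- 1 # {e2, e3}
  expect_equal(jaccard_similarity(m1, m2), 1 / 3)
  set.seed(9)
  ws <- replicate(3, matrix(runif(25), 5, 5), simplify = FALSE)
  st <- graph_stability(ws, fraction = 0.2)
  expect_equal(st$metric, c("jaccard", "pearson"))
  expect_equal(st$n_pairs, c(3L, 3L))
  stid <- graph_stability(list(ws[[1]], ws[[1]]), fraction = 0.2)
  expect_equal(stid$mean, c(1, 1))
  expect_error(graph_stability(ws[1]), "at least 2")
})

test_that("recovery AUROC is 1 for a perfectly aligned ranking and 0.5 at chance", {
  truth <- default_coupling_graph(5L)
  perfect <- truth + 0.01
  expect_equal(graph_recovery_auroc(perfect, truth), 1)
  flat <- matrix(1, 5, 5)
  set.seed(10)
  aur <- replicate(200, {
    graph_recovery_auroc(matrix(runif(25), 5, 5), truth)
  })
  expect_lt(abs(mean(aur) - 0.5), 0.05)
})
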