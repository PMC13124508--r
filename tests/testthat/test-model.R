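# End-to-end forward pass checked against an independent step-by-step
# re-computation of every stage on a tiny two-variable episode.

trace_config <- function() {
  model_config(
    scales = c(1, 2), window_end = 2, horizon = 2,
    d_t = 2L, d_time = 2L, d_freq = 4L, d_fused = 3L, d_input_tf = 4L,
    d_h = 2L, l_ifan = 1L, d_fourier = 2L, d_g = 2L,
    n_heads = 1L, n_layers_tf = 1L, ff_mult = 2L, dropout = 0,
    n_blocks = 1L, alpha = 0.1
  )
}

trace_cohort <- function() {
  obs <- tibble::tibble(
    episode_id = "t1", variable_id = c(1L, 1L, 2L),
    time_hours = c(0.3, 1.2, 0.7), value = c(0.5, -0.4, 1.0)
  )
  qry <- tibble::tibble(
    episode_id = "t1", variable_id = c(1L, 2L),
    query_time_hours = c(3.0, 2.5), target_value = c(0.2, NA)
  )
  imts_cohort(obs, qry, n_variables = 2L, window_end = 2, horizon = 2)
}

gelu0 <- function(x) x * pnorm(x)

# independent oracle written straight from the architecture definition
trace_oracle <- function(p, cfg) {
  phi <- function(t) c(p$te_omega[1, 1] * t + p$te_alpha[1, 1],
                       sin(p$te_omega[1, 2] * t + p$te_alpha[1, 2]))
  ttcn <- function(tt, vv) {
    z <- t(vapply(seq_along(tt), function(j) c(phi(tt[j]), vv[j]), numeric(3)))
    vapply(1:2, function(k) {
      w1 <- p[[paste0("ttcn", k, "_w1")]]; b1 <- p[[paste0("ttcn", k, "_b1")]]
      w2 <- p[[paste0("ttcn", k, "_w2")]]; b2 <- p[[paste0("ttcn", k, "_b2")]]
      s <- t(vapply(seq_along(tt), function(j) {
        as.vector(gelu0(z[j, , drop = FALSE] %*% w1 + b1) %*% w2 + b2)
      }, numeric(3)))
      f <- apply(s, 2L, function(col) exp(col - max(col)) / sum(exp(col - max(col))))
      f <- matrix(f, nrow = length(tt))
      sum(f * z)
    }, 0)
  }
  ifan <- function(tt, vv) {
    xs <- t(vapply(seq_along(tt), function(j) {
      u <- vv[j] * p$ifan1_wp[1, ] + tt[j] * p$ifan1_up[1, ]
      g <- gelu0(p$ifan1_bpb[1, ] + vv[j] * p$ifan1_wpb[1, ] +
                   tt[j] * p$ifan1_vpb[1, ])
      c(cos(u), sin(u), g)
    }, numeric(4)))
    colMeans(xs)
  }
  fuse <- function(tt, vv) {
    as.vector(c(ttcn(tt, vv), ifan(tt, vv)) %*% p$fus_w + p$fus_b)
  }
  # patches (scale 1: spans [0,1), [1,2]; scale 2: [0,2])
  h_s1 <- list(
    v1 = list(fuse(0.3, 0.5), fuse(0.2, -0.4)),
    v2 = list(fuse(0.7, 1.0), p$etok[1, ]) # empty patch token, scale 1
  )
  h_s2 <- list(
    v1 = fuse(c(0.15, 0.6), c(0.5, -0.4)),
    v2 = fuse(0.35, 1.0)
  )
  # canonical alignment and multi-scale fusion + positional encodings
  pe <- getFromNamespace("pe_table", "imtscast")(2L, 4L)
  m <- array(0, c(2, 2, 4)) # [variable, interval, dim]
  for (i in 1:2) {
    hv1 <- if (i == 1) h_s1$v1 else h_s1$v2
    hv2 <- if (i == 1) h_s2$v1 else h_s2$v2
    for (k in 1:2) {
      cat_ <- c(hv1[[k]], hv2)
      m[i, k, ] <- gelu0(as.vector(cat_ %*% p$ms_w + p$ms_b)) + pe[k, ]
    }
  }
  # transformer per variable (pre-norm, one head, one layer)
  ln <- function(x, g, b) {
    mu <- rowMeans(x); xc <- x - mu
    v <- rowMeans(xc^2)
    xc / sqrt(v + 1e-5) * matrix(g, nrow(x), length(g), byrow = TRUE) +
      matrix(b, nrow(x), length(b), byrow = TRUE)
  }
  mt <- array(0, dim(m))
  for (i in 1:2) {
    x <- m[i, , ]
    h1 <- ln(x, p$bl1_tf1_ln1_g[1, ], p$bl1_tf1_ln1_b[1, ])
    q <- h1 %*% p$bl1_tf1_wq; k_ <- h1 %*% p$bl1_tf1_wk; v_ <- h1 %*% p$bl1_tf1_wv
    sc <- q %*% t(k_) / sqrt(4)
    a <- t(apply(sc, 1L, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    att <- (a %*% v_) %*% p$bl1_tf1_wo +
      matrix(p$bl1_tf1_bo, 2, 4, byrow = TRUE)
    x <- x + att
    h2 <- ln(x, p$bl1_tf1_ln2_g[1, ], p$bl1_tf1_ln2_b[1, ])
    ff <- gelu0(h2 %*% p$bl1_tf1_w1 +
                  matrix(p$bl1_tf1_b1, 2, 8, byrow = TRUE)) %*% p$bl1_tf1_w2 +
      matrix(p$bl1_tf1_b2, 2, 4, byrow = TRUE)
    mt[i, , ] <- x + ff
  }
  # dynamic graph per interval (spectral features degenerate to zeros here)
  adjacency <- list()
  mbar <- array(0, dim(m))
  for (k in 1:2) {
    C <- cbind(rbind(mt[1, k, ], mt[2, k, ]), matrix(0, 2, 2))
    es <- C %*% p$bl1_g_ws; et <- C %*% p$bl1_g_wt
    s <- pmax(es %*% t(et), 0)
    a <- t(apply(s, 1L, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
    adjacency[[k]] <- a
    ahat <- a + diag(2)
    dg <- rowSums(ahat)
    abar <- ahat * ((1 / sqrt(dg)) %o% (1 / sqrt(dg)))
    out <- gelu0(abar %*% rbind(mt[1, k, ], mt[2, k, ]) %*% p$bl1_g_wgnn)
    mbar[1, k, ] <- out[1, ]; mbar[2, k, ] <- out[2, ]
  }
  # prediction head from the last canonical interval
  pred <- function(i, tau) {
    ctx <- mbar[i, 2, ]
    tf_ <- (tau - cfg$window_end) / cfg$horizon
    u <- as.vector(ctx %*% p$hd_wp) + tf_ * p$hd_up[1, ]
    g <- gelu0(p$hd_bpb[1, ] + as.vector(ctx %*% p$hd_wpb) + tf_ * p$hd_vpb[1, ])
    sum(c(cos(u), sin(u), g) * p$hd_wout[, 1]) + p$hd_bout[1, 1]
  }
  list(yhat = c(pred(1, 3.0), pred(2, 2.5)), adjacency = adjacency,
       loss = (1 + 0.1 * (3.0 - 2)) * (pred(1, 3.0) - 0.2)^2)
}

test_that("the full forward pass matches the step-by-step oracle trace", {
  cfg <- trace_config()
  model <- init_model(cfg, seed = 5L)
  co <- trace_cohort()
  preps <- imtscast:::prepare_cohort(co, cfg, probe_freqs = c(0.25, 0.5))
  batch <- imtscast:::assemble_batch(preps, cfg)
  fw <- imtscast:::forward_batch(model, batch, train = FALSE, store_adj = TRUE)
  oracle <- trace_oracle(model$params, cfg)
  got <- as.vector(fw$yhat$value)
  ord <- order(fw$qtab$variable_id)
  expect_equal(got[ord], oracle$yhat, tolerance = 1e-6)
  adj <- fw$adjacency[[1]]
  expect_equal(adj[, , 1], oracle$adjacency[[1]], tolerance = 1e-6)
  expect_equal(adj[, , 2], oracle$adjacency[[2]], tolerance = 1e-6)
  expect_equal(fw$loss$value[1, 1], oracle$loss, tolerance = 1e-6)
})

test_that("evaluation-mode forwards are bit-identical across calls", {
  co <- quick_sim(3L, seed = 19L)$cohort
  mc <- model_config_small(max_epochs = 1L, dropout = 0)
  fit <- train_imts(co, NULL, mc, seed = 3L)
  f1 <- forecast_queries(fit, co)
  f2 <- forecast_queries(fit, co)
  expect_identical(f1$prediction, f2$prediction)
})

test_that("predictions are invariant to batch composition", {
  co <- quick_sim(5L, seed = 23L)$cohort
  mc <- model_config_small(max_epochs = 1L, dropout = 0)
  fit <- train_imts(co, NULL, mc, seed = 4L)
  all_at_once <- forecast_queries(fit, co, batch_size = 5L)
  one_by_one <- forecast_queries(fit, co, batch_size = 1L)
  j <- dplyr::left_join(
    all_at_once, one_by_one,
    by = c("episode_id", "variable_id", "query_time_hours")
  )
  expect_equal(j$prediction.x, j$prediction.y, tolerance = 1e-10)
})

test_that("stacking K = 2 blocks runs and changes the forward output", {
  co <- quick_sim(3L, seed = 29L)$cohort
  mc1 <- model_config_small(max_epochs = 1L, dropout = 0)
  mc2 <- model_config_small(max_epochs = 1L, dropout = 0, n_blocks = 2L)
  f1 <- train_imts(co, NULL, mc1, seed = 5L)
  f2 <- train_imts(co, NULL, mc2, seed = 5L)
  expect_gt(n_params(f2), n_params(f1))
  p1 <- forecast_queries(f1, co)$prediction
  p2 <- forecast_queries(f2, co)$prediction
  expect_false(isTRUE(all.equal(p1, p2)))
})
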