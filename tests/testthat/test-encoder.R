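# Unit tests of the dual-domain patch encoders against hand/brute-force
# computations of the defining formulas.

test_that("time embedding combines a linear channel with sin channels", {
  p <- time_embed_params(4L, seed = 1L)
  p$omega[] <- 0; p$alpha[] <- 0
  expect_equal(time_embed(c(0.1, 0.9), p), matrix(0, 2, 4))
  p2 <- time_embed_params(4L, seed = 1L)
  p2$alpha[1, 2:4] <- pi / 2
  p2$omega[1, 2:4] <- 0
  te <- time_embed(0, p2)
  expect_equal(te[1, 2:4], rep(1, 3)) # sin(pi/2)
  expect_equal(te[1, 1], p2$alpha[1, 1])
  # generic parameters give a t-sensitive embedding
  p3 <- time_embed_params(4L, seed = 2L)
  fd <- (time_embed(0.5 + 1e-6, p3) - time_embed(0.5 - 1e-6, p3)) / 2e-6
  expect_gt(sqrt(sum(fd^2)), 0)
})

test_that("TTCN filters are softmax-normalized and singleton patches force uniform filters", {
  tp <- time_embed_params(3L, seed = 5L)
  pp <- ttcn_params(4L, d_time = 3L, d_h = 4L, seed = 6L)
  one <- list(t_rescaled = 0.4, value = 0.7)
  h1 <- ttcn_encode(one, tp, pp)
  f <- attr(h1, "filters")
  for (fk in f) expect_equal(unname(fk), matrix(1, 1, 4)) # softmax of a singleton
  z1 <- c(time_embed(0.4, tp), 0.7)
  expect_equal(as.vector(h1), rep(sum(z1), 3)) # all channels collapse to sum(z)
  # filter columns sum to one on a larger random patch
  set.seed(3)
  patch <- list(t_rescaled = sort(runif(7)), value = rnorm(7))
  hf <- ttcn_encode(patch, tp, pp)
  for (fk in attr(hf, "filters")) {
    expect_equal(unname(colSums(fk)), rep(1, 4), tolerance = 1e-6)
  }
})

test_that("TTCN matches a brute-force scalar computation on a 3-observation patch", {
  tp <- time_embed_params(2L, seed = 9L)
  pp <- ttcn_params(3L, d_time = 2L, d_h = 2L, seed = 10L)
  patch <- list(t_rescaled = c(0.1, 0.5, 0.9), value = c(1, -1, 0.5))
  got <- as.vector(ttcn_encode(patch, tp, pp))
  # independent oracle: explicit loops over observations and channels
  gelu0 <- function(x) x * pnorm(x)
  phi <- cbind(tp$omega[1, 1] * patch$t_rescaled + tp$alpha[1, 1],
               sin(tp$omega[1, 2] * patch$t_rescaled + tp$alpha[1, 2]))
  z <- cbind(phi, patch$value)
  oracle <- numeric(2)
  for (k in 1:2) {
    ch <- pp$channels[[k]]
    s <- matrix(0, 3, 3)
    for (j in 1:3) {
      s[j, ] <- gelu0(z[j, , drop = FALSE] %*% ch$w1 + ch$b1) %*% ch$w2 + ch$b2
    }
    fk <- apply(s, 2L, function(col) exp(col) / sum(exp(col)))
    acc <- 0
    for (j in 1:3) acc <- acc + sum(fk[j, ] * z[j, ])
    oracle[k] <- acc
  }
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("TTCN parameter count does not grow with patch length", {
  pp <- ttcn_params(4L, d_time = 2L, d_h = 3L, seed = 2L)
  count <- sum(vapply(unlist(pp$channels, recursive = FALSE), length, 0L))
  tp <- time_embed_params(3L, seed = 1L)
  for (L in c(1L, 5L, 50L)) {
    patch <- list(t_rescaled = sort(runif(L)), value = rnorm(L))
    expect_length(ttcn_encode(patch, tp, pp), 2L)
    # params untouched by encoding
    expect_equal(sum(vapply(unlist(pp$channels, recursive = FALSE), length, 0L)),
                 count)
  }
})

test_that("IFAN output is permutation-invariant with width 2 d_p + d_pbar", {
  pp <- ifan_params(1L, d_freq = 12L, n_layers = 2L, seed = 4L)
  expect_equal(pp$d_freq, 2L * pp$d_p + pp$d_pbar)
  set.seed(8)
  patch <- list(t_rescaled = runif(6), value = rnorm(6))
  h <- ifan_encode(patch, pp)
  expect_length(h, pp$d_freq)
  perm <- sample(6)
  h2 <- ifan_encode(list(t_rescaled = patch$t_rescaled[perm],
                         value = patch$value[perm]), pp)
  expect_equal(h, h2, tolerance = 1e-12)
  # duplicating every observation leaves the mean-pooled embedding unchanged
  h3 <- ifan_encode(list(t_rescaled = rep(patch$t_rescaled, 2),
                         value = rep(patch$value, 2)), pp)
  expect_equal(h, h3, tolerance = 1e-12)
})

test_that("IFAN with zeroed periodic weights emits cos = 1, sin = 0", {
  pp <- ifan_params(1L, d_freq = 8L, n_layers = 1L, seed = 3L)
  pp$layers[[1]]$wp[] <- 0
  pp$layers[[1]]$up[] <- 0
  h <- ifan_encode(list(t_rescaled = c(0.2, 0.8), value = c(1.4, -2)), pp)
  expect_equal(h[seq_len(pp$d_p)], rep(1, pp$d_p))
  expect_equal(h[pp$d_p + seq_len(pp$d_p)], rep(0, pp$d_p))
})

test_that("single-layer single-observation IFAN matches the layer formula", {
  pp <- ifan_params(1L, d_freq = 4L, n_layers = 1L, seed = 7L)
  v <- 0.3; t <- 0.25
  got <- ifan_encode(list(t_rescaled = t, value = v), pp)
  ly <- pp$layers[[1]]
  u <- v * ly$wp[1, ] + t * ly$up[1, ]
  g <- (function(x) x * pnorm(x))(ly$bpb[1, ] + v * ly$wpb[1, ] + t * ly$vpb[1, ])
  expect_equal(got, c(cos(u), sin(u), g), tolerance = 1e-12)
})

test_that("dual-domain fusion is affine with a learned empty-patch token", {
  fp <- fusion_params(d_time = 2L, d_freq = 2L, d_fused = 4L, n_scales = 3L,
                      seed = 5L)
  fp$w <- diag(4); fp$b <- matrix(0, 1, 4)
  expect_equal(as.vector(fuse_patch(c(1, 2), c(3, 4), fp)), c(1, 2, 3, 4))
  fp2 <- fusion_params(2L, 2L, 4L, 3L, seed = 5L)
  expect_equal(as.vector(fuse_patch(c(0, 0), c(0, 0), fp2)),
               as.vector(fp2$b))
  # affine property: f(a+b) - f(a) - f(b) + f(0) = 0
  a <- c(0.3, -1); b <- c(2, 0.5); fz <- c(0, 0)
  lhs <- fuse_patch(a + b, a + b, fp2) - fuse_patch(a, a, fp2) -
    fuse_patch(b, b, fp2) + fuse_patch(fz, fz, fp2)
  expect_equal(as.vector(lhs), rep(0, 4), tolerance = 1e-12)
  emp <- fuse_patch(NULL, NULL, fp2, empty = TRUE, scale_idx = 2L)
  expect_true(attr(emp, "empty"))
  expect_equal(as.vector(emp), as.vector(fp2$empty_tokens[2, ]))
  expect_error(fuse_patch(c(1, 2, 3), c(1, 2), fp2), "width")
})

test_that("gradients reach the time-awareness parameters", {
  # finite-difference sensitivity of encoder outputs to omega, U_p, V_pbar
  tp <- time_embed_params(3L, seed = 11L)
  pp <- ttcn_params(4L, 2L, 3L, seed = 12L)
  patch <- list(t_rescaled = c(0.2, 0.6), value = c(0.5, -0.5))
  f_omega <- function(w) {
    tp2 <- tp; tp2$omega[1, 2] <- w
    sum(ttcn_encode(patch, tp2, pp))
  }
  expect_gt(abs(num_grad(f_omega, tp$omega[1, 2])), 0)
  ip <- ifan_params(1L, 8L, 1L, seed = 13L)
  f_up <- function(u) {
    ip2 <- ip; ip2$layers[[1]]$up[1, 1] <- u
    sum(ifan_encode(patch, ip2))
  }
  expect_gt(abs(num_grad(f_up, ip$layers[[1]]$up[1, 1])), 0)
  f_vp <- function(v) {
    ip2 <- ip; ip2$layers[[1]]$vpb[1, 1] <- v
    sum(ifan_encode(patch, ip2))
  }
  expect_gt(abs(num_grad(f_vp, ip$layers[[1]]$vpb[1, 1])), 0)
})
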