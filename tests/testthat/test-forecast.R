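# Prediction head, interval-weighted loss, and evaluation metrics.

head_fixture <- function(d = 3L, d_p = 2L, d_pb = 2L, seed = 1L) {
  with_seed_ <- getFromNamespace("with_seed", "imtscast")
  with_seed_(seed, list(
    wp = matrix(rnorm(d * d_p), d, d_p), up = matrix(rnorm(d_p), 1),
    wpb = matrix(rnorm(d * d_pb), d, d_pb), vpb = matrix(rnorm(d_pb), 1),
    bpb = matrix(rnorm(d_pb), 1),
    wout = matrix(rnorm(2 * d_p + d_pb), ncol = 1), bout = matrix(0.1, 1, 1)
  ))
}

test_that("zeroed periodic head weights leave only the non-linear time pathway", {
  hp <- head_fixture()
  hp$wp[] <- 0; hp$up[] <- 0
  ctx <- matrix(c(0.5, -1, 2), 1, 3)
  y1 <- prediction_head(ctx, 0.2, hp)
  y2 <- prediction_head(ctx, 0.9, hp)
  f1 <- attr(y1, "features"); f2 <- attr(y2, "features")
  expect_equal(f1[, 1:2], c(1, 1))  # cos block
  expect_equal(f1[, 3:4], c(0, 0))  # sin block
  expect_equal(f2[, 1:4], f1[, 1:4])
  expect_false(isTRUE(all.equal(f1[, 5:6], f2[, 5:6]))) # GELU branch moves with t
})

test_that("the head matches a scalar hand computation", {
  hp <- head_fixture(seed = 3L)
  ctx <- matrix(c(0.3, -0.7, 1.2), 1, 3)
  tfut <- 0.6
  got <- prediction_head(ctx, tfut, hp)
  u <- as.vector(ctx %*% hp$wp) + tfut * hp$up[1, ]
  g <- (function(x) x * pnorm(x))(
    hp$bpb[1, ] + as.vector(ctx %*% hp$wpb) + tfut * hp$vpb[1, ]
  )
  z <- c(cos(u), sin(u), g)
  expect_equal(got[1, 1], sum(z * hp$wout[, 1]) + 0.1, tolerance = 1e-12)
})

test_that("episodes with zero queries for a variable forecast without error", {
  co <- toy_cohort() # episode a queries var 1 only, b queries var 2 only
  mc <- model_config_small(max_epochs = 1L, dropout = 0)
  fit <- suppressWarnings(train_imts(co, NULL, mc, seed = 2L))
  fc <- forecast_queries(fit, co)
  expect_equal(nrow(fc), 2L)
  expect_true(all(is.finite(fc$prediction)))
  expect_error(forecast_queries(fit, co) |>
                 dplyr::filter(FALSE) |> mta_loss(), "no scored")
})

test_that("alpha = 0 reduces the interval-weighted loss to the masked MSE", {
  fc <- tibble::tibble(
    episode_id = "a", variable_id = c(1L, 1L, 2L, 2L),
    query_time_hours = c(25, 30, 27, 48),
    prediction = c(0.5, -0.2, 1.0, 2.0),
    target_value = c(0.3, NA, 1.5, 1.0)
  )
  sc <- !is.na(fc$target_value)
  expect_equal(mta_loss(fc, alpha = 0),
               mean((fc$prediction[sc] - fc$target_value[sc])^2),
               tolerance = 1e-12)
})

test_that("the worked two-query example evaluates to 0.12 exactly", {
  fc <- tibble::tibble(
    episode_id = "a", variable_id = 1L,
    query_time_hours = c(25, 26), # horizons 1 h and 2 h past T = 24
    prediction = c(0.2, 0.3),
    target_value = c(0.0, 0.0)
  )
  fc$target_value <- fc$prediction - c(0.2, 0.3) # squared errors 0.04, 0.09
  expect_equal(mta_loss(fc, alpha = 0.5, window_end = 24),
               (1.5 * 0.04 + 2.0 * 0.09) / 2)
  expect_identical(mta_loss(fc, alpha = 0.5, window_end = 24), 0.12)
})

test_that("increasing alpha shifts loss weight toward later queries", {
  fc <- tibble::tibble(
    episode_id = "a", variable_id = 1L, query_time_hours = c(25, 47),
    prediction = c(1, 1), target_value = c(0, 0)
  )
  ratio <- function(alpha) {
    w <- 1 + alpha * (fc$query_time_hours - 24)
    (w[2] * 1) / (w[1] * 1)
  }
  expect_true(all(diff(sapply(c(0, 0.1, 0.5, 1), ratio)) > 0))
  expect_gt(mta_loss(fc, 0.5), mta_loss(fc, 0.1))
  expect_error(mta_loss(fc, -1), "non-negative")
})

test_that("metrics vanish for perfect forecasts and follow hand computations", {
  perfect <- tibble::tibble(
    episode_id = "a", variable_id = c(1L, 2L), query_time_hours = c(25, 26),
    prediction = c(1, 2), target_value = c(1, 2)
  )
  ev <- evaluate_forecasts(perfect)
  expect_equal(ev$mse + ev$mae + ev$rmse + ev$mre + ev$mape, 0)
  single <- tibble::tibble(
    episode_id = "a", variable_id = 1L, query_time_hours = 25,
    prediction = 0.8, target_value = 0.5
  )
  ev1 <- evaluate_forecasts(single)
  expect_equal(ev1$mse, 0.09)
  expect_equal(ev1$mae, 0.3)
  expect_equal(ev1$rmse, 0.3)
})

test_that("MSE/MAE use the per-variable then across-variable average", {
  # variable 1 has 3 queries, variable 2 has 2: the two-level average is not
  # the pooled mean
  fc <- tibble::tibble(
    episode_id = "a", variable_id = c(1L, 1L, 1L, 2L, 2L),
    query_time_hours = 25:29,
    prediction = c(1, 2, 3, 4, 5),
    target_value = c(0, 0, 0, 0, 0)
  )
  ev <- evaluate_forecasts(fc)
  mse_oracle <- mean(c(mean(c(1, 4, 9)), mean(c(16, 25))))
  mae_oracle <- mean(c(mean(c(1, 2, 3)), mean(c(4, 5))))
  expect_equal(ev$mse, mse_oracle)
  expect_equal(ev$mae, mae_oracle)
  expect_equal(ev$mre, 15 / 0) # sum|y| = 0: MRE degenerates to Inf here
  expect_equal(ev$n_mape_excluded, 5L)
  expect_true(is.na(ev$mape))
  # MAE <= RMSE on random fixtures (Jensen)
  set.seed(11)
  for (r in 1:5) {
    fcr <- tibble::tibble(
      episode_id = "a", variable_id = rep(1:3, each = 4),
      query_time_hours = rep(25:28, 3),
      prediction = rnorm(12), target_value = rnorm(12)
    )
    evr <- evaluate_forecasts(fcr)
    expect_lte(evr$mae, evr$rmse + 1e-12)
  }
})
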