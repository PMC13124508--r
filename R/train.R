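# End-to-end training with Adam, early stopping on validation loss, and the
# interval-weighted squared-error objective.

clip_global_norm <- function(grads, max_norm) {
  tot <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (is.finite(tot) && tot > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / tot))
  }
  grads
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

batch_grads <- function(model, batch, params) {
  fw <- forward_batch(model, batch, train = TRUE, params = params)
  if (is.null(fw$loss)) return(NULL)
  grads_all <- ad_backward(fw$tape, fw$loss)
  grads <- lapply(fw$leaves, function(l) grads_all[[l$id]])
  list(loss = fw$loss$value[1L, 1L], grads = grads, n_scored = fw$n_scored)
}

eval_loss <- function(model, batches, params) {
  tot <- 0; n <- 0L
  for (b in batches) {
    fw <- forward_batch(model, b, train = FALSE, params = params)
    if (is.null(fw$loss)) next
    tot <- tot + fw$loss$value[1L, 1L] * fw$n_scored
    n <- n + fw$n_scored
  }
  if (n == 0L) return(NA_real_)
  tot / n
}

make_batches <- function(preps, config, order_ids = names(preps)) {
  bs <- config$batch_size
  idx <- split(order_ids, ceiling(seq_along(order_ids) / bs))
  lapply(idx, function(ids) assemble_batch(preps[ids], config))
}

#' Train the forecaster on a cohort
#'
#' Values are standardized with training-set statistics; Lomb-Scargle probe
#' frequencies are fixed from the training cohort; the model is optimized
#' with Adam under the interval-weighted loss, with early stopping on the
#' validation loss and the best-validation parameters retained.
#'
#' @param train_cohort,valid_cohort `imts_cohort`s (validation may be `NULL`,
#'   disabling early stopping).
#' @param config A [model_config()].
#' @param seed Seed of the parameter-initialization stream.
#' @param data_seed Seed of the data-ordering (shuffling/dropout) stream;
#'   defaults to `seed + 10000` and is independent of `seed`.
#' @param verbose Print one line per epoch.
#' @return An `imts_fit`: the trained model plus the standardizer, probe
#'   frequencies and the training history tibble.
#' @export
train_imts <- function(train_cohort, valid_cohort = NULL, config = model_config(),
                       seed = 1L, data_seed = NULL, verbose = FALSE) {
  if (is.null(data_seed)) data_seed <- seed + 10000L
  st <- fit_standardizer(train_cohort)
  trs <- apply_standardizer(train_cohort, st)
  probe <- if (config$no_frequency) numeric(0) else
    probe_frequencies(trs, config$d_fourier)
  model <- init_model(config, seed)
  preps_tr <- prepare_cohort(trs, config, probe)
  valid_batches <- NULL
  if (!is.null(valid_cohort)) {
    vas <- apply_standardizer(valid_cohort, st)
    preps_va <- prepare_cohort(vas, config, probe)
    valid_batches <- make_batches(preps_va, config)
  }
  params <- model$params
  state <- adam_state(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- list()
  wait <- 0L
  ids <- names(preps_tr)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(data_seed + epoch, sample(ids))
    batches <- make_batches(preps_tr, config, ord)
    ep_loss <- 0; ep_n <- 0L
    for (bi in seq_along(batches)) {
      bg <- with_seed(data_seed + 100000L + epoch * 1000L + bi,
                      batch_grads(model, batches[[bi]], params))
      if (is.null(bg)) next
      if (!is.finite(bg$loss)) {
        stop("training diverged: non-finite loss at epoch ", epoch)
      }
      grads <- clip_global_norm(bg$grads, config$grad_clip)
      upd <- adam_step(params, grads, state, config$lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bg$loss * bg$n_scored
      ep_n <- ep_n + bg$n_scored
    }
    tr_loss <- if (ep_n) ep_loss / ep_n else NA_real_
    va_loss <- if (!is.null(valid_batches)) {
      eval_loss(model, valid_batches, params)
    } else NA_real_
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tr_loss,
                                       valid_loss = va_loss)
    if (verbose) {
      message(sprintf("epoch %3d  train %.5f  valid %.5f", epoch, tr_loss,
                      va_loss))
    }
    monitor <- if (is.na(va_loss)) tr_loss else va_loss
    if (monitor < best$loss - 1e-12) {
      best <- list(loss = monitor, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (!is.null(valid_batches) && wait > config$patience) break
    }
  }
  structure(list(
    config = config, params = best$params, standardizer = st,
    probe_frequencies = probe,
    history = dplyr::bind_rows(history),
    best_epoch = best$epoch, best_valid_loss = best$loss,
    seed = seed, data_seed = data_seed
  ), class = c("imts_fit", "imts_model"))
}

#' @export
print.imts_fit <- function(x, ...) {
  cat(sprintf(
    "<imts_fit> %d parameters, trained %d epochs (best epoch %d, monitored loss %.5f)\n",
    n_params(x), nrow(x$history), x$best_epoch, x$best_valid_loss
  ))
  invisible(x)
}

#' Forecast the queries of a cohort
#'
#' Runs the trained model over each episode's history and predicts the value
#' of every query row. Predictions are made in standardized space;
#' `rescale = TRUE` maps predictions and targets back to the raw scale.
#'
#' @param fit An `imts_fit`.
#' @param cohort An `imts_cohort` with query rows (raw scale).
#' @param rescale Return raw-scale values instead of standardized ones.
#' @param batch_size Episodes per forward pass.
#' @return A forecast tibble: `episode_id`, `variable_id`,
#'   `query_time_hours`, `prediction`, `target_value`, `scored`.
#' @export
forecast_queries <- function(fit, cohort, rescale = FALSE, batch_size = 32L) {
  stopifnot(inherits(fit, "imts_fit"))
  std <- apply_standardizer(cohort, fit$standardizer)
  preps <- prepare_cohort(std, fit$config, fit$probe_frequencies)
  ids <- names(preps)
  out <- list()
  for (chunk in split(ids, ceiling(seq_along(ids) / batch_size))) {
    batch <- assemble_batch(preps[chunk], fit$config)
    fw <- forward_batch(fit, batch, train = FALSE)
    if (is.null(fw$qtab) || !nrow(fw$qtab)) next
    out[[length(out) + 1L]] <- tibble::tibble(
      episode_id = fw$qtab$episode_id,
      variable_id = fw$qtab$variable_id,
      query_time_hours = fw$qtab$query_time_hours,
      prediction = as.vector(fw$yhat$value),
      target_value = fw$qtab$target,
      scored = !is.na(fw$qtab$target)
    )
  }
  fc <- dplyr::bind_rows(out)
  if (rescale && nrow(fc)) {
    mu <- fit$standardizer$mean[match(fc$variable_id, fit$standardizer$variable_id)]
    sd <- fit$standardizer$sd[match(fc$variable_id, fit$standardizer$variable_id)]
    fc$prediction <- fc$prediction * sd + mu
    fc$target_value <- fc$target_value * sd + mu
  }
  fc
}

#' Forward one episode, returning forecasts and its interval graphs
#'
#' @param fit An `imts_fit`.
#' @param cohort The cohort holding the episode (raw scale).
#' @param episode_id Which episode to run.
#' @return List with `forecasts` (tibble) and `graphs` (list per block of
#'   `N x N x P1` adjacency arrays).
#' @export
forward_episode <- function(fit, cohort, episode_id) {
  std <- apply_standardizer(filter_episodes(cohort, episode_id),
                            fit$standardizer)
  preps <- prepare_cohort(std, fit$config, fit$probe_frequencies)
  batch <- assemble_batch(preps, fit$config)
  fw <- forward_batch(fit, batch, train = FALSE, store_adj = TRUE)
  fc <- if (!is.null(fw$qtab) && nrow(fw$qtab)) tibble::tibble(
    episode_id = fw$qtab$episode_id, variable_id = fw$qtab$variable_id,
    query_time_hours = fw$qtab$query_time_hours,
    prediction = as.vector(fw$yhat$value), target_value = fw$qtab$target
  ) else tibble::tibble()
  list(forecasts = fc, graphs = fw$adjacency)
}

#' Episode-aggregated learned graphs of a cohort
#'
#' Runs the model over the cohort and returns, per episode, the temporal mean
#' of the interval adjacencies of the last modelling block, plus the grand
#' mean across episodes.
#'
#' @param fit An `imts_fit`.
#' @param cohort An `imts_cohort`.
#' @param batch_size Episodes per forward pass.
#' @return List with `per_episode` (named list of `N x N` summaries) and
#'   `mean` (`imts_graph_summary`).
#' @export
episode_graphs <- function(fit, cohort, batch_size = 32L) {
  if (fit$config$no_graph) stop("model was trained without the graph stage")
  std <- apply_standardizer(cohort, fit$standardizer)
  preps <- prepare_cohort(std, fit$config, fit$probe_frequencies)
  ids <- names(preps)
  per <- list()
  for (chunk in split(ids, ceiling(seq_along(ids) / batch_size))) {
    batch <- assemble_batch(preps[chunk], fit$config)
    fw <- forward_batch(fit, batch, train = FALSE, store_adj = TRUE)
    adj <- fw$adjacency[[length(fw$adjacency)]] # last block
    bm <- batch$block_map
    for (id in unique(bm$episode_id)) {
      sel <- which(bm$episode_id == id)
      per[[id]] <- aggregate_episode_graph(adj[, , sel, drop = FALSE])
    }
  }
  gm <- aggregate_episode_graph(per)
  list(per_episode = per, mean = gm)
}

#' Interval-weighted forecasting loss
#'
#' `L = mean over scored queries of (1 + alpha (tau - T)) (yhat - y)^2`.
#' With `alpha = 0` this is the plain masked mean squared error; `alpha > 0`
#' up-weights queries farther into the future (horizon distance in hours).
#'
#' @param forecasts Forecast tibble from [forecast_queries()].
#' @param alpha Non-negative horizon-weight slope.
#' @param window_end Observation window end `T` (hours).
#' @return Scalar loss.
#' @export
mta_loss <- function(forecasts, alpha = 0.1, window_end = 24) {
  if (alpha < 0) stop("alpha must be non-negative")
  sc <- forecasts[!is.na(forecasts$target_value), ]
  if (!nrow(sc)) stop("no scored queries")
  w <- 1 + alpha * (sc$query_time_hours - window_end)
  mean(w * (sc$prediction - sc$target_value)^2)
}

#' Forecast-accuracy metrics
#'
#' MSE and MAE use the two-level average of the evaluation protocol: per
#' variable over its scored queries, then over variables. RMSE is the square
#' root of MSE. MRE is the aggregate relative error `sum|e| / sum|y|`; MAPE
#' excludes targets with `|y| < eps` (their count is reported).
#'
#' @param forecasts Forecast tibble.
#' @param eps Guard for the MAPE denominator.
#' @return One-row tibble: `mse`, `mae`, `rmse`, `mre`, `mape`, `n_queries`,
#'   `n_mape_excluded`.
#' @export
evaluate_forecasts <- function(forecasts, eps = 1e-8) {
  sc <- forecasts[!is.na(forecasts$target_value), ]
  if (!nrow(sc)) stop("no scored queries")
  per_var <- sc |>
    dplyr::group_by(.data$variable_id) |>
    dplyr::summarise(
      mse = mean((.data$prediction - .data$target_value)^2),
      mae = mean(abs(.data$prediction - .data$target_value)),
      .groups = "drop"
    )
  mse <- mean(per_var$mse)
  mae <- mean(per_var$mae)
  mape_ok <- abs(sc$target_value) >= eps
  tibble::tibble(
    mse = mse, mae = mae, rmse = sqrt(mse),
    mre = sum(abs(sc$prediction - sc$target_value)) / sum(abs(sc$target_value)),
    mape = if (any(mape_ok)) {
      100 * mean(abs((sc$prediction - sc$target_value) /
                       sc$target_value)[mape_ok])
    } else NA_real_,
    n_queries = nrow(sc), n_mape_excluded = sum(!mape_ok)
  )
}

#' Save / load a fit as JSON (text-only checkpoint)
#' @param fit An `imts_fit`.
#' @param path Destination file.
#' @return The fit (invisibly for write).
#' @export
write_fit <- function(fit, path) {
  ser <- list(
    config = fit$config[setdiff(names(fit$config), "spec")],
    params = lapply(fit$params, function(p) list(dim = dim(p), x = as.vector(p))),
    standardizer = as.data.frame(fit$standardizer),
    probe_frequencies = fit$probe_frequencies,
    history = as.data.frame(fit$history),
    best_epoch = fit$best_epoch, best_valid_loss = fit$best_valid_loss,
    seed = fit$seed, data_seed = fit$data_seed
  )
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(fit)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgargs <- ser$config
  cfgargs <- cfgargs[names(cfgargs) %in% names(formals(model_config))]
  if (isTRUE(cfgargs$single_scale)) {
    # scales were already reduced before saving; avoid re-reducing
    cfgargs$single_scale <- FALSE
    cfg <- do.call(model_config, cfgargs)
    cfg$single_scale <- TRUE
  } else {
    cfg <- do.call(model_config, cfgargs)
  }
  params <- lapply(ser$params, function(p) {
    if (is.null(p$dim)) matrix(p$x, 1L) else matrix(p$x, p$dim[1L], p$dim[2L])
  })
  st <- tibble::as_tibble(ser$standardizer)
  st$variable_id <- as.integer(st$variable_id)
  structure(list(
    config = cfg, params = params,
    standardizer = structure(st, class = c("imts_standardizer", class(st))),
    probe_frequencies = as.numeric(ser$probe_frequencies),
    history = tibble::as_tibble(ser$history),
    best_epoch = ser$best_epoch, best_valid_loss = ser$best_valid_loss,
    seed = ser$seed, data_seed = ser$data_seed
  ), class = c("imts_fit", "imts_model"))
}
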