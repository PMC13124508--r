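#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameter groups of a fit
#'
#' One row per parameter matrix: its name, shape and Frobenius norm — handy
#' for spotting dead or exploding components.
#'
#' @param x An `imts_fit`.
#' @param ... Unused.
#' @return Tibble with columns `parameter`, `rows`, `cols`, `n`, `norm`.
#' @exportS3Method generics::tidy
tidy.imts_fit <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$params),
    rows = vapply(x$params, nrow, 0L),
    cols = vapply(x$params, ncol, 0L),
    n = vapply(x$params, length, 0L),
    norm = vapply(x$params, function(p) sqrt(sum(p^2)), 0)
  )
}

#' One-row summary of a fit
#'
#' @param x An `imts_fit`.
#' @param ... Unused.
#' @return Tibble with `n_params`, `epochs`, `best_epoch`, `best_valid_loss`,
#'   `final_train_loss`.
#' @exportS3Method generics::glance
glance.imts_fit <- function(x, ...) {
  tibble::tibble(
    n_params = n_params(x),
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_valid_loss = x$best_valid_loss,
    final_train_loss = utils::tail(x$history$train_loss, 1L)
  )
}

#' Training-curve plot
#' @param object An `imts_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.imts_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(.data$epoch, .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "interval-weighted loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of an episode-aggregated learned graph
#' @param object An `imts_graph_summary`.
#' @param normalize Rescale weights to `[0, 1]` for display.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.imts_graph_summary <- function(object, normalize = TRUE, ...) {
  w <- unclass(object)
  if (normalize) {
    rng <- range(w)
    if (diff(rng) > 0) w <- (w - rng[1L]) / diff(rng)
  }
  df <- tidyr::expand_grid(source = seq_len(nrow(w)), target = seq_len(ncol(w)))
  df$weight <- w[cbind(df$source, df$target)]
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$source,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "target variable", y = "source variable",
                  fill = "mean edge\nweight") +
    ggplot2::theme_minimal()
}

#' Observed history and forecasts of one episode
#'
#' @param cohort The raw-scale `imts_cohort`.
#' @param forecasts A forecast tibble from [forecast_queries()] (same scale
#'   as the cohort — use `rescale = TRUE` for raw-scale cohorts).
#' @param episode_id Episode to display.
#' @return A ggplot: observations as points, forecasts as crosses, targets as
#'   open circles, faceted by variable.
#' @export
plot_episode_forecast <- function(cohort, forecasts, episode_id) {
  obs <- dplyr::filter(cohort$observations, .data$episode_id == !!episode_id)
  fc <- dplyr::filter(forecasts, .data$episode_id == !!episode_id)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = obs, ggplot2::aes(.data$time_hours, .data$value),
                        size = 0.8) +
    ggplot2::geom_point(data = fc, ggplot2::aes(.data$query_time_hours,
                                                .data$prediction),
                        shape = 4, colour = "red") +
    ggplot2::geom_point(data = fc[!is.na(fc$target_value), ],
                        ggplot2::aes(.data$query_time_hours, .data$target_value),
                        shape = 1, colour = "blue") +
    ggplot2::geom_vline(xintercept = cohort$window_end, linetype = 2) +
    ggplot2::facet_wrap(~variable_id, scales = "free_y") +
    ggplot2::labs(x = "hours since admission", y = "value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
"_PACKAGE"
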