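#' Test-time robustness to additional missingness
#'
#' Perturbs the test cohort only (trained parameters fixed): for every
#' combination of additional missingness rate `rho` and masking pattern
#' (point-wise MCAR, block-wise), the perturbation is repeated with
#' `n_seeds` seeds and the forecast metrics are reported. The `rho = 0` rows
#' are the unperturbed evaluation and are identical across patterns.
#'
#' @param fit An `imts_fit`.
#' @param test_cohort Test `imts_cohort` (raw scale).
#' @param rhos Additional missingness rates.
#' @param patterns Subset of `c("pointwise", "blockwise")`.
#' @param n_seeds Perturbation seeds per cell.
#' @param seed Base seed for the perturbation streams.
#' @return Tibble with one row per (rho, pattern, seed) and the metric
#'   columns of [evaluate_forecasts()].
#' @export
run_robustness <- function(fit, test_cohort, rhos = c(0, 0.1, 0.2, 0.3, 0.4, 0.5),
                           patterns = c("pointwise", "blockwise"),
                           n_seeds = 5L, seed = 1L) {
  patterns <- match.arg(patterns, several.ok = TRUE)
  base_fc <- forecast_queries(fit, test_cohort)
  base_metrics <- evaluate_forecasts(base_fc)
  out <- list()
  for (pattern in patterns) {
    for (rho in rhos) {
      for (s in seq_len(n_seeds)) {
        if (rho == 0) {
          met <- base_metrics
        } else {
          pseed <- seed + 1000L * s + round(1e6 * rho)
          pc <- if (pattern == "pointwise") {
            perturb_pointwise_mcar(test_cohort, rho, pseed)
          } else {
            perturb_blockwise(test_cohort, rho, pseed)
          }
          met <- evaluate_forecasts(forecast_queries(fit, pc))
        }
        out[[length(out) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(rho = rho, pattern = pattern, seed = s), met
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Summarize a robustness table as mean +/- sd per cell
#' @param robustness Output of [run_robustness()].
#' @return Tibble with per-(rho, pattern) mean and sd of MSE and MAE.
#' @export
summarize_robustness <- function(robustness) {
  robustness |>
    dplyr::group_by(.data$rho, .data$pattern) |>
    dplyr::summarise(
      mse_mean = mean(.data$mse), mse_sd = stats::sd(.data$mse),
      mae_mean = mean(.data$mae), mae_sd = stats::sd(.data$mae),
      .groups = "drop"
    )
}

ablation_variants <- c("complete", "no_patching", "single_scale",
                       "no_frequency", "no_transformer", "no_graph")

apply_variant <- function(config, variant) {
  variant <- match.arg(variant, ablation_variants)
  if (variant == "complete") return(config)
  args <- config[names(config) %in% names(formals(model_config))]
  if (isTRUE(config$single_scale)) args$scales <- NULL # already reduced
  args[[variant]] <- TRUE
  do.call(model_config, args)
}

#' Train and evaluate the model and its ablation variants
#'
#' Variants: `no_patching` (-P, one patch per union timestamp),
#' `single_scale` (-M, finest scale only), `no_frequency` (-F, TTCN-only
#' embeddings, no spectral features in graph construction),
#' `no_transformer` (-T, contextualization replaced by identity),
#' `no_graph` (-G, GCN stage skipped). Every variant is trained on the same
#' split with the same seeds.
#'
#' @param train_cohort,valid_cohort,test_cohort `imts_cohort`s.
#' @param config Base [model_config()].
#' @param variants Subset of the variant names (default: all plus complete).
#' @param seeds Training seeds (results are reported per seed).
#' @param verbose Print progress.
#' @return Tibble with one row per (variant, seed): metric columns plus
#'   `n_params`.
#' @export
run_ablation <- function(train_cohort, valid_cohort, test_cohort,
                         config = model_config(), variants = ablation_variants,
                         seeds = 1:3, verbose = FALSE) {
  out <- list()
  for (variant in variants) {
    cfg <- apply_variant(config, variant)
    for (s in seeds) {
      if (verbose) message("training variant ", variant, " seed ", s)
      fit <- train_imts(train_cohort, valid_cohort, cfg, seed = s)
      met <- evaluate_forecasts(forecast_queries(fit, test_cohort))
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(variant = variant, seed = s, n_params = n_params(fit)),
        met
      )
    }
  }
  dplyr::bind_rows(out)
}
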