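#' Multi-scale patch specification
#'
#' Defines the `S` patch duration scales `L_1 < ... < L_S` (hours) used to cut
#' every univariate series into non-overlapping, temporally aligned patches
#' over the observation window `[0, T]`. The default scale set is
#' `{1, 2, 4, 8, 24}` hours over a 24-hour window, giving
#' `P_s = T / L_s = {24, 12, 6, 3, 1}` patches per scale; the finest scale
#' defines the canonical timeline used downstream.
#'
#' @param scales Strictly increasing patch durations; every scale must be an
#'   integer multiple of the finest.
#' @param window_end Observation window end `T` (hours).
#' @return A `patch_spec`.
#' @export
patch_spec <- function(scales = c(1, 2, 4, 8, 24), window_end = 24) {
  if (length(scales) < 1L || any(diff(scales) <= 0)) {
    stop("scales must be strictly increasing")
  }
  if (any(abs(scales / scales[1L] - round(scales / scales[1L])) > 1e-9)) {
    stop("every scale must be an integer multiple of the finest scale")
  }
  if (max(scales) > window_end) stop("scales cannot exceed the window length")
  structure(list(scales = as.numeric(scales), window_end = window_end),
            class = "patch_spec")
}

#' Number of patches per scale
#'
#' `floor(T / L_s)`, plus one short trailing patch when `T` is not an integer
#' multiple of `L_s` (so no observation is dropped).
#'
#' @param spec A [patch_spec()].
#' @return Integer vector, one count per scale.
#' @export
patch_counts <- function(spec) {
  full <- floor(spec$window_end / spec$scales + 1e-9)
  extra <- (spec$window_end - full * spec$scales) > 1e-9
  as.integer(full + extra)
}

# patch index of times under the half-open rule, with the final patch closed
# on the right so an observation exactly at t = T stays in the history
patch_index <- function(t, scale, spec) {
  np <- ceiling(spec$window_end / scale - 1e-9)
  p <- floor(t / scale) + 1L
  pmin(as.integer(p), as.integer(np))
}

# rescaled within-patch time in [0, 1); boundary-closed points clamp to 1-eps
rescale_time <- function(t, p, scale) {
  pmin((t - (p - 1) * scale) / scale, 1 - 1e-9)
}

#' Build the multi-scale patch grid of one episode
#'
#' Assigns every observation with `t <= T` to exactly one patch per scale by
#' the half-open rule `(p-1) L_s <= t < p L_s` (the final patch additionally
#' includes `t = T`), and attaches the linearly rescaled within-patch
#' timestamp `t_rescaled in [0, 1)`. Patches with equal index share the exact
#' same span across variables, which is what aligns the variables in time.
#'
#' @param observations Tibble with columns `variable_id`, `time_hours`,
#'   `value` for a single episode (e.g. one episode of an `imts_cohort`).
#' @param spec A [patch_spec()].
#' @return A `patch_grid` tibble with one row per (observation, scale):
#'   columns `variable_id`, `scale_idx`, `scale`, `patch`, `span_start`,
#'   `span_end`, `time_hours`, `value`, `t_rescaled`.
#' @export
build_patch_grid <- function(observations, spec) {
  stopifnot(inherits(spec, "patch_spec"))
  obs <- tibble::as_tibble(observations)
  if (any(obs$time_hours > spec$window_end)) {
    stop("observations beyond window_end cannot be patched")
  }
  np <- patch_counts(spec)
  out <- purrr::map_dfr(seq_along(spec$scales), function(s) {
    L <- spec$scales[s]
    p <- patch_index(obs$time_hours, L, spec)
    tibble::tibble(
      variable_id = obs$variable_id,
      scale_idx = s, scale = L, patch = p,
      span_start = (p - 1) * L,
      span_end = pmin(p * L, spec$window_end),
      time_hours = obs$time_hours, value = obs$value,
      t_rescaled = rescale_time(obs$time_hours, p, L)
    )
  })
  out <- dplyr::arrange(out, .data$scale_idx, .data$variable_id,
                        .data$patch, .data$time_hours)
  attr(out, "spec") <- spec
  attr(out, "patch_counts") <- np
  class(out) <- c("patch_grid", class(out))
  out
}

#' Patch spans and occupancy of a grid (debug view)
#' @param grid A `patch_grid`.
#' @return Tibble with per-(variable, scale, patch) observation counts.
#' @export
patch_grid_summary <- function(grid) {
  dplyr::count(tibble::as_tibble(grid), .data$variable_id, .data$scale_idx,
               .data$scale, .data$patch, .data$span_start, .data$span_end,
               name = "n_obs")
}

#' Dump a patch grid's spans and counts to JSON for inspection
#' @param grid A `patch_grid`.
#' @param path JSON destination.
#' @return The grid, invisibly.
#' @export
write_patch_grid <- function(grid, path) {
  jsonlite::write_json(as.data.frame(patch_grid_summary(grid)), path, digits = NA)
  invisible(grid)
}

# representative patch of scale s covering canonical interval k: the unique
# scale-s patch whose span contains the k-th finest-scale interval
covering_patch <- function(k, scale, spec) {
  l1 <- spec$scales[1L]
  np <- ceiling(spec$window_end / scale - 1e-9)
  pmin(as.integer(ceiling(k * l1 / scale - 1e-9)), as.integer(np))
}
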