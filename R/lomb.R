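# Classical Lomb-Scargle periodogram for unevenly sampled series. The
# Scargle-normalized form with mean-centering is used (no floating-mean
# generalization): with omega = 2 pi f and tau defined by
# tan(2 omega tau) = sum sin(2 omega t) / sum cos(2 omega t),
#   P(f) = 1/(2 sigma^2) [ (sum yc cos(omega(t - tau)))^2 / sum cos^2 +
#                          (sum yc sin(omega(t - tau)))^2 / sum sin^2 ].

#' Lomb-Scargle normalized power at given frequencies
#'
#' @param times Observation times (hours), irregularly spaced.
#' @param values Observation values.
#' @param frequencies Probe frequencies (cycles/hour), non-negative.
#' @return Numeric vector of normalized powers (zero at frequency 0 and for
#'   degenerate inputs such as constant signals).
#' @export
lomb_scargle_power <- function(times, values, frequencies) {
  n <- length(times)
  stopifnot(length(values) == n)
  yc <- values - mean(values)
  s2 <- mean(yc^2)
  out <- numeric(length(frequencies))
  if (n < 2L || s2 <= .Machine$double.eps) return(out)
  for (q in seq_along(frequencies)) {
    f <- frequencies[q]
    if (f <= 0) next
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    ct <- cos(w * (times - tau))
    st <- sin(w * (times - tau))
    cc <- sum(ct^2); ss <- sum(st^2)
    pc <- if (cc > 0) sum(yc * ct)^2 / cc else 0
    ps <- if (ss > 0) sum(yc * st)^2 / ss else 0
    out[q] <- (pc + ps) / (2 * s2)
  }
  out
}

#' Probe frequency grid for spectral node features
#'
#' `n` frequencies evenly spaced in `(0, f_max]`, with
#' `f_max = 1 / (2 * median inter-observation gap)` of the training cohort,
#' capped at `cap` cycles/hour.
#'
#' @param cohort Training `imts_cohort`.
#' @param n Number of probe frequencies (default 10).
#' @param cap Upper cap on `f_max` (cycles/hour).
#' @return Numeric vector of length `n`.
#' @export
probe_frequencies <- function(cohort, n = 10L, cap = 2) {
  obs <- cohort$observations
  gaps <- obs |>
    dplyr::group_by(.data$episode_id, .data$variable_id) |>
    dplyr::summarise(g = list(diff(.data$time_hours)), .groups = "drop")
  g <- unlist(gaps$g)
  g <- g[g > 0]
  med <- if (length(g)) stats::median(g) else 1
  fmax <- min(1 / (2 * med), cap)
  seq(fmax / n, fmax, length.out = n)
}

#' Spectral node features for one variable around a canonical interval
#'
#' Lomb-Scargle power at the probe frequencies, computed over the
#' coarsest-scale patch covering canonical interval `k` (a single
#' finest-scale interval rarely holds enough points at ICU-level
#' missingness). Windows with fewer than 3 observations return a zero vector
#' flagged as degenerate.
#'
#' @param observations One episode's observations (tibble with
#'   `variable_id`, `time_hours`, `value`).
#' @param variable Variable index.
#' @param interval_k Canonical interval index.
#' @param spec A [patch_spec()].
#' @param frequencies Probe frequency grid.
#' @return Numeric vector of length `length(frequencies)` with attribute
#'   `degenerate` (logical).
#' @export
lomb_scargle_features <- function(observations, variable, interval_k, spec,
                                  frequencies) {
  ls <- spec$scales[length(spec$scales)]
  p <- covering_patch(interval_k, ls, spec)
  lo <- (p - 1) * ls
  hi <- min(p * ls, spec$window_end)
  obs <- observations[observations$variable_id == variable &
                        observations$time_hours >= lo &
                        (observations$time_hours < hi |
                           (observations$time_hours <= hi & hi >= spec$window_end)), ]
  if (nrow(obs) < 3L) {
    return(structure(numeric(length(frequencies)), degenerate = TRUE))
  }
  structure(lomb_scargle_power(obs$time_hours, obs$value, frequencies),
            degenerate = FALSE)
}
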