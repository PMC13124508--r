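#' Irregular multivariate time-series cohorts
#'
#' An `imts_cohort` bundles the long-format observation table of a set of
#' patient episodes with the future query table used for forecasting. Each
#' episode covers an observation window `[0, window_end]` (hours since episode
#' start); forecasts are requested at query times in
#' `(window_end, window_end + horizon]`.
#'
#' @param observations Tibble with columns `episode_id` (character),
#'   `variable_id` (integer in `1..n_variables`), `time_hours`, `value`.
#' @param queries Tibble with columns `episode_id`, `variable_id`,
#'   `query_time_hours`, `target_value` (may be `NA` when the future truth is
#'   unknown). May be `NULL`.
#' @param n_variables Number of variables `N` (at least 2).
#' @param window_end End of the observation window `T` in hours.
#' @param horizon Forecast horizon `H` in hours.
#'
#' @return An object of class `imts_cohort`.
#' @export
imts_cohort <- function(observations, queries = NULL, n_variables,
                        window_end = 24, horizon = 24) {
  observations <- tibble::as_tibble(observations)
  req <- c("episode_id", "variable_id", "time_hours", "value")
  if (!all(req %in% names(observations))) {
    stop("observations must have columns ", paste(req, collapse = ", "))
  }
  observations$episode_id <- as.character(observations$episode_id)
  observations$variable_id <- as.integer(observations$variable_id)
  if (nrow(observations)) {
    if (any(!is.finite(observations$value))) stop("observation values must be finite")
    if (any(observations$time_hours < 0)) stop("observation times must be non-negative")
    if (any(observations$time_hours > window_end)) {
      stop("observation times must lie within [0, window_end]")
    }
    if (any(observations$variable_id < 1L | observations$variable_id > n_variables)) {
      stop("variable_id out of range 1..n_variables")
    }
  }
  observations <- dplyr::arrange(observations, .data$episode_id,
                                 .data$variable_id, .data$time_hours)
  dup <- duplicated(observations[, c("episode_id", "variable_id", "time_hours")])
  if (any(dup)) {
    d <- observations[dup, ][1L, ]
    stop(sprintf(
      "duplicate observation for episode '%s', variable %d at t = %g h",
      d$episode_id, d$variable_id, d$time_hours
    ))
  }
  if (is.null(queries)) {
    queries <- tibble::tibble(episode_id = character(), variable_id = integer(),
                              query_time_hours = double(), target_value = double())
  }
  queries <- tibble::as_tibble(queries)
  reqq <- c("episode_id", "variable_id", "query_time_hours")
  if (!all(reqq %in% names(queries))) {
    stop("queries must have columns ", paste(reqq, collapse = ", "))
  }
  if (!"target_value" %in% names(queries)) queries$target_value <- NA_real_
  queries$episode_id <- as.character(queries$episode_id)
  queries$variable_id <- as.integer(queries$variable_id)
  if (nrow(queries)) {
    bad <- queries$query_time_hours <= window_end |
      queries$query_time_hours > window_end + horizon
    if (any(bad)) stop("query times must lie in (window_end, window_end + horizon]")
  }
  if (n_variables < 2L) stop("an IMTS cohort needs at least 2 variables")
  structure(
    list(observations = observations, queries = queries,
         n_variables = as.integer(n_variables),
         window_end = window_end, horizon = horizon),
    class = "imts_cohort"
  )
}

#' @export
print.imts_cohort <- function(x, ...) {
  cat(sprintf(
    "<imts_cohort> %d episodes, %d variables, T = %g h, horizon = %g h\n",
    length(episode_ids(x)), x$n_variables, x$window_end, x$horizon
  ))
  cat(sprintf("  %d observations, %d queries\n",
              nrow(x$observations), nrow(x$queries)))
  invisible(x)
}

#' Episode identifiers of a cohort
#' @param cohort An `imts_cohort`.
#' @return Character vector of distinct episode ids (sorted).
#' @export
episode_ids <- function(cohort) {
  sort(unique(c(cohort$observations$episode_id, cohort$queries$episode_id)))
}

#' Restrict a cohort to a subset of episodes
#' @param cohort An `imts_cohort`.
#' @param ids Episode ids to keep.
#' @return An `imts_cohort` containing only the requested episodes.
#' @export
filter_episodes <- function(cohort, ids) {
  out <- cohort
  out$observations <- dplyr::filter(cohort$observations, .data$episode_id %in% ids)
  out$queries <- dplyr::filter(cohort$queries, .data$episode_id %in% ids)
  out
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Read a cohort from long-format CSV tables
#'
#' The canonical on-disk format is a delimited text table with one row per
#' observation (`episode_id, variable_id, time_hours, value`) plus an optional
#' companion query table (`episode_id, variable_id, query_time_hours,
#' target_value`).
#'
#' @param obs_path Path to the observation CSV (header required).
#' @param query_path Optional path to the query CSV.
#' @inheritParams imts_cohort
#' @return An `imts_cohort`.
#' @examples
#' obs <- system.file("extdata", "example_observations.csv", package = "imtscast")
#' qry <- system.file("extdata", "example_queries.csv", package = "imtscast")
#' read_imts(obs, qry)
#' @export
read_imts <- function(obs_path, query_path = NULL, n_variables = NULL,
                      window_end = 24, horizon = 24) {
  obs <- readr::read_csv(obs_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           episode_id = readr::col_character(),
                           variable_id = readr::col_integer(),
                           time_hours = readr::col_double(),
                           value = readr::col_double()
                         ))
  pr <- readr::problems(obs)
  if (nrow(pr)) {
    stop(sprintf("malformed observation row at line %d: %s",
                 pr$row[1L] + 1L, pr$expected[1L]))
  }
  qr <- NULL
  if (!is.null(query_path)) {
    qr <- readr::read_csv(query_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            episode_id = readr::col_character(),
                            variable_id = readr::col_integer(),
                            query_time_hours = readr::col_double(),
                            target_value = readr::col_double()
                          ))
    pq <- readr::problems(qr)
    if (nrow(pq)) {
      stop(sprintf("malformed query row at line %d: %s",
                   pq$row[1L] + 1L, pq$expected[1L]))
    }
  }
  if (is.null(n_variables)) {
    n_variables <- max(2L, obs$variable_id, qr$variable_id)
  }
  imts_cohort(obs, qr, n_variables = n_variables,
              window_end = window_end, horizon = horizon)
}

#' Write a cohort to long-format CSV tables
#' @param cohort An `imts_cohort`.
#' @param obs_path Destination for the observation table.
#' @param query_path Optional destination for the query table.
#' @return `cohort`, invisibly.
#' @export
write_imts <- function(cohort, obs_path, query_path = NULL) {
  readr::write_csv(cohort$observations, obs_path)
  if (!is.null(query_path)) readr::write_csv(cohort$queries, query_path)
  invisible(cohort)
}

#' Split a cohort into train/validation/test sets at the episode level
#'
#' Episodes are partitioned randomly; every episode lands in exactly one
#' subset. Default fractions are 60/20/20.
#'
#' @param cohort An `imts_cohort`.
#' @param fractions Numeric vector summing to 1 (names are used for the output).
#' @param seed Integer seed making the partition reproducible.
#' @return Named list of `imts_cohort`s, one per fraction.
#' @export
split_episodes <- function(cohort, fractions = c(train = 0.6, valid = 0.2, test = 0.2),
                           seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  ids <- episode_ids(cohort)
  n <- length(ids)
  nz <- sum(fractions > 0)
  if (n < nz) stop("fewer episodes than non-empty subsets")
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) { # largest remainders get the leftover episodes
    fr <- fractions * n - sizes
    ord <- order(fr, decreasing = TRUE)
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
  }
  perm <- with_seed(seed, sample(ids))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  out <- lapply(seq_along(fractions), function(j) {
    keep <- if (sizes[j] > 0) perm[starts[j]:ends[j]] else character(0)
    filter_episodes(cohort, keep)
  })
  names(out) <- if (!is.null(names(fractions))) names(fractions) else
    paste0("subset", seq_along(fractions))
  out
}

#' Per-variable standardization statistics
#'
#' Means and standard deviations are estimated on training episodes only and
#' later applied to any cohort. The standard deviation uses the population
#' convention (divide by n). Variables with zero variance get sd 1 (with a
#' warning); variables never observed in training get mean 0, sd 1.
#'
#' @param cohort Training `imts_cohort`.
#' @return An `imts_standardizer`: a tibble with columns `variable_id`,
#'   `mean`, `sd`.
#' @export
fit_standardizer <- function(cohort) {
  obs <- cohort$observations
  st <- obs |>
    dplyr::group_by(.data$variable_id) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = sqrt(mean((.data$value - mean(.data$value))^2)),
      .groups = "drop"
    )
  all_vars <- tibble::tibble(variable_id = seq_len(cohort$n_variables))
  st <- dplyr::left_join(all_vars, st, by = "variable_id")
  st$mean[is.na(st$mean)] <- 0
  st$sd[is.na(st$sd)] <- 1
  if (any(st$sd == 0)) {
    warning("zero-variance variable(s): standard deviation forced to 1")
    st$sd[st$sd == 0] <- 1
  }
  structure(st, class = c("imts_standardizer", class(st)))
}

#' Standardize (or de-standardize) a cohort's values
#'
#' Observation values and known query targets are transformed with the
#' training-set statistics. The transform is exactly invertible.
#'
#' @param cohort An `imts_cohort`.
#' @param standardizer An `imts_standardizer` from [fit_standardizer()].
#' @param invert If `TRUE`, map standardized values back to the raw scale.
#' @return The transformed `imts_cohort`.
#' @export
apply_standardizer <- function(cohort, standardizer, invert = FALSE) {
  mu <- standardizer$mean[match(cohort$observations$variable_id,
                                standardizer$variable_id)]
  sd <- standardizer$sd[match(cohort$observations$variable_id,
                              standardizer$variable_id)]
  out <- cohort
  out$observations$value <- if (invert) cohort$observations$value * sd + mu else
    (cohort$observations$value - mu) / sd
  if (nrow(cohort$queries)) {
    muq <- standardizer$mean[match(cohort$queries$variable_id,
                                   standardizer$variable_id)]
    sdq <- standardizer$sd[match(cohort$queries$variable_id,
                                 standardizer$variable_id)]
    out$queries$target_value <- if (invert)
      cohort$queries$target_value * sdq + muq else
      (cohort$queries$target_value - muq) / sdq
  }
  out
}

#' Save / load standardizer statistics as JSON
#' @param standardizer An `imts_standardizer`.
#' @param path JSON file path.
#' @return The standardizer (invisibly for write).
#' @export
write_standardizer <- function(standardizer, path) {
  jsonlite::write_json(as.data.frame(standardizer), path, digits = NA)
  invisible(standardizer)
}

#' @rdname write_standardizer
#' @export
read_standardizer <- function(path) {
  st <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  st$variable_id <- as.integer(st$variable_id)
  structure(st, class = c("imts_standardizer", class(st)))
}

#' Point-wise MCAR test-time perturbation
#'
#' Independently removes each observation with probability `rho`, emulating
#' additional missing-completely-at-random dropout at inference time. Query
#' rows are never touched.
#'
#' @param cohort An `imts_cohort`.
#' @param rho Additional missingness rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return The perturbed `imts_cohort`.
#' @export
perturb_pointwise_mcar <- function(cohort, rho, seed = 1L) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (rho == 0) return(cohort)
  n <- nrow(cohort$observations)
  drop <- with_seed(seed, stats::runif(n) < rho)
  out <- cohort
  out$observations <- cohort$observations[!drop, ]
  out
}

#' Block-wise test-time perturbation
#'
#' For each (episode, variable) series, removes contiguous runs of observed
#' indices whose total length approximates `rho` times the number of observed
#' points, emulating interrupted monitoring or delayed lab panels. Blocks have
#' length `max(min_block, round(block_frac * n))` and are placed without
#' overlap; the removed total is within one block length of `rho * n`.
#'
#' @inheritParams perturb_pointwise_mcar
#' @param block_frac Block length as a fraction of the series' observed count.
#' @param min_block Minimum block length (indices).
#' @return The perturbed `imts_cohort`.
#' @export
perturb_blockwise <- function(cohort, rho, seed = 1L, block_frac = 0.1,
                              min_block = 2L) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (rho == 0) return(cohort)
  obs <- cohort$observations
  key <- paste(obs$episode_id, obs$variable_id, sep = "\r")
  drop <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(obs)), key), function(rows) {
      n <- length(rows)
      L <- max(min_block, round(block_frac * n))
      if (L >= n) return(integer(0)) # too short to lose a whole block
      target <- rho * n
      nblocks <- max(0L, round(target / L))
      if (nblocks == 0L) return(integer(0))
      removed <- logical(n)
      starts <- sample(seq_len(n - L + 1L))
      taken <- 0L
      for (s in starts) {
        if (taken >= nblocks) break
        span <- s:(s + L - 1L)
        if (any(removed[span])) next
        removed[span] <- TRUE
        taken <- taken + 1L
      }
      rows[removed]
    }), use.names = FALSE)
  })
  out <- cohort
  if (length(drop)) out$observations <- obs[-drop, ]
  out
}
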