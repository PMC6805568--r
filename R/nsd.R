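# Net squared displacement (NSD) analysis: daily mean locations, squared
# great-circle displacement from the first day, latent-state segmentation
# (Gaussian HMM on sqrt-NSD), winter-range occupancy and a PCA of the
# environmental conditions met during the winter residency state.

#' Daily mean locations of a track
#'
#' Per-UTC-day arithmetic mean of latitude and unwrapped longitude of all
#' fixes that day (so days straddling the prime meridian or antimeridian
#' average along the short arc). Days without fixes are simply absent.
#'
#' @param track Data frame with `id`, `time`, `lon`, `lat` (extra columns such
#'   as `stage`/`year` are carried through, first value per day).
#' @return Tibble `id, date, lon, lat` (+ carried columns).
#' @export
daily_mean_locations <- function(track) {
  stopifnot(all(c("id", "time", "lon", "lat") %in% names(track)))
  carry <- intersect(c("stage", "year"), names(track))
  track |>
    dplyr::arrange(.data$id, .data$time) |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(.ulon = unwrap_lon(.data$lon)) |>
    dplyr::group_by(.data$id, date = as.Date(.data$time)) |>
    dplyr::summarise(
      lon = norm_lon(mean(.data$.ulon)),
      lat = mean(.data$lat),
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      .groups = "drop"
    )
}

#' Net squared displacement series
#'
#' Squared great-circle distance (km^2) between each daily mean location and
#' the first daily location of the individual's trip.
#'
#' @param daily Output of [daily_mean_locations()].
#' @return `daily` with an `nsd_km2` column; 0 on the first day by
#'   construction.
#' @export
compute_nsd <- function(daily) {
  stopifnot(all(c("id", "date", "lon", "lat") %in% names(daily)))
  daily |>
    dplyr::arrange(.data$id, .data$date) |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(
      nsd_km2 = great_circle_km(.data$lon[1], .data$lat[1], .data$lon, .data$lat)^2
    ) |>
    dplyr::ungroup()
}

#' Segment NSD series into three latent movement states
#'
#' Fits, per individual, a Gaussian hidden Markov model to the transformed
#' NSD series (square-root by default, so the emission scale is displacement
#' in km) and attaches the Viterbi-decoded state to each day. States are
#' relabelled so that 1 = first (summer) encampment (small mean), 2 = winter
#' encampment (large mean) and 3 = transit (largest emission SD). Individuals
#' tracked for fewer than `min_duration_days` are excluded (short deployments
#' carry too little information to support a 3-state fit).
#'
#' @param nsd Output of [compute_nsd()].
#' @param n_states Number of latent states (default 3).
#' @param transform `"sqrt"` (default) or `"log1p"`.
#' @param n_restarts,seed EM restarts and seed, passed to
#'   [fit_gaussian_hmm()].
#' @param min_duration_days Minimum days of data required per individual
#'   (default 120).
#' @return Object of class `nsd_states`: the input tibble (excluded
#'   individuals dropped) with a `state` column, plus attributes `fits` (named
#'   list of `gaussian_hmm`) and `excluded` (ids).
#' @export
segment_nsd <- function(nsd, n_states = 3, transform = c("sqrt", "log1p"),
                        n_restarts = 10, seed = 1L, min_duration_days = 120) {
  stopifnot(all(c("id", "date", "nsd_km2") %in% names(nsd)))
  transform <- match.arg(transform)
  tf <- switch(transform, sqrt = sqrt, log1p = log1p)
  counts <- dplyr::count(nsd, .data$id)
  excluded <- counts$id[counts$n < min_duration_days]
  if (length(excluded) > 0) {
    inform(sprintf(
      "segment_nsd(): excluding %d individual(s) with < %d tracking days: %s",
      length(excluded), min_duration_days, paste(excluded, collapse = ", ")
    ))
  }
  keep <- dplyr::filter(nsd, !.data$id %in% excluded) |>
    dplyr::arrange(.data$id, .data$date)
  ids <- unique(keep$id)
  fits <- list()
  out <- purrr::map_dfr(ids, function(i) {
    d <- dplyr::filter(keep, .data$id == i)
    fit <- fit_gaussian_hmm(tf(d$nsd_km2), n_states = n_states,
                            n_restarts = n_restarts,
                            seed = .sub_seed(seed, match(i, ids)))
    fits[[i]] <<- fit
    d$state <- as.integer(fit$states)
    d
  })
  structure(out, fits = fits, excluded = excluded, transform = transform,
            class = c("nsd_states", class(out)))
}

#' @export
tidy.nsd_states <- function(x, ...) {
  fits <- attr(x, "fits")
  purrr::imap_dfr(fits, function(f, id) {
    dplyr::mutate(tidy(f), id = id, .before = 1)
  })
}

#' @export
glance.nsd_states <- function(x, ...) {
  fits <- attr(x, "fits")
  purrr::imap_dfr(fits, function(f, id) {
    dplyr::mutate(glance(f), id = id, .before = 1)
  })
}

#' Winter-range occupancy grid
#'
#' Bins all state-2 (winter residency) daily locations into cells of
#' `cell_deg` degrees and counts the days per cell.
#'
#' @param states An `nsd_states` object (or any tibble with `lon`, `lat`,
#'   `state`).
#' @param cell_deg Cell size in degrees (default 1).
#' @return Tibble `lon_bin, lat_bin, days` (cell lower-left corners). If no
#'   day is in state 2, an empty tibble with attribute `empty = TRUE`.
#' @export
winter_range <- function(states, cell_deg = 1) {
  stopifnot(all(c("lon", "lat", "state") %in% names(states)))
  w <- dplyr::filter(tibble::as_tibble(states), .data$state == 2L)
  if (nrow(w) == 0) {
    warn("winter_range(): no state-2 days; empty occupancy grid")
    return(structure(
      tibble::tibble(lon_bin = numeric(0), lat_bin = numeric(0), days = integer(0)),
      empty = TRUE
    ))
  }
  w |>
    dplyr::mutate(
      lon_bin = floor(.data$lon / cell_deg) * cell_deg,
      lat_bin = floor(.data$lat / cell_deg) * cell_deg
    ) |>
    dplyr::count(.data$lon_bin, .data$lat_bin, name = "days")
}

#' PCA of winter environmental conditions
#'
#' Column-standardized principal component analysis (via SVD, [prcomp]) of
#' the environmental variables sampled at state-2 daily locations, to
#' describe inter- and intra-individual variability of the conditions used
#' in winter. Constant columns are dropped with a warning; rows with missing
#' values are excluded.
#'
#' @param env_matrix Data frame of numeric environmental variables (one row
#'   per state-2 daily location); non-numeric columns (e.g. `id`) are carried
#'   into the scores.
#' @return List of class `winter_pca`: `loadings`, `scores` (tibble),
#'   `variance_explained` (fractions summing to 1), `dropped` (constant
#'   columns).
#' @export
winter_env_pca <- function(env_matrix) {
  env_matrix <- tibble::as_tibble(env_matrix)
  is_num <- vapply(env_matrix, is.numeric, logical(1))
  meta <- env_matrix[!is_num]
  num <- env_matrix[is_num]
  cc <- complete.cases(num)
  num <- num[cc, , drop = FALSE]
  meta <- meta[cc, , drop = FALSE]
  if (nrow(num) < 2) abort("winter_env_pca(): need at least 2 complete rows")
  sds <- vapply(num, sd, numeric(1))
  dropped <- names(num)[sds < 1e-12]
  if (length(dropped) > 0) {
    warn(sprintf("winter_env_pca(): dropping constant column(s): %s",
                 paste(dropped, collapse = ", ")))
    num <- num[setdiff(names(num), dropped)]
  }
  p <- prcomp(as.matrix(num), center = TRUE, scale. = TRUE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(
      loadings = p$rotation,
      scores = dplyr::bind_cols(meta, tibble::as_tibble(p$x)),
      variance_explained = ve,
      dropped = dropped
    ),
    class = "winter_pca"
  )
}

#' @exportS3Method base::print
print.winter_pca <- function(x, ...) {
  cat("Winter environmental PCA\n")
  cat("variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(x$variance_explained),
                    100 * x$variance_explained), collapse = ", "), "\n")
  invisible(x)
}
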