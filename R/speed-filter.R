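# Maximum-speed filtering of Argos location series. The filter is the
# McConnell-style iterative scheme: at each pass the interior fix with the
# largest root-mean-square speed to its (up to) two previous and two following
# retained neighbours is removed if that RMS exceeds vmax, until no interior
# fix exceeds the limit. Endpoints are never removed (no two-sided evidence).

#' Travel speed between consecutive fixes, km/h
#'
#' Great-circle distance divided by elapsed time.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees.
#' @param t1,t2 POSIXct times, `t2 > t1`.
#' @return Speed in km/h.
#' @export
travel_speed_kmh <- function(lon1, lat1, t1, lon2, lat2, t2) {
  dt_h <- as.numeric(difftime(t2, t1, units = "hours"))
  if (any(dt_h <= 0)) abort("travel_speed_kmh(): timestamps must be strictly increasing")
  great_circle_km(lon1, lat1, lon2, lat2) / dt_h
}

#' Filter implausible fixes from one track by maximum travel speed
#'
#' @param track Data frame with columns `time` (POSIXct), `lon`, `lat` for a
#'   single individual (an `id` column, if present, must be constant), sorted
#'   or sortable by time.
#' @param vmax Maximum plausible travel speed, km/h (default 14, the value
#'   used for king penguins).
#' @return The retained fixes as a tibble, with the filter report attached as
#'   attribute `"filter_report"` (see [filter_report()]).
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   time = as.POSIXct("2014-01-01", tz = "UTC") + 3600 * (0:5),
#'   lon = c(51.8, 51.82, 53.0, 51.86, 51.88, 51.9), lat = rep(-46.4, 6)
#' )
#' filtered <- speed_filter(tr, vmax = 14)
#' filter_report(filtered)
speed_filter <- function(track, vmax = 14) {
  stopifnot(all(c("time", "lon", "lat") %in% names(track)))
  if ("id" %in% names(track) && dplyr::n_distinct(track$id) > 1) {
    abort("speed_filter() expects one individual; use filter_tracks() for a dataset")
  }
  track <- dplyr::arrange(tibble::as_tibble(track), .data$time)
  n <- nrow(track)
  if (n < 3) {
    warn("speed_filter(): fewer than 3 fixes; track passed through unfiltered")
    rep <- .filter_report(n, integer(0))
    rep$n_residual_violations <- 0L
    return(structure(track, filter_report = rep))
  }
  keep <- rep(TRUE, n)
  t_num <- as.numeric(track$time)
  if (any(diff(t_num) <= 0)) abort("speed_filter(): timestamps must be strictly increasing")
  repeat {
    idx <- which(keep)
    m <- length(idx)
    if (m < 3) break
    rms <- .rms_neighbour_speeds(track$lon[idx], track$lat[idx], t_num[idx])
    bad <- which(rms > vmax) # interior positions only (rms is NA at endpoints)
    if (length(bad) == 0) break
    worst <- bad[which.max(rms[bad])] # ties: which.max takes the earliest
    keep[idx[worst]] <- FALSE
  }
  removed <- which(!keep)
  out <- track[keep, , drop = FALSE]
  rep <- .filter_report(n, removed)
  # residual consecutive-pair violations (possible only next to the exempt
  # endpoints, which carry no two-sided evidence) are reported, not fixed
  idx <- which(keep)
  if (length(idx) >= 2) {
    sp <- great_circle_km(track$lon[idx[-length(idx)]], track$lat[idx[-length(idx)]],
                          track$lon[idx[-1]], track$lat[idx[-1]]) /
      (diff(t_num[idx]) / 3600)
    rep$n_residual_violations <- sum(sp > vmax)
  } else {
    rep$n_residual_violations <- 0L
  }
  structure(out, filter_report = rep)
}

# RMS of speeds from each interior fix to up to two previous and two
# following fixes in the current retained sequence; NA at endpoints.
.rms_neighbour_speeds <- function(lon, lat, t_num) {
  m <- length(lon)
  sum_sq <- numeric(m)
  cnt <- numeric(m)
  for (lag in 1:2) {
    if (m <= lag) break
    i <- seq_len(m - lag)
    j <- i + lag
    sp2 <- (great_circle_km(lon[i], lat[i], lon[j], lat[j]) /
              ((t_num[j] - t_num[i]) / 3600))^2
    sum_sq[i] <- sum_sq[i] + sp2
    cnt[i] <- cnt[i] + 1
    sum_sq[j] <- sum_sq[j] + sp2
    cnt[j] <- cnt[j] + 1
  }
  rms <- sqrt(sum_sq / cnt)
  rms[c(1, m)] <- NA_real_
  rms
}

.filter_report <- function(n_input, removed_indices) {
  tibble::tibble(
    n_input = n_input,
    n_removed = length(removed_indices),
    removed_fraction = if (n_input > 0) length(removed_indices) / n_input else 0,
    removed_indices = list(as.integer(removed_indices))
  )
}

#' Retrieve the report attached by [speed_filter()] / [filter_tracks()]
#'
#' @param filtered A tibble returned by [speed_filter()] or [filter_tracks()].
#' @return A tibble with columns `n_input`, `n_removed`, `removed_fraction`
#'   and a list-column `removed_indices` (per individual for datasets, plus a
#'   `total` row).
#' @export
filter_report <- function(filtered) {
  rep <- attr(filtered, "filter_report")
  if (is.null(rep)) abort("no filter report attached to this object")
  rep
}

#' Speed-filter every individual of a dataset
#'
#' Applies [speed_filter()] per `id` and aggregates the per-track reports.
#'
#' @param tracks Data frame with columns `id`, `time`, `lon`, `lat`.
#' @inheritParams speed_filter
#' @return Filtered tracks (tibble) with a combined report attribute: one row
#'   per individual plus a `total` row.
#' @export
filter_tracks <- function(tracks, vmax = 14) {
  stopifnot(all(c("id", "time", "lon", "lat") %in% names(tracks)))
  if (nrow(tracks) == 0) {
    rep <- dplyr::mutate(.filter_report(0L, integer(0)), id = "total", .before = 1)
    return(structure(tibble::as_tibble(tracks), filter_report = rep))
  }
  pieces <- tracks |>
    dplyr::group_by(.data$id) |>
    dplyr::group_split()
  filtered <- purrr::map(pieces, speed_filter, vmax = vmax)
  reports <- purrr::map2_dfr(
    pieces, filtered,
    ~ dplyr::mutate(filter_report(.y), id = .x$id[1], .before = 1)
  )
  total <- tibble::tibble(
    id = "total",
    n_input = sum(reports$n_input),
    n_removed = sum(reports$n_removed),
    removed_fraction = sum(reports$n_removed) / sum(reports$n_input),
    removed_indices = list(integer(0)),
    n_residual_violations = sum(reports$n_residual_violations)
  )
  structure(
    dplyr::bind_rows(filtered),
    filter_report = dplyr::bind_rows(reports, total)
  )
}

#' @export
tidy.speed_filter_report <- function(x, ...) tibble::as_tibble(x)
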