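# Spherical geometry and track time-series utilities shared by all stages.
# Earth is modelled as a sphere of radius 6371.0 km; longitudes are kept in
# [-180, 180) and bearings in [0, 360), degrees clockwise from true north.

#' Radius of the spherical Earth model, in kilometres
#' @export
earth_radius_km <- 6371.0

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Normalize longitudes to the half-open interval [-180, 180)
#'
#' @param lon Numeric vector of longitudes in degrees east.
#' @return Numeric vector with each value mapped into `[-180, 180)`.
#' @export
#' @examples
#' norm_lon(c(185, -185, 360, 51.86))
norm_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Wrap bearings into [0, 360)
#'
#' @param bearing Numeric vector of bearings in degrees.
#' @return Bearings reduced modulo 360.
#' @export
wrap_bearing <- function(bearing) {
  bearing %% 360
}

#' Great-circle distance between points, in kilometres
#'
#' Haversine distance on a sphere of radius [earth_radius_km]. Vectorized and
#' symmetric; coincident points give exactly 0 and antipodal points
#' `pi * 6371` km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' great_circle_km(51.86, -46.43, 52.86, -46.43)
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE))
  phi1 <- .deg2rad(lat1)
  phi2 <- .deg2rad(lat2)
  dphi <- phi2 - phi1
  dlam <- .deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * earth_radius_km * asin(sqrt(a))
}

#' Initial (forward azimuth) bearing from one point toward another
#'
#' @inheritParams great_circle_km
#' @return Bearing in degrees clockwise from true north, in `[0, 360)`.
#'   Coincident points have no defined heading and return `NA` with a warning.
#' @export
initial_bearing <- function(lon1, lat1, lon2, lat2) {
  phi1 <- .deg2rad(lat1)
  phi2 <- .deg2rad(lat2)
  dlam <- .deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  b <- wrap_bearing(.rad2deg(atan2(y, x)))
  coincident <- (lon1 %% 360 == lon2 %% 360) & (lat1 == lat2)
  if (any(coincident, na.rm = TRUE)) {
    warn("initial_bearing(): coincident points have undefined heading; returning NA")
    b[coincident] <- NA_real_
  }
  b
}

#' Lambert azimuthal equal-area forward projection (spherical)
#'
#' Snyder's spherical forward equations, centred on `(center_lon, center_lat)`;
#' the centre maps to (0, 0) and output is in kilometres.
#'
#' @param lon,lat Point coordinates, degrees.
#' @param center_lon,center_lat Projection centre, degrees.
#' @return A tibble with columns `x_km`, `y_km`.
#' @export
laea_project <- function(lon, lat, center_lon, center_lat) {
  phi <- .deg2rad(lat)
  phi0 <- .deg2rad(center_lat)
  dlam <- .deg2rad(lon - center_lon)
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dlam)
  if (any(denom < 1e-12, na.rm = TRUE)) {
    abort("laea_project(): point antipodal to projection centre is outside the projection domain")
  }
  kp <- sqrt(2 / denom)
  tibble::tibble(
    x_km = earth_radius_km * kp * cos(phi) * sin(dlam),
    y_km = earth_radius_km * kp * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dlam))
  )
}

#' Inverse of [laea_project()]
#'
#' @param x_km,y_km Projected coordinates in km.
#' @inheritParams laea_project
#' @return A tibble with columns `lon`, `lat` (lon normalized to `[-180, 180)`).
#' @export
laea_inverse <- function(x_km, y_km, center_lon, center_lat) {
  phi0 <- .deg2rad(center_lat)
  rho <- sqrt(x_km^2 + y_km^2)
  c_ang <- 2 * asin(pmin(rho / (2 * earth_radius_km), 1))
  lat <- ifelse(
    rho < 1e-12,
    center_lat,
    .rad2deg(asin(cos(c_ang) * sin(phi0) + y_km * sin(c_ang) * cos(phi0) / rho))
  )
  lon <- ifelse(
    rho < 1e-12,
    center_lon,
    center_lon + .rad2deg(atan2(
      x_km * sin(c_ang),
      rho * cos(phi0) * cos(c_ang) - y_km * sin(phi0) * sin(c_ang)
    ))
  )
  tibble::tibble(lon = norm_lon(lon), lat = lat)
}

#' Unwrap a longitude sequence so consecutive steps take the short way round
#'
#' Adds multiples of 360 so that no consecutive difference exceeds 180 in
#' magnitude; antimeridian and prime-meridian crossings then interpolate along
#' the short arc.
#'
#' @param lon Numeric vector of longitudes in degrees, in track order.
#' @return Unwrapped longitudes (not normalized).
#' @export
unwrap_lon <- function(lon) {
  if (length(lon) < 2) return(lon)
  d <- diff(lon)
  adj <- cumsum(ifelse(d > 180, -360, ifelse(d < -180, 360, 0)))
  lon + c(0, adj)
}

#' Re-interpolate a track onto a regular time grid
#'
#' Linear interpolation of latitude and unwrapped longitude on a grid of
#' `step_hours` anchored at each individual's first fix. No extrapolation is
#' done beyond the first or last fix, and grid points falling strictly inside a
#' data gap longer than `max_gap_hours` are dropped.
#'
#' @param track A data frame with columns `id`, `time` (POSIXct, UTC), `lon`,
#'   `lat`; other columns are dropped.
#' @param step_hours Grid step in hours (default 12, i.e. two positions/day).
#' @param max_gap_hours Longest data gap that is bridged by interpolation.
#' @return A tibble `id, time, lon, lat` on the regular grid.
#' @export
interpolate_regular <- function(track, step_hours = 12, max_gap_hours = 48) {
  stopifnot(all(c("id", "time", "lon", "lat") %in% names(track)))
  track |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(~ .interp_one(.x, step_hours, max_gap_hours)) |>
    dplyr::ungroup()
}

.interp_one <- function(tr, step_hours, max_gap_hours) {
  tr <- dplyr::arrange(tr, .data$time)
  if (nrow(tr) < 2) {
    return(tibble::tibble(time = tr$time, lon = tr$lon, lat = tr$lat)[0, ])
  }
  t_num <- as.numeric(tr$time)
  if (any(diff(t_num) <= 0)) {
    abort("interpolate_regular(): timestamps must be strictly increasing within an individual")
  }
  grid <- seq(t_num[1], t_num[length(t_num)], by = step_hours * 3600)
  ulon <- unwrap_lon(tr$lon)
  lat_i <- approx(t_num, tr$lat, xout = grid, ties = "ordered")$y
  lon_i <- approx(t_num, ulon, xout = grid, ties = "ordered")$y
  # drop grid points strictly inside gaps longer than max_gap_hours
  idx <- findInterval(grid, t_num)
  gap_h <- (t_num[pmin(idx + 1, length(t_num))] - t_num[idx]) / 3600
  interior <- !(grid %in% t_num)
  keep <- !(interior & gap_h > max_gap_hours)
  tibble::tibble(
    time = as.POSIXct(grid[keep], tz = "UTC", origin = "1970-01-01"),
    lon = norm_lon(lon_i[keep]),
    lat = lat_i[keep]
  )
}

#' Angular difference between a heading and a flow direction
#'
#' `(heading - flow_toward) mod 360`: 0 means the animal moves exactly with
#' the flow, 180 exactly against it.
#'
#' @param heading,flow_toward Bearings in degrees (degrees clockwise from
#'   north; flow in the "toward" convention).
#' @return Difference in degrees, in `[0, 360)`.
#' @export
angular_difference <- function(heading, flow_toward) {
  wrap_bearing(heading - flow_toward)
}

#' Direction a (u, v) flow vector points toward
#'
#' `u` is the eastward and `v` the northward component (oceanographic "toward"
#' convention); a pure eastward flow has direction 90.
#'
#' @param u,v Vector components (any common speed unit).
#' @return Bearing in degrees `[0, 360)`; `NA` for zero-length vectors.
#' @export
flow_direction <- function(u, v) {
  out <- wrap_bearing(.rad2deg(atan2(u, v)))
  out[u == 0 & v == 0] <- NA_real_
  out
}

#' Austral season of a date
#'
#' Summer = Dec-Feb, Autumn = Mar-May, Winter = Jun-Aug, Spring = Sep-Nov
#' (configurable boundary months).
#'
#' @param date Date or POSIXct vector.
#' @param boundaries Named list mapping season names to month numbers.
#' @return Factor with levels summer, autumn, winter, spring.
#' @export
season_of <- function(date,
                      boundaries = list(
                        summer = c(12, 1, 2), autumn = 3:5,
                        winter = 6:8, spring = 9:11
                      )) {
  m <- lubridate::month(date)
  out <- rep(NA_character_, length(m))
  for (s in names(boundaries)) out[m %in% boundaries[[s]]] <- s
  factor(out, levels = names(boundaries))
}
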