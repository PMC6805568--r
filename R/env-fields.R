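# Container for gridded space-time environmental covariates (SST, MLD, SIC,
# CHLA, current u/v, wind u/v) on a regular lon x lat x time grid, plus
# bilinear along-track sampling.

#' Construct a gridded environmental field set
#'
#' @param lon,lat Strictly monotone coordinate vectors (degrees). Descending
#'   latitude axes are normalized to ascending.
#' @param time Date vector of field time slices (strictly increasing).
#' @param fields Named list of numeric arrays of dim
#'   `c(length(lon), length(lat), length(time))`.
#' @param units Named character vector of units per field (optional).
#' @return An object of class `env_fields`.
#' @export
env_fields <- function(lon, lat, time, fields, units = NULL) {
  lon <- as.numeric(lon); lat <- as.numeric(lat); time <- as.Date(time)
  if (length(lon) < 2 || length(lat) < 2) abort("env_fields(): need at least a 2x2 spatial grid")
  if (any(diff(lon) <= 0)) abort("env_fields(): longitude axis must be strictly increasing")
  dlat <- diff(lat)
  if (all(dlat < 0)) {
    lat <- rev(lat)
    fields <- lapply(fields, function(a) a[, rev(seq_along(lat)), , drop = FALSE])
  } else if (any(dlat <= 0)) {
    abort("env_fields(): latitude axis must be strictly monotone")
  }
  if (length(time) > 1 && any(diff(as.numeric(time)) <= 0)) {
    abort("env_fields(): time axis must be strictly increasing")
  }
  for (nm in names(fields)) {
    d <- dim(fields[[nm]])
    if (is.null(d) || length(d) != 3 ||
        !all(d == c(length(lon), length(lat), length(time)))) {
      abort(sprintf("env_fields(): field '%s' has wrong dimensions", nm))
    }
  }
  structure(list(lon = lon, lat = lat, time = time, fields = fields,
                 units = units),
            class = "env_fields")
}

#' @exportS3Method base::print
print.env_fields <- function(x, ...) {
  cat(sprintf(
    "env_fields: %d x %d grid, %d time slices (%s to %s)\n  fields: %s\n",
    length(x$lon), length(x$lat), length(x$time),
    min(x$time), max(x$time), paste(names(x$fields), collapse = ", ")
  ))
  invisible(x)
}

#' Sample a gridded field along points
#'
#' Bilinear interpolation in space at the nearest time slice. Points outside
#' the grid bounding box give `NA` (callers drop those rows and log the
#' count).
#'
#' @param env An [env_fields] object.
#' @param var Field name.
#' @param lon,lat,time Vectors of equal length (time as Date or POSIXct).
#' @return Numeric vector of sampled values.
#' @export
sample_env <- function(env, var, lon, lat, time) {
  stopifnot(inherits(env, "env_fields"))
  if (!var %in% names(env$fields)) {
    abort(sprintf("sample_env(): unknown field '%s'", var))
  }
  arr <- env$fields[[var]]
  n <- length(lon)
  ti <- .nearest_index(as.numeric(as.Date(time)), as.numeric(env$time))
  xi <- findInterval(lon, env$lon, rightmost.closed = TRUE)
  yi <- findInterval(lat, env$lat, rightmost.closed = TRUE)
  ok <- !is.na(lon) & !is.na(lat) &
    lon >= env$lon[1] & lon <= env$lon[length(env$lon)] &
    lat >= env$lat[1] & lat <= env$lat[length(env$lat)]
  out <- rep(NA_real_, n)
  if (!any(ok)) return(out)
  xi <- pmin(pmax(xi, 1), length(env$lon) - 1)
  yi <- pmin(pmax(yi, 1), length(env$lat) - 1)
  fx <- (lon - env$lon[xi]) / (env$lon[xi + 1] - env$lon[xi])
  fy <- (lat - env$lat[yi]) / (env$lat[yi + 1] - env$lat[yi])
  idx <- function(i, j) cbind(i, j, ti)
  v00 <- arr[idx(xi, yi)]
  v10 <- arr[idx(xi + 1, yi)]
  v01 <- arr[idx(xi, yi + 1)]
  v11 <- arr[idx(xi + 1, yi + 1)]
  vals <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
  out[ok] <- vals[ok]
  out
}

.nearest_index <- function(x, grid) {
  i <- findInterval(x, grid, all.inside = TRUE)
  ifelse(x - grid[i] > grid[pmin(i + 1, length(grid))] - x, pmin(i + 1, length(grid)), i)
}

#' Convert an env_fields object to a long tibble
#'
#' @param env An [env_fields] object.
#' @return Tibble `var, time, lon, lat, value`.
#' @export
env_to_tibble <- function(env) {
  stopifnot(inherits(env, "env_fields"))
  purrr::map_dfr(names(env$fields), function(nm) {
    tibble::tibble(
      var = nm,
      time = rep(env$time, each = length(env$lon) * length(env$lat)),
      lon = rep(env$lon, times = length(env$lat) * length(env$time)),
      lat = rep(rep(env$lat, each = length(env$lon)), times = length(env$time)),
      value = as.vector(env$fields[[nm]])
    )
  })
}
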