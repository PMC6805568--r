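# Readers and writers for the study bundle: tracks and dives as CSV,
# gridded environmental fields as a long-format CSV (var, time, lon, lat,
# value), model fits and manifests as JSON. Timestamps are always UTC
# ISO-8601.

.read_csv_quiet <- function(path, ...) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

# lenient ISO-8601 parsing; unparseable values become NA (reported upstream)
.parse_time <- function(x) {
  x <- as.character(x)
  tm <- suppressWarnings(readr::parse_datetime(x))
  nas <- is.na(tm) & !is.na(x)
  if (any(nas)) {
    d <- suppressWarnings(readr::parse_date(x[nas]))
    tm[nas] <- as.POSIXct(d, tz = "UTC")
  }
  lubridate::with_tz(tm, "UTC")
}

#' Read a track CSV
#'
#' Expects columns `id`, `timestamp` (ISO-8601 UTC), `lon`, `lat` and
#' optionally `quality` plus any extra columns, which are kept. Rows are
#' sorted by time within individual; duplicate timestamps are collapsed to
#' the first with a warning.
#'
#' @param path CSV file path.
#' @return Tibble `id, time, lon, lat, ...`.
#' @export
read_tracks <- function(path) {
  df <- .read_csv_quiet(path)
  nm <- names(df)
  if ("timestamp" %in% nm) df <- dplyr::rename(df, time = "timestamp")
  missing <- setdiff(c("id", "time", "lon", "lat"), names(df))
  if (length(missing) > 0) {
    abort(sprintf("read_tracks(): missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) return(tibble::as_tibble(df))
  if (!inherits(df$time, "POSIXct")) {
    df$time <- .parse_time(df$time)
  }
  bad <- which(is.na(df$time) | is.na(df$lon) | is.na(df$lat))
  if (length(bad) > 0) {
    abort(sprintf("read_tracks(): unparseable row(s) at line(s): %s",
                  paste(bad + 1, collapse = ", ")))
  }
  out <- df |>
    dplyr::arrange(.data$id, .data$time) |>
    dplyr::distinct(.data$id, .data$time, .keep_all = TRUE)
  n_dup <- nrow(df) - nrow(out)
  if (n_dup > 0) {
    warn(sprintf("read_tracks(): collapsed %d duplicate timestamp(s)", n_dup))
  }
  structure(out, n_duplicates = n_dup)
}

#' Write tracks to CSV
#'
#' @param tracks Track tibble (`time` written as ISO-8601 UTC `timestamp`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks |>
    dplyr::mutate(timestamp = format(.data$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) |>
    dplyr::select(-"time") |>
    dplyr::relocate("timestamp", .after = "id")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a dive-summary CSV
#'
#' Expects columns `id`, `start` (ISO-8601 UTC), `max_depth_m`, `duration_s`,
#' `surface_s`.
#'
#' @param path CSV file path.
#' @return Tibble sorted by individual and start time.
#' @export
read_dives <- function(path) {
  df <- .read_csv_quiet(path)
  missing <- setdiff(c("id", "start", "max_depth_m", "duration_s", "surface_s"),
                     names(df))
  if (length(missing) > 0) {
    abort(sprintf("read_dives(): missing column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!inherits(df$start, "POSIXct")) {
    df$start <- .parse_time(df$start)
  }
  dplyr::arrange(df, .data$id, .data$start)
}

#' Write dives to CSV
#'
#' @param dives Dive tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dives <- function(dives, path) {
  out <- dplyr::mutate(dives, start = format(.data$start, "%Y-%m-%dT%H:%M:%SZ",
                                             tz = "UTC"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read gridded environmental fields from long-format CSV
#'
#' The file must have columns `var, time, lon, lat, value` with every
#' variable on the same regular grid. Variables can be renamed on input via
#' `name_map` (e.g. `c(sst = "analysed_sst")`). A descending latitude axis is
#' normalized to ascending.
#'
#' @param path CSV path.
#' @param name_map Optional named character vector: names are the canonical
#'   variable names, values the names used in the file.
#' @param required Variables that must be present after renaming.
#' @return An [env_fields] object.
#' @export
read_env_fields <- function(path, name_map = NULL,
                            required = c("sst", "mld", "sic", "chla",
                                         "uo", "vo", "u10", "v10")) {
  df <- .read_csv_quiet(path)
  missing <- setdiff(c("var", "time", "lon", "lat", "value"), names(df))
  if (length(missing) > 0) {
    abort(sprintf("read_env_fields(): missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (!is.null(name_map)) {
    for (canon in names(name_map)) {
      df$var[df$var == name_map[[canon]]] <- canon
    }
  }
  have <- unique(df$var)
  lack <- setdiff(required, have)
  if (length(lack) > 0) {
    abort(sprintf("read_env_fields(): missing variable(s): %s",
                  paste(lack, collapse = ", ")))
  }
  lon <- sort(unique(df$lon))
  lat_raw <- unique(df$lat)
  lat <- sort(lat_raw)
  tms <- sort(unique(as.Date(df$time)))
  fields <- lapply(split(df, df$var), function(d) {
    a <- array(NA_real_, c(length(lon), length(lat), length(tms)))
    a[cbind(match(d$lon, lon), match(d$lat, lat), match(as.Date(d$time), tms))] <- d$value
    if (anyNA(a)) abort("read_env_fields(): grid is not complete/regular")
    a
  })
  env_fields(lon, lat, tms, fields)
}

#' Write gridded environmental fields to long-format CSV
#'
#' @param env An [env_fields] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_env_fields <- function(env, path) {
  readr::write_csv(env_to_tibble(env), path, progress = FALSE)
  invisible(path)
}

#' Write / read a study-bundle manifest (JSON)
#'
#' @param manifest Named list (must include `seed` for synthetic bundles).
#' @param path JSON path.
#' @return `path` / the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a complete study bundle to a directory
#'
#' Writes `tracks.csv`, `dives.csv`, `env.csv` and `manifest.json`.
#'
#' @param bundle A `study_bundle` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_tracks(bundle$tracks, file.path(dir, "tracks.csv"))
  write_dives(bundle$dives, file.path(dir, "dives.csv"))
  write_env_fields(bundle$env, file.path(dir, "env.csv"))
  write_manifest(bundle$manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a study bundle from a directory
#'
#' @param dir Directory written by [write_study_bundle()].
#' @return A `study_bundle` list.
#' @export
read_study_bundle <- function(dir) {
  bundle <- list(
    tracks = read_tracks(file.path(dir, "tracks.csv")),
    dives = read_dives(file.path(dir, "dives.csv")),
    env = read_env_fields(file.path(dir, "env.csv")),
    manifest = read_manifest(file.path(dir, "manifest.json"))
  )
  ids_d <- unique(bundle$dives$id)
  ids_t <- unique(bundle$tracks$id)
  if (!all(ids_d %in% ids_t)) {
    abort("read_study_bundle(): dive individuals missing from tracks")
  }
  structure(bundle, class = "study_bundle")
}
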