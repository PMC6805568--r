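# Behavioural-mode inference: dive-to-dive travel speed, hourly aggregation,
# agglomerative clustering (Manhattan distance on standardized variables,
# UPGMA linkage, tree cut at k = 3) and mapping of clusters to traveling /
# foraging modes.

#' Locate dives on the track and compute dive-to-dive travel speed
#'
#' Each dive is located by linear time-interpolation of the filtered track
#' (latitude and unwrapped longitude) at the dive start; dives farther than
#' `max_match_min` minutes from the nearest fix, or outside the track's time
#' span, are dropped and counted. Snapping to the single nearest fix is
#' deliberately avoided: with realistic Argos position error it makes the
#' speed between close-in-time dives jump between 0 and tens of km/h
#' depending on whether a fix boundary falls between them.
#'
#' The travel speed attached to a dive is the great-circle distance from the
#' previous dive of the same individual on the same recording day divided by
#' the time between dive initiations (which therefore includes the dive
#' duration); the first dive of a day has no speed.
#'
#' @param dives Tibble `id, start, max_depth_m, duration_s, surface_s`.
#' @param tracks Filtered tracks `id, time, lon, lat`.
#' @param max_match_min Maximum time to the nearest fix, minutes (default 90).
#' @param max_speed_kmh Physical maximum travel speed; dive-to-dive speeds
#'   above it are residual location-error artefacts and are set to missing
#'   (default 14, the speed-filter threshold).
#' @return `dives` with `lon`, `lat`, `speed_kmh` columns; attribute
#'   `n_unmatched` counts dropped dives.
#' @export
dive_travel_speed <- function(dives, tracks, max_match_min = 90,
                              max_speed_kmh = 14) {
  stopifnot(all(c("id", "start") %in% names(dives)),
            all(c("id", "time", "lon", "lat") %in% names(tracks)))
  matched <- dives |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(d, key) {
      tr <- dplyr::filter(tracks, .data$id == key$id) |> dplyr::arrange(.data$time)
      if (nrow(tr) < 2) {
        d$lon <- NA_real_
        d$lat <- NA_real_
        return(d)
      }
      tt <- as.numeric(tr$time)
      ts <- as.numeric(d$start)
      i <- .nearest_index(ts, tt)
      dt_min <- abs(ts - tt[i]) / 60
      ok <- dt_min <= max_match_min & ts >= tt[1] & ts <= tt[length(tt)]
      ulon <- unwrap_lon(tr$lon)
      d$lon <- ifelse(ok, norm_lon(approx(tt, ulon, xout = ts, ties = "ordered")$y),
                      NA_real_)
      d$lat <- ifelse(ok, approx(tt, tr$lat, xout = ts, ties = "ordered")$y,
                      NA_real_)
      d
    }) |>
    dplyr::ungroup()
  n_unmatched <- sum(is.na(matched$lon))
  out <- matched |>
    dplyr::filter(!is.na(.data$lon)) |>
    dplyr::arrange(.data$id, .data$start) |>
    dplyr::group_by(.data$id, day = as.Date(.data$start)) |>
    dplyr::mutate(
      speed_kmh = {
        dkm <- great_circle_km(dplyr::lag(.data$lon), dplyr::lag(.data$lat),
                               .data$lon, .data$lat)
        dth <- as.numeric(.data$start - dplyr::lag(.data$start), units = "hours")
        sp <- dkm / dth
        replace(sp, sp > max_speed_kmh, NA_real_)
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"day")
  structure(out, n_unmatched = n_unmatched)
}

#' Hourly averages of dive parameters and travel speed
#'
#' Arithmetic means per individual-hour of maximum depth, dive duration,
#' surface interval and travel speed; hours with no dives are absent. Hours
#' whose dives all lack a defined speed (single dive in a day) are dropped.
#'
#' @param dives Output of [dive_travel_speed()].
#' @return Tibble `id, hour, lon, lat, depth_m, duration_s, surface_s,
#'   speed_kmh, n_dives` (+ `stage`/`year` if present in the input).
#' @export
hourly_aggregate <- function(dives) {
  need <- c("id", "start", "max_depth_m", "duration_s", "surface_s", "speed_kmh")
  stopifnot(all(need %in% names(dives)))
  carry <- intersect(c("stage", "year"), names(dives))
  dives |>
    dplyr::group_by(.data$id, hour = lubridate::floor_date(.data$start, "hour")) |>
    dplyr::summarise(
      lon = if ("lon" %in% names(dives)) mean(.data$lon) else NA_real_,
      lat = if ("lat" %in% names(dives)) mean(.data$lat) else NA_real_,
      depth_m = mean(.data$max_depth_m),
      duration_s = mean(.data$duration_s),
      surface_s = mean(.data$surface_s),
      speed_kmh = mean(.data$speed_kmh, na.rm = TRUE),
      n_dives = dplyr::n(),
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      .groups = "drop"
    ) |>
    dplyr::filter(is.finite(.data$speed_kmh))
}

.cluster_vars <- c("depth_m", "duration_s", "surface_s", "speed_kmh")

#' Cluster hourly records into behavioural clusters
#'
#' Agglomerative hierarchical clustering with Manhattan (L1) distance on the
#' four standardized variables (depth, duration, surface interval, travel
#' speed) and UPGMA (unweighted average) linkage, cut at `k` clusters. The
#' variables are standardized to zero mean and unit variance first: the raw
#' variables mix metres, seconds and km/h and an unscaled L1 distance would be
#' dominated by depth (`scale = FALSE` retains the raw scale).
#'
#' By default the tree cut is followed by a k-means consolidation step
#' (Lloyd iterations seeded from tree-cut centroids), the re-assignment step
#' the source clustering tool (HCPC) applies after cutting: average-linkage
#' cuts on noisy data regularly isolate a handful of outlying records as
#' their own cluster, and consolidation restores a substantive partition
#' while keeping the tree as the seeding structure. Because the outlier
#' clusters make the plain k-cut centroids unreliable seeds, candidate
#' seedings are taken from successively deeper cuts (the `k` largest
#' clusters' centroids at each depth) and the consolidation with the lowest
#' within-cluster sum of squares is kept - a deterministic procedure with no
#' extra randomness. Set `consolidate = FALSE` for the raw tree cut.
#'
#' For datasets larger than `max_n` records the tree is built on a seeded
#' random subsample; consolidation (or nearest-centroid assignment when
#' `consolidate = FALSE`) labels the remaining records.
#'
#' @param records Hourly records from [hourly_aggregate()] (or any tibble with
#'   the four variables).
#' @param k Number of clusters (default 3).
#' @param scale Standardize variables before clustering (default TRUE).
#' @param consolidate Refine the cut by centroid-seeded k-means (default TRUE).
#' @param max_n Largest number of records clustered exactly (default 4000).
#' @param seed Seed for the subsample draw.
#' @return Object of class `dive_clusters`: `records` with a `cluster` column
#'   and `mode` label, plus attributes `summary` (see [cluster_summary()]),
#'   `tree` (hclust, on the clustered subset) and `mode_flags`.
#' @export
cluster_hourly <- function(records, k = 3, scale = TRUE, consolidate = TRUE,
                           max_n = 4000, seed = 1L) {
  records <- tibble::as_tibble(records)
  stopifnot(all(.cluster_vars %in% names(records)))
  n <- nrow(records)
  if (k > n) abort("cluster_hourly(): k exceeds the number of records")
  X <- as.matrix(records[.cluster_vars])
  if (scale) {
    X <- base::scale(X)
    stopifnot(all(abs(colMeans(X)) < 1e-8), all(abs(apply(X, 2, sd) - 1) < 1e-8))
  }
  sub <- if (n > max_n) {
    .with_seed(seed, sort(sample.int(n, max_n)))
  } else {
    seq_len(n)
  }
  tree <- hclust(dist(X[sub, , drop = FALSE], method = "manhattan"),
                 method = "average")
  cl_sub <- cutree(tree, k = k)
  centroids <- rowsum(X[sub, , drop = FALSE], cl_sub) / as.vector(table(cl_sub))
  cluster <- integer(n)
  if (consolidate) {
    Xs <- X[sub, , drop = FALSE]
    best <- NULL
    for (kc in k:min(k + 10, length(sub))) {
      cl_c <- cutree(tree, kc)
      sizes <- table(cl_c)
      top <- as.integer(names(sort(sizes, decreasing = TRUE)))[seq_len(k)]
      cent_all <- rowsum(Xs, cl_c) / as.vector(sizes)
      seeds <- cent_all[as.character(top), , drop = FALSE]
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = seeds, iter.max = 100,
                                       algorithm = "Lloyd")),
        error = function(e) NULL
      )
      if (!is.null(km) && all(km$size > 0) &&
          (is.null(best) || km$tot.withinss < best$tot.withinss)) {
        best <- km
      }
    }
    if (is.null(best)) abort("cluster_hourly(): consolidation failed for every seeding")
    cluster <- best$cluster
  } else {
    cluster[sub] <- cl_sub
    rest <- setdiff(seq_len(n), sub)
    if (length(rest) > 0) {
      d1 <- vapply(seq_len(k), function(j) {
        rowSums(abs(sweep(X[rest, , drop = FALSE], 2, centroids[j, ])))
      }, numeric(length(rest)))
      cluster[rest] <- max.col(-matrix(d1, nrow = length(rest)), ties.method = "first")
    }
  }
  records$cluster <- cluster
  summ <- .summarise_clusters(records, k)
  lab <- label_modes(summ)
  records$mode <- lab$summary$mode[match(records$cluster, lab$summary$cluster)]
  structure(records,
            summary = lab$summary, tree = tree, mode_flags = lab$flags,
            class = c("dive_clusters", class(records)))
}

.summarise_clusters <- function(records, k) {
  records |>
    dplyr::group_by(cluster = factor(.data$cluster, levels = seq_len(k))) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(
        dplyr::all_of(.cluster_vars),
        list(mean = mean, sd = sd)
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      cluster = as.integer(as.character(.data$cluster)),
      prop_time = .data$n / sum(.data$n)
    )
}

#' Assign traveling / foraging modes to clusters
#'
#' The cluster with the highest mean travel speed is labelled `traveling`;
#' all others `foraging`. The assignment is validated against depth: a
#' traveling cluster that is also the deepest is implausible and raises a
#' review flag (the labels are still returned, never silently altered).
#'
#' @param summary Cluster summary tibble (from [cluster_summary()] or
#'   internal), with `cluster`, `speed_kmh_mean`, `depth_m_mean`.
#' @return List with `summary` (a `mode` column added) and `flags`
#'   (character vector of warnings raised).
#' @export
label_modes <- function(summary) {
  stopifnot(all(c("cluster", "speed_kmh_mean", "depth_m_mean") %in% names(summary)))
  flags <- character(0)
  sp <- summary$speed_kmh_mean
  top <- which(sp == max(sp))
  if (length(top) > 1) {
    flags <- c(flags, "speed tie between clusters; earliest cluster labelled traveling")
    warn("label_modes(): two clusters tied on mean travel speed")
    top <- top[1]
  }
  if (summary$depth_m_mean[top] == max(summary$depth_m_mean)) {
    flags <- c(flags, "traveling cluster has the deepest mean depth; review")
    warn("label_modes(): traveling cluster is also the deepest; flagged for review")
  }
  summary$mode <- ifelse(seq_len(nrow(summary)) == top, "traveling", "foraging")
  list(summary = summary, flags = flags)
}

#' Per-cluster summary of a clustering result
#'
#' @param clusters A `dive_clusters` object.
#' @return Tibble with per-cluster mean and SD of the four variables, record
#'   counts, allocated-time proportion and assigned mode.
#' @export
cluster_summary <- function(clusters) {
  stopifnot(inherits(clusters, "dive_clusters"))
  attr(clusters, "summary")
}

#' @export
tidy.dive_clusters <- function(x, ...) cluster_summary(x)

#' @export
glance.dive_clusters <- function(x, ...) {
  s <- cluster_summary(x)
  tibble::tibble(
    n_records = nrow(x), k = nrow(s),
    prop_traveling = sum(s$prop_time[s$mode == "traveling"]),
    flagged = length(attr(x, "mode_flags")) > 0
  )
}

#' Weekly time allocation to traveling vs foraging modes
#'
#' Proportion of hourly records in each mode per week since the individual's
#' departure (first record), averaged within stage.
#'
#' @param clusters A `dive_clusters` object (needs `id`, `hour`, `mode`; uses
#'   `stage` if present).
#' @return Tibble `stage, week, mode, n, prop`; proportions sum to 1 within
#'   stage-week.
#' @export
mode_time_series <- function(clusters) {
  stopifnot(all(c("id", "hour", "mode") %in% names(clusters)))
  df <- tibble::as_tibble(clusters)
  if (!"stage" %in% names(df)) df$stage <- "all"
  df |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(week = 1 + floor(as.numeric(.data$hour - min(.data$hour),
                                              units = "days") / 7)) |>
    dplyr::group_by(.data$stage, .data$week, .data$mode) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}
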