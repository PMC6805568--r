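# Synthetic study-data generator: correlated-random-walk tracks with three
# movement phases (encamp - transit - encamp), duty-cycled dive records drawn
# from per-cluster parameter distributions, and smooth gridded environmental
# fields. The defaults emulate the real deployment: departure from Crozet
# (46.43 S, 51.86 E), ~14.5 Argos fixes/day, dive data 1 day ON / 2 days OFF
# with ~55 dives per recording day, and a weak (~0.11 m/s) eastward mean
# current. Everything is driven by a single integer seed.

#' Colony of departure (Possession Island, Crozet Archipelago)
#' @export
crozet_colony <- c(lon = 51.86, lat = -46.43)

#' Default per-cluster dive/travel parameter table
#'
#' Mean and SD of maximum dive depth (m), dive duration (s), post-dive surface
#' interval (s) and travel speed (km/h) for three behavioural clusters per
#' stage, with the long-run proportion of hourly records allocated to each
#' cluster. Cluster 1 is the shallow/fast traveling regime; clusters 2-3 are
#' foraging regimes.
#'
#' @return A tibble with one row per stage x cluster.
#' @export
default_mode_params <- function() {
  tibble::tribble(
    ~stage, ~cluster, ~depth_mean, ~depth_sd, ~dur_mean, ~dur_sd,
    ~surf_mean, ~surf_sd, ~speed_mean, ~speed_sd, ~prop, ~mode,
    "juvenile", 1L, 37.1, 31.8, 141.2, 56.6, 41.4, 22.9, 2.7, 0.7, 0.3, "traveling",
    "juvenile", 2L, 31.0, 28.9, 120.7, 59.0, 57.1, 40.1, 1.1, 0.5, 0.4, "foraging",
    "juvenile", 3L, 144.7, 42.9, 280.3, 59.2, 97.9, 37.4, 1.4, 0.8, 0.3, "foraging",
    "non-breeder", 1L, 37.2, 40.6, 156.0, 65.9, 38.6, 21.6, 3.6, 0.9, 0.3, "traveling",
    "non-breeder", 2L, 30.3, 34.6, 123.5, 67.9, 65.9, 49.0, 1.4, 0.7, 0.3, "foraging",
    "non-breeder", 3L, 170.8, 48.2, 316.5, 58.0, 90.3, 28.0, 0.4, NA, 0.4, "foraging"
  ) |>
    dplyr::mutate(speed_sd = dplyr::coalesce(.data$speed_sd, 0.9))
}

#' Build a simulation configuration
#'
#' All tunable knobs of the synthetic study generator, with defaults matching
#' the deployment the package emulates.
#'
#' @param seed Integer master seed; fixing it makes every output byte-identical.
#' @param n_juveniles,n_nonbreeders Number of individuals per stage.
#' @param duration_days Named vector: mean at-sea duration per stage (days).
#' @param duration_sd_days SD of per-individual duration jitter.
#' @param fixes_per_day_mean Mean Argos fixes per day (daily counts are
#'   Poisson; within a day fixes are placed on a jittered regular grid, which
#'   reproduces the ~2 h Argos cadence and avoids unrealistically tight pairs).
#' @param dive_duty_cycle Integer vector `c(on, off)` days (default 1 ON, 2 OFF).
#' @param dives_per_day_mean Mean number of relayed dives per recording day.
#' @param phase_days Named vector: days spent in the first encampment and in
#'   transit; the second encampment fills the remaining duration.
#' @param transit_speed_kmh,transit_heading_deg Mean transit speed and
#'   base heading (degrees; 225 = south-west).
#' @param encamp_sd_km Named vector: stationary SD (km) of the
#'   Ornstein-Uhlenbeck wander during the first and second encampments.
#' @param encamp_step_kmh Hourly step SD (km) of the encampment wander; keeps
#'   implied swim speeds realistic while the spread is set by `encamp_sd_km`.
#' @param argos_noise_sd_km Isotropic Gaussian Argos position error SD, km.
#' @param outlier_rate,outlier_jump_km Probability that a fix is displaced by
#'   an extra `outlier_jump_km` jump (labelled `true_outlier` in the output).
#' @param mode_params Per-cluster parameter table, see [default_mode_params()].
#' @param regime_persistence Hour-to-hour persistence of the 2-state Markov
#'   dive-regime schedule (0.8 gives traveling dwells of roughly 6-14 h).
#' @param regime_p_traveling Named vector: stationary probability of the
#'   traveling regime during encampment and transit phases. Coupling the
#'   regime to the movement phase makes traveling dives co-occur with fast
#'   movement, as observed; the defaults average to the ~0.3/0.7
#'   traveling/foraging time split over a full deployment.
#' @param env_spec List of environmental field parameters (see
#'   [simulate_env()] for the fields generated).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_juveniles = 17L,
                       n_nonbreeders = 6L,
                       duration_days = c(juvenile = 206, `non-breeder` = 220),
                       duration_sd_days = 15,
                       fixes_per_day_mean = 14.5,
                       dive_duty_cycle = c(on = 1L, off = 2L),
                       dives_per_day_mean = 55,
                       phase_days = c(encamp1 = 70, transit = 50),
                       transit_speed_kmh = 3.0,
                       transit_heading_deg = 225,
                       encamp_sd_km = c(encamp1 = 60, encamp2 = 180),
                       encamp_step_kmh = 1.2,
                       argos_noise_sd_km = 1.5,
                       outlier_rate = 0.05,
                       outlier_jump_km = 100,
                       mode_params = default_mode_params(),
                       regime_persistence = 0.8,
                       regime_p_traveling = c(encamp = 0.17, transit = 0.65),
                       env_spec = default_env_spec()) {
  stopifnot(
    is.numeric(seed), length(seed) == 1,
    fixes_per_day_mean > 0, dives_per_day_mean > 0,
    all(dive_duty_cycle >= 1), sum(dive_duty_cycle) >= 2,
    argos_noise_sd_km >= 0, outlier_rate >= 0, outlier_rate <= 1,
    regime_persistence >= 0, regime_persistence < 1,
    all(regime_p_traveling > 0), all(regime_p_traveling < 1)
  )
  cfg <- list(
    seed = as.integer(seed), n_juveniles = n_juveniles,
    n_nonbreeders = n_nonbreeders, duration_days = duration_days,
    duration_sd_days = duration_sd_days,
    fixes_per_day_mean = fixes_per_day_mean,
    dive_duty_cycle = dive_duty_cycle,
    dives_per_day_mean = dives_per_day_mean,
    phase_days = phase_days, transit_speed_kmh = transit_speed_kmh,
    transit_heading_deg = transit_heading_deg, encamp_sd_km = encamp_sd_km,
    encamp_step_kmh = encamp_step_kmh,
    argos_noise_sd_km = argos_noise_sd_km, outlier_rate = outlier_rate,
    outlier_jump_km = outlier_jump_km, mode_params = mode_params,
    regime_persistence = regime_persistence,
    regime_p_traveling = regime_p_traveling, env_spec = env_spec
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default environmental field specification
#'
#' @param grid_res_deg Grid resolution, degrees.
#' @param time_step_days Temporal resolution of the field stack.
#' @param current_mean_ms Mean (u, v) current, m/s (eastward 0.11 by default).
#' @param wind_mean_ms Mean (u, v) 10-m wind, m/s (westerlies).
#' @param noise_sd Named vector of per-field Gaussian noise SDs.
#' @return A list consumed by [simulate_env()].
#' @export
default_env_spec <- function(grid_res_deg = 1,
                             time_step_days = 7,
                             current_mean_ms = c(u = 0.11, v = 0),
                             wind_mean_ms = c(u = 8, v = 0),
                             noise_sd = c(sst = 0.3, mld = 8, sic = 2, chla = 0.03,
                                          current = 0.03, wind = 2)) {
  list(
    grid_res_deg = grid_res_deg, time_step_days = time_step_days,
    sst_base = 8, sst_grad_per_deg = 0.45, sst_ref_lat = -52,
    sst_seasonal_amp = 1.5,
    mld_base = 80, mld_seasonal_amp = 50,
    sic_edge_lat = -58, sic_per_deg = 10,
    chla_background = 0.15,
    chla_patches = tibble::tibble(
      lon = c(30, 3, 45), lat = c(-50, -53, -57),
      amp = c(0.8, 1.0, 0.6), sigma_deg = c(4, 5, 3)
    ),
    current_mean_ms = current_mean_ms, wind_mean_ms = wind_mean_ms,
    noise_sd = noise_sd
  )
}

.with_seed <- function(seed, code) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# derived per-individual/stream sub-seed, kept below 2^31
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

# movement phase of each 0-based day since departure
.phase_of_day <- function(day, cfg) {
  ifelse(day < cfg$phase_days[["encamp1"]], "encamp1",
         ifelse(day < sum(cfg$phase_days), "transit", "encamp2"))
}

# truncated-normal sampler (lower truncation only)
.rtnorm <- function(n, mean, sd, lower) {
  plo <- pnorm(lower, mean, sd)
  plo <- pmin(plo, 1 - 1e-12)
  stats::qnorm(runif(n, plo, 1), mean, sd)
}

#' Simulate one individual's Argos-like track
#'
#' Correlated random walk in the Lambert equal-area plane centred on the
#' colony: a first encampment (Ornstein-Uhlenbeck wander around the colony), a
#' directed transit with persistent heading, and a second (winter) encampment,
#' so that daily net squared displacement shows the plateau - ramp - plateau
#' signature. Argos error is isotropic Gaussian jitter; with probability
#' `outlier_rate` a fix receives an additional `outlier_jump_km` displacement
#' (labelled, so filter performance can be scored).
#'
#' @param cfg A [sim_config()].
#' @param id Individual identifier.
#' @param stage `"juvenile"` or `"non-breeder"`.
#' @param start Departure date-time (POSIXct, UTC).
#' @param duration_days Track duration; must cover the phase schedule.
#' @param seed Integer seed for this individual.
#' @return Tibble `id, stage, time, lon, lat, true_lon, true_lat, true_phase,
#'   true_outlier`, sorted by time.
#' @export
simulate_track <- function(cfg, id, stage = "juvenile",
                           start = as.POSIXct("2013-12-01", tz = "UTC"),
                           duration_days = NULL, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  duration_days <- duration_days %||% unname(cfg$duration_days[stage])
  if (duration_days <= sum(cfg$phase_days)) {
    abort("simulate_track(): duration shorter than the phase schedule")
  }
  .with_seed(seed, {
    n_h <- ceiling(duration_days * 24)
    day_of <- floor((seq_len(n_h + 1) - 1) / 24)
    phase <- .phase_of_day(day_of, cfg)
    pos <- matrix(0, n_h + 1, 2) # km in LAEA plane centred on colony
    heading <- cfg$transit_heading_deg + rnorm(1, 0, 15)
    anchor <- c(0, 0)
    for (t in seq_len(n_h)) {
      ph <- as.character(phase[t])
      if (ph == "transit") {
        heading <- cfg$transit_heading_deg +
          0.95 * (heading - cfg$transit_heading_deg) + rnorm(1, 0, 8)
        sp <- pmax(rnorm(1, cfg$transit_speed_kmh, 0.6), 0)
        step <- sp * c(sin(.deg2rad(heading)), cos(.deg2rad(heading)))
        pos[t + 1, ] <- pos[t, ] + step
        anchor <- pos[t + 1, ]
      } else {
        # slow Ornstein-Uhlenbeck wander: hourly step at realistic swim speed,
        # reversion rate set by the phase's target stationary spread
        sig <- cfg$encamp_step_kmh
        theta_ph <- min(sig^2 / (2 * cfg$encamp_sd_km[[ph]]^2), 0.05)
        pos[t + 1, ] <- pos[t, ] - theta_ph * (pos[t, ] - anchor) + rnorm(2, 0, sig)
      }
    }
    # Argos fix times: Poisson daily counts, jittered-regular placement
    fix_h <- unlist(lapply(0:(duration_days - 1), function(d) {
      nf <- rpois(1, cfg$fixes_per_day_mean)
      if (nf == 0) return(numeric(0))
      d * 24 + (seq_len(nf) - 1 + 0.1 + 0.8 * runif(nf)) * 24 / nf
    }))
    fix_h <- sort(fix_h[fix_h <= n_h])
    tx <- approx(0:n_h, pos[, 1], xout = fix_h)$y
    ty <- approx(0:n_h, pos[, 2], xout = fix_h)$y
    nfix <- length(fix_h)
    jit <- matrix(rnorm(2 * nfix, 0, cfg$argos_noise_sd_km), ncol = 2)
    is_out <- runif(nfix) < cfg$outlier_rate
    ang <- runif(nfix, 0, 2 * pi)
    ox <- tx + jit[, 1] + is_out * cfg$outlier_jump_km * cos(ang)
    oy <- ty + jit[, 2] + is_out * cfg$outlier_jump_km * sin(ang)
    obs_ll <- laea_inverse(ox, oy, crozet_colony["lon"], crozet_colony["lat"])
    true_ll <- laea_inverse(tx, ty, crozet_colony["lon"], crozet_colony["lat"])
    ph_fix <- phase[pmin(floor(fix_h) + 1, n_h + 1)]
    tibble::tibble(
      id = id, stage = stage,
      time = start + round(fix_h * 3600),
      lon = obs_ll$lon, lat = obs_ll$lat,
      true_lon = true_ll$lon, true_lat = true_ll$lat,
      true_phase = as.character(ph_fix),
      true_outlier = is_out
    ) |>
      dplyr::distinct(.data$time, .keep_all = TRUE)
  })
}

#' Simulate duty-cycled dive summaries along a track
#'
#' Dives occur only on ON days of the tag duty cycle. Within a recording day,
#' an hourly 2-state Markov schedule alternates traveling and foraging
#' regimes; traveling hours draw dives from cluster 1 and foraging hours from
#' the mixture of clusters 2 and 3 of `cfg$mode_params` for the individual's
#' stage. Depths are truncated below at 2 m (tags only log dives deeper than
#' that); durations and surface intervals are truncated at small positive
#' floors.
#'
#' @param cfg A [sim_config()].
#' @param track A track from [simulate_track()] (uses `id`, `stage`, `time`).
#' @param seed Integer seed.
#' @return Tibble `id, start, max_depth_m, duration_s, surface_s, true_regime,
#'   true_cluster`.
#' @export
simulate_dives <- function(cfg, track, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), nrow(track) > 0)
  stage <- track$stage[1]
  pars <- dplyr::filter(cfg$mode_params, .data$stage == !!stage)
  if (nrow(pars) == 0) pars <- dplyr::filter(cfg$mode_params, .data$stage == "juvenile")
  day0 <- lubridate::floor_date(min(track$time), "day")
  last_day <- as.integer(difftime(lubridate::floor_date(max(track$time), "day"),
                                  day0, units = "days"))
  cyc <- sum(cfg$dive_duty_cycle)
  on_days <- (0:last_day)[(0:last_day) %% cyc < cfg$dive_duty_cycle[["on"]]]
  rho <- cfg$regime_persistence
  fg <- dplyr::filter(pars, .data$cluster != 1L)
  fg_w <- fg$prop / sum(fg$prop)
  .with_seed(seed, {
    out <- purrr::map_dfr(on_days, function(d) {
      # phase-coupled 2-state Markov regime schedule: next state drawn from a
      # mixture of persistence and the phase's stationary traveling share
      ph <- .phase_of_day(d, cfg)
      pi_t <- cfg$regime_p_traveling[[if (ph == "transit") "transit" else "encamp"]]
      regime <- character(24)
      regime[1] <- if (runif(1) < pi_t) "traveling" else "foraging"
      for (h in 2:24) {
        p_trav <- (1 - rho) * pi_t + rho * (regime[h - 1] == "traveling")
        regime[h] <- if (runif(1) < p_trav) "traveling" else "foraging"
      }
      nd <- rpois(24, cfg$dives_per_day_mean / 24)
      hrs <- rep(0:23, nd)
      reg <- rep(regime, nd)
      n <- length(hrs)
      if (n == 0) return(NULL)
      cl <- ifelse(reg == "traveling", 1L,
                   sample(fg$cluster, n, replace = TRUE, prob = fg_w))
      p <- pars[match(cl, pars$cluster), ]
      depth <- .rtnorm(n, p$depth_mean, p$depth_sd, 2)
      dur <- .rtnorm(n, p$dur_mean, p$dur_sd, 10)
      surf <- .rtnorm(n, p$surf_mean, p$surf_sd, 1)
      # dives are sequential, non-overlapping events: each starts after the
      # previous dive's duration and surface interval have elapsed
      start_s <- numeric(n)
      prev_end <- -Inf
      for (i in seq_len(n)) {
        start_s[i] <- max(hrs[i] * 3600 + runif(1, 0, 3599), prev_end)
        prev_end <- start_s[i] + dur[i] + surf[i]
      }
      keep <- start_s < 86400
      tibble::tibble(
        id = track$id[1],
        start = day0 + d * 86400 + round(start_s[keep]),
        max_depth_m = depth[keep],
        duration_s = dur[keep],
        surface_s = surf[keep],
        true_regime = reg[keep],
        true_cluster = cl[keep]
      )
    })
    dplyr::arrange(out, .data$start)
  })
}

#' Simulate gridded environmental fields
#'
#' Generates the eight fields the analysis consumes, on a regular
#' lon x lat x time grid: `sst` (smooth meridional gradient plus seasonal
#' cycle, strictly decreasing poleward when noise is off), `mld` (winter
#' deepening), `sic` (non-zero only near the southern edge, winter maximum),
#' `chla` (background plus fixed Gaussian patches, never negative), current
#' components `uo`/`vo` (weak eastward mean) and wind components `u10`/`v10`
#' (prevailing westerlies).
#'
#' @param cfg A [sim_config()].
#' @param bbox Named numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param dates Date vector; the field stack spans their range at the
#'   configured time step.
#' @param seed Integer seed.
#' @return An [env_fields] object.
#' @export
simulate_env <- function(cfg, bbox, dates, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), length(bbox) == 4)
  sp <- cfg$env_spec
  lon <- seq(bbox[[1]], bbox[[2]], by = sp$grid_res_deg)
  lat <- seq(bbox[[3]], bbox[[4]], by = sp$grid_res_deg)
  tms <- seq(min(as.Date(dates)), max(as.Date(dates)), by = sp$time_step_days)
  nl <- length(lon); nla <- length(lat); nt <- length(tms)
  doy <- as.numeric(format(tms, "%j"))
  winter <- 0.5 - 0.5 * cos(2 * pi * (doy - 15) / 365.25) # ~0 mid-Jan, ~1 mid-Jul
  grid_lat <- array(rep(lat, each = nl), c(nl, nla, nt))
  wint_arr <- array(rep(winter, each = nl * nla), c(nl, nla, nt))
  .with_seed(seed, {
    nz <- function(s) array(rnorm(nl * nla * nt, 0, s), c(nl, nla, nt))
    ns <- sp$noise_sd
    sst <- sp$sst_base + sp$sst_grad_per_deg * (grid_lat - sp$sst_ref_lat) -
      sp$sst_seasonal_amp * (2 * wint_arr - 1) + nz(ns[["sst"]])
    mld <- pmax(sp$mld_base + sp$mld_seasonal_amp * (2 * wint_arr - 1) +
                  nz(ns[["mld"]]), 10)
    sic <- pmin(pmax(sp$sic_per_deg * (sp$sic_edge_lat - grid_lat) * wint_arr +
                       nz(ns[["sic"]]), 0), 100)
    chla_sp <- matrix(sp$chla_background, nl, nla)
    for (i in seq_len(nrow(sp$chla_patches))) {
      p <- sp$chla_patches[i, ]
      d2 <- outer((lon - p$lon)^2, (lat - p$lat)^2, "+")
      chla_sp <- chla_sp + p$amp * exp(-d2 / (2 * p$sigma_deg^2))
    }
    chla <- pmax(array(rep(chla_sp, nt), c(nl, nla, nt)) + nz(ns[["chla"]]), 0)
    uo <- sp$current_mean_ms[["u"]] + nz(ns[["current"]])
    vo <- sp$current_mean_ms[["v"]] + nz(ns[["current"]])
    u10 <- sp$wind_mean_ms[["u"]] + nz(ns[["wind"]])
    v10 <- sp$wind_mean_ms[["v"]] + nz(ns[["wind"]])
    env_fields(
      lon = lon, lat = lat, time = tms,
      fields = list(sst = sst, mld = mld, sic = sic, chla = chla,
                    uo = uo, vo = vo, u10 = u10, v10 = v10),
      units = c(sst = "degC", mld = "m", sic = "%", chla = "mg m-3",
                uo = "m s-1", vo = "m s-1", u10 = "m s-1", v10 = "m s-1")
    )
  })
}

#' Simulate a complete synthetic study bundle
#'
#' Tracks, dives and environmental fields for the default deployment: 17
#' juveniles departing Crozet in early summer over two cohort years and 6
#' non-breeding adults departing after their moult, plus a manifest echoing
#' the configuration.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `study_bundle`: `tracks`, `dives`, `env`,
#'   `manifest`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  roster <- .study_roster(cfg)
  tracks <- purrr::pmap_dfr(roster, function(id, stage, year, start, k) {
    dur <- .with_seed(.sub_seed(cfg$seed, 90000 + k), {
      max(round(rnorm(1, cfg$duration_days[[stage]], cfg$duration_sd_days)),
          sum(cfg$phase_days) + 30)
    })
    simulate_track(cfg, id, stage, start = start, duration_days = dur,
                   seed = .sub_seed(cfg$seed, k)) |>
      dplyr::mutate(year = year)
  })
  dives <- purrr::map_dfr(
    dplyr::group_split(tracks, .data$id),
    ~ simulate_dives(cfg, .x, seed = .sub_seed(cfg$seed, 50000 + match(.x$id[1], roster$id)))
  )
  bbox <- c(
    floor(min(tracks$lon)) - 2, ceiling(max(tracks$lon)) + 2,
    floor(min(tracks$lat)) - 2, ceiling(max(tracks$lat)) + 2
  )
  env <- simulate_env(cfg, bbox, range(as.Date(tracks$time)),
                      seed = .sub_seed(cfg$seed, 77777))
  manifest <- list(
    seed = cfg$seed,
    n_juveniles = cfg$n_juveniles, n_nonbreeders = cfg$n_nonbreeders,
    individuals = as.data.frame(roster[c("id", "stage", "year")]),
    fixes_per_day_mean = cfg$fixes_per_day_mean,
    dives_per_day_mean = cfg$dives_per_day_mean,
    dive_duty_cycle = as.list(cfg$dive_duty_cycle),
    fix_time_model = "Poisson daily counts, jittered-regular within-day placement (assumption; true Argos fix-time process unknown)",
    outlier_rate = cfg$outlier_rate,
    argos_noise_sd_km = cfg$argos_noise_sd_km
  )
  structure(list(tracks = tracks, dives = dives, env = env, manifest = manifest),
            class = "study_bundle")
}

.study_roster <- function(cfg) {
  nj <- cfg$n_juveniles; nn <- cfg$n_nonbreeders
  j_year <- rep(c("2013-14", "2014-15"), length.out = nj)
  n_year <- rep(c("2013-14", "2014-15"), length.out = nn)
  j_start0 <- c(`2013-14` = "2013-12-01", `2014-15` = "2014-12-01")
  n_start0 <- c(`2013-14` = "2014-02-20", `2014-15` = "2015-02-20")
  offs <- .with_seed(.sub_seed(cfg$seed, 424243), round(runif(nj + nn, 0, 25)))
  tibble::tibble(
    id = c(sprintf("juv%02d", seq_len(nj)), sprintf("nb%02d", seq_len(nn))),
    stage = c(rep("juvenile", nj), rep("non-breeder", nn)),
    year = c(j_year, n_year),
    start = as.POSIXct(c(j_start0[j_year], n_start0[n_year]), tz = "UTC") +
      offs * 86400,
    k = seq_len(nj + nn)
  )
}

#' Simulate hourly behavioural records directly from cluster distributions
#'
#' Draws hourly dive/travel records straight from the per-cluster Gaussian
#' distributions of `params` with the given mixing proportions - the planted
#' ground truth used to score the clustering stage.
#'
#' @param n Number of hourly records.
#' @param params Parameter table for one stage (rows = clusters), as in
#'   [default_mode_params()].
#' @param seed Integer seed.
#' @return Tibble `depth_m, duration_s, surface_s, speed_kmh, true_cluster`.
#' @export
simulate_hourly_records <- function(n, params = dplyr::filter(default_mode_params(),
                                                              .data$stage == "juvenile"),
                                    seed = 1L) {
  .with_seed(seed, {
    cl <- sample(params$cluster, n, replace = TRUE, prob = params$prop)
    p <- params[match(cl, params$cluster), ]
    tibble::tibble(
      depth_m = .rtnorm(n, p$depth_mean, p$depth_sd, 2),
      duration_s = .rtnorm(n, p$dur_mean, p$dur_sd, 10),
      surface_s = .rtnorm(n, p$surf_mean, p$surf_sd, 1),
      speed_kmh = .rtnorm(n, p$speed_mean, p$speed_sd, 0),
      true_cluster = cl
    )
  })
}

#' Simulate a plateau-ramp-plateau NSD series with known states
#'
#' Ground-truth series for scoring the latent-state segmentation: an encamped
#' plateau near zero, a linear ramp (transit) and a second encamped plateau,
#' with Gaussian noise added on the sqrt-NSD scale.
#'
#' The defaults mirror the track generator's geometry: a transit of ~50 days
#' at ~3 km/h covers ~3000 km of displacement, while the encampment wander
#' (and Argos noise surviving the daily average) perturbs displacement by
#' the order of 100 km.
#'
#' @param n_days Total series length.
#' @param plateau_days Named vector: days in the first and second plateau.
#' @param plateau_sep Separation of the two plateaus on the sqrt-NSD scale
#'   (i.e. in km of displacement).
#' @param noise_sd Emission SD on the sqrt-NSD scale (km; an absolute scale,
#'   set by the encampment wander, not a fraction of the separation).
#' @param seed Integer seed.
#' @return Tibble `day, nsd_km2, true_state` (1, 3, 2 blocks).
#' @export
simulate_nsd_series <- function(n_days = 180,
                                plateau_days = c(first = 60, second = 70),
                                plateau_sep = 3000,
                                noise_sd = 100,
                                seed = 1L) {
  ramp_days <- n_days - sum(plateau_days)
  stopifnot(ramp_days > 0)
  state <- rep(c(1L, 3L, 2L), c(plateau_days[["first"]], ramp_days,
                                plateau_days[["second"]]))
  base <- c(
    rep(0, plateau_days[["first"]]),
    seq(0, plateau_sep, length.out = ramp_days),
    rep(plateau_sep, plateau_days[["second"]])
  )
  .with_seed(seed, {
    r <- pmax(base + rnorm(n_days, 0, noise_sd), 0)
    tibble::tibble(day = seq_len(n_days), nsd_km2 = r^2, true_state = state)
  })
}
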