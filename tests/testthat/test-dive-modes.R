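# Dive-to-dive speeds, hourly aggregation, clustering and mode labels.

test_that("dive-to-dive speed follows the along-track definition", {
  t0 <- as.POSIXct("2014-01-05 08:00:00", tz = "UTC")
  # a straight track moving 0.02 deg lon per hour
  tr <- toy_track(12, step_h = 1, dlon = 0.02, t0 = t0)
  dives <- tibble::tibble(
    id = "a",
    start = t0 + c(0, 600, 1800, 3600, 5400),
    max_depth_m = 50, duration_s = 120, surface_s = 60
  )
  dv <- dive_travel_speed(dives, tr)
  expect_true(is.na(dv$speed_kmh[1])) # first dive of the day
  # constant track speed: all dive-to-dive speeds equal the track speed
  v_track <- great_circle_km(tr$lon[1], tr$lat[1], tr$lon[2], tr$lat[2]) / 1
  expect_equal(dv$speed_kmh[-1], rep(v_track, 4), tolerance = 1e-6)

  # consecutive dives at the same location -> 0
  tr0 <- toy_track(12, step_h = 1, dlon = 0, t0 = t0)
  dv0 <- dive_travel_speed(dives, tr0)
  expect_equal(dv0$speed_kmh[-1], rep(0, 4))

  # 2 km apart, initiations 600 s apart -> 12 km/h
  p2 <- laea_inverse(2, 0, 51.86, -46.43)
  tr2 <- tibble::tibble(
    id = "a", time = t0 + c(0, 600),
    lon = c(51.86, p2$lon), lat = c(-46.43, p2$lat)
  )
  d2 <- tibble::tibble(id = "a", start = t0 + c(0, 600),
                       max_depth_m = 10, duration_s = 60, surface_s = 30)
  out2 <- dive_travel_speed(d2, tr2)
  expect_equal(out2$speed_kmh[2], 12, tolerance = 1e-3)
})

test_that("dives far from any fix are dropped and speeds above the physical limit are censored", {
  t0 <- as.POSIXct("2014-01-05 08:00:00", tz = "UTC")
  tr <- toy_track(4, step_h = 2, dlon = 0.02, t0 = t0)
  dives <- tibble::tibble(
    id = "a",
    start = c(t0 + 3600, t0 + 20 * 3600), # second is 14 h past the last fix
    max_depth_m = 50, duration_s = 120, surface_s = 60
  )
  dv <- dive_travel_speed(dives, tr)
  expect_equal(nrow(dv), 1)
  expect_equal(attr(dv, "n_unmatched"), 1)

  # implausible speed (teleporting fixes) is censored to NA
  trj <- tibble::tibble(
    id = "a", time = t0 + c(0, 600),
    lon = c(51.86, 53.86), lat = c(-46.43, -46.43)
  )
  dj <- tibble::tibble(id = "a", start = t0 + c(0, 600),
                       max_depth_m = 10, duration_s = 60, surface_s = 30)
  expect_true(is.na(dive_travel_speed(dj, trj)$speed_kmh[2]))
})

test_that("hourly aggregation averages within individual-hours", {
  t0 <- as.POSIXct("2014-01-05 08:00:00", tz = "UTC")
  dv <- tibble::tibble(
    id = "a",
    start = t0 + c(60, 1800, 3700),
    max_depth_m = c(100, 200, 50),
    duration_s = c(100, 200, 300),
    surface_s = c(30, 60, 90),
    speed_kmh = c(NA, 2, 4),
    lon = 51.9, lat = -46.4
  )
  h <- hourly_aggregate(dv)
  expect_equal(nrow(h), 2)
  expect_equal(h$depth_m[1], 150) # mean of 100, 200
  expect_equal(h$n_dives, c(2L, 1L))
  expect_equal(h$speed_kmh, c(2, 4)) # NA speed ignored in the mean
  # an hour whose dives all lack speed is dropped
  dv$speed_kmh <- c(NA, NA, 3)
  expect_equal(nrow(hourly_aggregate(dv)), 1)
})

test_that("clustering recovers planted regimes from the reference mixture", {
  h <- simulate_hourly_records(4000, seed = 21)
  names(h)[1:4] <- c("depth_m", "duration_s", "surface_s", "speed_kmh")
  cl <- cluster_hourly(h, k = 3, seed = 1)
  s <- cluster_summary(cl)
  expect_equal(sum(s$prop_time), 1)
  expect_equal(sum(s$mode == "traveling"), 1)
  # deepest cluster tracks the planted deep-foraging component
  expect_lt(abs(max(s$depth_m_mean) - 144.7) / 144.7, 0.10)
  # traveling = fastest cluster, and it is shallow
  trav <- s[s$mode == "traveling", ]
  expect_lt(abs(trav$speed_kmh_mean - 2.7) / 2.7, 0.15)
  expect_lt(trav$depth_m_mean, max(s$depth_m_mean))
  # planted-label agreement via best one-to-one matching
  tab <- table(cl$cluster, h$true_cluster)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  agree <- max(vapply(perms, function(p) sum(tab[cbind(1:3, p)]), numeric(1))) / nrow(h)
  expect_gte(agree, 0.90)
})

test_that("clustering is deterministic and equivariant under row permutation", {
  skip_if_not_installed("mclust")
  h <- simulate_hourly_records(600, seed = 5)
  names(h)[1:4] <- c("depth_m", "duration_s", "surface_s", "speed_kmh")
  c1 <- cluster_hourly(h, seed = 2)
  c2 <- cluster_hourly(h, seed = 2)
  expect_identical(c1$cluster, c2$cluster)
  withr::with_seed(9, perm <- sample.int(nrow(h)))
  c3 <- cluster_hourly(h[perm, ], seed = 2)
  expect_equal(mclust::adjustedRandIndex(c1$cluster[perm], c3$cluster), 1)
})

test_that("a duplicated record joins its twin's cluster", {
  h <- simulate_hourly_records(300, seed = 6)
  names(h)[1:4] <- c("depth_m", "duration_s", "surface_s", "speed_kmh")
  h2 <- dplyr::bind_rows(h, h[17, ])
  cl <- cluster_hourly(h2, seed = 1)
  expect_equal(cl$cluster[nrow(h2)], cl$cluster[17])
})

test_that("mode labelling follows speed, validates depth, and flags ties", {
  s <- tibble::tibble(
    cluster = 1:3,
    depth_m_mean = c(37.1, 31.0, 144.7),
    speed_kmh_mean = c(2.7, 1.1, 1.4)
  )
  lab <- label_modes(s)
  expect_equal(lab$summary$mode, c("traveling", "foraging", "foraging"))
  expect_length(lab$flags, 0)

  tie <- dplyr::mutate(s, speed_kmh_mean = c(2, 2, 1))
  expect_warning(lt <- label_modes(tie), "tied")
  expect_equal(sum(lt$summary$mode == "traveling"), 1)

  deep_fast <- dplyr::mutate(s, speed_kmh_mean = c(1, 1.2, 3))
  expect_warning(ld <- label_modes(deep_fast), "deepest")
  expect_equal(ld$summary$mode[3], "traveling") # labelled, never silently altered
})

test_that("weekly mode proportions sum to one and track a planted schedule", {
  t0 <- as.POSIXct("2014-01-01", tz = "UTC")
  withr::with_seed(13, {
    recs <- tibble::tibble(
      id = "a",
      hour = t0 + 3600 * seq_len(21 * 24),
      mode = ifelse(runif(21 * 24) < 0.3, "traveling", "foraging")
    )
  })
  mts <- mode_time_series(recs)
  sums <- mts |>
    dplyr::group_by(.data$week) |>
    dplyr::summarise(s = sum(prop))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  trav <- dplyr::filter(mts, mode == "traveling")
  # ~0.3 within binomial error at n = 168/week
  expect_true(all(abs(trav$prop - 0.3) < 3 * sqrt(0.3 * 0.7 / 168)))
  # an all-traveling week
  all_t <- mode_time_series(dplyr::mutate(recs, mode = "traveling"))
  expect_true(all(all_t$prop == 1))
})
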