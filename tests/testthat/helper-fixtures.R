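# Shared fixtures, built in code.

toy_track <- function(n = 6, id = "a", t0 = as.POSIXct("2014-01-01", tz = "UTC"),
                      step_h = 2, lon0 = 51.86, lat0 = -46.43, dlon = 0.02) {
  tibble::tibble(
    id = id,
    time = t0 + 3600 * step_h * (seq_len(n) - 1),
    lon = lon0 + dlon * (seq_len(n) - 1),
    lat = lat0
  )
}

# small constant-in-time env field set on a tiny grid; values are simple
# analytic functions so samples can be verified by hand
toy_env <- function(lon = seq(40, 60, by = 1), lat = seq(-55, -40, by = 1),
                    time = as.Date("2014-01-01") + c(0, 7, 14),
                    u10 = 5, v10 = 0, uo = 0.1, vo = 0) {
  shape <- c(length(lon), length(lat), length(time))
  lat_arr <- array(rep(lat, each = length(lon)), shape)
  lon_arr <- array(lon, shape)
  const <- function(v) array(v, shape)
  env_fields(
    lon, lat, time,
    fields = list(
      sst = 10 + 0.5 * (lat_arr + 50),        # linear in lat
      mld = 100 + 0 * lat_arr,
      sic = pmax(-5 * (lat_arr + 52), 0),
      chla = 0.2 + 0.01 * (lon_arr - 40),      # linear in lon
      uo = const(uo), vo = const(vo),
      u10 = const(u10), v10 = const(v10)
    )
  )
}

# minimum-cardinality removal satisfying the consecutive-speed constraint,
# endpoints kept and pairs involving the first/last fix exempt (the filter
# cannot remove endpoints, so violations there are reported, not fixed);
# exhaustive search, for tracks of <= 10 fixes
minimal_removal_oracle <- function(track, vmax) {
  n <- nrow(track)
  t_num <- as.numeric(track$time)
  ok <- function(keep) {
    idx <- which(keep)
    sp <- great_circle_km(track$lon[idx[-length(idx)]], track$lat[idx[-length(idx)]],
                          track$lon[idx[-1]], track$lat[idx[-1]]) /
      (diff(t_num[idx]) / 3600)
    interior_pair <- idx[-length(idx)] != 1 & idx[-1] != n
    all(sp[interior_pair] <= vmax)
  }
  interior <- 2:(n - 1)
  for (m in 0:length(interior)) {
    sets <- if (m == 0) list(integer(0)) else
      asplit(utils::combn(interior, m), 2)
    sols <- Filter(function(rm) {
      keep <- rep(TRUE, n)
      keep[rm] <- FALSE
      ok(keep)
    }, sets)
    if (length(sols) > 0) {
      return(list(n_removed = m, solutions = lapply(sols, as.integer)))
    }
  }
  list(n_removed = NA_integer_, solutions = list())
}

expect_tbl_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}

# habitat-style observations with a known generative logit model:
# eta = b0 + f_sst(sst) + beta_wind * (wind - 8) + individual intercept
sim_habitat_obs <- function(n, n_ind = 20, re_sd = 0, beta_wind = -0.4,
                            sst_effect = TRUE, b0 = 0.3, seed = 1) {
  withr::with_seed(seed, {
    ind <- factor(sample(sprintf("i%02d", seq_len(n_ind)), n, replace = TRUE))
    b <- stats::setNames(rnorm(n_ind, 0, re_sd), levels(ind))
    sst <- runif(n, 0, 12)
    wind <- runif(n, 2, 14)
    chla <- runif(n, 0.1, 1.5)
    curr <- runif(n, 0, 0.3)
    eta <- b0 + beta_wind * (wind - 8) + b[as.character(ind)]
    if (sst_effect) eta <- eta + 0.8 * sin(sst / 12 * pi)
    y <- rbinom(n, 1, plogis(eta))
    tibble::tibble(y = y, sst = sst, wind = wind, chla = chla, curr = curr,
                   individual = ind)
  })
}
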