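# Spherical geometry primitives: distances, bearings, projection,
# interpolation, angular differences.

test_that("great-circle distance handles identity, antipodes and agrees with independent oracles", {
  expect_equal(great_circle_km(51.86, -46.43, 51.86, -46.43), 0)
  expect_equal(great_circle_km(0, 0, 180, 0), pi * 6371)
  expect_equal(great_circle_km(30, 45, 30 + 180, -45), pi * 6371)

  # spherical law of cosines oracle, one degree of longitude at Crozet
  slc <- function(lon1, lat1, lon2, lat2) {
    p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
    dl <- (lon2 - lon1) * pi / 180
    6371 * acos(pmin(1, sin(p1) * sin(p2) + cos(p1) * cos(p2) * cos(dl)))
  }
  d_hav <- great_circle_km(51.86, -46.43, 52.86, -46.43)
  expect_lt(abs(d_hav - slc(51.86, -46.43, 52.86, -46.43)), 1e-3) # < 1 m

  # geosphere as an external oracle on random pairs
  skip_if_not_installed("geosphere")
  withr::with_seed(11, {
    lon <- runif(50, -180, 180); lat <- runif(50, -85, 85)
    lon2 <- runif(50, -180, 180); lat2 <- runif(50, -85, 85)
    ref <- geosphere::distHaversine(cbind(lon, lat), cbind(lon2, lat2), r = 6371)
    expect_equal(great_circle_km(lon, lat, lon2, lat2), ref, tolerance = 1e-10)
  })
})

test_that("great-circle distance is symmetric and satisfies the triangle inequality", {
  withr::with_seed(4, {
    for (i in 1:50) {
      p <- cbind(runif(3, -180, 180), runif(3, -88, 88))
      ab <- great_circle_km(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
      ba <- great_circle_km(p[2, 1], p[2, 2], p[1, 1], p[1, 2])
      bc <- great_circle_km(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
      ac <- great_circle_km(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
      expect_equal(ab, ba)
      expect_lte(ac, ab + bc + 1e-9)
    }
  })
})

test_that("initial bearing matches cardinal directions and a finite-difference oracle", {
  expect_equal(initial_bearing(10, -50, 10, -40), 0)
  expect_equal(initial_bearing(0, 0, 10, 0), 90)
  expect_warning(b <- initial_bearing(5, 5, 5, 5), "undefined")
  expect_true(is.na(b))

  # forward azimuth from the local direction of the great circle: step a tiny
  # fraction along the path via spherical linear interpolation and measure
  # the local ENU direction
  withr::with_seed(21, {
    for (i in 1:25) {
      lon1 <- runif(1, -170, 170); lat1 <- runif(1, -80, 80)
      lon2 <- runif(1, -170, 170); lat2 <- runif(1, -80, 80)
      v1 <- c(cos(lat1 * pi / 180) * cos(lon1 * pi / 180),
              cos(lat1 * pi / 180) * sin(lon1 * pi / 180), sin(lat1 * pi / 180))
      v2 <- c(cos(lat2 * pi / 180) * cos(lon2 * pi / 180),
              cos(lat2 * pi / 180) * sin(lon2 * pi / 180), sin(lat2 * pi / 180))
      ang <- acos(sum(v1 * v2))
      eps <- 1e-7
      vm <- (sin((1 - eps) * ang) * v1 + sin(eps * ang) * v2) / sin(ang)
      latm <- asin(vm[3]) * 180 / pi
      lonm <- atan2(vm[2], vm[1]) * 180 / pi
      # ENU components of the step
      de <- (lonm - lon1)
      de <- ((de + 180) %% 360) - 180
      de <- de * cos(lat1 * pi / 180)
      dn <- latm - lat1
      oracle <- (atan2(de, dn) * 180 / pi) %% 360
      got <- initial_bearing(lon1, lat1, lon2, lat2)
      dd <- abs(got - oracle)
      expect_lt(min(dd, 360 - dd), 1e-3)
    }
  })
})

test_that("Lambert equal-area projection maps its centre to the origin and matches an azimuth/chord oracle", {
  ctr <- laea_project(51.86, -46.43, 51.86, -46.43)
  expect_equal(c(ctr$x_km, ctr$y_km), c(0, 0))

  # independent derivation: planar radius is the chord 2R sin(c/2) laid out
  # along the initial azimuth
  withr::with_seed(31, {
    for (i in 1:25) {
      clon <- runif(1, -150, 150); clat <- runif(1, -70, 70)
      lon <- clon + runif(1, -40, 40); lat <- pmax(pmin(clat + runif(1, -30, 30), 89), -89)
      d <- great_circle_km(clon, clat, lon, lat)
      c_ang <- d / 6371
      rho <- 2 * 6371 * sin(c_ang / 2)
      az <- initial_bearing(clon, clat, lon, lat) * pi / 180
      got <- laea_project(lon, lat, clon, clat)
      expect_lt(abs(got$x_km - rho * sin(az)), 1e-3) # < 1 m
      expect_lt(abs(got$y_km - rho * cos(az)), 1e-3)
    }
  })
})

test_that("Lambert equal-area projection preserves area (spherical-excess oracle)", {
  # small quadrilateral near the study area, as two spherical triangles
  # (L'Huilier), compared with the planar shoelace area of its projection
  quad <- cbind(lon = c(48, 52, 52, 48), lat = c(-48, -48, -45, -45))
  sph_tri <- function(p1, p2, p3) {
    a <- great_circle_km(p2[1], p2[2], p3[1], p3[2]) / 6371
    b <- great_circle_km(p1[1], p1[2], p3[1], p3[2]) / 6371
    cc <- great_circle_km(p1[1], p1[2], p2[1], p2[2]) / 6371
    s <- (a + b + cc) / 2
    e <- 4 * atan(sqrt(tan(s / 2) * tan((s - a) / 2) * tan((s - b) / 2) * tan((s - cc) / 2)))
    e * 6371^2
  }
  area_sph <- sph_tri(quad[1, ], quad[2, ], quad[3, ]) +
    sph_tri(quad[1, ], quad[3, ], quad[4, ])
  pr <- laea_project(quad[, "lon"], quad[, "lat"], 50, -46.5)
  x <- pr$x_km; y <- pr$y_km
  area_pl <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  expect_lt(abs(area_pl - area_sph) / area_sph, 1e-3) # well within 0.1%
})

test_that("Lambert projection round-trips through its inverse", {
  withr::with_seed(7, {
    clon <- 51.86; clat <- -46.43
    lon <- clon + runif(100, -80, 80)
    lat <- pmax(pmin(clat + runif(100, -40, 40), 89), -89)
    xy <- laea_project(lon, lat, clon, clat)
    back <- laea_inverse(xy$x_km, xy$y_km, clon, clat)
    expect_lt(max(abs(back$lon - norm_lon(lon))), 1e-6)
    expect_lt(max(abs(back$lat - lat)), 1e-6)
  })
  expect_error(laea_project(-180 + 51.86, 46.43, 51.86, -46.43), "antipodal")
})

test_that("regular re-interpolation hits the grid, the midpoint, and never extrapolates", {
  tr <- tibble::tibble(
    id = "a",
    time = as.POSIXct("2014-01-01", tz = "UTC") + c(0, 24) * 3600,
    lon = c(50, 52), lat = c(-46, -48)
  )
  out <- interpolate_regular(tr, step_hours = 12)
  expect_equal(nrow(out), 3)
  expect_equal(out$lon[2], 51)
  expect_equal(out$lat[2], -47)
  expect_true(all(out$time >= min(tr$time) & out$time <= max(tr$time)))
  expect_true(all(as.numeric(out$time - out$time[1], units = "hours") %% 12 == 0))
})

test_that("interpolation crosses the prime meridian the short way", {
  tr <- tibble::tibble(
    id = "a",
    time = as.POSIXct("2014-01-01", tz = "UTC") + c(0, 24) * 3600,
    lon = c(-0.5, 0.5), lat = c(-50, -50)
  )
  out <- interpolate_regular(tr, step_hours = 12)
  expect_equal(out$lon[2], 0)
  tr$lon <- c(179.5, -179.5) # antimeridian
  out <- interpolate_regular(tr, step_hours = 12)
  expect_true(abs(out$lon[2]) >= 179.99 || out$lon[2] == -180)
})

test_that("interpolation equals an exact per-coordinate linear oracle on an irregular series", {
  t_h <- c(0, 5, 7, 16, 26, 31, 48)
  tr <- tibble::tibble(
    id = "a",
    time = as.POSIXct("2014-01-01", tz = "UTC") + t_h * 3600,
    lon = c(50, 50.4, 50.5, 51.3, 52.0, 52.1, 53.0),
    lat = c(-46, -46.2, -46.25, -46.7, -47.2, -47.3, -48.0)
  )
  out <- interpolate_regular(tr, step_hours = 12)
  grid <- seq(0, 48, by = 12)
  oracle <- function(v, tq) {
    i <- findInterval(tq, t_h)
    i <- pmin(i, length(t_h) - 1)
    w <- (tq - t_h[i]) / (t_h[i + 1] - t_h[i])
    v[i] * (1 - w) + v[i + 1] * w
  }
  expect_equal(out$lon, oracle(tr$lon, grid), tolerance = 1e-12)
  expect_equal(out$lat, oracle(tr$lat, grid), tolerance = 1e-12)
})

test_that("interpolation refuses to bridge gaps beyond max_gap_hours", {
  tr <- tibble::tibble(
    id = "a",
    time = as.POSIXct("2014-01-01", tz = "UTC") + c(0, 12, 84, 96) * 3600,
    lon = c(50, 50.5, 54, 54.5), lat = rep(-46, 4)
  )
  out <- interpolate_regular(tr, step_hours = 12, max_gap_hours = 48)
  hrs <- as.numeric(out$time - tr$time[1], units = "hours")
  expect_false(any(hrs > 12 & hrs < 84))
  expect_true(all(c(0, 12, 84, 96) %in% hrs))
})

test_that("angular difference wraps correctly", {
  expect_equal(angular_difference(90, 90), 0)
  expect_equal(angular_difference(0, 180), 180)
  expect_equal(angular_difference(10, 350), 20)
  expect_equal(angular_difference(350, 10), 340)
})

test_that("flow direction follows the toward convention", {
  expect_equal(flow_direction(1, 0), 90)   # eastward
  expect_equal(flow_direction(0, 1), 0)    # northward
  expect_equal(flow_direction(0, -2), 180)
  expect_equal(flow_direction(-1, 0), 270)
  expect_true(is.na(flow_direction(0, 0)))
})

test_that("longitude normalization and austral seasons behave", {
  expect_equal(norm_lon(c(185, -185, 360, 180)), c(-175, 175, 0, -180))
  s <- season_of(as.Date(c("2014-01-15", "2014-04-15", "2014-07-15", "2014-10-15", "2013-12-25")))
  expect_equal(as.character(s), c("summer", "autumn", "winter", "spring", "summer"))
})
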