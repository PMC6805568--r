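# Orientation classification, records, proportion tables, GLMM contrasts
# and the CHLA orientation model.

test_that("direction classification is exhaustive, exclusive, and honours closed boundaries", {
  expect_equal(as.character(classify_direction(c(0, 45, 315, 359.9))),
               rep("similar", 4))
  expect_equal(as.character(classify_direction(c(135, 180, 225))),
               rep("against", 3))
  expect_equal(as.character(classify_direction(c(46, 90, 134.99, 225.01, 270, 314.9))),
               rep("cross", 6))
  # exhaustive and mutually exclusive over a fine grid
  grid <- seq(0, 359.99, by = 0.01)
  k <- classify_direction(grid)
  expect_false(any(is.na(k)))
  expect_error(classify_direction(360))
  # bin measures: 90 / 90 / 180 degrees
  expect_equal(as.numeric(prop.table(table(k))), c(0.25, 0.25, 0.5),
               tolerance = 1e-3)
})

test_that("orientation records combine heading, flow and CHLA correctly", {
  # eastward-moving bird in an eastward wind -> similar; flow_toward = 90
  tr <- tibble::tibble(
    id = "a", stage = "juvenile",
    time = as.POSIXct("2014-01-01", tz = "UTC") + (0:6) * 12 * 3600,
    lon = 45 + 0.5 * (0:6), lat = rep(-50, 7)
  )
  env <- toy_env(u10 = 5, v10 = 0)
  rec <- orientation_records(tr, env, medium = "wind")
  expect_equal(nrow(rec), 6)
  expect_true(all(rec$flow_toward == 90))
  expect_true(all(rec$klass == "similar"))
  expect_true(all(abs(rec$heading - 90) < 2)) # near-east on a parallel
  # CHLA sampled at start (t) and end (t+1) of each segment: linear in lon
  expect_equal(rec$chla_t, 0.2 + 0.01 * (tr$lon[1:6] - 40), tolerance = 1e-9)
  expect_equal(rec$chla_t1, 0.2 + 0.01 * (tr$lon[2:7] - 40), tolerance = 1e-9)
  # against the current when moving west in an eastward current
  tr_w <- dplyr::mutate(tr, lon = rev(lon))
  rec_w <- orientation_records(tr_w, env, medium = "current")
  expect_true(all(rec_w$klass == "against"))
  # meteorological "from" convention flips the flow
  rec_f <- orientation_records(tr, env, medium = "wind", flow_convention = "from")
  expect_true(all(rec_f$flow_toward == 270))
  expect_true(all(rec_f$klass == "against"))
})

test_that("isotropic headings against a constant flow split 25/25/50 across classes", {
  withr::with_seed(77, {
    # random-walk track with isotropic segment headings
    n <- 1500
    ang <- runif(n, 0, 2 * pi)
    x <- cumsum(c(0, 10 * cos(ang)))
    y <- cumsum(c(0, 10 * sin(ang)))
    ll <- laea_inverse(x - mean(x), y - mean(y), 50, -47.5)
  })
  tr <- tibble::tibble(
    id = "a",
    time = as.POSIXct("2014-01-01", tz = "UTC") + (0:n) * 12 * 3600,
    lon = ll$lon, lat = ll$lat
  )
  env <- toy_env(lon = seq(30, 70, 2), lat = seq(-60, -35, 2),
                 time = as.Date("2014-01-01") + seq(0, 800, 100))
  rec <- orientation_records(tr, env, medium = "wind")
  p <- prop.table(table(rec$klass))
  se <- sqrt(0.25 * 0.75 / nrow(rec))
  expect_lt(abs(p[["similar"]] - 0.25), 4 * se)
  expect_lt(abs(p[["against"]] - 0.25), 4 * se)
  expect_lt(abs(p[["cross"]] - 0.50), 4 * sqrt(0.5 * 0.5 / nrow(rec)))
})

test_that("proportion tables average per individual first and conserve structure", {
  rec <- tibble::tibble(
    id = rep(c("a", "b", "c"), each = 10),
    stage = "juvenile",
    season = factor("winter", levels = c("summer", "autumn", "winter", "spring")),
    medium = "wind",
    klass = factor(c(rep("similar", 6), rep("against", 2), rep("cross", 2),
                     rep("similar", 2), rep("against", 6), rep("cross", 2),
                     rep("cross", 10)),
                   levels = c("similar", "against", "cross"))
  )
  tab <- proportion_table(rec)
  cell <- dplyr::filter(tab, season == "winter")
  expect_equal(sum(cell$mean_pct), 100)
  # mean across the three individuals' proportions
  expect_equal(cell$mean_pct[cell$klass == "similar"], 100 * mean(c(0.6, 0.2, 0)))
  expect_equal(cell$n_individuals, rep(3L, 3))
  # single individual: SD omitted and flagged
  one <- proportion_table(rec[rec$id == "c", ], min_individuals = 2)
  expect_true(all(is.na(one$sd_pct)))
  expect_true(all(one$flagged))
  # record conservation: per-individual counts sum to the total
  expect_equal(sum(dplyr::count(rec, id)$n), nrow(rec))
})

test_that("compact letter display separates exactly the significant pairs", {
  groups <- c("g1", "g2", "g3")
  pairs <- list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3"))
  # only g1 vs g3 differs
  lt <- cld_letters(groups, pairs, c(FALSE, TRUE, FALSE))
  expect_false(any(strsplit(lt[["g1"]], "")[[1]] %in% strsplit(lt[["g3"]], "")[[1]]))
  expect_true(any(strsplit(lt[["g1"]], "")[[1]] %in% strsplit(lt[["g2"]], "")[[1]]))
  expect_true(any(strsplit(lt[["g2"]], "")[[1]] %in% strsplit(lt[["g3"]], "")[[1]]))
  # nothing significant -> everyone shares one letter
  lt0 <- cld_letters(groups, pairs, c(FALSE, FALSE, FALSE))
  expect_equal(unname(lt0), rep("a", 3))
  # everything significant -> all letters distinct
  lt1 <- cld_letters(groups, pairs, c(TRUE, TRUE, TRUE))
  expect_equal(length(unique(lt1)), 3)
})

sim_orient_records <- function(p_by_cell, n_per_cell, n_ind = 10, re_sd = 0.3,
                               seed = 1) {
  withr::with_seed(seed, {
    purrr::imap_dfr(p_by_cell, function(p, cell) {
      parts <- strsplit(cell, ":")[[1]]
      ind <- sample(sprintf("%s_i%02d", parts[1], seq_len(n_ind)),
                    n_per_cell, replace = TRUE)
      b <- stats::setNames(rnorm(n_ind, 0, re_sd),
                           sprintf("%s_i%02d", parts[1], seq_len(n_ind)))
      up <- rbinom(n_per_cell, 1, plogis(qlogis(p) + b[ind]))
      tibble::tibble(
        id = ind, stage = parts[1],
        season = factor(parts[2], levels = c("summer", "autumn", "winter", "spring")),
        medium = "wind",
        klass = factor(ifelse(up == 1, "against", "similar"),
                       levels = c("similar", "against", "cross"))
      )
    })
  })
}

test_that("the orientation GLMM detects a planted contrast and reports Bonferroni-adjusted p-values", {
  rec <- sim_orient_records(
    c("juvenile:autumn" = 0.70, "juvenile:winter" = 0.35),
    n_per_cell = 400, seed = 42
  )
  cmp <- compare_proportions(rec)
  expect_equal(nrow(cmp$contrasts), 1)
  expect_lt(cmp$contrasts$p.value[1], 0.05)
  lets <- cmp$emmeans$letters
  expect_false(any(strsplit(lets[1], "")[[1]] %in% strsplit(lets[2], "")[[1]]))
  # Bonferroni definition: adjusted p = min(1, raw * n contrasts)
  raw <- summary(emmeans::contrast(emmeans::emmeans(cmp$model, ~cell), "pairwise",
                                   adjust = "none"))$p.value
  expect_equal(cmp$contrasts$p.value, pmin(1, raw * length(raw)), tolerance = 1e-8)
  expect_s3_class(glance(cmp), "tbl_df")
})

test_that("null cells share a letter", {
  rec <- sim_orient_records(
    c("juvenile:autumn" = 0.5, "juvenile:winter" = 0.5),
    n_per_cell = 300, seed = 7
  )
  cmp <- compare_proportions(rec)
  lets <- cmp$emmeans$letters
  expect_true(any(strsplit(lets[1], "")[[1]] %in% strsplit(lets[2], "")[[1]]))
})

test_that("the CHLA orientation model recovers a planted rising effect and yields probabilities", {
  withr::with_seed(3, {
    n <- 2500
    chla_t <- runif(n, 0.1, 1.5)
    chla_t1 <- runif(n, 0.1, 1.5)
    ind <- factor(sample(sprintf("i%02d", 1:12), n, replace = TRUE))
    eta <- -0.5 + 1.6 * chla_t1
    up <- rbinom(n, 1, plogis(eta))
    rec <- tibble::tibble(
      id = as.character(ind), stage = "juvenile",
      season = factor(sample(c("autumn", "winter"), n, TRUE),
                      levels = c("summer", "autumn", "winter", "spring")),
      medium = "wind",
      klass = factor(ifelse(up == 1, "against", "similar"),
                     levels = c("similar", "against", "cross")),
      chla_t = chla_t, chla_t1 = chla_t1
    )
  })
  fit <- fit_chla_orientation(rec)
  sm <- smooth_estimate(fit, "chla_t1", coverage = 0.9)
  expect_true(all(diff(sm$effect) >= -1e-8))
  expect_gt(diff(range(sm$effect)), 1)
  # the no-effect smooth shrinks toward flat
  sm0 <- smooth_estimate(fit, "chla_t", coverage = 0.9)
  expect_lt(diff(range(sm0$effect)), 0.5)
  pr <- predict(fit$gam, type = "response")
  expect_true(all(pr > 0 & pr < 1))
})
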