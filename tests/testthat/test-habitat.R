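# Environmental sampling, spline basis machinery and the binomial habitat
# GAMM (fitting, selection, prediction).

test_that("bilinear sampling recovers node values, flat patches and linear fields exactly", {
  env <- toy_env()
  # on a grid node
  expect_equal(sample_env(env, "sst", 45, -50, as.Date("2014-01-02")),
               10 + 0.5 * (-50 + 50))
  # midpoint of 4 equal nodes (mld is constant)
  expect_equal(sample_env(env, "mld", 45.5, -50.5, as.Date("2014-01-01")), 100)
  # linear fields are reproduced exactly anywhere (bilinear is exact on them)
  withr::with_seed(2, {
    lon <- runif(50, 40, 60); lat <- runif(50, -55, -40)
    expect_equal(sample_env(env, "sst", lon, lat, rep(as.Date("2014-01-01"), 50)),
                 10 + 0.5 * (lat + 50), tolerance = 1e-12)
    expect_equal(sample_env(env, "chla", lon, lat, rep(as.Date("2014-01-08"), 50)),
                 0.2 + 0.01 * (lon - 40), tolerance = 1e-12)
  })
  # outside the bounding box -> NA
  expect_true(is.na(sample_env(env, "sst", 70, -50, as.Date("2014-01-01"))))
  expect_error(sample_env(env, "nope", 45, -50, as.Date("2014-01-01")), "unknown field")
})

test_that("the cubic B-spline basis is a partition of unity and matches a de Boor oracle", {
  withr::with_seed(5, x <- sort(runif(200, -3, 7)))
  bb <- build_smooth_basis(x, n_basis = 10)
  expect_equal(dim(bb$X), c(200, 10))
  expect_equal(rowSums(bb$X), rep(1, 200), tolerance = 1e-9)

  # independent Cox-de Boor recursion
  deboor <- function(x, knots, i, p) {
    if (p == 0) {
      return(as.numeric(knots[i] <= x & x < knots[i + 1]))
    }
    d1 <- knots[i + p] - knots[i]
    d2 <- knots[i + p + 1] - knots[i + 1]
    t1 <- if (d1 > 0) (x - knots[i]) / d1 * deboor(x, knots, i, p - 1) else 0
    t2 <- if (d2 > 0) (knots[i + p + 1] - x) / d2 * deboor(x, knots, i + 1, p - 1) else 0
    t1 + t2
  }
  kn <- c(rep(bb$knots$boundary[1], 4), bb$knots$interior, rep(bb$knots$boundary[2], 4))
  xe <- x[x < max(x)] # de Boor's half-open convention differs at the right end
  for (i in c(1, 4, 7, 10)) {
    expect_equal(bb$X[x < max(x), i], deboor(xe, kn, i, 3), tolerance = 1e-9)
  }

  # penalty: second differences plus ridge; heavy penalization collapses a
  # penalized LS fit toward a straight line
  withr::with_seed(6, y <- 2 + 0.5 * x + rnorm(200, 0, 0.3))
  lam <- 1e8
  beta <- solve(crossprod(bb$X) + lam * bb$penalty, crossprod(bb$X, y))
  fitted <- as.numeric(bb$X %*% beta)
  lin <- stats::lm.fit(cbind(1, x), fitted)
  expect_lt(sqrt(mean(lin$residuals^2)), 0.05)

  expect_warning(small <- build_smooth_basis(rep(1:5, 10), n_basis = 10), "distinct")
  expect_equal(ncol(small$X), 5)
})

test_that("an intercept-only fit on balanced outcomes gives probability one half", {
  obs <- tibble::tibble(y = rep(c(0L, 1L), 100), individual = factor("a"))
  fit <- fit_habitat_gamm(obs, env_terms = character(0), factors = character(0),
                          spatial = FALSE, random = FALSE)
  expect_equal(unname(plogis(coef(fit$gam)[1])), 0.5, tolerance = 1e-9)
})

test_that("a planted decreasing wind effect is recovered as a monotone smooth", {
  obs <- sim_habitat_obs(2500, re_sd = 0, beta_wind = -0.4, seed = 31)
  fit <- fit_habitat_gamm(obs, env_terms = c("sst", "wind"), factors = character(0),
                          spatial = FALSE, random = TRUE)
  sm <- smooth_estimate(fit, "wind", n = 80, coverage = 0.9)
  expect_true(all(diff(sm$effect) <= 1e-8))
  # and the fitted effect has meaningful magnitude (not shrunk away)
  expect_gt(diff(range(sm$effect)), 1)
})

test_that("the random-intercept SD is recovered from planted heterogeneity", {
  obs <- sim_habitat_obs(3000, n_ind = 20, re_sd = 1, beta_wind = -0.4, seed = 13)
  fit <- fit_habitat_gamm(obs, env_terms = "wind", factors = character(0),
                          spatial = FALSE, random = TRUE)
  sd_hat <- random_intercept_sd(fit)
  expect_gt(sd_hat, 0.5)
  expect_lt(sd_hat, 1.6)
  expect_equal(glance(fit)$re_sd, sd_hat)
})

test_that("AIC dredge ranks subsets, keeps likelihood monotone in nesting, and finds the true terms", {
  obs <- sim_habitat_obs(2500, re_sd = 0.5, beta_wind = -0.5, seed = 77)
  dr <- dredge_habitat(obs, candidates = c("sst", "wind", "chla", "curr"),
                       factors = character(0), spatial = FALSE, random = TRUE,
                       k = 6)
  expect_equal(nrow(dr$table), 16)
  expect_equal(dr$table$delta[1], 0)
  # the selected subset contains the true drivers
  expect_true(all(c("sst", "wind") %in% dr$best_terms))
  # nested-model likelihood monotonicity: full set vs any subset
  full_ll <- dr$table$logLik[dr$table$n_terms == 4]
  expect_true(all(full_ll >= dr$table$logLik - 1e-6))
  expect_s3_class(tidy(dr), "tbl_df")
})

test_that("predictions are probabilities, match fitted values, and flag extrapolation", {
  obs <- sim_habitat_obs(1500, re_sd = 0.3, seed = 5)
  fit <- fit_habitat_gamm(obs, env_terms = c("sst", "wind"), factors = character(0),
                          spatial = FALSE, random = TRUE)
  pr <- predict_foraging(fit, obs)
  expect_true(all(pr$p > 0 & pr$p < 1))
  expect_false(any(pr$extrapolated))
  # at a training point (random effect included) prediction matches fitted
  eta_fit <- predict(fit$gam, type = "link")
  pr_re <- predict(fit$gam, newdata = as.data.frame(obs), type = "link")
  expect_equal(as.numeric(pr_re), as.numeric(eta_fit), tolerance = 1e-8)
  out <- predict_foraging(fit, dplyr::mutate(obs[1:5, ], wind = 100))
  expect_true(all(out$extrapolated))
})

test_that("with infinite smoothing the model collapses to the parametric GLM", {
  obs <- sim_habitat_obs(1200, re_sd = 0, seed = 9)
  obs$grp <- factor(rep(c("a", "b"), length.out = nrow(obs)))
  g_pen <- mgcv::gam(y ~ grp + s(sst, bs = "cs", k = 8) + s(wind, bs = "cs", k = 8),
                     family = binomial, data = obs, sp = c(1e10, 1e10))
  g_lm <- stats::glm(y ~ grp, family = binomial, data = obs)
  expect_lt(abs(deviance(g_pen) - deviance(g_lm)) / deviance(g_lm), 1e-3)
})
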