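# Habitat preference modelling: probability of being in the foraging (vs
# traveling) dive mode as smooth functions of environmental covariates, with
# categorical fixed effects (year, stage, season), a 2-D spatial smooth on
# Lambert-equal-area-projected coordinates, and a per-individual random
# intercept. Fitted as binomial (logit) penalized-spline models via mgcv::gam
# with cubic regression splines with shrinkage (bs = "cs"), REML smoothing
# parameter estimation, and exhaustive AIC subset selection over the
# environmental terms.

#' Cubic B-spline basis with a second-difference shrinkage penalty
#'
#' Builds a cubic B-spline design matrix on quantile-spaced interior knots
#' and the associated penalty: squared second differences of the basis
#' coefficients plus a small ridge, so heavy penalization can shrink a term
#' all the way to zero (the behaviour of shrinkage smoothers). Exposed as the
#' package's reference basis machinery; model fitting itself uses mgcv.
#'
#' @param x Numeric covariate vector.
#' @param n_basis Number of basis functions (default 10). If `x` has fewer
#'   distinct values the basis is reduced with a warning.
#' @param ridge Ridge weight added to the difference penalty (default 1e-6).
#' @param knots Optional list with `interior` and `boundary` knots (as
#'   returned in the output), to evaluate the same basis at new points.
#' @return List of class `smooth_basis`: `X` (n x n_basis design, rows sum to
#'   1), `penalty` (n_basis x n_basis), `knots`.
#' @export
build_smooth_basis <- function(x, n_basis = 10, ridge = 1e-6, knots = NULL) {
  stopifnot(is.numeric(x), n_basis >= 4)
  if (is.null(knots)) {
    nd <- length(unique(x))
    if (nd < n_basis) {
      warn(sprintf("build_smooth_basis(): only %d distinct values; reducing basis to %d",
                   nd, max(4, nd)))
      n_basis <- max(4, nd)
    }
    n_interior <- n_basis - 4
    interior <- if (n_interior > 0) {
      quantile(x, probs = seq_len(n_interior) / (n_interior + 1), names = FALSE)
    } else {
      numeric(0)
    }
    boundary <- range(x)
    knots <- list(interior = interior, boundary = boundary)
  }
  all_knots <- c(rep(knots$boundary[1], 4), knots$interior, rep(knots$boundary[2], 4))
  X <- splines::splineDesign(all_knots, pmin(pmax(x, knots$boundary[1]), knots$boundary[2]),
                             ord = 4)
  nb <- ncol(X)
  D2 <- diff(diag(nb), differences = 2)
  penalty <- crossprod(D2) + ridge * diag(nb)
  structure(list(X = X, penalty = penalty, knots = knots),
            class = "smooth_basis")
}

#' Assemble habitat observations from labelled hourly records
#'
#' Builds the model frame for habitat fitting: binary response
#' (traveling = 0, foraging = 1), environmental covariates sampled at each
#' record's location and time (bilinear in space, nearest field time slice),
#' projected coordinates (Lambert azimuthal equal-area, km) and factors.
#' Current and wind speeds are vector magnitudes of the (u, v) fields. Rows
#' with any missing covariate (e.g. outside the field bounding box) are
#' dropped and counted.
#'
#' @param records A `dive_clusters` object (hourly records with `mode`,
#'   `lon`, `lat`, `hour`, `id`; `stage`/`year` used if present).
#' @param env An [env_fields] object.
#' @param center Projection centre `c(lon, lat)`; defaults to the data
#'   centroid.
#' @param covariates Environmental covariates to extract (subset of
#'   `sst, mld, sic, chla, curr, wind`).
#' @return Tibble with `y`, covariates, `x_km`, `y_km`, `year`, `stage`,
#'   `season`, `individual`; attributes `n_dropped` and `center`.
#' @export
habitat_observations <- function(records, env, center = NULL,
                                 covariates = c("sst", "mld", "chla", "curr", "wind")) {
  stopifnot(all(c("id", "hour", "lon", "lat", "mode") %in% names(records)))
  df <- tibble::as_tibble(records)
  center <- center %||% c(lon = mean(df$lon), lat = mean(df$lat))
  xy <- laea_project(df$lon, df$lat, center[["lon"]], center[["lat"]])
  out <- tibble::tibble(
    y = as.integer(df$mode == "foraging"),
    x_km = xy$x_km, y_km = xy$y_km,
    year = factor(if ("year" %in% names(df)) df$year else "y1"),
    stage = factor(if ("stage" %in% names(df)) df$stage else "all"),
    season = season_of(df$hour),
    individual = factor(df$id)
  )
  samp <- function(v) sample_env(env, v, df$lon, df$lat, df$hour)
  if ("sst" %in% covariates) out$sst <- samp("sst")
  if ("mld" %in% covariates) out$mld <- samp("mld")
  if ("sic" %in% covariates) out$sic <- samp("sic")
  if ("chla" %in% covariates) out$chla <- samp("chla")
  if ("curr" %in% covariates) out$curr <- sqrt(samp("uo")^2 + samp("vo")^2)
  if ("wind" %in% covariates) out$wind <- sqrt(samp("u10")^2 + samp("v10")^2)
  cc <- complete.cases(out)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    inform(sprintf("habitat_observations(): dropped %d row(s) with missing covariates",
                   n_dropped))
  }
  structure(out[cc, ], n_dropped = n_dropped, center = center)
}

# shared binomial GAM builder used by habitat and orientation models
.fit_binomial_gam <- function(data, response, smooth_terms, factors,
                              spatial = FALSE, re_var = "individual",
                              k = 10, k_spatial = 25, method = "REML",
                              select_fallback = TRUE) {
  data <- as.data.frame(data)
  # keep only factors with >= 2 observed levels (simulated designs may be flat)
  factors <- factors[vapply(factors, function(f) {
    dplyr::n_distinct(data[[f]]) >= 2
  }, logical(1))]
  smooth_terms <- smooth_terms[vapply(smooth_terms, function(s) {
    dplyr::n_distinct(data[[s]]) >= 4
  }, logical(1))]
  rhs <- c(
    factors,
    sprintf("s(%s, bs = 'cs', k = %d)", smooth_terms, k),
    if (spatial) sprintf("s(x_km, y_km, k = %d)", k_spatial),
    if (!is.null(re_var) && dplyr::n_distinct(data[[re_var]]) >= 2) {
      sprintf("s(%s, bs = 're')", re_var)
    }
  )
  if (length(rhs) == 0) rhs <- "1"
  form <- as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
  fit <- mgcv::gam(form, family = binomial(link = "logit"), data = data,
                   method = method)
  fit
}

#' Fit the binomial habitat GAMM
#'
#' Penalized-spline binomial model of foraging probability: cubic regression
#' splines with shrinkage for each environmental covariate, an optional 2-D
#' smooth of the projected coordinates, categorical fixed effects and a
#' per-individual random intercept (as an `mgcv` random-effect smooth).
#' Estimation is by penalized likelihood with REML smoothing-parameter
#' selection.
#'
#' @param obs Observations from [habitat_observations()] (needs `y` and the
#'   requested terms).
#' @param env_terms Environmental smooth terms to include.
#' @param factors Categorical fixed effects always included (factors with a
#'   single observed level are dropped automatically).
#' @param spatial Include the 2-D spatial smooth `s(x_km, y_km)`.
#' @param random Include the individual random intercept.
#' @param k,k_spatial Basis dimensions for 1-D smooths and the spatial smooth.
#' @return Object of class `habitat_fit` wrapping the `gam` fit; supports
#'   [tidy()], [glance()], [predict_foraging()], [smooth_estimate()].
#' @export
fit_habitat_gamm <- function(obs,
                             env_terms = c("sst", "mld", "chla", "curr", "wind"),
                             factors = c("year", "stage", "season"),
                             spatial = TRUE, random = TRUE,
                             k = 10, k_spatial = 25) {
  stopifnot("y" %in% names(obs))
  env_terms <- intersect(env_terms, names(obs))
  fit <- .fit_binomial_gam(
    obs, "y", env_terms, intersect(factors, names(obs)),
    spatial = spatial && all(c("x_km", "y_km") %in% names(obs)),
    re_var = if (random && "individual" %in% names(obs)) "individual" else NULL,
    k = k, k_spatial = k_spatial
  )
  structure(
    list(gam = fit, env_terms = env_terms, factors = factors,
         spatial = spatial, random = random,
         train_ranges = lapply(obs[intersect(c(env_terms, "x_km", "y_km"), names(obs))],
                               range)),
    class = "habitat_fit"
  )
}

#' @exportS3Method base::print
print.habitat_fit <- function(x, ...) {
  cat("Binomial habitat GAMM (logit link)\n")
  cat("terms:", paste(x$env_terms, collapse = ", "),
      if (x$spatial) "+ s(x_km, y_km)", if (x$random) "+ (1|individual)", "\n")
  cat(sprintf("AIC %.1f, logLik %.1f, n %d\n", AIC(x$gam),
              as.numeric(logLik(x$gam)), stats::nobs(x$gam)))
  invisible(x)
}

#' @rdname fit_habitat_gamm
#' @param x A `habitat_fit` object.
#' @param ... Unused.
#' @export
tidy.habitat_fit <- function(x, ...) {
  s <- summary(x$gam)
  para <- tibble::tibble(
    term = rownames(s$p.table),
    type = "parametric",
    estimate = s$p.table[, 1], std_error = s$p.table[, 2],
    statistic = s$p.table[, 3], p_value = s$p.table[, 4], edf = NA_real_
  )
  if (!is.null(s$s.table) && nrow(s$s.table) > 0) {
    sm <- tibble::tibble(
      term = rownames(s$s.table),
      type = "smooth",
      estimate = NA_real_, std_error = NA_real_,
      statistic = s$s.table[, 3], p_value = s$s.table[, 4],
      edf = s$s.table[, 1]
    )
    para <- dplyr::bind_rows(para, sm)
  }
  para
}

#' @rdname fit_habitat_gamm
#' @export
glance.habitat_fit <- function(x, ...) {
  g <- x$gam
  tibble::tibble(
    AIC = AIC(g), logLik = as.numeric(logLik(g)),
    deviance = g$deviance, null_deviance = g$null.deviance,
    edf_total = sum(g$edf), n = stats::nobs(g),
    converged = g$converged,
    re_sd = random_intercept_sd(x)
  )
}

#' Estimated standard deviation of the individual random intercept
#'
#' @param fit A `habitat_fit` (or `orientation_chla_fit`) object.
#' @return SD on the logit scale, or `NA` if the model has no random term.
#' @export
random_intercept_sd <- function(fit) {
  g <- if (inherits(fit, "gam")) fit else fit$gam
  vc <- tryCatch(
    {
      out <- NULL
      utils::capture.output(out <- suppressWarnings(mgcv::gam.vcomp(g, rescale = TRUE)))
      out
    },
    error = function(e) NULL
  )
  if (is.null(vc)) return(NA_real_)
  rn <- rownames(vc)
  hit <- grep("individual", rn)
  if (length(hit) == 0) return(NA_real_)
  unname(vc[hit[1], "std.dev"])
}

#' Exhaustive AIC model selection over environmental terms
#'
#' Fits every subset of `candidates` (factors, the spatial smooth and the
#' random intercept are in every model), ranks models by AIC and selects the
#' lowest. If the runner-up is within `delta_rule` AIC units the selection is
#' flagged ambiguous (the conventional delta-AIC > 2 retention rule).
#'
#' @param obs Observations from [habitat_observations()].
#' @param candidates Candidate environmental smooth terms (at most 12).
#' @inheritParams fit_habitat_gamm
#' @param delta_rule Ambiguity threshold on delta AIC (default 2).
#' @return Object of class `habitat_dredge`: list with `table` (one row per
#'   subset: terms, df, logLik, AIC, delta), `best` (refitted `habitat_fit`),
#'   `ambiguous`, `failed` (subsets whose fit errored).
#' @export
dredge_habitat <- function(obs, candidates = c("sst", "mld", "chla", "curr", "wind"),
                           factors = c("year", "stage", "season"),
                           spatial = FALSE, random = TRUE,
                           k = 10, k_spatial = 25, delta_rule = 2) {
  candidates <- intersect(candidates, names(obs))
  if (length(candidates) > 12) abort("dredge_habitat(): more than 12 candidate terms")
  subsets <- unlist(lapply(0:length(candidates), function(m) {
    if (m == 0) list(character(0)) else {
      asplit(combn(candidates, m), 2)
    }
  }), recursive = FALSE)
  failed <- character(0)
  rows <- purrr::map(subsets, function(terms) {
    terms <- as.character(terms)
    fit <- tryCatch(
      fit_habitat_gamm(obs, env_terms = terms, factors = factors,
                       spatial = spatial, random = random, k = k,
                       k_spatial = k_spatial),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      failed <<- c(failed, paste(terms, collapse = "+"))
      return(NULL)
    }
    tibble::tibble(
      terms = paste(sort(terms), collapse = "+"),
      n_terms = length(terms),
      edf = sum(fit$gam$edf),
      logLik = as.numeric(logLik(fit$gam)),
      AIC = AIC(fit$gam)
    )
  })
  tab <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$AIC) |>
    dplyr::mutate(delta = .data$AIC - .data$AIC[1])
  best_terms <- if (tab$terms[1] == "") character(0) else strsplit(tab$terms[1], "\\+")[[1]]
  best <- fit_habitat_gamm(obs, env_terms = best_terms, factors = factors,
                           spatial = spatial, random = random, k = k,
                           k_spatial = k_spatial)
  ambiguous <- nrow(tab) > 1 && tab$delta[2] <= delta_rule
  structure(list(table = tab, best = best, best_terms = best_terms,
                 ambiguous = ambiguous, failed = failed),
            class = "habitat_dredge")
}

#' @exportS3Method base::print
print.habitat_dredge <- function(x, ...) {
  cat(sprintf("AIC dredge over %d models; best: {%s}%s\n",
              nrow(x$table), paste(x$best_terms, collapse = ", "),
              if (x$ambiguous) " (ambiguous: runner-up within 2 AIC)" else ""))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' @export
tidy.habitat_dredge <- function(x, ...) x$table

#' Predict foraging probability
#'
#' Inverse-logit predictions from a fitted habitat model with the individual
#' random effect set to its population mean (zero). Covariates outside the
#' training range are flagged, not refused.
#'
#' @param fit A `habitat_fit` object.
#' @param newdata Data frame of covariate values (an `individual` column is
#'   supplied automatically if absent).
#' @return Tibble `p` (probability in (0,1)) and `extrapolated` (logical).
#' @export
predict_foraging <- function(fit, newdata) {
  stopifnot(inherits(fit, "habitat_fit"))
  newdata <- as.data.frame(newdata)
  g <- fit$gam
  vars <- all.vars(stats::formula(g))[-1]
  if ("individual" %in% vars && !"individual" %in% names(newdata)) {
    newdata$individual <- factor(levels(g$model$individual)[1],
                                 levels = levels(g$model$individual))
  }
  exclude <- grep("individual", sapply(g$smooth, function(s) s$label), value = TRUE)
  eta <- predict(g, newdata = newdata, type = "link", exclude = exclude,
                 newdata.guaranteed = TRUE)
  extrap <- rep(FALSE, nrow(newdata))
  for (v in names(fit$train_ranges)) {
    if (v %in% names(newdata)) {
      r <- fit$train_ranges[[v]]
      extrap <- extrap | newdata[[v]] < r[1] | newdata[[v]] > r[2]
    }
  }
  tibble::tibble(p = as.numeric(plogis(eta)), extrapolated = extrap)
}

#' Evaluate one fitted smooth term on a grid
#'
#' Returns the centred smooth effect (logit scale) of a single covariate over
#' a regular grid spanning its central `coverage` quantile range, all other
#' terms held fixed - convenient for monotonicity checks and effect plots.
#'
#' @param fit A `habitat_fit` object.
#' @param term Covariate name (must be one of the fitted smooth terms).
#' @param n Grid size.
#' @param coverage Central quantile span of the covariate (default 0.9).
#' @return Tibble `value, effect`.
#' @export
smooth_estimate <- function(fit, term, n = 100, coverage = 0.9) {
  stopifnot(inherits(fit, "habitat_fit"), term %in% fit$env_terms)
  g <- fit$gam
  mf <- g$model
  qs <- quantile(mf[[term]], c((1 - coverage) / 2, 1 - (1 - coverage) / 2))
  grid <- seq(qs[1], qs[2], length.out = n)
  nd <- mf[rep(1, n), , drop = FALSE]
  nd[[term]] <- grid
  lab <- sprintf("s(%s)", term)
  eff <- predict(g, newdata = nd, type = "terms", terms = lab,
                 newdata.guaranteed = TRUE)
  tibble::tibble(value = grid, effect = as.numeric(eff[, lab]))
}
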