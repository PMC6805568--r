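# Orientation analysis: 12-h movement segments classified relative to wind
# and ocean-current directions (downstream / upstream / cross), seasonal
# proportion tables, binomial GLMM contrasts with Bonferroni-adjusted
# pairwise comparisons, and a smooth model of upstream choice versus CHLA
# along the trajectory.

#' Classify an angular difference into an orientation class
#'
#' Differences between 315 and 45 degrees mean bird and flow point the same
#' way (`similar`, downstream); between 135 and 225 the bird opposes the flow
#' (`against`, upstream); everything else is `cross`. Boundary values (45,
#' 135, 225, 315) belong to the similar/against bins (closed bins).
#'
#' @param delta Angular differences in degrees `[0, 360)`.
#' @return Factor with levels `similar`, `against`, `cross`.
#' @export
#' @examples
#' classify_direction(c(0, 45, 90, 180, 270, 315))
classify_direction <- function(delta) {
  stopifnot(all(delta >= 0 & delta < 360, na.rm = TRUE))
  out <- dplyr::case_when(
    delta >= 315 | delta <= 45 ~ "similar",
    delta >= 135 & delta <= 225 ~ "against",
    TRUE ~ "cross"
  )
  out[is.na(delta)] <- NA
  factor(out, levels = c("similar", "against", "cross"))
}

#' Build orientation records from tracks and flow fields
#'
#' Re-interpolates each track at `step_hours` (12 h by default), computes the
#' heading of each consecutive segment, samples the flow (u, v) components of
#' the chosen medium at the segment start position and nearest field time
#' ("toward" convention), and classifies the angular difference. CHLA is
#' sampled at the segment start (time t) and end (time t + 1) positions.
#' Zero-length segments and zero flow vectors are skipped (counted).
#'
#' @param tracks Filtered tracks `id, time, lon, lat` (+ `stage` carried).
#' @param env An [env_fields] object with `u10`/`v10` and `uo`/`vo`.
#' @param medium `"wind"` or `"current"`.
#' @param step_hours Re-interpolation step (default 12).
#' @param flow_convention `"toward"` (oceanographic, default) if the (u, v)
#'   fields point where the flow goes; `"from"` (meteorological) inputs are
#'   rotated 180 degrees.
#' @return Tibble `id, stage, time, season, medium, heading, flow_toward,
#'   delta, klass, chla_t, chla_t1`; attribute `n_skipped`.
#' @export
orientation_records <- function(tracks, env, medium = c("wind", "current"),
                                step_hours = 12,
                                flow_convention = c("toward", "from")) {
  medium <- match.arg(medium)
  flow_convention <- match.arg(flow_convention)
  uv <- if (medium == "wind") c("u10", "v10") else c("uo", "vo")
  stage_map <- if ("stage" %in% names(tracks)) {
    dplyr::distinct(tracks, .data$id, .data$stage)
  } else {
    dplyr::distinct(tracks, .data$id) |> dplyr::mutate(stage = "all")
  }
  interp <- interpolate_regular(tracks, step_hours = step_hours)
  seg <- interp |>
    dplyr::group_by(.data$id) |>
    dplyr::mutate(
      lon1 = dplyr::lead(.data$lon), lat1 = dplyr::lead(.data$lat),
      time1 = dplyr::lead(.data$time)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$lon1))
  zero_len <- seg$lon == seg$lon1 & seg$lat == seg$lat1
  seg <- seg[!zero_len, , drop = FALSE]
  u <- sample_env(env, uv[1], seg$lon, seg$lat, seg$time)
  v <- sample_env(env, uv[2], seg$lon, seg$lat, seg$time)
  if (flow_convention == "from") {
    u <- -u
    v <- -v
  }
  flow <- flow_direction(u, v)
  heading <- suppressWarnings(initial_bearing(seg$lon, seg$lat, seg$lon1, seg$lat1))
  out <- tibble::tibble(
    id = seg$id,
    time = seg$time,
    season = season_of(seg$time),
    medium = medium,
    heading = heading,
    flow_toward = flow,
    delta = angular_difference(heading, flow),
    chla_t = sample_env(env, "chla", seg$lon, seg$lat, seg$time),
    chla_t1 = sample_env(env, "chla", seg$lon1, seg$lat1, seg$time1)
  ) |>
    dplyr::left_join(stage_map, by = "id") |>
    dplyr::relocate("stage", .after = "id")
  bad <- is.na(out$heading) | is.na(out$flow_toward)
  n_skipped <- sum(zero_len) + sum(bad)
  out <- out[!bad, , drop = FALSE]
  out$klass <- classify_direction(out$delta)
  structure(out, n_skipped = n_skipped)
}

#' Seasonal proportion table of orientation classes
#'
#' Proportions are computed per individual first and then averaged within
#' stage x season x medium cells, so the reported SD reflects
#' inter-individual spread. Cells with fewer than `min_individuals`
#' individuals have their SD omitted and are flagged.
#'
#' @param records Output of [orientation_records()].
#' @param min_individuals Minimum individuals per cell for an SD (default 2).
#' @return Tibble `medium, stage, season, klass, mean_pct, sd_pct,
#'   n_individuals, flagged`; the three class means sum to 100 within each
#'   cell.
#' @export
proportion_table <- function(records, min_individuals = 2) {
  stopifnot(all(c("id", "stage", "season", "medium", "klass") %in% names(records)))
  per_ind <- records |>
    dplyr::count(.data$medium, .data$stage, .data$season, .data$id, .data$klass,
                 .drop = FALSE) |>
    dplyr::group_by(.data$medium, .data$stage, .data$season, .data$id) |>
    dplyr::mutate(total = sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$total > 0) |>
    dplyr::mutate(prop = .data$n / .data$total)
  per_ind |>
    dplyr::group_by(.data$medium, .data$stage, .data$season, .data$klass) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      mean_pct = 100 * mean(.data$prop),
      sd_pct = if (dplyr::n() >= min_individuals) 100 * sd(.data$prop) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$n_individuals < min_individuals)
}

#' Compare upstream vs downstream proportions across stage and season
#'
#' Binomial random-intercept GLMM (upstream = 1, downstream = 0; cross
#' records excluded) with a stage-by-season cell fixed effect and an
#' individual random intercept, fitted by adaptive Gauss-Hermite maximum
#' likelihood (`lme4::glmer`, `nAGQ` nodes). All pairwise cell contrasts are
#' tested on the logit scale with Bonferroni-adjusted p-values (emmeans), and
#' cells sharing no significant contrast share a letter.
#'
#' @param records Output of [orientation_records()] (one medium).
#' @param alpha Significance level for the letter display (default 0.05).
#' @param nAGQ Gauss-Hermite nodes for the 1-D random-effect integrals
#'   (default 9).
#' @return Object of class `orientation_glmm`: list with `model` (glmer fit),
#'   `emmeans` (cell estimates tibble with letters), `contrasts` (pairwise
#'   tibble), `n_records`.
#' @export
compare_proportions <- function(records, alpha = 0.05, nAGQ = 9) {
  stopifnot(all(c("id", "stage", "season", "klass") %in% names(records)))
  d <- records |>
    dplyr::filter(.data$klass != "cross") |>
    dplyr::mutate(
      upstream = as.integer(.data$klass == "against"),
      cell = droplevels(interaction(.data$stage, .data$season, sep = ":")),
      individual = factor(.data$id)
    )
  if (dplyr::n_distinct(d$cell) < 2) {
    abort("compare_proportions(): need records in at least 2 stage-season cells")
  }
  fit <- lme4::glmer(upstream ~ cell + (1 | individual), data = d,
                     family = binomial, nAGQ = nAGQ)
  emm <- emmeans::emmeans(fit, ~cell)
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "bonferroni"))
  emm_df <- as.data.frame(emm)
  sig <- prs$p.value < alpha
  pair_names <- strsplit(as.character(prs$contrast), " - ")
  # emmeans backticks non-syntactic cell names in contrasts; strip them
  pair_names <- lapply(pair_names, function(p) gsub("^`|`$", "", p))
  letters <- cld_letters(as.character(emm_df$cell), pair_names, sig)
  emm_df$letters <- letters[as.character(emm_df$cell)]
  structure(
    list(
      model = fit,
      emmeans = tibble::as_tibble(emm_df),
      contrasts = tibble::as_tibble(prs),
      n_records = nrow(d), alpha = alpha
    ),
    class = "orientation_glmm"
  )
}

#' Compact letter display from pairwise significance
#'
#' Insert-and-absorb algorithm: groups that are not significantly different
#' share at least one letter; every significant pair shares none.
#'
#' @param groups Character vector of group names.
#' @param pairs List of length-2 character vectors (the tested pairs).
#' @param significant Logical vector parallel to `pairs`.
#' @return Named character vector of letter strings.
#' @export
cld_letters <- function(groups, pairs, significant) {
  cols <- list(groups) # each column = set of groups sharing a letter
  for (i in seq_along(pairs)) {
    if (!significant[i]) next
    a <- pairs[[i]][1]
    b <- pairs[[i]][2]
    for (j in seq_along(cols)) {
      if (a %in% cols[[j]] && b %in% cols[[j]]) {
        cols[[length(cols) + 1]] <- setdiff(cols[[j]], a)
        cols[[j]] <- setdiff(cols[[j]], b)
      }
    }
    # absorb: drop columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (j in seq_along(cols)) {
      for (l in seq_along(cols)) {
        if (j != l && keep[l] && all(cols[[j]] %in% cols[[l]]) &&
            (length(cols[[j]]) < length(cols[[l]]) || j > l)) {
          keep[j] <- FALSE
          break
        }
      }
    }
    cols <- cols[keep]
  }
  out <- setNames(rep("", length(groups)), groups)
  for (j in seq_along(cols)) {
    for (g in cols[[j]]) out[g] <- paste0(out[g], letters[j])
  }
  out
}

#' @exportS3Method base::print
print.orientation_glmm <- function(x, ...) {
  cat(sprintf("Orientation GLMM (binomial, %d records): upstream vs downstream\n",
              x$n_records))
  print(x$emmeans[c("cell", "emmean", "SE", "letters")])
  invisible(x)
}

#' @rdname compare_proportions
#' @param x An `orientation_glmm` object.
#' @param ... Unused.
#' @export
tidy.orientation_glmm <- function(x, ...) x$contrasts

#' @rdname compare_proportions
#' @export
glance.orientation_glmm <- function(x, ...) {
  tibble::tibble(
    n = x$n_records,
    logLik = as.numeric(logLik(x$model)),
    AIC = AIC(x$model),
    re_sd = sqrt(as.numeric(lme4::VarCorr(x$model)$individual))
  )
}

#' Upstream orientation as a smooth function of CHLA along the track
#'
#' Binomial smooth model (logit link) of the upstream (1) vs downstream (0)
#' choice with 1-D shrinkage smooths of CHLA at the current (t) and next
#' (t + 1) location, stage and season as factors and an individual random
#' intercept - the same fitting core as the habitat models. Cross-oriented
#' records are excluded.
#'
#' @param records Output of [orientation_records()] (one medium).
#' @param k Basis dimension of the CHLA smooths.
#' @return A `habitat_fit` object (response is upstream probability).
#' @export
fit_chla_orientation <- function(records, k = 10) {
  stopifnot(all(c("klass", "chla_t", "chla_t1") %in% names(records)))
  d <- records |>
    dplyr::filter(.data$klass != "cross",
                  !is.na(.data$chla_t), !is.na(.data$chla_t1)) |>
    dplyr::mutate(
      y = as.integer(.data$klass == "against"),
      stage = factor(.data$stage), season = factor(.data$season),
      individual = factor(.data$id)
    )
  fit <- .fit_binomial_gam(d, "y", c("chla_t", "chla_t1"),
                           c("stage", "season"),
                           spatial = FALSE, re_var = "individual", k = k)
  structure(
    list(gam = fit, env_terms = c("chla_t", "chla_t1"),
         factors = c("stage", "season"), spatial = FALSE, random = TRUE,
         train_ranges = lapply(d[c("chla_t", "chla_t1")], range)),
    class = "habitat_fit"
  )
}
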