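#' Simulate transit flight performance under a track/season scenario
#'
#' The counterfactual engine: each transit step keeps its observed geometry
#' (length and bearing) while the wind is re-sampled at the step's location
#' and — when the season is swapped — at a time shifted by whole calendar
#' months. The focal species' wind model predicts the ground speed it would
#' attain under that wind, each step's duration is `length / speed`, and
#' per-trip durations are compared with the mean observed duration of the
#' focal species' real transit portions. Geometry is never altered (no
#' rerouting): total simulated distance equals total observed transit
#' distance in every scenario.
#'
#' @param transit_steps Decoded transit steps of the *source* tracks (own
#'   or other species): needs `trip_id`, `timestamp`, `lon`, `lat`,
#'   `step_km`, `bearing`, `ground_speed`.
#' @param fit The focal species' [fit_wind_gam()] model.
#' @param field `wind_field` covering the (possibly shifted) times.
#' @param season_shift_months Calendar-month shift applied to step times
#'   (0 = own season).
#' @param reference_hours Mean observed per-trip transit duration of the
#'   focal species' real trips (the % change reference). Defaults to the
#'   observed durations of `transit_steps` — correct for own-track
#'   scenarios; pass the focal species' own value for other-track runs.
#' @param speeds `"predicted"` (default) or `"observed"` (diagnostic mode:
#'   reproduces the observed durations exactly).
#' @param track_source,season Labels stored in the result (`"own"`/`"other"`).
#' @param min_speed Steps predicted below this speed (km/h) flag their trip
#'   for exclusion.
#' @return A `scenario_result`: per-trip tibble (`trip_id`,
#'   `duration_hours`, `mean_speed`, `pct_change`, `excluded`) with the
#'   scenario metadata attached.
#' @export
run_scenario <- function(transit_steps, fit, field, season_shift_months = 0,
                         reference_hours = NULL,
                         speeds = c("predicted", "observed"),
                         track_source = "own", season = "own",
                         min_speed = 1) {
  speeds <- match.arg(speeds)
  stopifnot_cols(transit_steps,
                 c("trip_id", "timestamp", "lon", "lat", "step_km"),
                 "transit_steps")
  st <- transit_steps
  obs_dur <- st |>
    group_by(.data$trip_id) |>
    summarise(obs_hours = sum(.data$step_km / .data$ground_speed),
              .groups = "drop")
  reference_hours <- reference_hours %||% mean(obs_dur$obs_hours)
  tm <- st$timestamp
  if (season_shift_months != 0) {
    tm <- lubridate::`%m+%`(tm, lubridate::period(month = as.integer(season_shift_months)))
  }
  if (speeds == "observed") {
    st$sim_speed <- st$ground_speed
  } else {
    w <- sample_wind(field, st$lon, st$lat, tm)
    ws_kmh <- sqrt(w$u^2 + w$v^2) * 3.6
    da <- delta_angle(st$bearing, wrap360(atan2(w$u, w$v) * 180 / pi))
    st$sim_speed <- predict_speed(fit, da, ws_kmh,
                                  warn_extrapolation = FALSE)$speed
  }
  st$sim_speed[is.na(st$sim_speed)] <- min_speed # stationary steps
  per_trip <- st |>
    group_by(.data$trip_id) |>
    summarise(
      duration_hours = sum(.data$step_km / .data$sim_speed),
      distance_km = sum(.data$step_km),
      mean_speed = sum(.data$step_km) / sum(.data$step_km / .data$sim_speed),
      n_slow = sum(.data$sim_speed <= min_speed),
      .groups = "drop"
    ) |>
    mutate(excluded = .data$n_slow > 0,
           pct_change = 100 * (.data$duration_hours - reference_hours) /
             reference_hours)
  if (any(per_trip$excluded)) {
    warn(sprintf(
      "run_scenario(): %d trip(s) excluded (predicted speed <= %.1f km/h).",
      sum(per_trip$excluded), min_speed))
  }
  structure(list(
    per_trip = per_trip,
    track_source = track_source, season = season,
    season_shift_months = season_shift_months,
    reference_hours = reference_hours, speeds = speeds
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  kept <- x$per_trip[!x$per_trip$excluded, ]
  cat(sprintf(
    "<scenario_result> track: %s, season: %s (shift %+d mo), %d/%d trips\n",
    x$track_source, x$season, x$season_shift_months, nrow(kept),
    nrow(x$per_trip)))
  cat(sprintf("  duration %.1f h (ref %.1f h), median %% change %+.1f%%\n",
              mean(kept$duration_hours), x$reference_hours,
              median(kept$pct_change)))
  invisible(x)
}

#' Welch two-sample t-test between scenario durations
#'
#' Welch (unequal variance) t-test on the per-trip simulated durations of
#' two scenarios, with the Welch-Satterthwaite degrees of freedom and a
#' two-sided p-value.
#'
#' @param res_a,res_b `scenario_result`s (or numeric duration vectors).
#' @param value Column compared (default `duration_hours`).
#' @return One-row tibble: `t`, `df`, `p_value`, group means.
#' @export
compare_scenarios <- function(res_a, res_b, value = "duration_hours") {
  pick <- function(r) {
    if (inherits(r, "scenario_result")) r$per_trip[[value]][!r$per_trip$excluded]
    else as.numeric(r)
  }
  a <- pick(res_a); b <- pick(res_b)
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Quartile summary of % duration change per scenario
#'
#' @param results List of `scenario_result`s.
#' @return Tidy tibble with per-scenario min/quartiles/median/max of the
#'   per-trip % change in duration.
#' @export
duration_boxplot_table <- function(results) {
  if (inherits(results, "scenario_result")) results <- list(results)
  if (!length(results)) {
    abort("duration_boxplot_table(): no scenarios supplied.",
          class = "petrelwind_input_error")
  }
  map(results, function(r) {
    x <- r$per_trip$pct_change[!r$per_trip$excluded]
    if (!length(x)) {
      abort("duration_boxplot_table(): a scenario has no retained trips.",
            class = "petrelwind_input_error")
    }
    q <- quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    tibble(track_source = r$track_source, season = r$season,
           n_trips = length(x), min = q[1], q25 = q[2], median = q[3],
           q75 = q[4], max = q[5])
  }) |> list_rbind()
}

#' Run the full four-cell scenario grid for one focal species
#'
#' Cells: (own track, own season), (own, other), (other, own), (other,
#' other). The % change reference in every cell is the mean observed
#' transit duration of the focal species' real trips.
#'
#' @param own_steps,other_steps Decoded transit steps of the focal and the
#'   other species.
#' @param fit Focal species' wind model.
#' @param field Wind field.
#' @param season_shift_months Phenology gap applied in other-season cells
#'   (sign = direction the focal species' clock moves).
#' @return Named list of four `scenario_result`s
#'   (`own_own`, `own_other`, `other_own`, `other_other`).
#' @export
scenario_grid <- function(own_steps, other_steps, fit, field,
                          season_shift_months = 2) {
  ref <- own_steps |>
    group_by(.data$trip_id) |>
    summarise(h = sum(.data$step_km / .data$ground_speed), .groups = "drop")
  ref_h <- mean(ref$h)
  list(
    own_own = run_scenario(own_steps, fit, field, 0, ref_h,
                           track_source = "own", season = "own"),
    own_other = run_scenario(own_steps, fit, field, season_shift_months,
                             ref_h, track_source = "own", season = "other"),
    other_own = run_scenario(other_steps, fit, field, 0, ref_h,
                             track_source = "other", season = "own"),
    other_other = run_scenario(other_steps, fit, field, season_shift_months,
                               ref_h, track_source = "other", season = "other")
  )
}
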