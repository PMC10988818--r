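#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_boxplot geom_line
#'   geom_point geom_contour scale_fill_viridis_c labs theme_minimal
#'   facet_wrap geom_hline
#' @export
ggplot2::autoplot

#' Tidy a fitted movement HMM
#'
#' One row per parameter and state, broom-style.
#'
#' @param x An `hmm_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `state`, `estimate`.
#' @method tidy hmm_fit
#' @export
tidy.hmm_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = rep(c("step_mean", "step_sd", "turn_kappa", "tpm_stay"), each = 2),
    state = rep(c("transit", "search"), 4),
    estimate = c(p$step_mean, p$step_sd, p$turn_kappa, diag(p$tpm))
  )
}

#' @rdname tidy.hmm_fit
#' @method glance hmm_fit
#' @export
glance.hmm_fit <- function(x, ...) {
  tibble(log_lik = x$log_lik, n_obs = x$n_obs, n_tracks = x$n_tracks,
         pct_transit = 100 * mean(x$viterbi == 1),
         restart = x$convergence$restart,
         iterations = x$convergence$iterations)
}

#' Tidy a BRT habitat fit
#'
#' `tidy()` returns the relative variable importance; `glance()` the
#' one-row fit summary.
#'
#' @param x A `brt_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy brt_fit
#' @export
tidy.brt_fit <- function(x, ...) variable_importance(x)

#' @rdname tidy.brt_fit
#' @method glance brt_fit
#' @export
glance.brt_fit <- function(x, ...) {
  tibble(n_trees = x$n_trees, learning_rate = x$learning_rate,
         tree_complexity = x$tree_complexity, n_obs = x$n_obs,
         cv_auc_mean = mean(x$cv_auc, na.rm = TRUE),
         cv_auc_sd = sd(x$cv_auc, na.rm = TRUE),
         cv_deviance_mean = mean(x$cv_deviance))
}

#' Tidy a wind-speed GAM
#'
#' Delegates to the smooth-term summary of the underlying mgcv fit.
#'
#' @param x A `wind_gam_fit`.
#' @param ... Unused.
#' @return A tibble of smooth terms (`edf`, `F`, `p_value`).
#' @method tidy wind_gam_fit
#' @export
tidy.wind_gam_fit <- function(x, ...) {
  s <- summary(x$gam)$s.table
  tibble(term = rownames(s), edf = s[, "edf"], ref_df = s[, "Ref.df"],
         statistic = s[, 3], p_value = s[, 4])
}

#' @rdname tidy.wind_gam_fit
#' @method glance wind_gam_fit
#' @export
glance.wind_gam_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_tracks = x$n_tracks,
         deviance_explained = 1 - x$gam$deviance / x$gam$null.deviance,
         reml = as.numeric(x$gam$gcv.ubre), rho = x$rho,
         ar1 = x$ar1)
}

#' Tidy a scenario result
#'
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return The per-trip tibble with scenario labels.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  mutate(x$per_trip, track_source = x$track_source, season = x$season)
}

#' @rdname tidy.scenario_result
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  kept <- x$per_trip[!x$per_trip$excluded, ]
  tibble(track_source = x$track_source, season = x$season,
         n_trips = nrow(kept), n_excluded = sum(x$per_trip$excluded),
         mean_duration_hours = mean(kept$duration_hours),
         median_pct_change = median(kept$pct_change),
         reference_hours = x$reference_hours)
}

#' Plot a utilization distribution
#'
#' Density heatmap with the 50% and 75% contour sets outlined.
#'
#' @param object A `ud_grid`.
#' @param levels Contour levels drawn on top.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ud_grid
#' @export
autoplot.ud_grid <- function(object, levels = c(0.5, 0.75), ...) {
  df <- tidyr::expand_grid(lat = object$lat, lon = object$lon)
  idx <- cbind(match(df$lat, object$lat), match(df$lon, object$lon))
  df$density <- object$density[idx]
  for (lv in levels) {
    m <- ud_contour(object, lv)
    df[[paste0("in_", lv * 100)]] <- m[idx]
  }
  p <- ggplot(df, aes(.data$lon, .data$lat)) +
    geom_tile(aes(fill = .data$density)) +
    scale_fill_viridis_c() +
    labs(x = "Longitude", y = "Latitude", fill = "UD") +
    theme_minimal()
  for (lv in levels) {
    p <- p + geom_contour(aes(z = as.numeric(.data[[paste0("in_", lv * 100)]])),
                          breaks = 0.5, colour = "white",
                          linewidth = 0.3)
  }
  p
}

#' Plot a predicted ground-speed surface
#'
#' Heatmap of the wind model over the delta-angle x wind-intensity plane,
#' masked to the training hull.
#'
#' @param object A `wind_gam_fit`.
#' @param ... Passed to [surface_heatmap()].
#' @return A ggplot.
#' @method autoplot wind_gam_fit
#' @export
autoplot.wind_gam_fit <- function(object, ...) {
  sh <- surface_heatmap(object, ...)
  ggplot(sh, aes(.data$delta_angle, .data$wind_speed_kmh)) +
    geom_tile(aes(fill = .data$speed)) +
    scale_fill_viridis_c(na.value = "grey90") +
    labs(x = expression(Delta * "angle (deg, 0 = tailwind)"),
         y = "Wind intensity (km/h)", fill = "Ground\nspeed (km/h)") +
    theme_minimal()
}

#' Plot the scenario-grid duration changes
#'
#' Boxplot of the per-trip % change in transit duration for each (track,
#' season) scenario cell, relative to the observed mean duration.
#'
#' @param object A list of `scenario_result`s (e.g. from
#'   [scenario_grid()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_scenarios <- function(object, ...) {
  if (inherits(object, "scenario_result")) object <- list(object)
  df <- map(object, tidy) |> list_rbind() |> filter(!.data$excluded)
  df$cell <- paste(df$track_source, "track,", df$season, "season")
  ggplot(df, aes(.data$cell, .data$pct_change)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_boxplot() +
    labs(x = NULL, y = "% change in transit duration") +
    theme_minimal()
}

#' Plot daily activity against moonlight
#'
#' @param activity_days The `days` tibble from [daily_activity()].
#' @return A ggplot of daily wet fraction with moon illumination overlaid.
#' @export
plot_activity <- function(activity_days) {
  ggplot(activity_days, aes(.data$date, .data$wet_fraction)) +
    geom_point(alpha = 0.25, size = 0.6) +
    geom_line(aes(y = .data$moon_illumination), colour = "steelblue") +
    labs(x = NULL, y = "Daily wet fraction (points) / moon (line)") +
    theme_minimal()
}
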