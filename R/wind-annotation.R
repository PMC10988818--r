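#' Sample a wind field at arbitrary points
#'
#' Trilinear interpolation of the u and v components in (lon, lat, time).
#' Queries outside the grid hull raise a classed error
#' (`petrelwind_domain_error`).
#'
#' @param field A `wind_field`.
#' @param lon,lat Query coordinates, degrees (vectorised).
#' @param time Query times, POSIXct.
#' @return Tibble with columns `u`, `v` (m/s).
#' @export
sample_wind <- function(field, lon, lat, time) {
  stopifnot(inherits(field, "wind_field"))
  n <- max(length(lon), length(lat), length(time))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  time <- rep(lubridate::as_datetime(time, tz = "UTC"), length.out = n)
  tsec <- as.numeric(time)
  gl <- field$lon; ga <- field$lat
  gt <- as.numeric(field$time)
  eps <- 1e-9
  bad <- lon < gl[1] - eps | lon > tail(gl, 1) + eps |
    lat < ga[1] - eps | lat > tail(ga, 1) + eps |
    tsec < gt[1] - eps | tsec > tail(gt, 1) + eps
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "sample_wind(): point %d (%.3f, %.3f, %s) is outside the wind grid hull.",
      i, lon[i], lat[i], format(time[i])), class = "petrelwind_domain_error")
  }
  frac_idx <- function(x, grid) {
    f <- (x - grid[1]) / (grid[2] - grid[1])
    i0 <- pmin(pmax(floor(f), 0), length(grid) - 2)
    list(i0 = i0 + 1, w = pmin(pmax(f - i0, 0), 1))
  }
  ix <- frac_idx(lon, gl); iy <- frac_idx(lat, ga); it <- frac_idx(tsec, gt)
  tri <- function(arr) {
    out <- numeric(n)
    for (dt in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dt) it$w else 1 - it$w) *
        (if (dy) iy$w else 1 - iy$w) *
        (if (dx) ix$w else 1 - ix$w)
      out <- out + w * arr[cbind(it$i0 + dt, iy$i0 + dy, ix$i0 + dx)]
    }
    out
  }
  tibble(u = tri(field$u), v = tri(field$v))
}

#' Fold the movement/wind angle difference to `[0, 180]`
#'
#' The delta-angle is the smallest absolute angular difference between the
#' bird's direction of movement and the direction the wind blows toward:
#' 0 deg is a pure tailwind, 180 deg a pure headwind.
#'
#' @param bearing Movement bearing, degrees clockwise from north.
#' @param wind_to_direction Direction the wind blows toward, degrees.
#' @return Degrees in `[0, 180]`.
#' @export
delta_angle <- function(bearing, wind_to_direction) {
  abs(wrap180(wind_to_direction - bearing))
}

#' Signed tail-wind component
#'
#' The component of the wind speed along the bird's direction of movement:
#' `wind_speed * cos(delta_angle)`. Positive values are tailwinds, negative
#' headwinds; the magnitude never exceeds the wind speed.
#'
#' @param wind_speed Scalar wind speed (any unit; output in the same unit).
#' @param delta_angle Degrees in `[0, 180]` from [delta_angle()].
#' @return Signed component, same unit as `wind_speed`.
#' @export
tail_wind_component <- function(wind_speed, delta_angle) {
  wind_speed * cos(delta_angle * pi / 180)
}

#' Annotate track steps with movement and wind variables
#'
#' Converts consecutive positions into movement steps and attaches, per
#' step: great-circle length (km), ground speed (km/h), bearing, turning
#' angle (radians, NA for each trip's first step), interpolated wind speed
#' (m/s and km/h), the direction the wind blows toward, the delta-angle and
#' the signed tail-wind component (km/h). Wind is sampled at the step's
#' start position and time. Pure per-step function of the positions and the
#' field, so annotation is order-independent.
#'
#' @param tracks Regularised positions with `trip_id`, `timestamp`, `lon`,
#'   `lat` (and optional `bird_id`, `species`, `state_true`).
#' @param field A `wind_field`.
#' @param wind_convention `"to"` (default; direction wind blows toward) or
#'   `"from"` (meteorological) for the reported `wind_dir` column. The
#'   delta-angle/TWC always use the to-vector.
#' @return Tibble of steps (one row per step).
#' @export
annotate_steps <- function(tracks, field, wind_convention = c("to", "from")) {
  wind_convention <- match.arg(wind_convention)
  stopifnot_cols(tracks, c("trip_id", "timestamp", "lon", "lat"), "tracks")
  steps <- tracks |>
    group_by(.data$trip_id) |>
    arrange(.data$timestamp, .by_group = TRUE) |>
    mutate(
      lon2 = lead(.data$lon), lat2 = lead(.data$lat),
      t2 = lead(.data$timestamp)
    ) |>
    filter(!is.na(.data$lon2)) |>
    mutate(
      step_km = haversine_km(.data$lon, .data$lat, .data$lon2, .data$lat2),
      dt_h = as.numeric(difftime(.data$t2, .data$timestamp, units = "hours")),
      ground_speed = .data$step_km / .data$dt_h,
      bearing = step_bearing(.data$lon, .data$lat, .data$lon2, .data$lat2),
      turn_rad = wrap_pi((.data$bearing - lag(.data$bearing)) * pi / 180)
    ) |>
    ungroup()
  w <- sample_wind(field, steps$lon, steps$lat, steps$timestamp)
  steps$wind_u <- w$u
  steps$wind_v <- w$v
  steps$wind_speed_ms <- sqrt(w$u^2 + w$v^2)
  steps$wind_speed_kmh <- steps$wind_speed_ms * 3.6
  to_dir <- wrap360(atan2(w$u, w$v) * 180 / pi)
  steps$wind_dir <- if (wind_convention == "to") to_dir else wrap360(to_dir + 180)
  steps$delta_angle <- delta_angle(steps$bearing, to_dir)
  steps$twc_kmh <- tail_wind_component(steps$wind_speed_kmh, steps$delta_angle)
  # stationary positions have no bearing: delta-angle/TWC undefined there
  steps$delta_angle[is.na(steps$bearing)] <- NA_real_
  steps$twc_kmh[is.na(steps$bearing)] <- NA_real_
  dplyr::select(steps, -dplyr::any_of(c("lon2", "lat2", "t2")))
}
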