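#' Configure a synthetic study world
#'
#' Defines the geographic domain, colony location, land mask, seamounts and
#' sea-surface-temperature model shared by every generator in the package.
#' The world emulates a subtropical/temperate North-Atlantic-like basin with
#' a single small colony island: central-place trips depart from and return
#' to `colony`, pseudo-absences avoid the land cells, and the SST model is a
#' smooth latitudinal gradient with an annual cycle.
#'
#' All generators are pure functions of `(config, seed)`: the single
#' `rng_seed` is split deterministically into independent sub-streams (one
#' salt per generator), so any component can be re-generated in isolation
#' and identical configs yield bit-identical output.
#'
#' @param colony Length-2 numeric, colony `(lon, lat)` in degrees.
#' @param lon_range,lat_range Length-2 numeric domain bounds, degrees.
#' @param res_deg Spatial grid resolution in degrees.
#' @param res_hours Temporal resolution of gridded fields, hours.
#' @param time_origin `POSIXct`/string, start of the gridded time axis (UTC).
#' @param n_days Length of the gridded time axis in days.
#' @param island_radius_km Radius of the colony island. The colony island
#'   is land for habitat sampling, but counts as the coast for trips:
#'   departures and arrivals pass through it.
#' @param islands Matrix/data frame of additional islands (`lon`, `lat`,
#'   `radius_km`); trips must avoid these.
#' @param seamounts Two-column matrix or data frame of seamount `(lon, lat)`.
#' @param sst_mean,sst_lat_gradient,sst_seasonal_amp SST model: mean at the
#'   colony latitude (deg C), cooling per degree of latitude northwards, and
#'   amplitude of the annual cycle (peak in late summer).
#' @param rng_seed Integer master seed.
#' @return A `world_config` list.
#' @export
world_config <- function(colony = c(-16.9, 32.75),
                         lon_range = c(-60, -10),
                         lat_range = c(20, 55),
                         res_deg = 1,
                         res_hours = 6,
                         time_origin = "2019-01-01 00:00:00",
                         n_days = 365,
                         island_radius_km = 25,
                         islands = cbind(lon = -27.2, lat = 38.6,
                                         radius_km = 70),
                         seamounts = cbind(lon = c(-26, -32, -14.3),
                                           lat = c(36, 40, 33.1)),
                         sst_mean = 21,
                         sst_lat_gradient = 0.45,
                         sst_seasonal_amp = 2.5,
                         rng_seed = 1L) {
  if (res_deg <= 0 || res_hours <= 0 || n_days <= 0) {
    abort("world_config(): grid sizes must be positive.",
          class = "petrelwind_config_error")
  }
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0) {
    abort("world_config(): degenerate lon/lat range.",
          class = "petrelwind_config_error")
  }
  lon <- seq(lon_range[1], lon_range[2], by = res_deg)
  lat <- seq(lat_range[1], lat_range[2], by = res_deg)
  islands <- if (is.null(islands) || !NROW(islands)) {
    matrix(numeric(0), 0, 3, dimnames = list(NULL, c("lon", "lat", "radius_km")))
  } else as.matrix(as.data.frame(islands))
  land <- outer(lat, lon, function(la, lo) {
    hit <- haversine_km(lo, la, colony[1], colony[2]) <= island_radius_km
    for (k in seq_len(nrow(islands))) {
      hit <- hit | haversine_km(lo, la, islands[k, 1], islands[k, 2]) <=
        islands[k, 3]
    }
    hit
  })
  if (all(land)) {
    abort("world_config(): land mask covers the whole domain.",
          class = "petrelwind_config_error")
  }
  structure(list(
    colony = c(lon = colony[1], lat = colony[2]),
    island_radius_km = island_radius_km,
    islands = islands,
    lon = lon, lat = lat,
    res_deg = res_deg, res_hours = res_hours,
    time_origin = lubridate::as_datetime(time_origin, tz = "UTC"),
    n_days = n_days,
    land_mask = land,
    seamounts = as.matrix(as.data.frame(seamounts)),
    sst_mean = sst_mean,
    sst_lat_gradient = sst_lat_gradient,
    sst_seasonal_amp = sst_seasonal_amp,
    rng_seed = as.integer(rng_seed)
  ), class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config>\n")
  cat(sprintf("  domain : %g..%g E x %g..%g N @ %g deg / %g h\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat),
              x$res_deg, x$res_hours))
  cat(sprintf("  colony : (%.2f, %.2f); %d land cells; %d seamounts\n",
              x$colony[1], x$colony[2], sum(x$land_mask),
              nrow(x$seamounts)))
  cat(sprintf("  time   : %s + %d days; seed %d\n",
              format(x$time_origin, "%Y-%m-%d"), x$n_days, x$rng_seed))
  invisible(x)
}

# TRUE where (lon, lat) falls on land (geometric test against the colony
# island and any additional islands)
is_land <- function(config, lon, lat) {
  hit <- haversine_km(lon, lat, config$colony["lon"], config$colony["lat"]) <=
    config$island_radius_km
  for (k in seq_len(nrow(config$islands))) {
    hit <- hit | haversine_km(lon, lat, config$islands[k, 1],
                              config$islands[k, 2]) <= config$islands[k, 3]
  }
  hit
}

# land excluding the colony island: what a departing/arriving trip must avoid
is_land_offcolony <- function(config, lon, lat) {
  hit <- rep(FALSE, max(length(lon), length(lat)))
  for (k in seq_len(nrow(config$islands))) {
    hit <- hit | haversine_km(lon, lat, config$islands[k, 1],
                              config$islands[k, 2]) <= config$islands[k, 3]
  }
  hit
}

# smooth synthetic SST (deg C) at points and times
sst_at <- function(config, lon, lat, time) {
  doy <- lubridate::yday(time)
  config$sst_mean -
    config$sst_lat_gradient * (lat - config$colony["lat"]) +
    config$sst_seasonal_amp * sin(2 * pi * (doy - 50) / 365.25) +
    0.6 * sin(lon * pi / 18)
}

# smooth synthetic bathymetry (m, negative = depth) with seamount bumps
depth_at <- function(config, lon, lat) {
  base <- -4200 + 250 * sin(lat * pi / 15) * cos(lon * pi / 20)
  for (k in seq_len(nrow(config$seamounts))) {
    d <- haversine_km(lon, lat, config$seamounts[k, 1], config$seamounts[k, 2])
    base <- base + 3900 * exp(-(d / 60)^2 / 2)
  }
  pmin(base, -10)
}

#' Generate a smooth synthetic wind field
#'
#' Builds gridded eastward/northward 10-m wind components on the config's
#' lon x lat x time grid. The scalar speed field is a band-limited (few
#' low-order Fourier modes) spatial pattern around `mean_speed`, plus a
#' sinusoidal annual cycle of the given amplitude peaking in boreal winter
#' (mirroring the seasonal strengthening of North Atlantic winds between an
#' early and a late breeding season). Wind direction varies smoothly in
#' space and drifts slowly in time.
#'
#' @param config A [world_config()].
#' @param mean_speed Target domain-mean scalar wind speed, m/s.
#' @param seasonal_amplitude Amplitude of the annual speed cycle, m/s
#'   (monthly means span about twice this value).
#' @param n_modes Number of random spatial Fourier modes.
#' @return A `wind_field` object: strictly increasing `lon`, `lat`, regular
#'   `time`, and `u`, `v` arrays of dim `(time, lat, lon)` in m/s.
#' @export
make_windfield <- function(config, mean_speed = 8, seasonal_amplitude = 2,
                           n_modes = 4) {
  stopifnot(inherits(config, "world_config"))
  if (seasonal_amplitude < 0) {
    abort("make_windfield(): seasonal_amplitude must be >= 0.",
          class = "petrelwind_config_error")
  }
  if (mean_speed <= 0) {
    abort("make_windfield(): mean_speed must be positive.",
          class = "petrelwind_config_error")
  }
  lon <- config$lon; lat <- config$lat
  time <- seq(config$time_origin,
              by = config$res_hours * 3600,
              length.out = ceiling(config$n_days * 24 / config$res_hours))
  nt <- length(time); nla <- length(lat); nlo <- length(lon)

  with_subseed(config$rng_seed, salt = 11L, {
    # normalised coordinates in [0,1]
    xs <- (lon - min(lon)) / diff(range(lon))
    ys <- (lat - min(lat)) / diff(range(lat))
    rand_field <- function() {
      f <- matrix(0, nla, nlo)
      for (k in seq_len(n_modes)) {
        fx <- sample(1:2, 1); fy <- sample(1:2, 1)
        ph <- runif(2, 0, 2 * pi); a <- rnorm(1, 0, 1)
        f <- f + a * outer(sin(2 * pi * fy * ys + ph[1]),
                           sin(2 * pi * fx * xs + ph[2]))
      }
      f / max(1e-9, sd(f))
    }
    sp_pattern <- rand_field()          # spatial anomaly, unit sd
    dir_pattern <- rand_field()

    doy <- lubridate::yday(time) + lubridate::hour(time) / 24
    seasonal <- seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
    # with zero seasonal amplitude the field is exactly time-invariant
    dir_drift <- (seasonal_amplitude > 0) * 25 * sin(2 * pi * doy / 365.25 + 0.7)

    s0 <- mean_speed + 0.15 * mean_speed * sp_pattern
    s0 <- s0 - mean(s0) + mean_speed    # exact spatial mean
    dir0 <- 60 + 40 * dir_pattern       # mean flow towards ENE

    u <- array(0, c(nt, nla, nlo))
    v <- array(0, c(nt, nla, nlo))
    for (t in seq_len(nt)) {
      spd <- pmax(s0 + seasonal[t], 0.3)
      th <- (dir0 + dir_drift[t]) * pi / 180
      u[t, , ] <- spd * sin(th)
      v[t, , ] <- spd * cos(th)
    }
    structure(list(lon = lon, lat = lat, time = time, u = u, v = v,
                   res_deg = config$res_deg, res_hours = config$res_hours),
              class = "wind_field")
  })
}

#' @export
print.wind_field <- function(x, ...) {
  cat(sprintf("<wind_field> %d x %d x %d (time x lat x lon), %g deg / %g h\n",
              length(x$time), length(x$lat), length(x$lon),
              x$res_deg, x$res_hours))
  spd <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("  speed: mean %.2f m/s, range [%.2f, %.2f]\n",
              mean(spd), min(spd), max(spd)))
  invisible(x)
}

#' Ground-truth movement parameters for trip simulation
#'
#' Describes the two-state (1 = transit, 2 = search) switching process that
#' drives synthetic central-place trips: gamma step lengths, von Mises
#' turning angles (mean 0), and a 2x2 transition matrix. Transit is the
#' fast, persistent state (larger mean step, higher angular concentration).
#'
#' @param step_mean,step_sd Length-2 numeric, km per step, `(transit, search)`.
#' @param turn_kappa Length-2 von Mises concentrations `(transit, search)`.
#' @param tpm 2x2 transition probability matrix (rows sum to 1).
#' @param speed_wind_coef Coefficients `(a, b)` of the true log-speed law
#'   `speed = exp(a + b cos(delta_angle))` used by wind-aware generators.
#' @return A `trip_truth` list.
#' @export
trip_truth <- function(step_mean = c(30, 10), step_sd = c(10, 6),
                       turn_kappa = c(12, 0.8),
                       tpm = matrix(c(0.92, 0.08, 0.12, 0.88), 2, 2,
                                    byrow = TRUE),
                       speed_wind_coef = c(a = log(28), b = 0.25)) {
  stopifnot(length(step_mean) == 2, length(step_sd) == 2,
            all(step_mean > 0), all(step_sd > 0), all(turn_kappa >= 0),
            all(dim(tpm) == c(2, 2)),
            max(abs(rowSums(tpm) - 1)) < 1e-8, all(tpm >= 0))
  if (step_mean[1] <= step_mean[2]) {
    abort("trip_truth(): transit mean step must exceed search mean step.",
          class = "petrelwind_config_error")
  }
  structure(list(step_mean = step_mean, step_sd = step_sd,
                 turn_kappa = turn_kappa, tpm = tpm,
                 speed_wind_coef = speed_wind_coef),
            class = "trip_truth")
}

#' Simulate one central-place foraging trip
#'
#' Positions follow a two-state Markov switching process: the hidden state
#' selects a gamma step length and a von Mises turning angle applied to the
#' running heading. An adaptive homing bias rotates transit headings toward
#' the colony once `homing_start` of the trip has elapsed, strengthening as
#' the remaining steps become scarce, so trips depart from and return to the
#' colony; the final approach snaps to the colony once it is within one step.
#' Steps landing on a land cell are re-drawn (up to `max_retries`).
#'
#' @param config A [world_config()].
#' @param truth A [trip_truth()] (defines the generating parameters).
#' @param start_time POSIXct departure time (UTC).
#' @param n_steps Number of movement steps (>= 1, giving `n_steps + 1`
#'   positions).
#' @param resolution_hours Time step between positions.
#' @param trip_id,bird_id Identifiers stamped on the output.
#' @param homing_start Fraction of the trip after which homing begins.
#' @param start_state Optional initial state (1 = transit, 2 = search);
#'   default draws it uniformly.
#' @param max_retries Land-avoidance resampling budget per step.
#' @param seed Optional integer; defaults to the config seed so that
#'   identical `(config, trip_id)` pairs reproduce exactly.
#' @return A tibble with one row per position: `bird_id`, `trip_id`,
#'   `timestamp`, `lon`, `lat`, plus the true state (`state_true`, NA for
#'   the first position, which precedes any step) — the ground-truth
#'   sidecar for recovery tests. The trip ends when the bird regains the
#'   colony, so it may be shorter than `n_steps`.
#' @export
simulate_trip <- function(config, truth = trip_truth(),
                          start_time = config$time_origin + 150 * 86400,
                          n_steps = 200, resolution_hours = 1,
                          trip_id = "T1", bird_id = "B1",
                          homing_start = 0.5, start_state = NULL,
                          max_retries = 20, seed = NULL) {
  stopifnot(inherits(config, "world_config"), inherits(truth, "trip_truth"))
  if (n_steps < 1) {
    abort("simulate_trip(): n_steps must be >= 1.",
          class = "petrelwind_config_error")
  }
  seed <- seed %||% config$rng_seed
  salt <- 100L + sum(utf8ToInt(paste0(trip_id, bird_id))) %% 10000L
  with_subseed(seed, salt, {
    lon <- numeric(n_steps + 1); lat <- numeric(n_steps + 1)
    state <- integer(n_steps)
    lon[1] <- config$colony["lon"]; lat[1] <- config$colony["lat"]
    heading <- runif(1, 0, 360)
    s <- start_state %||% (if (runif(1) < 0.5) 1L else 2L)
    shape <- gamma_shape(truth$step_mean, truth$step_sd)
    rate <- gamma_rate(truth$step_mean, truth$step_sd)
    arrived_at <- NA_integer_
    for (t in seq_len(n_steps)) {
      if (t > 1) s <- sample(1:2, 1, prob = truth$tpm[s, ])
      state[t] <- s
      frac <- t / n_steps
      steps_left <- n_steps - t + 1
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        d <- rgamma(1, shape = shape[s], rate = rate[s])
        turn <- rvonmises(1, 0, truth$turn_kappa[s]) * 180 / pi
        h <- wrap360(heading + turn)
        if (frac >= homing_start) {
          # rotate toward colony; urgency grows as remaining travel budget
          # approaches the distance home
          to_col <- step_bearing(lon[t], lat[t], config$colony["lon"],
                                 config$colony["lat"])
          dist_home <- haversine_km(lon[t], lat[t], config$colony["lon"],
                                    config$colony["lat"])
          budget <- steps_left * truth$step_mean[1] *
            sum(c(0.6, 0.4) * c(1, truth$step_mean[2] / truth$step_mean[1]))
          w <- min(1, max(0.05, 1.6 * dist_home / max(budget, 1e-6)))
          if (!is.na(to_col)) h <- wrap360(h + w * wrap180(to_col - h))
          if (dist_home <= d) {
            # final approach: land at the colony and end the trip
            heading <- if (is.na(to_col)) heading else to_col
            lon[t + 1] <- unname(config$colony["lon"])
            lat[t + 1] <- unname(config$colony["lat"])
            arrived_at <- t
            ok <- TRUE
            break
          }
        }
        cand <- move_point(lon[t], lat[t], h, d)
        land_hit <- is_land_offcolony(config, cand$lon, cand$lat)
        out_of_domain <- cand$lon < min(config$lon) | cand$lon > max(config$lon) |
          cand$lat < min(config$lat) | cand$lat > max(config$lat)
        if (!land_hit && !out_of_domain) {
          heading <- h
          lon[t + 1] <- cand$lon; lat[t + 1] <- cand$lat
          ok <- TRUE
          break
        }
        # bias retries back toward the domain/sea
        heading <- wrap360(heading + runif(1, 90, 270))
      }
      if (!ok) {
        abort(sprintf(
          "simulate_trip(): step %d could not avoid land/domain edge within %d retries near (%.2f, %.2f).",
          t, max_retries, lon[t], lat[t]), class = "petrelwind_generation_error")
      }
      if (!is.na(arrived_at)) break
    }
    n_used <- if (is.na(arrived_at)) n_steps else arrived_at
    tibble(
      bird_id = bird_id, trip_id = trip_id,
      timestamp = start_time + (0:n_used) * resolution_hours * 3600,
      lon = lon[1:(n_used + 1)], lat = lat[1:(n_used + 1)],
      state_true = c(NA_integer_, state[1:n_used])
    )
  })
}

#' Simulate a fleet of trips for one species
#'
#' Convenience wrapper around [simulate_trip()] producing `n_trips`
#' independent trips with trip-level variation in length. Short trips
#' (smaller spatial scale and duration, emulating the near-colony movements
#' a trip classifier should discard) can be mixed in via `prop_short`.
#'
#' @inheritParams simulate_trip
#' @param n_trips Number of trips.
#' @param n_steps_mean Mean steps per long trip (Poisson-ish variation).
#' @param prop_short Proportion of short trips; short trips use ~1/8 the
#'   steps and ~1/3 the step lengths of long trips.
#' @param species Species label stamped on the output.
#' @param start_times Optional vector of departure times (recycled).
#' @return Tibble of positions for all trips, with `species` and a
#'   `trip_class_true` column (`"long"`/`"short"`).
#' @export
simulate_fleet <- function(config, truth = trip_truth(), n_trips = 10,
                           n_steps_mean = 200, prop_short = 0,
                           resolution_hours = 1, species = "A",
                           start_times = NULL, seed = NULL) {
  seed <- seed %||% config$rng_seed
  short_truth <- trip_truth(
    step_mean = truth$step_mean / 3, step_sd = truth$step_sd / 3,
    turn_kappa = truth$turn_kappa, tpm = truth$tpm,
    speed_wind_coef = truth$speed_wind_coef)
  with_subseed(seed, salt = 23L, {
    is_short <- runif(n_trips) < prop_short
    n_steps <- pmax(2, stats::rpois(n_trips, n_steps_mean))
    n_steps[is_short] <- pmax(2, stats::rpois(sum(is_short), n_steps_mean / 8))
    starts <- start_times %||%
      (config$time_origin + round(runif(n_trips, 120, 220)) * 86400)
    starts <- rep(lubridate::as_datetime(starts, tz = "UTC"),
                  length.out = n_trips)
    sub_seeds <- sample.int(1e6, n_trips)
    purrr::map(seq_len(n_trips), function(i) {
      tr <- simulate_trip(
        config, if (is_short[i]) short_truth else truth,
        start_time = starts[i], n_steps = n_steps[i],
        resolution_hours = resolution_hours,
        trip_id = sprintf("%s_T%02d", species, i),
        bird_id = sprintf("%s_B%02d", species, (i %% max(1, n_trips %/% 2)) + 1),
        seed = sub_seeds[i])
      tr$species <- species
      tr$trip_class_true <- if (is_short[i]) "short" else "long"
      tr
    }) |> list_rbind()
  })
}

#' Simulate a year of GLS-like locations and immersion data
#'
#' Emulates light-level geolocator output: one noisy position per day over a
#' full year plus a daily saltwater-immersion (wet) fraction. The latent
#' path stays near the colony during the breeding season and migrates to a
#' wintering centroid outside it; the wet fraction is lower during breeding
#' (birds fly more) than during non-breeding, and the non-breeding dry
#' (flight) fraction is modulated by moon illumination. Defaults calibrate
#' the breeding and non-breeding wet fractions to 0.30 and 0.51.
#'
#' @param config A [world_config()].
#' @param n_birds Number of birds.
#' @param error_sd_deg Gaussian location noise, degrees.
#' @param breeding_months Integer months of the breeding season.
#' @param wintering_centroid `(lon, lat)` of the non-breeding core.
#' @param breeding_wet,nonbreeding_wet Mean daily wet fractions by phase.
#' @param wet_sd Day-to-day s.d. of the wet fraction.
#' @param moon_amp Amplitude of the moonlight effect on non-breeding flight
#'   activity (wet fraction decreases when the moon is full).
#' @param colony_day_prob Probability a breeding-season day is spent at the
#'   nest (flagged `at_colony`, wet fraction ~ 0).
#' @param seed Optional integer seed (defaults to the config seed).
#' @return List of two tibbles: `locations` (`bird_id, timestamp, lon, lat`)
#'   and `immersion` (`bird_id, date, wet_fraction, at_colony, phase`).
#' @export
simulate_gls_year <- function(config, n_birds = 8, error_sd_deg = 0.5,
                              breeding_months = 4:10,
                              wintering_centroid = c(-35, 12),
                              breeding_wet = 0.30, nonbreeding_wet = 0.51,
                              wet_sd = 0.07, moon_amp = 0.10,
                              colony_day_prob = 0.25, seed = NULL) {
  stopifnot(inherits(config, "world_config"))
  if (error_sd_deg < 0) {
    abort("simulate_gls_year(): error_sd_deg must be >= 0.",
          class = "petrelwind_config_error")
  }
  seed <- seed %||% config$rng_seed
  days <- seq(lubridate::as_date(config$time_origin), by = "day",
              length.out = max(config$n_days, 365))
  breeding <- lubridate::month(days) %in% breeding_months
  moon <- moon_illumination(days)
  with_subseed(seed, salt = 37L, {
    out <- purrr::map(seq_len(n_birds), function(b) {
      # latent path: smooth pull between colony (breeding) and wintering core
      tgt_lon <- ifelse(breeding, config$colony["lon"], wintering_centroid[1])
      tgt_lat <- ifelse(breeding, config$colony["lat"], wintering_centroid[2])
      lon <- numeric(length(days)); lat <- numeric(length(days))
      lon[1] <- tgt_lon[1] + rnorm(1, 0, 1); lat[1] <- tgt_lat[1] + rnorm(1, 0, 1)
      for (t in 2:length(days)) {
        lon[t] <- lon[t - 1] + 0.12 * (tgt_lon[t] - lon[t - 1]) + rnorm(1, 0, 0.6)
        lat[t] <- lat[t - 1] + 0.12 * (tgt_lat[t] - lat[t - 1]) + rnorm(1, 0, 0.6)
      }
      obs_lon <- lon + rnorm(length(days), 0, error_sd_deg)
      obs_lat <- lat + rnorm(length(days), 0, error_sd_deg)
      at_colony <- breeding & runif(length(days)) < colony_day_prob
      wet <- ifelse(breeding, breeding_wet, nonbreeding_wet) +
        rnorm(length(days), 0, wet_sd)
      wet <- wet - (!breeding) * moon_amp * (moon - mean(moon[!breeding]))
      wet[at_colony] <- runif(sum(at_colony), 0, 0.03)
      wet <- pmin(pmax(wet, 0), 1)
      bid <- sprintf("GLS%02d", b)
      list(
        locations = tibble(bird_id = bid,
                           timestamp = lubridate::as_datetime(days) + 43200,
                           lon = obs_lon, lat = obs_lat),
        immersion = tibble(bird_id = bid, date = days, wet_fraction = wet,
                           at_colony = at_colony,
                           phase = if_else(breeding, "breeding", "non-breeding"))
      )
    })
    list(locations = list_rbind(map(out, "locations")),
         immersion = list_rbind(map(out, "immersion")))
  })
}

#' Simulate two-species stable-isotope samples
#'
#' Whole-blood delta13C / delta15N values drawn as additive species and year
#' effects plus Gaussian noise, emulating a two-species, two-year incubation
#' sampling design.
#'
#' @param n_per_group Samples per species x year cell (>= 2).
#' @param baseline Named numeric `c(d13C = ..., d15N = ...)`.
#' @param species_offsets Additive effect of the second species, per isotope.
#' @param year_offsets Additive effect of the second year, per isotope.
#' @param noise_sd Residual s.d. (single value or per-isotope length 2).
#' @param species,years Group labels.
#' @param seed Optional integer seed.
#' @return Tibble `species, year, d13C, d15N`.
#' @export
simulate_isotopes <- function(n_per_group = 25,
                              baseline = c(d13C = -20.5, d15N = 8.2),
                              species_offsets = c(d13C = 0.6, d15N = 0.8),
                              year_offsets = c(d13C = 0.0, d15N = 0.7),
                              noise_sd = 0.3,
                              species = c("zino", "deserta"),
                              years = c(2018L, 2019L),
                              seed = NULL) {
  if (n_per_group < 2) {
    abort("simulate_isotopes(): n_per_group must be >= 2.",
          class = "petrelwind_config_error")
  }
  noise_sd <- rep(noise_sd, length.out = 2)
  with_subseed(seed %||% 1L, salt = 53L, {
    grid <- tidyr::expand_grid(species = species, year = years)
    purrr::pmap(grid, function(species, year) {
      sp2 <- species != grid$species[[1]]
      yr2 <- year != grid$year[[1]]
      tibble(
        species = species, year = year,
        d13C = baseline["d13C"] + sp2 * species_offsets["d13C"] +
          yr2 * year_offsets["d13C"] + rnorm(n_per_group, 0, noise_sd[1]),
        d15N = baseline["d15N"] + sp2 * species_offsets["d15N"] +
          yr2 * year_offsets["d15N"] + rnorm(n_per_group, 0, noise_sd[2])
      )
    }) |> list_rbind()
  })
}

#' Read and write track tables
#'
#' Tracks are exchanged as plain CSV with columns `bird_id`, `trip_id`,
#' `timestamp` (ISO 8601 UTC), `lon`, `lat`; extra columns pass through.
#'
#' @param tracks Track tibble.
#' @param path File path.
#' @return `read_tracks_csv()` returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot_cols(tracks, c("bird_id", "trip_id", "timestamp", "lon", "lat"),
                 "tracks")
  out <- tracks
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot_cols(df, c("bird_id", "trip_id", "timestamp", "lon", "lat"),
                 "track file")
  df$timestamp <- lubridate::as_datetime(df$timestamp, tz = "UTC")
  df
}

#' Read and write wind fields
#'
#' Wind fields are serialized as long-format CSV (`time, lat, lon, u10,
#' v10`, m/s), a text encoding of the usual gridded (time, lat, lon) u/v
#' layout.
#'
#' @param field A `wind_field`.
#' @param path File path.
#' @return `read_windfield_csv()` returns a `wind_field`; the writer
#'   returns `path` invisibly.
#' @export
write_windfield_csv <- function(field, path) {
  stopifnot(inherits(field, "wind_field"))
  grid <- tidyr::expand_grid(time = field$time, lat = field$lat,
                             lon = field$lon)
  # fill by index arithmetic: expand_grid varies lon fastest, time slowest
  nt <- length(field$time); nla <- length(field$lat); nlo <- length(field$lon)
  ti <- rep(seq_len(nt), each = nla * nlo)
  lai <- rep(rep(seq_len(nla), each = nlo), times = nt)
  loi <- rep(seq_len(nlo), times = nt * nla)
  grid$u10 <- field$u[cbind(ti, lai, loi)]
  grid$v10 <- field$v[cbind(ti, lai, loi)]
  grid$time <- format(grid$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(grid, path)
  invisible(path)
}

#' @rdname write_windfield_csv
#' @export
read_windfield_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot_cols(df, c("time", "lat", "lon", "u10", "v10"), "wind file")
  time <- sort(unique(lubridate::as_datetime(df$time, tz = "UTC")))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  df$time <- lubridate::as_datetime(df$time, tz = "UTC")
  ti <- match(df$time, time); lai <- match(df$lat, lat)
  loi <- match(df$lon, lon)
  u <- array(NA_real_, c(length(time), length(lat), length(lon)))
  v <- u
  u[cbind(ti, lai, loi)] <- df$u10
  v[cbind(ti, lai, loi)] <- df$v10
  if (anyNA(u) || anyNA(v)) {
    abort("read_windfield_csv(): incomplete grid in wind file.",
          class = "petrelwind_input_error")
  }
  structure(list(lon = lon, lat = lat, time = time, u = u, v = v,
                 res_deg = if (length(lon) > 1) diff(lon[1:2]) else NA_real_,
                 res_hours = if (length(time) > 1)
                   as.numeric(difftime(time[2], time[1], units = "hours"))
                 else NA_real_),
            class = "wind_field")
}

#' Write a ground-truth sidecar
#'
#' Serializes the generating parameters of a synthetic dataset (a
#' [trip_truth()] plus free-form extras) as JSON next to the data.
#'
#' @param truth A [trip_truth()] or plain list.
#' @param path Output path.
#' @param ... Extra named fields to record.
#' @export
write_truth_json <- function(truth, path, ...) {
  x <- c(unclass(truth), list(...))
  x <- purrr::map(x, function(v) if (is.matrix(v)) as.data.frame(v) else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
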