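# Small shared fixtures, built in code. Helpers are deliberately cheap so
# each test file can rebuild them.

tiny_world <- function(seed = 1L, n_days = 170) {
  world_config(lon_range = c(-40, -5), lat_range = c(22, 48),
               res_deg = 1, res_hours = 6, n_days = n_days,
               rng_seed = seed)
}

tiny_field <- function(config = tiny_world(), mean_speed = 8,
                       seasonal_amplitude = 0) {
  make_windfield(config, mean_speed = mean_speed,
                 seasonal_amplitude = seasonal_amplitude)
}

# a flat, constant wind field built by hand: u eastward everywhere
const_field <- function(u = 5, v = 0, n_time = 4) {
  structure(list(
    lon = seq(-40, -5, by = 1), lat = seq(22, 48, by = 1),
    time = seq(lubridate::as_datetime("2019-06-01", tz = "UTC"),
               by = 6 * 3600, length.out = n_time),
    u = array(u, c(n_time, 27, 36)), v = array(v, c(n_time, 27, 36)),
    res_deg = 1, res_hours = 6
  ), class = "wind_field")
}

# deterministic straight-line hourly track heading due east along a parallel
straight_track <- function(n = 11, lat = 30, lon0 = -30, speed_kmh = 20,
                           t0 = "2019-06-05 00:00:00") {
  km_per_deg_lon <- 111.1949 * cos(lat * pi / 180)
  tibble::tibble(
    bird_id = "B1", trip_id = "T1",
    timestamp = lubridate::as_datetime(t0, tz = "UTC") + (0:(n - 1)) * 3600,
    lon = lon0 + (0:(n - 1)) * speed_kmh / km_per_deg_lon,
    lat = lat
  )
}
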