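test_that("wind fields are finite, deterministic and hit the target mean", {
  wc <- tiny_world(n_days = 365)
  f1 <- make_windfield(wc, mean_speed = 8, seasonal_amplitude = 2)
  f2 <- make_windfield(wc, mean_speed = 8, seasonal_amplitude = 2)
  expect_identical(f1$u, f2$u)
  expect_identical(f1$v, f2$v)
  expect_true(all(is.finite(f1$u)), all(is.finite(f1$v)))
  expect_true(all(diff(f1$lon) > 0), all(diff(f1$lat) > 0))
  spd <- sqrt(f1$u^2 + f1$v^2)
  expect_lt(abs(mean(spd) - 8) / 8, 0.05)
})

test_that("zero seasonal amplitude gives equal monthly means; amplitude 3 a 4-8 m/s annual swing", {
  wc <- tiny_world(n_days = 365)
  monthly_means <- function(field) {
    spd <- sqrt(field$u^2 + field$v^2)
    per_t <- apply(spd, 1, mean)
    tapply(per_t, lubridate::month(field$time), mean)
  }
  m0 <- monthly_means(make_windfield(wc, 8, seasonal_amplitude = 0))
  expect_lt((max(m0) - min(m0)) / mean(m0), 0.01)
  # oracle: direct monthly averaging of the generated arrays
  m3 <- monthly_means(make_windfield(wc, 8, seasonal_amplitude = 3))
  expect_gte(max(m3) - min(m3), 4)
  expect_lte(max(m3) - min(m3), 8)
})

test_that("wind field configuration errors are raised", {
  expect_error(world_config(res_deg = -1), class = "petrelwind_config_error")
  expect_error(world_config(lon_range = c(0, 0)),
               class = "petrelwind_config_error")
  expect_error(make_windfield(tiny_world(), seasonal_amplitude = -1),
               class = "petrelwind_config_error")
})

test_that("trips follow the two-state switching process with correct moments", {
  wc <- tiny_world()
  truth <- trip_truth(step_mean = c(30, 10), step_sd = c(10, 6))
  tr <- simulate_trip(wc, truth, n_steps = 500, seed = 42,
                      homing_start = 0.6)
  d <- haversine_km(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)],
                    tr$lon[-1], tr$lat[-1])
  s <- tr$state_true[-1]
  # oracle: group by true state and average
  m <- tapply(d, s, mean)
  expect_lt(abs(m[["1"]] - 30) / 30, 0.10)
  expect_lt(abs(m[["2"]] - 10) / 10, 0.10)
  expect_gt(m[["1"]], m[["2"]])
})

test_that("trips depart from and return to the colony and avoid land", {
  wc <- tiny_world()
  for (s in 1:5) {
    tr <- simulate_trip(wc, trip_truth(), n_steps = 150, seed = s)
    expect_equal(tr$lon[1], unname(wc$colony["lon"]))
    expect_lt(haversine_km(tr$lon[nrow(tr)], tr$lat[nrow(tr)],
                           wc$colony["lon"], wc$colony["lat"]),
              wc$res_deg * 111.1949)
    # no point on non-colony land (the colony island is the coast)
    mid <- tr[-c(1, nrow(tr)), ]
    expect_false(any(petrelwind:::is_land_offcolony(wc, mid$lon, mid$lat)))
  }
})

test_that("identity transition matrix freezes the state; degenerate trips work", {
  wc <- tiny_world()
  truth <- trip_truth(tpm = matrix(c(1, 0, 0, 1), 2, 2))
  tr <- simulate_trip(wc, truth, n_steps = 60, seed = 3, start_state = 1L,
                      homing_start = 0.7)
  expect_true(all(tr$state_true[-1] == 1L))
  tr2 <- simulate_trip(wc, trip_truth(), n_steps = 2, seed = 4)
  expect_lte(nrow(tr2), 3)
  expect_gte(nrow(tr2), 2)
  expect_lt(haversine_km(tr2$lon[nrow(tr2)], tr2$lat[nrow(tr2)],
                         wc$colony["lon"], wc$colony["lat"]), 150)
  expect_error(simulate_trip(wc, trip_truth(), n_steps = 0),
               class = "petrelwind_config_error")
})

test_that("trip generation is reproducible and fails loudly when trapped", {
  wc <- tiny_world()
  t1 <- simulate_trip(wc, trip_truth(), n_steps = 100, seed = 9)
  t2 <- simulate_trip(wc, trip_truth(), n_steps = 100, seed = 9)
  expect_identical(t1, t2)
  # a colony ringed closely by land leaves no escape within the budget
  trapped <- world_config(islands = cbind(
    lon = c(-16.4, -17.4, -16.9, -16.9), lat = c(32.75, 32.75, 33.2, 32.3),
    radius_km = 40), island_radius_km = 5)
  expect_error(simulate_trip(trapped, trip_truth(step_mean = c(30, 10),
                                                 step_sd = c(2, 1)),
                             n_steps = 50, seed = 1),
               class = "petrelwind_generation_error")
})

test_that("GLS year generator calibrates phase wet fractions and is reproducible", {
  wc <- tiny_world(n_days = 365)
  g1 <- simulate_gls_year(wc, n_birds = 2, seed = 5)
  g2 <- simulate_gls_year(wc, n_birds = 2, seed = 5)
  expect_identical(g1, g2)
  imm <- g1$immersion
  expect_true(all(imm$wet_fraction >= 0 & imm$wet_fraction <= 1))
  at_sea <- imm[!imm$at_colony, ]
  mb <- mean(at_sea$wet_fraction[at_sea$phase == "breeding"])
  mn <- mean(at_sea$wet_fraction[at_sea$phase == "non-breeding"])
  expect_lt(abs(mb - 0.30), 0.03)
  expect_lt(abs(mn - 0.51), 0.03)
  expect_gte(min(as.numeric(diff(range(imm$date)))), 364)
})

test_that("GLS location noise has the configured scale", {
  wc <- tiny_world(n_days = 365)
  g0 <- simulate_gls_year(wc, n_birds = 1, error_sd_deg = 0, seed = 11)
  g5 <- simulate_gls_year(wc, n_birds = 1, error_sd_deg = 0.5, seed = 11)
  # same latent path, different measurement noise: the difference is the
  # noise itself
  dd <- g5$locations$lon - g0$locations$lon
  expect_lt(abs(sd(dd) - 0.5), 0.08)
  expect_error(simulate_gls_year(wc, error_sd_deg = -1),
               class = "petrelwind_config_error")
})

test_that("isotope generator reproduces its offsets", {
  iso0 <- simulate_isotopes(n_per_group = 5, noise_sd = 0,
                            species_offsets = c(d13C = 0, d15N = 0),
                            year_offsets = c(d13C = 0, d15N = 0), seed = 1)
  expect_equal(length(unique(round(iso0$d15N, 12))), 1)
  # noiseless offsets are recovered exactly by group-mean differences
  iso1 <- simulate_isotopes(n_per_group = 10, noise_sd = 0,
                            species_offsets = c(d13C = 0.4, d15N = 1.2),
                            year_offsets = c(d13C = 0.1, d15N = 0.5),
                            seed = 1)
  sp_diff <- mean(iso1$d15N[iso1$species == "deserta"]) -
    mean(iso1$d15N[iso1$species == "zino"])
  expect_equal(sp_diff, 1.2, tolerance = 1e-12)
  # with noise 0.3 at n = 25 the offset comes back within +-0.2
  iso2 <- simulate_isotopes(n_per_group = 25, noise_sd = 0.3,
                            species_offsets = c(d13C = 0, d15N = 1.0),
                            year_offsets = c(d13C = 0, d15N = 0), seed = 7)
  est <- mean(iso2$d15N[iso2$species == "deserta"]) -
    mean(iso2$d15N[iso2$species == "zino"])
  expect_lt(abs(est - 1.0), 0.2)
  expect_error(simulate_isotopes(n_per_group = 1),
               class = "petrelwind_config_error")
})

test_that("track and wind CSV round trips preserve the data", {
  wc <- tiny_world(n_days = 4)
  tr <- simulate_trip(wc, trip_truth(), n_steps = 20, seed = 2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(tr, p)
  back <- read_tracks_csv(p)
  expect_equal(back$lon, tr$lon, tolerance = 1e-9)
  expect_equal(back$timestamp, tr$timestamp)
  f <- tiny_field(wc)
  pw <- withr::local_tempfile(fileext = ".csv")
  write_windfield_csv(f, pw)
  fb <- read_windfield_csv(pw)
  expect_equal(fb$u, f$u, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fb$time, f$time)
  pt <- withr::local_tempfile(fileext = ".json")
  write_truth_json(trip_truth(), pt, species = "A")
  expect_true(jsonlite::validate(paste(readLines(pt), collapse = "")))
})
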