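test_that("interpolation is exact on regular input and linear between fixes", {
  tr <- straight_track(n = 6)
  out <- interpolate_track(tr, 1)
  expect_equal(out$lon, tr$lon)
  expect_equal(attr(out, "imputed_fraction"), 0)
  expect_false(any(out$imputed))
  # two fixes 2 h apart, 1 h output: midpoint at the linear midpoint
  raw <- tibble::tibble(
    timestamp = lubridate::as_datetime("2019-06-01", tz = "UTC") +
      c(0, 2) * 3600,
    lon = c(0, 2), lat = c(10, 10))
  out2 <- interpolate_track(raw, 1)
  expect_equal(out2$lon, c(0, 1, 2))
  expect_equal(out2$imputed, c(FALSE, TRUE, FALSE))
})

test_that("deleted fixes are imputed close to the truth and counted", {
  wc <- tiny_world()
  full <- simulate_trip(wc, trip_truth(), n_steps = 200, seed = 6)
  n <- nrow(full)
  withr::with_seed(1, {
    drop <- sort(sample(2:(n - 1), round(0.05 * n)))
  })
  out <- interpolate_track(full[-drop, ], 1)
  expect_equal(nrow(out), n)
  expect_equal(mean(out$imputed), length(drop) / n, tolerance = 0.01)
  # oracle: compare imputed positions to the pre-deletion track
  err_km <- haversine_km(out$lon[drop], out$lat[drop],
                         full$lon[drop], full$lat[drop])
  expect_lt(max(err_km), 30) # within one transit step of the truth
  expect_lt(median(err_km), 15)
})

test_that("interpolation rejects large gaps and never extrapolates", {
  raw <- straight_track(n = 30)[-(5:25), ]
  expect_error(interpolate_track(raw, 1), class = "petrelwind_gap_error")
  raw2 <- straight_track(n = 5)
  raw2$timestamp <- raw2$timestamp + 1800 # offset off the hour grid
  out <- interpolate_track(raw2, 1)
  expect_gte(min(out$timestamp), min(raw2$timestamp))
  expect_lte(max(out$timestamp), max(raw2$timestamp))
  expect_error(interpolate_track(raw2[1, ], 1),
               class = "petrelwind_input_error")
  expect_error(interpolate_track(raw2, 3), class = "petrelwind_config_error")
})

test_that("2 h resampling thins correctly and is guarded", {
  tr <- interpolate_track(straight_track(n = 11), 1)
  out <- resample_to_2h(tr)
  expect_equal(nrow(out), 6)
  expect_equal(attr(out, "resolution_hours"), 2)
  expect_error(resample_to_2h(out), class = "petrelwind_config_error")
  # straight-line motion: each output step is the sum of two input steps
  st1 <- haversine_km(tr$lon[-1], tr$lat[-1],
                      tr$lon[-nrow(tr)], tr$lat[-nrow(tr)])
  st2 <- haversine_km(out$lon[-1], out$lat[-1],
                      out$lon[-nrow(out)], out$lat[-nrow(out)])
  expect_equal(st2, st1[c(TRUE, FALSE)] + st1[c(FALSE, TRUE)],
               tolerance = 1e-6)
})

test_that("trip summaries use the 6371-km sphere", {
  # closed form: 1 degree of latitude = 111.19 km
  expect_equal(haversine_km(0, 0, 0, 1), pi * 6371 / 180, tolerance = 1e-6)
  expect_equal(round(haversine_km(0, 0, 0, 1), 2), 111.19)
  tr <- tibble::tibble(
    trip_id = "t", bird_id = "b",
    timestamp = lubridate::as_datetime("2019-06-01", tz = "UTC") +
      (0:2) * 3600,
    lon = c(0, 0, 0), lat = c(0, 1, 2))
  s <- trip_summaries(tr, colony = c(0, 0))
  expect_equal(s$cumulative_km, 2 * haversine_km(0, 0, 0, 1))
  expect_equal(s$max_colony_km, haversine_km(0, 0, 0, 2))
  expect_equal(s$duration_days, 2 / 24)
})

test_that("k-means trip classification matches the exhaustive 2-partition oracle", {
  stats <- tibble::tibble(
    trip_id = c("a", "b", "c", "d"),
    max_colony_km = c(2000, 2100, 60, 80),
    duration_days = c(11, 13, 1, 1.5))
  # oracle: exhaustive 2-partition minimising within-cluster SS on the
  # standardized features
  Z <- scale(cbind(stats$max_colony_km, stats$duration_days))
  best <- NULL; best_ss <- Inf
  for (m in 1:(2^4 - 2)) {
    g <- as.logical(bitwAnd(m, 2^(0:3)))
    if (!any(g) || all(g)) next
    ss <- sum(scale(Z[g, , drop = FALSE], scale = FALSE)^2) +
      sum(scale(Z[!g, , drop = FALSE], scale = FALSE)^2)
    if (ss < best_ss) { best_ss <- ss; best <- g }
  }
  cls <- classify_trips(stats, seed = 1)
  expect_setequal(cls$trip_id[cls$trip_class == "long"],
                  stats$trip_id[if (best[1]) best else !best])
  expect_equal(cls$trip_class, c("long", "long", "short", "short"))
  # reproducible under a fixed seed
  expect_identical(cls$trip_class, classify_trips(stats, seed = 1)$trip_class)
})

test_that("classification is invariant to positive rescaling of features", {
  stats <- tibble::tibble(
    trip_id = sprintf("t%d", 1:6),
    max_colony_km = c(1800, 2200, 1900, 70, 90, 120),
    duration_days = c(10, 12, 9, 1, 2, 1.5))
  base <- classify_trips(stats, seed = 2)$trip_class
  scaled <- stats
  scaled$max_colony_km <- scaled$max_colony_km * 1000
  scaled$duration_days <- scaled$duration_days * 0.01
  expect_identical(classify_trips(scaled, seed = 2)$trip_class, base)
  dup <- stats[rep(1, 4), ]
  dup$trip_id <- sprintf("d%d", 1:4)
  expect_error(classify_trips(dup), class = "petrelwind_degenerate_error")
  expect_error(classify_trips(stats[1, ]), class = "petrelwind_input_error")
})

test_that("filter_long retains long trips and accounts for removed time", {
  stats <- tibble::tibble(
    trip_id = c("L1", "L2", "S1"),
    bird_id = "b", species = "A", n_points = 10,
    duration_days = c(10, 12, 1),
    cumulative_km = c(5000, 6000, 100),
    max_colony_km = c(2000, 2100, 50),
    imputed_fraction = 0,
    trip_class = c("long", "long", "short"))
  tracks <- tibble::tibble(trip_id = rep(c("L1", "L2", "S1"), each = 3),
                           lon = 0, lat = 0,
                           timestamp = lubridate::now())
  out <- suppressMessages(filter_long(tracks, stats))
  expect_setequal(unique(out$trip_id), c("L1", "L2"))
  # oracle: direct computation of the removed time share
  expect_equal(attr(out, "time_removed_fraction"), 1 / 23)
  all_long <- stats; all_long$trip_class <- "long"
  expect_equal(nrow(suppressMessages(filter_long(tracks, all_long))),
               nrow(tracks))
  none <- stats; none$trip_class <- "short"
  expect_warning(out0 <- filter_long(tracks, none))
  expect_equal(nrow(out0), 0)
})

test_that("split_trips cuts a track at the colony radius", {
  colony <- c(-17, 32.75)
  mk <- function(dists_km) {
    tibble::tibble(
      bird_id = "b",
      timestamp = lubridate::as_datetime("2019-06-01", tz = "UTC") +
        seq_along(dists_km) * 3600,
      lon = colony[1], lat = colony[2] + dists_km / 111.1949)
  }
  track <- mk(c(0, 2, 50, 120, 60, 3, 1, 80, 150, 2))
  out <- split_trips(track, colony, radius_km = 5)
  expect_equal(length(unique(out$trip_id)), 2)
  expect_equal(sum(out$trip_id == "b_S1"), 5) # bracketed by inside fixes
})
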