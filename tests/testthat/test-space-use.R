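test_that("locations map to the fixed two-month window cycle", {
  locs <- tibble::tibble(
    timestamp = lubridate::as_datetime(c("2019-09-15", "2020-01-10",
                                         "2019-12-31", "2019-07-04"),
                                       tz = "UTC"))
  w <- seasonal_windows(locs)$window
  expect_equal(as.character(w), c("Sep-Oct", "Jan-Feb", "Nov-Dec",
                                  "Jul-Aug"))
  # a uniform year of daily points splits roughly 1/6 per window
  yr <- tibble::tibble(timestamp = lubridate::as_datetime("2019-01-01",
                                                          tz = "UTC") +
                         (0:364) * 86400)
  tab <- table(seasonal_windows(yr)$window)
  expect_equal(length(tab), 6)
  expect_true(all(abs(tab / 365 - 1 / 6) < 0.01))
})

test_that("kernel UDs normalize to one and peak at the data", {
  pt <- tibble::tibble(lon = -25.05, lat = 38.02)
  ud <- kernel_ud(pt, h_deg = 2.25, grid_res = 0.25)
  expect_equal(sum(ud$density), 1, tolerance = 1e-9)
  peak <- which(ud$density == max(ud$density), arr.ind = TRUE)
  expect_lt(abs(ud$lat[peak[1]] - pt$lat), 0.25)
  expect_lt(abs(ud$lon[peak[2]] - pt$lon), 0.25)
  expect_error(kernel_ud(pt[0, ]), class = "petrelwind_input_error")
})

test_that("the mean UD across individuals weights birds equally", {
  pts <- tibble::tibble(bird_id = c("a", "b"),
                        lon = c(-30, -18), lat = c(30, 42))
  ud <- mean_ud(pts, h_deg = 1, grid_res = 0.25,
                lon_range = c(-36, -12), lat_range = c(25, 47))
  expect_equal(sum(ud$density), 1, tolerance = 1e-9)
  expect_equal(ud$n_individuals, 2L)
  # two equal, well-separated modes: the two point cells carry equal mass
  d_a <- ud$density[which.min(abs(ud$lat - 30)), which.min(abs(ud$lon + 30))]
  d_b <- ud$density[which.min(abs(ud$lat - 42)), which.min(abs(ud$lon + 18))]
  expect_equal(d_a, d_b, tolerance = 1e-6)
})

test_that("contours are the smallest cell sets reaching the level", {
  # uniform density over 100 cells: the 50% set has exactly 50 cells
  ud <- structure(list(density = matrix(1 / 100, 10, 10),
                       lon = seq(0, 2.25, by = 0.25),
                       lat = seq(0, 2.25, by = 0.25),
                       h_deg = 1, grid_res = 0.25, n_points = 1,
                       n_individuals = 1L), class = "ud_grid")
  expect_equal(sum(ud_contour(ud, 0.5)), 50)
  # a delta UD needs one cell at any level
  ud2 <- ud
  ud2$density <- matrix(0, 10, 10); ud2$density[4, 7] <- 1
  expect_equal(sum(ud_contour(ud2, 0.5)), 1)
  expect_equal(sum(ud_contour(ud2, 0.75)), 1)
  # nesting: the 50% set is inside the 75% set
  wc <- tiny_world()
  g <- simulate_gls_year(wc, n_birds = 3, seed = 2)
  ud3 <- mean_ud(g$locations, grid_res = 0.5)
  m50 <- ud_contour(ud3, 0.50); m75 <- ud_contour(ud3, 0.75)
  expect_true(all(m75[m50]))
  expect_gte(attr(m50, "mass"), 0.50)
  expect_gte(attr(m75, "mass"), 0.75)
})

test_that("the 50% contour captures half the mass of a Gaussian sample", {
  withr::with_seed(7, {
    pts <- tibble::tibble(lon = rnorm(10000, -25, 3),
                          lat = rnorm(10000, 38, 3))
  })
  ud <- kernel_ud(pts, h_deg = 0.5, grid_res = 0.25)
  m <- ud_contour(ud, 0.5)
  # Monte-Carlo oracle: fraction of fresh draws falling inside the contour
  withr::with_seed(8, {
    new <- tibble::tibble(lon = rnorm(10000, -25, 3),
                          lat = rnorm(10000, 38, 3))
  })
  i <- round((new$lat - ud$lat[1]) / 0.25) + 1
  j <- round((new$lon - ud$lon[1]) / 0.25) + 1
  ok <- i >= 1 & i <= length(ud$lat) & j >= 1 & j <= length(ud$lon)
  inside <- m[cbind(i[ok], j[ok])]
  expect_gte(mean(inside), 0.48)
  expect_lte(mean(inside), 0.56)
  expect_equal(attr(m, "mass"), 0.5, tolerance = 0.01)
})

test_that("directed overlap behaves on identical, disjoint and nested cores", {
  pts <- tibble::tibble(bird_id = "a", lon = rnorm(50, -25, 1),
                        lat = rnorm(50, 38, 1))
  withr::with_seed(1, pts <- pts)
  rng <- list(lon = c(-40, -10), lat = c(28, 48))
  ud <- mean_ud(pts, h_deg = 1, grid_res = 0.5, rng$lon, rng$lat)
  ov <- ud_overlap(ud, ud, 0.5)
  expect_equal(ov$prop_a_in_b, 1)
  expect_equal(ov$prop_b_in_a, 1)
  pts2 <- dplyr::mutate(pts, lon = lon + 12)
  ud2 <- mean_ud(pts2, h_deg = 1, grid_res = 0.5, rng$lon, rng$lat)
  ov2 <- ud_overlap(ud, ud2, 0.5)
  expect_equal(ov2$prop_a_in_b, 0)
  expect_equal(ov2$prop_b_in_a, 0)
  expect_error(ud_overlap(ud, mean_ud(pts2, h_deg = 1, grid_res = 0.5,
                                      c(-41, -10), rng$lat)),
               class = "petrelwind_input_error")
})

test_that("overlap proportions follow constructed masks exactly", {
  # A's core strictly inside half of B's core: A-in-B = 1, B-in-A = 0.5.
  # Rows 5 and 6 sit at +-0.25 deg latitude, so their cos(lat) cell areas
  # are identical and the cell-count oracle applies exactly.
  lats <- seq(-2.25, 2.25, by = 0.5)
  mk_ud <- function(cells) {
    d <- matrix(0, 10, 10)
    d[cells] <- 1 / nrow(cells)
    structure(list(density = d, lon = seq(0, 4.5, 0.5), lat = lats,
                   h_deg = 1, grid_res = 0.5, n_points = nrow(cells),
                   n_individuals = 1L), class = "ud_grid")
  }
  udA <- mk_ud(cbind(5, 1:10))
  udB <- mk_ud(rbind(cbind(5, 1:10), cbind(6, 1:10)))
  ov <- ud_overlap(udA, udB, 0.999)
  expect_equal(ov$prop_a_in_b, 1, tolerance = 1e-9)
  expect_equal(ov$prop_b_in_a, 0.5, tolerance = 1e-9)
})

test_that("phenology synchronisation shifts calendar months with clamping", {
  locs <- tibble::tibble(timestamp = lubridate::as_datetime(
    c("2019-03-15 12:00:00", "2019-12-31 06:00:00"), tz = "UTC"))
  sh <- synchronize_phenology(locs, 2)
  expect_equal(lubridate::month(sh$timestamp), c(5, 2))
  expect_equal(lubridate::day(sh$timestamp), c(15, 29)) # clamped (2020 leap)
  expect_equal(lubridate::hour(sh$timestamp), c(12, 6))
  # shifting a uniform year leaves window occupancies unchanged
  yr <- tibble::tibble(timestamp = lubridate::as_datetime("2019-01-15",
                                                          tz = "UTC") +
                         30.4375 * 86400 * (0:11))
  t1 <- table(seasonal_windows(yr)$window)
  t2 <- table(seasonal_windows(synchronize_phenology(yr, 2))$window)
  expect_equal(as.numeric(t1), as.numeric(t2))
})

test_that("synchronising an allochronic fleet increases spatial overlap", {
  wc <- tiny_world(n_days = 365)
  # species B's whole phenology lags species A by two months, with the
  # same spatial programme otherwise
  a <- simulate_gls_year(wc, n_birds = 4, breeding_months = 4:10, seed = 21)
  b <- simulate_gls_year(wc, n_birds = 4,
                         breeding_months = (c(4:10 + 2 - 1) %% 12) + 1,
                         seed = 22)
  obs <- overlap_by_window(a$locations, b$locations, grid_res = 0.5)
  syn <- overlap_by_window(a$locations, b$locations, grid_res = 0.5,
                           scenario = "synchronized", shift_months = 2)
  o <- obs[obs$window == "average", ]
  s <- syn[syn$window == "average", ]
  expect_gte(s$prop_a_in_b, o$prop_a_in_b)
  expect_true(all(obs$prop_a_in_b >= 0 & obs$prop_a_in_b <= 1))
  expect_true(all(obs$prop_b_in_a >= 0 & obs$prop_b_in_a <= 1))
})
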