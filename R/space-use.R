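#' Assign locations to two-month seasonal windows
#'
#' The fixed annual cycle of six windows starts with September-October and
#' ends with July-August; each calendar month belongs to exactly one
#' window.
#'
#' @param locations Tibble with a `timestamp` (or `date`) column.
#' @return `locations` with a `window` factor column.
#' @export
seasonal_windows <- function(locations) {
  tcol <- if ("timestamp" %in% names(locations)) "timestamp" else "date"
  stopifnot_cols(locations, tcol, "locations")
  m <- lubridate::month(locations[[tcol]])
  lv <- c("Sep-Oct", "Nov-Dec", "Jan-Feb", "Mar-Apr", "May-Jun", "Jul-Aug")
  idx <- ((m - 9) %% 12) %/% 2 + 1
  locations$window <- factor(lv[idx], levels = lv)
  locations
}

#' Kernel utilization distribution on a geographic grid
#'
#' Isotropic Gaussian kernel density in degree space (bandwidth `h_deg`,
#' the standard deviation of the kernel), evaluated at the centres of a
#' regular lon/lat grid and rescaled so the cell values sum to one.
#'
#' @param points Tibble with `lon`, `lat`.
#' @param h_deg Kernel bandwidth in degrees (2.25 deg is roughly 250 km).
#' @param grid_res Grid resolution in degrees.
#' @param lon_range,lat_range Grid extent; defaults to the data range
#'   padded by `3 * h_deg`.
#' @return A `ud_grid`: density matrix (`lat` rows x `lon` columns) summing
#'   to 1, with `lon`/`lat` cell-centre vectors and metadata.
#' @export
kernel_ud <- function(points, h_deg = 2.25, grid_res = 0.25,
                      lon_range = NULL, lat_range = NULL) {
  stopifnot_cols(points, c("lon", "lat"), "points")
  if (!nrow(points)) {
    abort("kernel_ud(): need at least one point.",
          class = "petrelwind_input_error")
  }
  pad <- 3 * h_deg
  lon_range <- lon_range %||% (range(points$lon) + c(-pad, pad))
  lat_range <- lat_range %||% (range(points$lat) + c(-pad, pad))
  glon <- seq(lon_range[1], lon_range[2], by = grid_res)
  glat <- seq(lat_range[1], lat_range[2], by = grid_res)
  # separable Gaussian: density[i, j] = sum_p A[i, p] * B[j, p]
  A <- exp(-outer(glat, points$lat, "-")^2 / (2 * h_deg^2))
  B <- exp(-outer(glon, points$lon, "-")^2 / (2 * h_deg^2))
  dens <- A %*% t(B)
  s <- sum(dens)
  if (s <= 0 || !is.finite(s)) {
    abort("kernel_ud(): degenerate density (points far outside grid?).",
          class = "petrelwind_input_error")
  }
  structure(list(density = dens / s, lon = glon, lat = glat,
                 h_deg = h_deg, grid_res = grid_res, n_points = nrow(points),
                 n_individuals = 1L),
            class = "ud_grid")
}

#' @export
print.ud_grid <- function(x, ...) {
  cat(sprintf(
    "<ud_grid> %d x %d cells @ %g deg, h = %g deg, %d points, %d individual(s); sum = %.6f\n",
    length(x$lat), length(x$lon), x$grid_res, x$h_deg, x$n_points,
    x$n_individuals, sum(x$density)))
  invisible(x)
}

#' Mean utilization distribution across individuals
#'
#' Computes one UD per individual (`bird_id`) on a common grid, averages
#' them cell-wise and renormalizes, giving each individual equal weight.
#'
#' @param points Tibble with `bird_id`, `lon`, `lat`.
#' @inheritParams kernel_ud
#' @return A `ud_grid`.
#' @export
mean_ud <- function(points, h_deg = 2.25, grid_res = 0.25,
                    lon_range = NULL, lat_range = NULL) {
  stopifnot_cols(points, c("bird_id", "lon", "lat"), "points")
  pad <- 3 * h_deg
  lon_range <- lon_range %||% (range(points$lon) + c(-pad, pad))
  lat_range <- lat_range %||% (range(points$lat) + c(-pad, pad))
  ids <- unique(points$bird_id)
  uds <- map(ids, function(b) {
    kernel_ud(points[points$bird_id == b, , drop = FALSE], h_deg, grid_res,
              lon_range, lat_range)
  })
  dens <- Reduce(`+`, map(uds, "density")) / length(uds)
  out <- uds[[1]]
  out$density <- dens / sum(dens)
  out$n_points <- nrow(points)
  out$n_individuals <- length(ids)
  out
}

#' Density contour of a utilization distribution
#'
#' The level-`p` contour is the smallest set of cells, filled in order of
#' decreasing density, whose summed density reaches `p` (the 50% set is the
#' "core distribution").
#'
#' @param ud A `ud_grid`.
#' @param level Contour level in (0, 1), e.g. 0.50 or 0.75.
#' @return Logical matrix (same shape as the density) marking member cells;
#'   attribute `mass` carries the exact included mass and `area_km2` the
#'   cos(lat)-weighted area.
#' @export
ud_contour <- function(ud, level = 0.50) {
  stopifnot(inherits(ud, "ud_grid"), level > 0, level < 1)
  d <- ud$density
  o <- order(d, decreasing = TRUE)
  csum <- cumsum(d[o])
  k <- which(csum >= level)[1]
  mask <- matrix(FALSE, nrow(d), ncol(d))
  mask[o[seq_len(k)]] <- TRUE
  cell_km2 <- (ud$grid_res * KM_PER_DEG)^2 *
    matrix(cos(ud$lat * pi / 180), nrow(d), ncol(d))
  attr(mask, "mass") <- csum[k]
  attr(mask, "area_km2") <- sum(cell_km2[mask])
  attr(mask, "level") <- level
  mask
}

#' Directed overlap between two core areas
#'
#' The proportion of species A's level-`level` contour area that falls
#' inside species B's (and vice versa); not symmetric in general. Both UDs
#' must share a grid (build them with common `lon_range`/`lat_range`).
#'
#' @param ud_a,ud_b `ud_grid`s on identical grids.
#' @param level Contour level.
#' @return One-row tibble: `prop_a_in_b`, `prop_b_in_a`, areas (km2).
#' @export
ud_overlap <- function(ud_a, ud_b, level = 0.50) {
  if (!isTRUE(all.equal(ud_a$lon, ud_b$lon)) ||
      !isTRUE(all.equal(ud_a$lat, ud_b$lat))) {
    abort("ud_overlap(): the two UDs are not on the same grid.",
          class = "petrelwind_input_error")
  }
  ma <- ud_contour(ud_a, level); mb <- ud_contour(ud_b, level)
  cell_km2 <- (ud_a$grid_res * KM_PER_DEG)^2 *
    matrix(cos(ud_a$lat * pi / 180), nrow(ma), ncol(ma))
  a_area <- sum(cell_km2[ma]); b_area <- sum(cell_km2[mb])
  i_area <- sum(cell_km2[ma & mb])
  tibble(level = level,
         prop_a_in_b = i_area / a_area,
         prop_b_in_a = i_area / b_area,
         area_a_km2 = a_area, area_b_km2 = b_area,
         area_intersection_km2 = i_area)
}

#' Shift timestamps by whole calendar months
#'
#' Synchronisation counterfactual for breeding allochrony: adds
#' `shift_months` calendar months to every timestamp (day-of-month clamped
#' to the target month's length, so Dec 31 + 2 months is Feb 28/29), after
#' which the same windowing/overlap pipeline can be re-run.
#'
#' @param locations Tibble with `timestamp` (or `date`).
#' @param shift_months Signed integer months (default +2).
#' @return `locations` with shifted times.
#' @export
synchronize_phenology <- function(locations, shift_months = 2) {
  tcol <- if ("timestamp" %in% names(locations)) "timestamp" else "date"
  stopifnot_cols(locations, tcol, "locations")
  locations[[tcol]] <- lubridate::`%m+%`(
    locations[[tcol]], lubridate::period(month = as.integer(shift_months)))
  locations
}

#' Seasonal between-species overlap table
#'
#' Runs the full seasonal overlap pipeline: splits each species' locations
#' into the six two-month windows, builds the mean (across individuals) UD
#' per species and window on a common grid, and reports the directed
#' overlap of the level contours, optionally under the synchronized
#' scenario (species A's clock shifted by `shift_months`).
#'
#' @param locs_a,locs_b Location tibbles (`bird_id`, `timestamp`, `lon`,
#'   `lat`) for species A and B.
#' @param level Contour level (0.50 = core).
#' @param h_deg,grid_res Kernel settings.
#' @param scenario `"observed"` or `"synchronized"`.
#' @param shift_months Applied to species A when synchronized.
#' @return Tibble: one row per window with directed overlaps, plus an
#'   `"average"` row.
#' @export
overlap_by_window <- function(locs_a, locs_b, level = 0.50, h_deg = 2.25,
                              grid_res = 0.25,
                              scenario = c("observed", "synchronized"),
                              shift_months = 2) {
  scenario <- match.arg(scenario)
  if (scenario == "synchronized") {
    locs_a <- synchronize_phenology(locs_a, shift_months)
  }
  la <- seasonal_windows(locs_a); lb <- seasonal_windows(locs_b)
  pad <- 3 * h_deg
  lon_range <- range(c(la$lon, lb$lon)) + c(-pad, pad)
  lat_range <- range(c(la$lat, lb$lat)) + c(-pad, pad)
  rows <- map(levels(la$window), function(w) {
    pa <- la[la$window == w, , drop = FALSE]
    pb <- lb[lb$window == w, , drop = FALSE]
    if (!nrow(pa) || !nrow(pb)) return(NULL)
    ua <- mean_ud(pa, h_deg, grid_res, lon_range, lat_range)
    ub <- mean_ud(pb, h_deg, grid_res, lon_range, lat_range)
    ov <- ud_overlap(ua, ub, level)
    ov$window <- w
    ov
  })
  out <- list_rbind(purrr::compact(rows))
  avg <- out |>
    summarise(level = first(.data$level),
              prop_a_in_b = mean(.data$prop_a_in_b),
              prop_b_in_a = mean(.data$prop_b_in_a),
              area_a_km2 = mean(.data$area_a_km2),
              area_b_km2 = mean(.data$area_b_km2),
              area_intersection_km2 = mean(.data$area_intersection_km2)) |>
    mutate(window = "average")
  out <- bind_rows(out, avg)
  out$scenario <- scenario
  dplyr::relocate(out, "window", "scenario")
}
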