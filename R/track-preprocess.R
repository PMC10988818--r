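#' Interpolate a raw track to a regular time step
#'
#' Linearly interpolates longitude and latitude (in degree space, as is
#' standard for sub-polar tracking data) onto a regular grid of timestamps
#' at exact multiples of `target_resolution` hours from the first fix.
#' Never extrapolates beyond the first/last fix. Grid points without a raw
#' fix at their timestamp are flagged `imputed`.
#'
#' @param raw_points Tibble with `timestamp`, `lon`, `lat` (plus optional
#'   `bird_id`/`trip_id`, carried through).
#' @param target_resolution Output resolution in hours (1 or 2).
#' @param max_gap_hours Trips containing a raw gap larger than this are
#'   rejected (classed error `petrelwind_gap_error`).
#' @return A tibble (`timestamp, lon, lat, imputed`, plus ids) with
#'   attributes `resolution_hours` and `imputed_fraction`.
#' @export
interpolate_track <- function(raw_points, target_resolution = 1,
                              max_gap_hours = 12) {
  stopifnot_cols(raw_points, c("timestamp", "lon", "lat"), "raw_points")
  if (!target_resolution %in% c(1, 2)) {
    abort("interpolate_track(): target_resolution must be 1 or 2 hours.",
          class = "petrelwind_config_error")
  }
  raw <- dplyr::arrange(raw_points, .data$timestamp)
  if (nrow(raw) < 2) {
    abort("interpolate_track(): need at least 2 raw fixes.",
          class = "petrelwind_input_error")
  }
  th <- as.numeric(difftime(raw$timestamp, raw$timestamp[1], units = "hours"))
  gaps <- diff(th)
  if (any(gaps <= 0)) {
    abort("interpolate_track(): duplicated or non-increasing timestamps.",
          class = "petrelwind_input_error")
  }
  if (max(gaps) > max_gap_hours) {
    abort(sprintf(
      "interpolate_track(): trip rejected, largest gap %.1f h exceeds max_gap %.1f h.",
      max(gaps), max_gap_hours), class = "petrelwind_gap_error")
  }
  grid_h <- seq(0, floor(tail(th, 1) / target_resolution) * target_resolution,
                by = target_resolution)
  out <- tibble(
    timestamp = raw$timestamp[1] + grid_h * 3600,
    lon = approx(th, raw$lon, xout = grid_h)$y,
    lat = approx(th, raw$lat, xout = grid_h)$y,
    imputed = !purrr::map_lgl(grid_h, function(g) any(abs(th - g) < 1e-6))
  )
  for (id in intersect(c("bird_id", "trip_id", "species"), names(raw))) {
    out[[id]] <- raw[[id]][1]
  }
  out <- dplyr::relocate(out, dplyr::any_of(c("bird_id", "trip_id", "species")))
  attr(out, "resolution_hours") <- target_resolution
  attr(out, "imputed_fraction") <- mean(out$imputed)
  out
}

#' Resample an hourly trip to 2-hour resolution
#'
#' Keeps every second position starting from the first (thinning, not
#' re-interpolation, to minimise the number of synthetic points).
#'
#' @param trip An hourly trip from [interpolate_track()] (or any tibble with
#'   a `resolution_hours` attribute of 1).
#' @return The thinned trip with `resolution_hours = 2`.
#' @export
resample_to_2h <- function(trip) {
  res <- attr(trip, "resolution_hours")
  if (is.null(res)) {
    th <- as.numeric(difftime(trip$timestamp, dplyr::lag(trip$timestamp),
                              units = "hours"))
    res <- stats::median(th, na.rm = TRUE)
  }
  if (!isTRUE(all.equal(res, 1))) {
    abort("resample_to_2h(): input must be at 1 h resolution (already resampled?).",
          class = "petrelwind_config_error")
  }
  out <- trip[seq(1, nrow(trip), by = 2), , drop = FALSE]
  attr(out, "resolution_hours") <- 2
  attr(out, "imputed_fraction") <- if ("imputed" %in% names(out))
    mean(out$imputed) else NA_real_
  out
}

#' Split a continuous track into colony-anchored trips
#'
#' A trip runs between successive crossings of a radius around the colony:
#' it starts when the bird moves beyond `radius_km` and ends when it next
#' comes back inside. Positions inside the radius between trips are
#' dropped; the last position inside before departure and the first inside
#' after return bracket each trip.
#'
#' @param track Tibble with `timestamp`, `lon`, `lat` for one bird.
#' @param colony `(lon, lat)` of the colony.
#' @param radius_km Trip start/end radius.
#' @return The track restricted to at-sea trips with a `trip_id` column
#'   (`<bird>_S1`, `_S2`, ...).
#' @export
split_trips <- function(track, colony, radius_km = 5) {
  stopifnot_cols(track, c("timestamp", "lon", "lat"), "track")
  tr <- dplyr::arrange(track, .data$timestamp)
  d <- haversine_km(tr$lon, tr$lat, colony[1], colony[2])
  at_sea <- d > radius_km
  # bracket each at-sea run with its adjacent inside positions
  run <- rle(at_sea)
  idx <- cumsum(c(1, head(run$lengths, -1)))
  trips <- list()
  k <- 0
  for (r in seq_along(run$lengths)) {
    if (!run$values[r]) next
    k <- k + 1
    i0 <- max(1, idx[r] - 1)
    i1 <- min(nrow(tr), idx[r] + run$lengths[r])
    seg <- tr[i0:i1, , drop = FALSE]
    seg$trip_id <- sprintf("%s_S%d",
                           if ("bird_id" %in% names(tr)) tr$bird_id[1] else "trk",
                           k)
    trips[[k]] <- seg
  }
  if (!length(trips)) {
    warn("split_trips(): no at-sea segments found.")
    return(tr[0, , drop = FALSE])
  }
  list_rbind(trips)
}

#' Summarise trips
#'
#' Per-trip duration (days), great-circle cumulative distance (km), maximum
#' distance from the colony (km) and imputed fraction — the trip-level
#' statistics used both for reporting and for long/short classification.
#'
#' @param tracks Position tibble with `trip_id`, `timestamp`, `lon`, `lat`.
#' @param colony `(lon, lat)`.
#' @return One row per trip.
#' @export
trip_summaries <- function(tracks, colony) {
  stopifnot_cols(tracks, c("trip_id", "timestamp", "lon", "lat"), "tracks")
  tracks |>
    group_by(.data$trip_id) |>
    summarise(
      bird_id = if ("bird_id" %in% names(tracks)) first(.data$bird_id) else NA,
      species = if ("species" %in% names(tracks)) first(.data$species) else NA,
      n_points = n(),
      duration_days = as.numeric(difftime(max(.data$timestamp),
                                          min(.data$timestamp),
                                          units = "days")),
      cumulative_km = sum(haversine_km(lag(.data$lon), lag(.data$lat),
                                       .data$lon, .data$lat),
                          na.rm = TRUE),
      max_colony_km = max(haversine_km(.data$lon, .data$lat,
                                       colony[1], colony[2])),
      imputed_fraction = if ("imputed" %in% names(tracks))
        mean(.data$imputed) else NA_real_,
      .groups = "drop"
    )
}

#' Classify trips as long or short by k-means
#'
#' Two-cluster k-means on standardized (zero mean, unit variance) maximum
#' colony distance and duration; the cluster whose centroid has the larger
#' norm in standardized space is labelled `"long"`. Standardization makes
#' the labels invariant to rescaling either feature.
#'
#' @param trip_stats Output of [trip_summaries()] (>= 2 trips).
#' @param seed RNG seed for the k-means restarts.
#' @param n_start Number of random restarts.
#' @return `trip_stats` with a `trip_class` column; centroids (original
#'   units) attached as attribute `centers`.
#' @export
classify_trips <- function(trip_stats, seed = 1L, n_start = 25) {
  stopifnot_cols(trip_stats, c("trip_id", "duration_days", "max_colony_km"),
                 "trip_stats")
  if (nrow(trip_stats) < 2) {
    abort("classify_trips(): need at least 2 trips.",
          class = "petrelwind_input_error")
  }
  X <- cbind(trip_stats$max_colony_km, trip_stats$duration_days)
  if (all(apply(X, 2, function(c) max(c) - min(c)) < 1e-9)) {
    abort("classify_trips(): all trips identical; clustering is degenerate.",
          class = "petrelwind_degenerate_error")
  }
  Z <- scale(X)
  Z[, apply(X, 2, sd) < 1e-12] <- 0
  km <- with_subseed(seed, salt = 71L,
                     kmeans(Z, centers = 2, nstart = n_start))
  # label using original-unit centroids: the "long" cluster is the one with
  # the larger distance/duration centroid, not the larger z-score norm
  ctr <- km$centers * matrix(attr(Z, "scaled:scale"), 2, 2, byrow = TRUE) +
    matrix(attr(Z, "scaled:center"), 2, 2, byrow = TRUE)
  colnames(ctr) <- c("max_colony_km", "duration_days")
  long_cluster <- which.max(rowSums(scale(ctr, center = FALSE,
                                          scale = apply(X, 2, max))^2))
  out <- trip_stats
  out$trip_class <- if_else(km$cluster == long_cluster, "long", "short")
  attr(out, "centers") <- ctr
  out
}

#' Keep only long trips
#'
#' Drops short trips (the near-colony movements of uncertain function) and
#' reports how much at-sea time was removed.
#'
#' @param tracks Position tibble with `trip_id`.
#' @param trip_stats Classified trip table from [classify_trips()].
#' @return The positions of long trips; attributes `n_removed` and
#'   `time_removed_fraction` record what was discarded.
#' @export
filter_long <- function(tracks, trip_stats) {
  stopifnot_cols(trip_stats, c("trip_id", "trip_class", "duration_days"),
                 "trip_stats")
  long_ids <- trip_stats$trip_id[trip_stats$trip_class == "long"]
  tot <- sum(trip_stats$duration_days)
  removed <- sum(trip_stats$duration_days[!trip_stats$trip_id %in% long_ids])
  out <- dplyr::filter(tracks, .data$trip_id %in% long_ids)
  if (!length(long_ids)) {
    warn("filter_long(): no long trips; returning an empty set.")
  } else {
    inform(sprintf(
      "filter_long(): kept %d/%d trips; removed %.1f%% of at-sea time.",
      length(long_ids), nrow(trip_stats),
      100 * removed / max(tot, 1e-12)))
  }
  attr(out, "n_removed") <- nrow(trip_stats) - length(long_ids)
  attr(out, "time_removed_fraction") <- removed / max(tot, 1e-12)
  out
}
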