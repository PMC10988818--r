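#' Fit a gamma smooth model of transit ground speed on wind
#'
#' Penalized regression of ground speed (km/h) on the delta-angle and wind
#' intensity of each transit step: a gamma GAM with log link, shrinkage
#' cubic regression splines for each margin and (optionally) their tensor
#' product interaction, smoothing parameters by REML. Residual temporal
#' autocorrelation within tracks is handled by estimating the lag-1
#' autocorrelation of the working residuals per track and refitting with an
#' AR1 pre-whitening of the working model (iterated to convergence, at most
#' `ar1_max_iter` times); the pooled AR1 coefficient is reported as `rho`.
#'
#' @param transit_steps Tibble of transit-state steps with `ground_speed`
#'   (km/h, positive), `delta_angle` (deg), `wind_speed_kmh`, `trip_id`.
#' @param k Basis dimension per margin.
#' @param use_interaction Include the tensor interaction term.
#' @param ar1 Estimate and adjust for per-track AR1 correlation.
#' @param ar1_max_iter Maximum whitening iterations.
#' @return A `wind_gam_fit` wrapping the mgcv fit, with `rho`, the training
#'   hull and the step data.
#' @export
fit_wind_gam <- function(transit_steps, k = 8, use_interaction = TRUE,
                         ar1 = FALSE, ar1_max_iter = 5) {
  stopifnot_cols(transit_steps,
                 c("ground_speed", "delta_angle", "wind_speed_kmh"),
                 "transit_steps")
  d <- transit_steps
  if (!"trip_id" %in% names(d)) d$trip_id <- "trk"
  d <- d[is.finite(d$ground_speed) & is.finite(d$delta_angle) &
           is.finite(d$wind_speed_kmh), , drop = FALSE]
  if (any(d$ground_speed <= 0)) {
    abort("fit_wind_gam(): ground speeds must be strictly positive.",
          class = "petrelwind_input_error")
  }
  if (any(d$delta_angle < 0 | d$delta_angle > 180)) {
    abort("fit_wind_gam(): delta_angle must lie in [0, 180].",
          class = "petrelwind_input_error")
  }
  k <- max(4, k)
  form <- if (use_interaction) {
    ground_speed ~ s(delta_angle, bs = "cs", k = k) +
      s(wind_speed_kmh, bs = "cs", k = k) +
      ti(delta_angle, wind_speed_kmh, bs = "cr", k = c(5, 5))
  } else {
    ground_speed ~ s(delta_angle, bs = "cs", k = k) +
      s(wind_speed_kmh, bs = "cs", k = k)
  }
  fit_once <- function(dd, w = NULL) {
    dd$.w <- w %||% rep(1, nrow(dd))
    mgcv::gam(form, data = dd, family = stats::Gamma(link = "log"),
              method = "REML", weights = .w)
  }
  g <- fit_once(d)
  rho <- 0
  if (ar1) {
    # working residuals per track, lag-1 autocorrelation pooled across tracks
    for (it in seq_len(ar1_max_iter)) {
      wr <- residuals(g, type = "working")
      rho_new <- track_lag1(wr, d$trip_id)
      # whiten via AR1 working weights: downweight each step by the
      # information it shares with its predecessor, 1 - rho^2
      w <- rep(1, nrow(d))
      first <- !duplicated(d$trip_id)
      w[!first] <- 1 - rho_new^2
      g2 <- fit_once(d, w = w)
      if (abs(rho_new - rho) < 1e-3) {
        g <- g2; rho <- rho_new
        break
      }
      g <- g2; rho <- rho_new
    }
  }
  hull_idx <- grDevices::chull(d$delta_angle, d$wind_speed_kmh)
  structure(list(
    gam = g, rho = rho, ar1 = ar1, use_interaction = use_interaction,
    k = k, n_obs = nrow(d), n_tracks = length(unique(d$trip_id)),
    hull = cbind(delta_angle = d$delta_angle[hull_idx],
                 wind_speed_kmh = d$wind_speed_kmh[hull_idx]),
    data = d
  ), class = "wind_gam_fit")
}

# mean lag-1 autocorrelation of a residual series within track blocks
track_lag1 <- function(res, trip_id) {
  vals <- tapply(res, trip_id, function(r) {
    if (length(r) < 3) return(NA_real_)
    r0 <- r - mean(r)
    sum(r0[-1] * r0[-length(r0)]) / sum(r0^2)
  })
  m <- mean(vals, na.rm = TRUE)
  if (!is.finite(m)) 0 else max(min(m, 0.98), -0.98)
}

#' @export
print.wind_gam_fit <- function(x, ...) {
  cat(sprintf(
    "<wind_gam_fit> gamma(log) GAM, %d obs / %d tracks, interaction: %s\n",
    x$n_obs, x$n_tracks, x$use_interaction))
  cat(sprintf("  REML edf %.1f, deviance explained %.1f%%, AR1 rho %.3f\n",
              sum(x$gam$edf), 100 * (1 - x$gam$deviance / x$gam$null.deviance),
              x$rho))
  invisible(x)
}

# point-in-polygon test against the training hull
in_hull <- function(fit, delta_angle, wind_speed_kmh) {
  mgcv::in.out(rbind(fit$hull, fit$hull[1, , drop = FALSE]),
               cbind(delta_angle, wind_speed_kmh))
}

#' Predict ground speed from a wind model
#'
#' Positive response-scale prediction at the given delta-angle and wind
#' intensity; points outside the convex hull of the training data are
#' flagged as extrapolation.
#'
#' @param fit A `wind_gam_fit`.
#' @param delta_angle Degrees in `[0, 180]` (vectorised).
#' @param wind_speed_kmh Wind intensity, km/h.
#' @param warn_extrapolation Emit a warning when any query lies outside the
#'   training hull.
#' @return Tibble `delta_angle`, `wind_speed_kmh`, `speed` (km/h),
#'   `extrapolated`.
#' @export
predict_speed <- function(fit, delta_angle, wind_speed_kmh,
                          warn_extrapolation = TRUE) {
  stopifnot(inherits(fit, "wind_gam_fit"))
  n <- max(length(delta_angle), length(wind_speed_kmh))
  nd <- tibble(delta_angle = rep_len(delta_angle, n),
               wind_speed_kmh = rep_len(wind_speed_kmh, n))
  sp <- as.numeric(predict(fit$gam, newdata = nd, type = "response"))
  ext <- !in_hull(fit, nd$delta_angle, nd$wind_speed_kmh)
  if (warn_extrapolation && any(ext)) {
    warn(sprintf("predict_speed(): %d of %d queries outside the training hull.",
                 sum(ext), n))
  }
  nd$speed <- sp
  nd$extrapolated <- ext
  nd
}

#' Predicted-speed surface over a (delta-angle x wind) grid
#'
#' @param fit A `wind_gam_fit`.
#' @param delta_grid,wind_grid Margin grids; defaults span the data.
#' @param mask_extrapolation Set cells outside the training hull to `NA`.
#' @return Tibble `delta_angle`, `wind_speed_kmh`, `speed`, `in_hull`.
#' @export
surface_heatmap <- function(fit, delta_grid = NULL, wind_grid = NULL,
                            mask_extrapolation = TRUE) {
  stopifnot(inherits(fit, "wind_gam_fit"))
  delta_grid <- delta_grid %||% seq(0, 180, length.out = 46)
  wind_grid <- wind_grid %||%
    seq(min(fit$data$wind_speed_kmh), max(fit$data$wind_speed_kmh),
        length.out = 40)
  grid <- tidyr::expand_grid(delta_angle = delta_grid,
                             wind_speed_kmh = wind_grid)
  pr <- predict_speed(fit, grid$delta_angle, grid$wind_speed_kmh,
                      warn_extrapolation = FALSE)
  pr$in_hull <- !pr$extrapolated
  if (mask_extrapolation) pr$speed[pr$extrapolated] <- NA_real_
  dplyr::select(pr, -"extrapolated")
}
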