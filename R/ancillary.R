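#' Daily at-sea activity from immersion data
#'
#' Summarises saltwater-immersion logs into a per-day activity table and
#' phase means. Days spent at the colony are retained in the table (flagged)
#' but excluded from the at-sea activity means, since a dry logger in the
#' nest does not measure flight.
#'
#' @param immersion Tibble with `bird_id`, `date`, `wet_fraction` and
#'   either an `at_colony` flag or none (then `colony_days` applies).
#' @param colony_days Optional tibble (`bird_id`, `date`) of nest days.
#' @param breeding_months Integer months defining the breeding phase (used
#'   when `immersion` has no `phase` column).
#' @return List: `days` (per-day table with `moon_illumination`) and
#'   `phase_means` (mean daily wet fraction by phase, colony days
#'   excluded).
#' @export
daily_activity <- function(immersion, colony_days = NULL,
                           breeding_months = 4:10) {
  stopifnot_cols(immersion, c("bird_id", "date", "wet_fraction"),
                 "immersion")
  days <- immersion
  if (!"at_colony" %in% names(days)) {
    days$at_colony <- FALSE
    if (!is.null(colony_days)) {
      key <- paste(colony_days$bird_id, colony_days$date)
      days$at_colony <- paste(days$bird_id, days$date) %in% key
    }
  }
  if (!"phase" %in% names(days)) {
    days$phase <- if_else(lubridate::month(days$date) %in% breeding_months,
                          "breeding", "non-breeding")
  }
  days$moon_illumination <- moon_illumination(days$date)
  phase_means <- days |>
    filter(!.data$at_colony) |>
    group_by(.data$phase) |>
    summarise(mean_wet = mean(.data$wet_fraction),
              sd_wet = sd(.data$wet_fraction),
              n_days = n(), .groups = "drop")
  list(days = days, phase_means = phase_means)
}

#' Fraction of the lunar disc illuminated
#'
#' Low-precision lunar ephemeris adequate at day resolution: the phase
#' angle is taken from the fraction of the mean synodic month (29.530589
#' days) elapsed since a reference new moon (2000-01-06 18:14 UTC), and the
#' illuminated fraction is `(1 - cos(phase)) / 2` — 0 at new moon, 1 at
#' full moon.
#'
#' @param date Date or POSIXct vector.
#' @return Numeric fraction in `[0, 1]`.
#' @export
moon_illumination <- function(date) {
  t <- lubridate::as_datetime(date, tz = "UTC")
  ref <- lubridate::as_datetime("2000-01-06 18:14:00", tz = "UTC")
  synodic <- 29.530588853
  lun <- (as.numeric(difftime(t, ref, units = "days")) / synodic) %% 1
  (1 - cos(2 * pi * lun)) / 2
}

#' Correlation between nightly flight activity and moonlight
#'
#' For non-breeding, at-sea days: Pearson correlation between the dry
#' (flight) fraction `1 - wet_fraction` and moon illumination, plus a
#' peak-alignment summary (mean illumination on the top-decile flight
#' nights vs overall).
#'
#' @param activity_days The `days` tibble from [daily_activity()] (or any
#'   table with `wet_fraction`, `moon_illumination`, optional `phase` and
#'   `at_colony`).
#' @return One-row tibble: `r`, `p_value`, `n`, `peak_moon_mean`,
#'   `overall_moon_mean`.
#' @export
activity_moon_correlation <- function(activity_days) {
  stopifnot_cols(activity_days, c("wet_fraction", "moon_illumination"),
                 "activity_days")
  d <- activity_days
  if ("at_colony" %in% names(d)) d <- d[!d$at_colony, , drop = FALSE]
  if ("phase" %in% names(d)) d <- d[d$phase == "non-breeding", , drop = FALSE]
  dry <- 1 - d$wet_fraction
  if (sd(dry) < 1e-12 || sd(d$moon_illumination) < 1e-12) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = nrow(d),
                  peak_moon_mean = NA_real_,
                  overall_moon_mean = mean(d$moon_illumination)))
  }
  ct <- stats::cor.test(dry, d$moon_illumination)
  thr <- quantile(dry, 0.9)
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d),
         peak_moon_mean = mean(d$moon_illumination[dry >= thr]),
         overall_moon_mean = mean(d$moon_illumination))
}

#' Two-factor ANOVA of isotope values
#'
#' Linear model `value ~ species + year` fitted separately to each isotope,
#' returning the F statistic, degrees of freedom and p-value per term.
#' With zero residual variance (noise-free constructed data) the F
#' statistic is infinite; it is reported as `Inf` rather than an error.
#'
#' @param samples Tibble with `species`, `year` and isotope columns.
#' @param isotopes Isotope column names (default `d13C`, `d15N`).
#' @return Tidy tibble: `isotope`, `term`, `df`, `df_resid`, `F`,
#'   `p_value`.
#' @export
isotope_anova <- function(samples, isotopes = c("d13C", "d15N")) {
  stopifnot_cols(samples, c("species", "year", isotopes), "samples")
  samples$species <- factor(samples$species)
  samples$year <- factor(samples$year)
  map(isotopes, function(iso) {
    fml <- stats::as.formula(paste(iso, "~ species + year"))
    a <- anova(lm(fml, data = samples))
    terms <- rownames(a)[rownames(a) != "Residuals"]
    tibble(isotope = iso, term = terms,
           df = a$Df[seq_along(terms)],
           df_resid = a$Df[nrow(a)],
           F = a$`F value`[seq_along(terms)],
           p_value = a$`Pr(>F)`[seq_along(terms)])
  }) |> list_rbind()
}

#' Wing loading
#'
#' Body mass divided by wing area, the key flight-morphology index: higher
#' wing loadings favour flight in stronger winds.
#'
#' @param mass_g Body mass in grams.
#' @param wing_area_cm2 Wing area in cm2.
#' @param digits Optional rounding.
#' @return Wing loading in g/cm2.
#' @export
wing_loading <- function(mass_g, wing_area_cm2, digits = NULL) {
  stopifnot(all(mass_g > 0), all(wing_area_cm2 > 0))
  wl <- mass_g / wing_area_cm2
  if (!is.null(digits)) round(wl, digits) else wl
}

#' Isometric mass increase implied by a length ratio
#'
#' Under isometric (geometric) scaling, mass scales with the cube of a
#' linear dimension, so a wingspan ratio `r` implies a mass increase of
#' `(r^3 - 1) * 100` percent — e.g. a ~10% wingspan difference implies
#' ~33%, against which an observed 50% mass difference indicates
#' non-isometric build.
#'
#' @param length_ratio Ratio of linear dimensions (> 0).
#' @param digits Optional rounding.
#' @return Percent mass increase.
#' @export
isometric_mass_increase <- function(length_ratio, digits = NULL) {
  stopifnot(all(length_ratio > 0))
  pct <- (length_ratio^3 - 1) * 100
  if (!is.null(digits)) round(pct, digits) else pct
}
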