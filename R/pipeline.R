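#' Configure an end-to-end pipeline run
#'
#' Bundles every stage's settings with a single master seed. Defaults give
#' a small but complete run (two species differing in trip extent and
#' phenology) that finishes in a few minutes on one CPU.
#'
#' @param world A [world_config()].
#' @param truth_a,truth_b [trip_truth()] per species.
#' @param n_trips Trips per species.
#' @param n_steps_mean Mean steps per trip.
#' @param prop_short Proportion of short near-colony trips mixed in (the
#'   preprocessing stage must find and discard them).
#' @param resolution_hours Track resolution for the wind analysis.
#' @param hmm Settings list: `n_restarts`, `tol`.
#' @param ud Settings list: `h_deg`, `grid_res`, `levels`.
#' @param brt Settings list: `learning_rate`, `tree_complexity`,
#'   `bag_fraction`, `n_folds`, `max_trees`, `step_size`, `ratio`.
#' @param gam Settings list: `k`, `use_interaction`, `ar1`.
#' @param season_shift_months Phenology gap between the species.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(world = world_config(),
                            truth_a = trip_truth(step_mean = c(26, 9),
                                                 step_sd = c(9, 5)),
                            truth_b = trip_truth(step_mean = c(32, 11),
                                                 step_sd = c(11, 6)),
                            n_trips = 8, n_steps_mean = 150,
                            prop_short = 0.25,
                            resolution_hours = 1,
                            hmm = list(n_restarts = 4, tol = 1e-8),
                            ud = list(h_deg = 2.25, grid_res = 0.25,
                                      levels = c(0.5, 0.75)),
                            brt = list(learning_rate = 0.05,
                                       tree_complexity = 3,
                                       bag_fraction = 0.75, n_folds = 5,
                                       max_trees = 400, step_size = 25,
                                       ratio = 3),
                            gam = list(k = 8, use_interaction = TRUE,
                                       ar1 = FALSE),
                            season_shift_months = 2,
                            seed = 1L) {
  structure(list(world = world, truth_a = truth_a, truth_b = truth_b,
                 n_trips = n_trips, n_steps_mean = n_steps_mean,
                 prop_short = prop_short,
                 resolution_hours = resolution_hours, hmm = hmm, ud = ud,
                 brt = brt, gam = gam,
                 season_shift_months = season_shift_months,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_stage <- function(outdir, name, files, overwrite, code) {
  paths <- file.path(outdir, files)
  if (!overwrite && all(file.exists(paths))) {
    inform(sprintf("[%s] cached, skipping", name))
    return(invisible(NULL))
  }
  t0 <- Sys.time()
  force(code)
  inform(sprintf("[%s] done in %.1f s", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate world and tracks, preprocess,
#' wind-annotate, HMM decode, seasonal UD overlap (observed and
#' synchronized), habitat BRT, wind GAM, the four-cell scenario grid and
#' the ancillary activity/isotope analyses — writing plain-text outputs
#' and a JSON manifest to `outdir`. Stages whose outputs already exist are
#' skipped unless `overwrite = TRUE`; results are byte-identical under a
#' fixed config.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param overwrite Re-run stages whose outputs exist.
#' @return `outdir`, invisibly; side effect: CSV/JSON reports.
#' @export
run_pipeline <- function(config, outdir = tempfile("petrelwind_run_"),
                         overwrite = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wc <- config$world
  manifest <- list(package_version = as.character(utils::packageVersion("petrelwind")),
                   r_version = R.version.string,
                   seed = config$seed, started = format(Sys.time(), tz = "UTC"))

  field <- make_windfield(wc)
  tr_a <- simulate_fleet(wc, config$truth_a, config$n_trips,
                         config$n_steps_mean, prop_short = config$prop_short,
                         resolution_hours = config$resolution_hours,
                         species = "A", seed = config$seed)
  tr_b <- simulate_fleet(wc, config$truth_b, config$n_trips,
                         config$n_steps_mean, prop_short = config$prop_short,
                         resolution_hours = config$resolution_hours,
                         species = "B", seed = config$seed + 1L)
  pipeline_stage(outdir, "simulate", c("tracks.csv", "wind.csv"), overwrite, {
    write_tracks_csv(bind_rows(tr_a, tr_b), file.path(outdir, "tracks.csv"))
    write_windfield_csv(field, file.path(outdir, "wind.csv"))
    write_truth_json(config$truth_a, file.path(outdir, "truth_a.json"),
                     species = "A", seed = config$seed)
    write_truth_json(config$truth_b, file.path(outdir, "truth_b.json"),
                     species = "B", seed = config$seed + 1L)
  })

  tracks <- bind_rows(tr_a, tr_b)
  stats_tbl <- trip_summaries(tracks, wc$colony)
  stats_tbl <- classify_trips(stats_tbl, seed = config$seed)
  long_tracks <- filter_long(tracks, stats_tbl)
  pipeline_stage(outdir, "preprocess", "trip_summary.csv", overwrite, {
    readr::write_csv(stats_tbl, file.path(outdir, "trip_summary.csv"))
  })

  steps <- long_tracks |>
    dplyr::group_split(.data$species) |>
    map(~annotate_steps(.x, field)) |>
    list_rbind()
  pipeline_stage(outdir, "annotate", "steps.csv", overwrite, {
    readr::write_csv(steps, file.path(outdir, "steps.csv"))
  })

  fits <- steps |>
    dplyr::group_split(.data$species) |>
    map(~fit_hmm(.x, n_restarts = config$hmm$n_restarts,
                 tol = config$hmm$tol, seed = config$seed))
  names(fits) <- sort(unique(steps$species))
  decoded <- steps |>
    dplyr::group_split(.data$species) |>
    purrr::imap(~decode_states(.x, fits[[unique(.x$species)]])) |>
    list_rbind()
  pipeline_stage(outdir, "hmm", "steps_decoded.csv", overwrite, {
    readr::write_csv(decoded, file.path(outdir, "steps_decoded.csv"))
    jsonlite::write_json(
      purrr::map(fits, function(f) c(unclass(tidy(f)), glance(f))),
      file.path(outdir, "hmm_fits.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns", pretty = TRUE)
  })

  gls <- simulate_gls_year(wc, n_birds = 6, seed = config$seed)
  gls_b <- simulate_gls_year(wc, n_birds = 6,
                             breeding_months = ((4:10 + config$season_shift_months - 1) %% 12) + 1,
                             wintering_centroid = c(-30, 10),
                             seed = config$seed + 7L)
  ov_obs <- overlap_by_window(gls$locations, gls_b$locations,
                              level = config$ud$levels[1],
                              h_deg = config$ud$h_deg,
                              grid_res = max(config$ud$grid_res, 0.5))
  ov_syn <- overlap_by_window(gls$locations, gls_b$locations,
                              level = config$ud$levels[1],
                              h_deg = config$ud$h_deg,
                              grid_res = max(config$ud$grid_res, 0.5),
                              scenario = "synchronized",
                              shift_months = config$season_shift_months)
  pipeline_stage(outdir, "ud", "overlap.csv", overwrite, {
    readr::write_csv(bind_rows(ov_obs, ov_syn),
                     file.path(outdir, "overlap.csv"))
  })

  search_pts <- decoded |> filter(.data$state_name == "search",
                                  .data$species == "A")
  pa <- draw_pseudo_absences(search_pts, wc, ratio = config$brt$ratio,
                             seed = config$seed)
  hab <- bind_rows(
    mutate(habitat_covariates(search_pts[c("lon", "lat", "timestamp")],
                              wc, field), label = 1),
    mutate(habitat_covariates(pa, wc, field), label = 0)
  ) |> dplyr::select("label", "sst", "dist_colony_km", "dist_seamount_km",
                     "wind_speed", "depth")
  brt <- fit_brt(hab, learning_rate = config$brt$learning_rate,
                 tree_complexity = config$brt$tree_complexity,
                 bag_fraction = config$brt$bag_fraction,
                 n_folds = config$brt$n_folds,
                 max_trees = config$brt$max_trees,
                 step_size = config$brt$step_size, seed = config$seed)
  pipeline_stage(outdir, "habitat", "importance.csv", overwrite, {
    readr::write_csv(variable_importance(brt),
                     file.path(outdir, "importance.csv"))
    readr::write_csv(partial_dependence(brt, "sst"),
                     file.path(outdir, "partial_sst.csv"))
    jsonlite::write_json(unclass(glance(brt)),
                         file.path(outdir, "brt_fit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  transit_a <- decoded |> filter(.data$species == "A",
                                 .data$state_name == "transit",
                                 !is.na(.data$bearing))
  transit_b <- decoded |> filter(.data$species == "B",
                                 .data$state_name == "transit",
                                 !is.na(.data$bearing))
  gam_a <- fit_wind_gam(transit_a, k = config$gam$k,
                        use_interaction = config$gam$use_interaction,
                        ar1 = config$gam$ar1)
  pipeline_stage(outdir, "windgam", "wind_surface.csv", overwrite, {
    readr::write_csv(surface_heatmap(gam_a),
                     file.path(outdir, "wind_surface.csv"))
  })

  grid <- scenario_grid(transit_a, transit_b, gam_a, field,
                        config$season_shift_months)
  pipeline_stage(outdir, "scenarios", "scenarios.csv", overwrite, {
    readr::write_csv(duration_boxplot_table(grid),
                     file.path(outdir, "scenarios.csv"))
    cmp <- bind_rows(
      mutate(compare_scenarios(grid$own_own, grid$other_own),
             contrast = "other_track_own_season"),
      mutate(compare_scenarios(grid$own_own, grid$own_other),
             contrast = "own_track_other_season"))
    readr::write_csv(cmp, file.path(outdir, "scenario_tests.csv"))
  })

  act <- daily_activity(gls$immersion)
  iso <- simulate_isotopes(seed = config$seed)
  pipeline_stage(outdir, "ancillary", "activity_phase_means.csv", overwrite, {
    readr::write_csv(act$phase_means,
                     file.path(outdir, "activity_phase_means.csv"))
    readr::write_csv(activity_moon_correlation(act$days),
                     file.path(outdir, "activity_moon.csv"))
    readr::write_csv(isotope_anova(iso), file.path(outdir, "isotopes.csv"))
  })

  manifest$finished <- format(Sys.time(), tz = "UTC")
  manifest$config <- list(n_trips = config$n_trips,
                          n_steps_mean = config$n_steps_mean,
                          resolution_hours = config$resolution_hours,
                          season_shift_months = config$season_shift_months)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
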