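# petrelwind

Movement, windscape and foraging-niche segregation analysis for sympatric
seabirds.

Two closely related gadfly petrels breed 40 km apart in the Madeira
archipelago with a two-month offset in their breeding calendars
(*allochrony*). Both are extreme central-place foragers whose
dynamic-soaring flight costs depend on wind. Did they diverge to exploit
different foraging niches — different waters, habitats and prey — or does
each breed at the time of year whose windscape best supports its flight?
`petrelwind` implements the complete analysis chain needed to weigh those
hypotheses on tracking, immersion and stable-isotope data, for movement
ecologists working with GPS/GLS-tracked pelagic seabirds.

## What it computes

- **Wind-relative track annotation.** Per movement step: ground speed,
  great-circle bearing, interpolated 10-m wind, the delta-angle
  `Δ ∈ [0°, 180°]` between the movement bearing and the direction the wind
  blows toward (0 = tailwind, 180 = headwind), and the signed tail-wind
  component `TWC = w · cos Δ`.
- **Behavioural decoding.** A two-state hidden Markov model on step length
  (gamma) and turning angle (von Mises, mean 0): fast/persistent *transit*
  vs slow/tortuous *search*. Exact scaled-forward likelihood, direct
  maximisation with restarts, Viterbi decoding.
- **Seasonal space use.** Kernel utilization distributions (Gaussian
  kernel, bandwidth *h* = 2.25° ≈ 250 km, 0.25° grid, rescaled to sum 1)
  per individual, averaged per species and two-month window; 50%/75%
  core-area contours; directed between-species overlap; and the
  synchronisation counterfactual that shifts one species' clock by two
  calendar months.
- **Habitat preference.** Presence (search points) vs 3:1 pseudo-absences
  from a land-free 110%-of-max-range colony buffer, fit by stagewise
  boosted regression trees on the bernoulli deviance with CV-selected
  ensemble size; relative importances summing to 100%; partial dependence;
  K-fold validation.
- **The wind model.** Transit ground speed as a gamma GAM (log link) on
  shrinkage cubic splines of Δangle and wind intensity with tensor
  interaction, with per-track AR1 residual handling.
- **The scenario engine.** Flight performance of each species simulated on
  (own | other) tracks during (own | other) breeding season: step geometry
  is held fixed, wind is re-sampled at (possibly season-shifted) times,
  speed comes from the focal species' wind model, and per-trip % change in
  transit duration is compared with Welch t-tests.
- **Ancillary analyses.** Daily immersion activity vs moon illumination,
  two-factor isotope contrasts (δ13C, δ15N), and the wing-loading /
  isometric-scaling morphometry arithmetic.

A synthetic-world generator (`world_config()`, `make_windfield()`,
`simulate_fleet()`, `simulate_gls_year()`, `simulate_isotopes()`) produces
every input with known ground truth, so the whole pipeline is testable
end-to-end without the archived field data.

## Worked example

Simulate a season of trips, classify and keep the long ones, annotate with
wind, and decode behaviour:

```r
library(petrelwind)
library(dplyr)

wc    <- world_config(n_days = 365, rng_seed = 42)
field <- make_windfield(wc, mean_speed = 8, seasonal_amplitude = 2)
fleet <- simulate_fleet(wc, trip_truth(step_mean = c(30, 10), step_sd = c(10, 6)),
                        n_trips = 6, n_steps_mean = 150, prop_short = 0.3,
                        species = "A")

stats <- classify_trips(trip_summaries(fleet, wc$colony), seed = 42)
select(stats, trip_id, duration_days, max_colony_km, trip_class)
#>   trip_id duration_days max_colony_km trip_class
#> 1 A_T01           4.71          476.  long
#> 2 A_T02           6.83          627.  long
#> 3 A_T03           5.96          863.  long
#> 4 A_T04           5.96          735.  long
#> 5 A_T05           5.71          990.  long
#> 6 A_T06           0.958          69.2 short

long  <- filter_long(fleet, stats)
#> filter_long(): kept 5/6 trips; removed 3.2% of at-sea time.
steps <- annotate_steps(long, field)
fit   <- fit_hmm(steps, n_restarts = 4, seed = 42)
fit$params
#> <hmm_params> 2 states (1 = transit, 2 = search)
#>   step  : gamma mean 29.57 / 10.23 km, sd 9.72 / 6.28
#>   turn  : von Mises kappa 9.25 / 1.03
#>   tpm   : [0.910 0.090; 0.121 0.879]  delta = (0.57, 0.43)
```

The generating truth was a 30 km transit / 10 km search step mean: the fit
recovers 29.6 and 10.2 km, with the expected persistent (kappa 9.3) vs
diffuse (kappa 1.0) turning behaviour. Decoded state summaries then feed
the habitat and wind models:

```r
s <- state_summaries(decode_states(steps, fit))
s$by_state[, c("state_name", "ground_speed_mean", "n_trips")]
#>   state_name ground_speed_mean n_trips
#> 1 search                  10.1       5
#> 2 transit                 29.4       5
s$overall
#>   pct_search_mean pct_search_sd n_trips
#> 1            41.4          11.3       5
```

Transit steps average ~29 km/h against ~10 km/h in search, and these birds
spent 41% of their time searching. `run_pipeline(pipeline_config())` runs
the full two-species chain — UD overlap with the synchronisation
counterfactual, habitat BRTs, the wind GAM and the four-cell scenario grid
— and writes CSV/JSON reports plus a manifest to an output directory.

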