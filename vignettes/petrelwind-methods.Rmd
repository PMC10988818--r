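---
title: "Movement, windscape and foraging-niche segregation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement, windscape and foraging-niche segregation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Two closely related gadfly petrels breed on neighbouring islands of the
Madeira archipelago with a two-month offset in their breeding calendars
(*allochrony*). Both are extreme central-place foragers: during incubation a
single trip can span thousands of kilometres of open North Atlantic, powered
by dynamic-soaring flight whose cost depends on wind. Two hypotheses compete
to explain the allochrony: the species may have diverged to exploit
different foraging niches (different waters, habitats and prey), or each may
breed at the time of year whose windscape best supports its flight. This
package implements the full analysis chain needed to weigh those hypotheses
on tracking, immersion and isotope data — and, because the original field
data are archived elsewhere, it ships a synthetic-world generator that
produces all inputs with known ground truth, so every stage is testable
end-to-end.

# Pipeline overview

The stages mirror the analysis workflow:

1. **Synthetic world** (`world_config()`, `make_windfield()`,
   `simulate_trip()`, `simulate_fleet()`, `simulate_gls_year()`,
   `simulate_isotopes()`) — gridded wind, central-place trips from a known
   two-state switching process, year-round geolocator-like locations with
   immersion, and two-species isotope samples.
2. **Track preprocessing** (`interpolate_track()`, `resample_to_2h()`,
   `split_trips()`, `trip_summaries()`, `classify_trips()`,
   `filter_long()`) — regularisation in time, trip segmentation, k-means
   long/short classification and retention of long trips only.
3. **Wind annotation** (`annotate_steps()`, `sample_wind()`,
   `delta_angle()`, `tail_wind_component()`) — per-step ground speed,
   bearing, wind vector, delta-angle and tail-wind component.
4. **Behavioural HMM** (`fit_hmm()`, `viterbi()`, `decode_states()`,
   `state_summaries()`) — two-state transit/search decoding.
5. **Space use** (`kernel_ud()`, `mean_ud()`, `ud_contour()`,
   `ud_overlap()`, `overlap_by_window()`, `synchronize_phenology()`) —
   seasonal utilization distributions, core areas, between-species overlap
   and the +2-month synchronisation counterfactual.
6. **Habitat preference** (`draw_pseudo_absences()`, `fit_brt()`,
   `variable_importance()`, `partial_dependence()`, `cv_evaluate()`) —
   presence/pseudo-absence boosted regression trees.
7. **Wind model** (`fit_wind_gam()`, `predict_speed()`,
   `surface_heatmap()`) — gamma smooth model of transit ground speed on
   delta-angle and wind intensity.
8. **Scenario simulation** (`run_scenario()`, `scenario_grid()`,
   `compare_scenarios()`, `duration_boxplot_table()`) — the track-swap /
   season-swap counterfactual of flight performance.
9. **Ancillary analyses** (`daily_activity()`, `moon_illumination()`,
   `activity_moon_correlation()`, `isotope_anova()`, `wing_loading()`,
   `isometric_mass_increase()`).

`run_pipeline(pipeline_config())` executes all stages in order with one
master seed and writes plain-text artefacts plus a JSON manifest; stages
with existing outputs are skipped on re-runs. The package is the interface:
it is an analysis library, not a shell tool, so orchestration is exposed as
R functions rather than a command-line binary.

# Models and their assumptions

## Movement HMM

Steps are summarised by length (km, gamma-distributed given the state) and
turning angle (radians, von Mises centred at zero given the state). State 1
("transit") has the larger step mean and higher angular concentration;
state 2 ("search") is slow and tortuous. The likelihood is computed by the
scaled forward recursion, exact for any series length, with independent
tracks contributing additively; each trip's first turning angle is
undefined and contributes nothing. Fitting maximises the likelihood
directly (BFGS on log/logit-transformed parameters) from several perturbed
moment-based starts; label switching is resolved by ordering states by step
mean. Decoding uses log-space Viterbi with ties broken toward transit.

Choices worth knowing about: the von Mises mean is fixed at zero rather
than estimated — movement data of this kind are overwhelmingly symmetric
about "keep going straight", and freeing the mean mostly absorbs noise;
zero step lengths (stationary fixes) are replaced by half the smallest
positive step so they stay inside the gamma support; a fit whose two states
end up nearly identical, or where one state decodes to under 2% of points,
raises a degeneracy warning rather than an error. Defaults: 10 restarts,
relative tolerance 1e-8.

Two separate fits are intended per species, as in field practice: one at
2 h resolution to extract search locations for the habitat models, one at
1 h for the wind/transit analysis.

## Utilization distributions and overlap

Locations are split into six fixed two-month windows (September–October
through July–August). Per individual, density is an isotropic Gaussian
kernel in degree space with bandwidth *h* = 2.25° (~250 km at the 111.19
km/degree scale of the 6371-km sphere used throughout), evaluated on a
0.25° grid and renormalised to sum to one; the species-window UD is the
equal-weight mean across individuals, renormalised again. The level-*p*
contour is the smallest set of cells, filled in decreasing density order,
reaching mass *p*; overlap is the directed area proportion of one species'
contour inside the other's, with cell areas cos(latitude)-weighted for km²
reporting. Working in degree space (no projection) matches a bandwidth
stated in degrees; the anisotropy this induces at high latitudes is
documented and immaterial below ~55° N. The synchronisation counterfactual
shifts one species' clock by whole calendar months (`%m+%`-style day
clamping: Dec 31 + 2 months → Feb 28/29) and re-runs the identical
pipeline. Raster cell masks, not polygonized contours, are the overlap
substrate.

## Habitat boosted regression trees

Presences are decoded search locations; for each, three background points
are drawn uniformly from the sea cells of a circular buffer centred on the
colony with radius 110% of the species' maximum colony distance,
intersected with the combined track bounding box. The model is stagewise
gradient boosting on the binomial deviance: each stage fits a small
regression tree (rpart, depth = tree complexity, no surrogate or competitor
splits) to the current gradient on a bagged subsample, shrunk by the
learning rate. The ensemble size is chosen where the mean K-fold
cross-validated predictive deviance is minimal — the staged-CV logic is
implemented in this package — and the final model is refit at that size.
Leaf values are mean-gradient (steepest-descent) steps rather than
one-step Newton values; with shrinkage this changes the step scale, not
the selected structure. Relative importance sums each covariate's primary
split improvements over all trees and normalises to 100%. Defaults follow
common slow-learning practice (learning rate 0.005, depth 3, bag fraction
0.75); the worked examples and tests use faster rates with correspondingly
fewer trees so the CV curve still reaches its minimum.

## Wind model

Transit ground speed (km/h) is modelled as gamma with log link on
shrinkage cubic regression splines of delta-angle and wind intensity plus
their tensor-product interaction, smoothing parameters by REML (mgcv).
Delta-angle is the absolute difference between the movement bearing and the
direction the wind blows *toward*, folded to [0°, 180°] (0 = tailwind); the
tail-wind component is the signed cosine projection. ERA5-style u/v
components define the to-direction; a `wind_convention` switch reports the
meteorological from-direction when wanted, but the to-vector always feeds
delta-angle and TWC. Within-track temporal autocorrelation is handled by
estimating the pooled lag-1 autocorrelation of working residuals per track
and refitting with AR1 effective-information weights (1 − ρ² on
non-initial steps), iterated to convergence: a Cochrane–Orcutt-flavoured
approximation chosen over a full GLS because the point estimate of the
surface is already consistent under working independence and the
approximation is robust on gamma responses. Predictions are flagged when
they extrapolate beyond the convex hull of the training covariates.

## Scenario simulation

The counterfactual engine holds each transit step's geometry (length and
bearing) fixed — there is no rerouting — and asks how long the trip would
take if the focal species' speed-wind law were driven by the wind actually
encountered (i) along the other species' tracks, and/or (ii) at times
shifted by the two-month phenology gap. Step duration is length divided by
predicted speed; per-trip percentage change is referenced to the mean
observed duration of the focal species' real transit portions. Because
geometry never changes, total simulated distance equals total observed
transit distance in every cell — a conservation identity the tests assert.
Predicted speeds at or below 1 km/h flag the trip for exclusion with a
diagnostic. Scenario cells are compared with Welch two-sample t-tests
(`stats::t.test`). Under season swaps, timestamps move by whole calendar
months; matching the other species' actual incubation date windows can be
achieved by choosing the shift, and the calendar-month mode is the default
because it needs no external date table.

## Ancillary analyses

Daily saltwater-immersion (wet) fractions summarise at-sea activity; days
at the nest are excluded from phase means since a dry logger in a burrow
measures nothing about flight. Moon illumination uses a low-precision
ephemeris — fraction of the mean synodic month (29.530589 d) since the
2000-01-06 reference new moon, illuminated fraction (1 − cos)/2 — accurate
at the day level, which is all the activity analysis needs. Isotope
contrasts fit `value ~ species + year` per isotope and report F tests;
noise-free constructed data give infinite F by design, not an error. The
morphometry helpers encode the allometric worked example: mass/area wing
loading, and the (r³ − 1) isometric mass increase implied by a wingspan
ratio — 1.10³ gives 33%, against the observed ~50% mass difference.

# The synthetic world: what it emulates and what it does not

The generator reproduces the *structure* of the study system: a smooth,
band-limited windscape with a sinusoidal annual cycle (stronger winds in
boreal winter, the seasonal contrast the two breeding seasons sample
differently); two-state switching trips that depart from and return to a
colony, with an adaptive homing bias that strengthens as the remaining
travel budget tightens and trips that end on regaining the colony; a mix of
long and short trips so the k-means classifier has real work to do;
year-round daily locations alternating between a breeding range near the
colony and a wintering centroid, with configurable phenology so a
two-month offset between species can be built in; immersion calibrated to
wet fractions of 0.30 (breeding) and 0.51 (non-breeding) with a moonlight
modulation of non-breeding flight; and isotope samples with additive
species and year effects.

It deliberately does *not* emulate: wind-driven track geometry (trips do
not steer by wind, so habitat-wind associations are null by construction);
geolocator error structure beyond isotropic Gaussian noise (no
equinox-dependent latitude error); light-curve processing of any kind;
real bathymetry, SST fields or mesopelagic ecoregions (covariates are
smooth synthetic surfaces with seamount bumps). Passing tests therefore
demonstrate that the estimators recover known generating processes and
that the pipeline's logic is correct — not that any ecological conclusion
transfers to real petrels.

Land handling: the colony island is land for habitat sampling but counts
as the coast for trips (departures and arrivals pass through it); other
islands must be avoided, with steps re-drawn up to 20 times before a loud
failure. Determinism: every generator is a pure function of its config and
seed; one master seed is split into fixed per-purpose substreams
(`seed * 7919 + salt mod 2^31 − 1`), so components can be regenerated in
isolation.

# Numerical choices and problem sizes

Distances use the haversine on a 6371-km sphere; bearings are initial
great-circle bearings; generator position updates use an equirectangular
step, adequate for sub-degree hops. Wind sampling is trilinear in
(lon, lat, time) with an explicit out-of-hull error. Gridded synthetic
fields default to 1° / 6 h over 60° W–10° W × 20° N–55° N — the study
region's extent at a resolution chosen so a full synthetic year fits
comfortably in memory; the interpolators and the pipeline accept 0.25° /
1 h fields over shorter windows. Trip classification standardizes features
to zero mean and unit variance (so labels are invariant to unit changes)
and labels the cluster whose original-unit centroid is larger as "long".
K-means uses 25 restarts under a fixed seed. Recovery tests run at ~2000
steps, UD fleets at 3–8 birds over a year, BRT suites at 240–600 rows, and
the wind model at 2000–6000 steps — sizes at which the estimators are
stable while the whole suite runs in minutes on one CPU.

Wind fields serialize as long-format CSV (`time, lat, lon, u10, v10`), a
text encoding of the standard gridded layout; tracks as CSV with ISO 8601
UTC timestamps; ground truth as JSON sidecars.

# Known limitations

- The AR1 treatment adjusts information weights; it is not a full joint
  GLS, and track-level random intercepts are not estimated.
- Importance uses primary-split improvements only (no surrogate credit),
  and the tree depth parameter bounds depth rather than gbm's
  interaction-order count.
- Degree-space kernels slightly overweight east–west spread at high
  latitude.
- The generator's short trips are simply smaller-scale long trips; nothing
  is known about the true generative structure of short trips, so the
  classifier is tested against that assumption only.
- The moon model ignores lunar anomaly (phase timing can be off by ~1 day),
  irrelevant at the day-level resolution used.
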