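#' Construct two-state movement HMM parameters
#'
#' State 1 is "transit" (fast, persistent: larger gamma step mean, higher
#' turning-angle concentration), state 2 "search" (slow, tortuous).
#' Emissions are a gamma density on step length (km) and a von Mises
#' density centred at zero on the turning angle (radians); the two streams
#' are conditionally independent given the state.
#'
#' @param step_mean,step_sd Length-2 gamma step moments (km), transit first.
#' @param turn_kappa Length-2 von Mises concentrations.
#' @param tpm 2x2 transition probability matrix, rows summing to 1.
#' @param delta Initial state distribution; default is the stationary
#'   distribution of `tpm`.
#' @return An `hmm_params` object.
#' @export
hmm_params <- function(step_mean, step_sd, turn_kappa, tpm, delta = NULL) {
  stopifnot(length(step_mean) == 2, all(step_mean > 0), all(step_sd > 0),
            all(turn_kappa >= 0), all(dim(tpm) == c(2, 2)),
            all(tpm >= 0), max(abs(rowSums(tpm) - 1)) < 1e-6)
  if (is.null(delta)) {
    ev <- eigen(t(tpm))
    i <- which.min(abs(ev$values - 1))
    delta <- abs(Re(ev$vectors[, i])); delta <- delta / sum(delta)
  }
  structure(list(step_mean = as.numeric(step_mean),
                 step_sd = as.numeric(step_sd),
                 turn_kappa = as.numeric(turn_kappa),
                 tpm = unname(tpm), delta = as.numeric(delta)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> 2 states (1 = transit, 2 = search)\n")
  cat(sprintf("  step  : gamma mean %.2f / %.2f km, sd %.2f / %.2f\n",
              x$step_mean[1], x$step_mean[2], x$step_sd[1], x$step_sd[2]))
  cat(sprintf("  turn  : von Mises kappa %.2f / %.2f\n",
              x$turn_kappa[1], x$turn_kappa[2]))
  cat(sprintf("  tpm   : [%.3f %.3f; %.3f %.3f]  delta = (%.2f, %.2f)\n",
              x$tpm[1, 1], x$tpm[1, 2], x$tpm[2, 1], x$tpm[2, 2],
              x$delta[1], x$delta[2]))
  invisible(x)
}

# per-point log emission matrix (T x 2); turning-angle NA contributes 1
hmm_log_emissions <- function(params, step_km, turn_rad) {
  shape <- gamma_shape(params$step_mean, params$step_sd)
  rate <- gamma_rate(params$step_mean, params$step_sd)
  le <- cbind(
    dgamma(step_km, shape[1], rate[1], log = TRUE),
    dgamma(step_km, shape[2], rate[2], log = TRUE)
  )
  has_turn <- !is.na(turn_rad)
  if (any(has_turn)) {
    le[has_turn, 1] <- le[has_turn, 1] +
      dvonmises(turn_rad[has_turn], 0, params$turn_kappa[1], log = TRUE)
    le[has_turn, 2] <- le[has_turn, 2] +
      dvonmises(turn_rad[has_turn], 0, params$turn_kappa[2], log = TRUE)
  }
  le
}

# split a step table into per-track lists of (step_km, turn_rad)
hmm_split_tracks <- function(steps) {
  stopifnot_cols(steps, c("step_km"), "steps")
  if (!"trip_id" %in% names(steps)) steps$trip_id <- "trk"
  if (!"turn_rad" %in% names(steps)) steps$turn_rad <- NA_real_
  keep <- is.finite(steps$step_km)
  steps <- steps[keep, , drop = FALSE]
  # gamma support: zero steps replaced by half the minimum positive step
  pos <- steps$step_km[steps$step_km > 0]
  if (!length(pos)) {
    abort("hmm: all step lengths are zero.", class = "petrelwind_input_error")
  }
  steps$step_km[steps$step_km == 0] <- min(pos) / 2
  split(steps[c("step_km", "turn_rad")], steps$trip_id)
}

#' Log-likelihood of a two-state movement HMM
#'
#' Scaled forward recursion, exact for any series length; multiple tracks
#' (distinct `trip_id`) contribute additively, each restarting from the
#' initial distribution.
#'
#' @param params An [hmm_params()].
#' @param steps Step tibble with `step_km`, optional `turn_rad` (radians,
#'   NA allowed) and `trip_id`.
#' @return Scalar log-likelihood.
#' @export
hmm_loglik <- function(params, steps) {
  tracks <- hmm_split_tracks(steps)
  sum(map_dbl(tracks, function(tr) {
    le <- hmm_log_emissions(params, tr$step_km, tr$turn_rad)
    m <- apply(le, 1, max)
    e <- exp(le - m)
    phi <- params$delta * e[1, ]
    ll <- m[1] + log(sum(phi))
    phi <- phi / sum(phi)
    Tn <- nrow(le)
    if (Tn > 1) for (t in 2:Tn) {
      phi <- as.numeric(phi %*% params$tpm) * e[t, ]
      s <- sum(phi)
      ll <- ll + m[t] + log(s)
      phi <- phi / s
    }
    ll
  }))
}

# pack/unpack working parameters for the optimiser
hmm_pack <- function(p) {
  c(log(p$step_mean), log(p$step_sd), log(p$turn_kappa + 1e-10),
    qlogis(pmin(pmax(c(p$tpm[1, 2], p$tpm[2, 1]), 1e-6), 1 - 1e-6)))
}
hmm_unpack <- function(w) {
  g12 <- plogis(w[7]); g21 <- plogis(w[8])
  hmm_params(step_mean = exp(w[1:2]), step_sd = exp(w[3:4]),
             turn_kappa = exp(w[5:6]),
             tpm = matrix(c(1 - g12, g12, g21, 1 - g21), 2, 2, byrow = TRUE))
}

#' Fit the two-state movement HMM by direct likelihood maximisation
#'
#' Maximises [hmm_loglik()] with BFGS from `n_restarts` perturbed starting
#' points (moment-based defaults from a step-length split at the median).
#' Label switching is resolved by ordering states by gamma step mean, so
#' state 1 is always the larger-step "transit" state.
#'
#' @param steps Step tibble (`step_km`, `turn_rad`, `trip_id`) at a uniform
#'   resolution.
#' @param n_restarts Number of perturbed restarts.
#' @param tol Relative convergence tolerance passed to the optimiser.
#' @param init Optional [hmm_params()] starting point.
#' @param seed RNG seed for the restart perturbations.
#' @return An `hmm_fit`: `params`, `log_lik`, per-point smoothed
#'   `state_probs`, `viterbi` states, and convergence metadata.
#' @export
fit_hmm <- function(steps, n_restarts = 10, tol = 1e-8, init = NULL,
                    seed = 1L) {
  tracks <- hmm_split_tracks(steps)
  all_steps <- unlist(map(tracks, "step_km"))
  med <- median(all_steps)
  lo <- all_steps[all_steps <= med]; hi <- all_steps[all_steps > med]
  if (!length(hi) || !length(lo) ||
      abs(mean(hi) - mean(lo)) < 1e-8 * max(mean(all_steps), 1)) {
    warn("fit_hmm(): step lengths look single-state; estimates may be degenerate.")
  }
  base <- init %||% hmm_params(
    step_mean = c(max(mean(hi), med * 1.5), max(mean(lo), 1e-3)),
    step_sd = c(max(sd(hi), 1e-2), max(sd(lo), 1e-2)),
    turn_kappa = c(5, 1),
    tpm = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
  nll <- function(w) {
    p <- try(hmm_unpack(w), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    v <- try(suppressWarnings(-hmm_loglik(p, steps)), silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }
  w0 <- hmm_pack(base)
  fits <- with_subseed(seed, salt = 97L, {
    map(seq_len(max(1, n_restarts)), function(r) {
      w <- if (r == 1) w0 else w0 + rnorm(length(w0), 0, 0.4)
      o <- try(optim(w, nll, method = "BFGS",
                     control = list(maxit = 500, reltol = tol)),
               silent = TRUE)
      if (inherits(o, "try-error") || !is.finite(o$value) || o$value >= 1e10)
        NULL else list(o = o, restart = r)
    })
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) {
    abort("fit_hmm(): all restarts failed to converge.",
          class = "petrelwind_estimation_error")
  }
  best <- fits[[which.min(map_dbl(fits, function(f) f$o$value))]]
  params <- hmm_unpack(best$o$par)
  # label switching: transit = larger gamma mean
  if (params$step_mean[1] < params$step_mean[2]) {
    params <- hmm_params(step_mean = rev(params$step_mean),
                         step_sd = rev(params$step_sd),
                         turn_kappa = rev(params$turn_kappa),
                         tpm = params$tpm[2:1, 2:1])
  }
  vit <- viterbi(params, steps)
  occ <- mean(vit == 1)
  if (abs(diff(params$step_mean)) / mean(params$step_mean) < 0.15 ||
      occ < 0.02 || occ > 0.98) {
    warn("fit_hmm(): degenerate two-state solution (near-identical states or one state unused); the data may be single-state.")
  }
  sp <- hmm_state_probs(params, steps)
  structure(list(
    params = params,
    log_lik = -best$o$value,
    state_probs = sp,
    viterbi = vit,
    n_obs = sum(map_dbl(tracks, function(t) length(t$step_km))),
    n_tracks = length(tracks),
    convergence = list(code = best$o$convergence,
                       iterations = best$o$counts[["function"]],
                       restart = best$restart,
                       n_restarts_ok = length(fits),
                       tol = tol)
  ), class = "hmm_fit")
}

# forward-backward smoothed state probabilities (T x 2, rows sum to 1)
hmm_state_probs <- function(params, steps) {
  tracks <- hmm_split_tracks(steps)
  out <- map(tracks, function(tr) {
    le <- hmm_log_emissions(params, tr$step_km, tr$turn_rad)
    Tn <- nrow(le)
    e <- exp(le - apply(le, 1, max))
    alpha <- matrix(0, Tn, 2); cvec <- numeric(Tn)
    phi <- params$delta * e[1, ]
    cvec[1] <- sum(phi); alpha[1, ] <- phi / cvec[1]
    if (Tn > 1) for (t in 2:Tn) {
      phi <- as.numeric(alpha[t - 1, ] %*% params$tpm) * e[t, ]
      cvec[t] <- sum(phi); alpha[t, ] <- phi / cvec[t]
    }
    beta <- matrix(1, Tn, 2)
    if (Tn > 1) for (t in (Tn - 1):1) {
      beta[t, ] <- as.numeric(params$tpm %*% (e[t + 1, ] * beta[t + 1, ])) /
        cvec[t + 1]
    }
    g <- alpha * beta
    g / rowSums(g)
  })
  do.call(rbind, out)
}

#' Viterbi decoding of the most likely state sequence
#'
#' Log-space dynamic programming; ties broken toward state 1 (transit).
#'
#' @param params An [hmm_params()].
#' @param steps Step tibble as for [hmm_loglik()].
#' @return Integer vector of states (1 = transit, 2 = search), one per step,
#'   in the row order of `steps` within each `trip_id` group.
#' @export
viterbi <- function(params, steps) {
  tracks <- hmm_split_tracks(steps)
  lt <- log(params$tpm)
  unlist(map(tracks, function(tr) {
    le <- hmm_log_emissions(params, tr$step_km, tr$turn_rad)
    Tn <- nrow(le)
    d <- matrix(-Inf, Tn, 2); ptr <- matrix(1L, Tn, 2)
    d[1, ] <- log(params$delta) + le[1, ]
    if (Tn > 1) for (t in 2:Tn) {
      for (j in 1:2) {
        cand <- d[t - 1, ] + lt[, j]
        ptr[t, j] <- which.max(cand) # ties -> state 1
        d[t, j] <- cand[ptr[t, j]] + le[t, j]
      }
    }
    s <- integer(Tn)
    s[Tn] <- which.max(d[Tn, ])
    if (Tn > 1) for (t in (Tn - 1):1) s[t] <- ptr[t + 1, s[t + 1]]
    s
  }), use.names = FALSE)
}

#' Decode annotated steps with a fitted HMM
#'
#' Adds `state` (integer) and `state_name` (`"transit"`/`"search"`) columns.
#'
#' @param steps Annotated step tibble.
#' @param fit An `hmm_fit` (or [hmm_params()]).
#' @return `steps` with decoded states.
#' @export
decode_states <- function(steps, fit) {
  params <- if (inherits(fit, "hmm_fit")) fit$params else fit
  # reproduce the internal split order (split() sorts by trip_id)
  if (!"trip_id" %in% names(steps)) steps$trip_id <- "trk"
  ord <- order(steps$trip_id)
  v <- viterbi(params, steps)
  steps$state <- NA_integer_
  steps$state[ord] <- v
  steps$state_name <- c("transit", "search")[steps$state]
  steps
}

#' Per-state summaries of annotated, decoded steps
#'
#' Means are computed per trip first, then averaged across trips (the trip
#' is the sampling unit), for ground speed, wind speed, tail-wind component
#' and delta-angle, plus the percentage of time in the search state.
#'
#' @param steps Decoded annotated steps (needs `state_name`, `trip_id`).
#' @return List of two tibbles: `by_state` (variable means/sds by state) and
#'   `overall` (incl. `pct_search`).
#' @export
state_summaries <- function(steps) {
  stopifnot_cols(steps, c("trip_id", "state_name"), "steps")
  vars <- intersect(c("ground_speed", "wind_speed_kmh", "twc_kmh",
                      "delta_angle"), names(steps))
  per_trip <- steps |>
    group_by(.data$trip_id, .data$state_name) |>
    summarise(across(dplyr::all_of(vars), ~mean(.x, na.rm = TRUE)),
              n_steps = n(), .groups = "drop")
  by_state <- per_trip |>
    group_by(.data$state_name) |>
    summarise(across(dplyr::all_of(vars),
                     list(mean = ~mean(.x, na.rm = TRUE),
                          sd = ~sd(.x, na.rm = TRUE))),
              n_trips = n(), .groups = "drop")
  pct_search <- steps |>
    group_by(.data$trip_id) |>
    summarise(pct = 100 * mean(.data$state_name == "search"),
              .groups = "drop")
  overall <- tibble(
    pct_search_mean = mean(pct_search$pct),
    pct_search_sd = sd(pct_search$pct),
    n_trips = nrow(pct_search)
  )
  list(by_state = by_state, overall = overall)
}
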