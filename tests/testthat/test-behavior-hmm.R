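# brute-force HMM log-likelihood by exhaustive path enumeration (oracle)
brute_loglik <- function(params, step_km, turn_rad) {
  le <- petrelwind:::hmm_log_emissions(params, step_km, turn_rad)
  Tn <- length(step_km)
  paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
  tot <- -Inf
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(params$delta[s[1]]) + le[1, s[1]]
    if (Tn > 1) for (t in 2:Tn) {
      lp <- lp + log(params$tpm[s[t - 1], s[t]]) + le[t, s[t]]
    }
    tot <- max(tot, lp) + log1p(exp(min(tot, lp) - max(tot, lp)))
  }
  tot
}

toy_params <- function() {
  hmm_params(step_mean = c(30, 8), step_sd = c(10, 4),
             turn_kappa = c(8, 0.5),
             tpm = matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE))
}

test_that("forward log-likelihood equals exhaustive enumeration for short series", {
  p <- toy_params()
  withr::with_seed(10, {
    for (Tn in c(3, 5, 8)) {
      steps <- tibble::tibble(step_km = rgamma(Tn, 4, 0.2),
                              turn_rad = c(NA, runif(Tn - 1, -pi, pi)))
      expect_equal(hmm_loglik(p, steps),
                   brute_loglik(p, steps$step_km, steps$turn_rad),
                   tolerance = 1e-10)
    }
  })
})

test_that("a degenerate single-state chain reduces to summed emission densities", {
  p <- hmm_params(step_mean = c(30, 8), step_sd = c(10, 4),
                  turn_kappa = c(8, 0.5),
                  tpm = matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE),
                  delta = c(1, 0))
  withr::with_seed(2, {
    steps <- tibble::tibble(step_km = rgamma(20, 4, 0.2),
                            turn_rad = c(NA, runif(19, -pi, pi)))
  })
  le <- petrelwind:::hmm_log_emissions(p, steps$step_km, steps$turn_rad)
  expect_equal(hmm_loglik(p, steps), sum(le[, 1]), tolerance = 1e-10)
})

test_that("independent tracks contribute additively to the likelihood", {
  p <- toy_params()
  withr::with_seed(3, {
    s1 <- tibble::tibble(trip_id = "a", step_km = rgamma(15, 4, 0.2),
                         turn_rad = c(NA, runif(14, -pi, pi)))
    s2 <- tibble::tibble(trip_id = "b", step_km = rgamma(12, 6, 0.3),
                         turn_rad = c(NA, runif(11, -pi, pi)))
  })
  expect_equal(hmm_loglik(p, dplyr::bind_rows(s1, s2)),
               hmm_loglik(p, s1) + hmm_loglik(p, s2), tolerance = 1e-10)
})

test_that("Viterbi matches the brute-force most likely path on toys", {
  p <- toy_params()
  withr::with_seed(4, {
    for (r in 1:5) {
      Tn <- 3
      steps <- tibble::tibble(step_km = rgamma(Tn, 4, 0.2),
                              turn_rad = c(NA, runif(Tn - 1, -pi, pi)))
      le <- petrelwind:::hmm_log_emissions(p, steps$step_km, steps$turn_rad)
      paths <- as.matrix(expand.grid(rep(list(1:2), Tn)))
      lp <- apply(paths, 1, function(s) {
        v <- log(p$delta[s[1]]) + le[1, s[1]]
        for (t in 2:Tn) v <- v + log(p$tpm[s[t - 1], s[t]]) + le[t, s[t]]
        v
      })
      expect_equal(viterbi(p, steps), unname(paths[which.max(lp), ]))
    }
  })
})

test_that("the Viterbi path is at least as likely as random paths", {
  p <- toy_params()
  path_lp <- function(s, le) {
    v <- log(p$delta[s[1]]) + le[1, s[1]]
    for (t in 2:length(s)) v <- v + log(p$tpm[s[t - 1], s[t]]) + le[t, s[t]]
    v
  }
  withr::with_seed(5, {
    steps <- tibble::tibble(step_km = rgamma(40, 4, 0.2),
                            turn_rad = c(NA, runif(39, -pi, pi)))
    le <- petrelwind:::hmm_log_emissions(p, steps$step_km, steps$turn_rad)
    v <- viterbi(p, steps)
    for (r in 1:20) {
      expect_gte(path_lp(v, le), path_lp(sample(1:2, 40, TRUE), le))
    }
  })
})

test_that("parameters are recovered from simulated two-state tracks", {
  wc <- tiny_world()
  truth <- trip_truth(step_mean = c(30, 10), step_sd = c(10, 6),
                      turn_kappa = c(12, 0.8))
  trips <- lapply(1:8, function(i) {
    tr <- simulate_trip(wc, truth, n_steps = 260, seed = 100 + i,
                        trip_id = sprintf("T%02d", i), homing_start = 0.8)
    tr
  })
  tracks <- dplyr::bind_rows(trips)
  # build step table directly from positions (no wind needed)
  steps <- tracks |>
    dplyr::group_by(trip_id) |>
    dplyr::mutate(
      step_km = haversine_km(lon, lat, dplyr::lead(lon), dplyr::lead(lat)),
      b = step_bearing(lon, lat, dplyr::lead(lon), dplyr::lead(lat)),
      turn_rad = petrelwind:::wrap_pi((b - dplyr::lag(b)) * pi / 180)) |>
    dplyr::filter(!is.na(step_km)) |>
    dplyr::ungroup()
  expect_gt(nrow(steps), 1500)
  fit <- fit_hmm(steps, n_restarts = 4, seed = 1)
  expect_lt(abs(fit$params$step_mean[1] - 30) / 30, 0.10)
  expect_lt(abs(fit$params$step_mean[2] - 10) / 10, 0.10)
  # state 1 is transit by construction (label switching resolved)
  expect_gt(fit$params$step_mean[1], fit$params$step_mean[2])
  # decoding recovers the true states for well-separated states
  truth_states <- (tracks |>
    dplyr::arrange(trip_id) |>
    dplyr::group_by(trip_id) |>
    dplyr::slice(-1) |>
    dplyr::ungroup())$state_true
  dec <- decode_states(steps, fit)
  expect_gte(mean(dec$state == truth_states), 0.95)
  # smoothed probabilities are a proper distribution per point
  expect_true(all(abs(rowSums(fit$state_probs) - 1) < 1e-9))
})

test_that("tighter tolerance never lowers the attained log-likelihood", {
  wc <- tiny_world()
  tr <- simulate_trip(wc, trip_truth(), n_steps = 250, seed = 55)
  steps <- tibble::tibble(
    step_km = haversine_km(tr$lon[-nrow(tr)], tr$lat[-nrow(tr)],
                           tr$lon[-1], tr$lat[-1]))
  f_loose <- fit_hmm(steps, n_restarts = 2, tol = 1e-3, seed = 2)
  f_tight <- fit_hmm(steps, n_restarts = 2, tol = 1e-9, seed = 2)
  expect_gte(f_tight$log_lik, f_loose$log_lik - 1e-6)
})

test_that("single-state data triggers the degeneracy warning but still fits", {
  withr::with_seed(6, {
    steps <- tibble::tibble(step_km = rgamma(300, 25, 1),
                            turn_rad = c(NA, rnorm(299, 0, 0.3)))
  })
  expect_warning(fit <- fit_hmm(steps, n_restarts = 2, seed = 3),
                 "single-state|degenerate")
  # the two states collapse onto similar step means
  expect_lt(abs(diff(fit$params$step_mean)) / mean(fit$params$step_mean), 0.5)
})

test_that("state summaries aggregate per trip then across trips", {
  steps <- tibble::tibble(
    trip_id = c("a", "a", "a", "a", "b", "b"),
    state_name = c("transit", "transit", "search", "search",
                   "transit", "search"),
    ground_speed = c(30, 34, 10, 12, 40, 8),
    wind_speed_kmh = c(20, 22, 18, 16, 25, 15),
    twc_kmh = c(5, 6, 2, 1, 8, 0),
    delta_angle = c(40, 50, 90, 100, 30, 120))
  s <- state_summaries(steps)
  tr_row <- s$by_state[s$by_state$state_name == "transit", ]
  # hand computation: trip a transit mean 32, trip b 40 -> mean 36
  expect_equal(tr_row$ground_speed_mean, mean(c(mean(c(30, 34)), 40)))
  expect_equal(s$overall$pct_search_mean, mean(c(50, 50)))
  all_transit <- dplyr::mutate(steps, state_name = "transit")
  expect_equal(state_summaries(all_transit)$overall$pct_search_mean, 0)
})
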