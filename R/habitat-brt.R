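#' Draw pseudo-absences for a habitat model
#'
#' Background points are drawn uniformly at random from the sea cells of a
#' circular buffer centred on the colony with radius `buffer_scale` (110%)
#' times the focal species' maximum distance from the colony, intersected
#' with a bounding box (typically the combined lon/lat range of both
#' species' tracks). `ratio` pseudo-absences are drawn per presence.
#'
#' @param presences Tibble with `lon`, `lat` of presence (search) points.
#' @param config A [world_config()] (supplies the colony and land mask).
#' @param ratio Pseudo-absences per presence.
#' @param buffer_scale Buffer radius as a multiple of the maximum presence
#'   distance from the colony.
#' @param bbox Optional `list(lon = c(min, max), lat = c(min, max))`
#'   bounding box; defaults to the domain.
#' @param seed RNG seed (fixed seed, identical draws).
#' @param max_tries Rejection-sampling budget multiplier.
#' @return Tibble of `lon`, `lat` with `ratio * nrow(presences)` rows.
#' @export
draw_pseudo_absences <- function(presences, config, ratio = 3,
                                 buffer_scale = 1.10, bbox = NULL,
                                 seed = 1L, max_tries = 200) {
  stopifnot_cols(presences, c("lon", "lat"), "presences")
  if (!nrow(presences)) {
    abort("draw_pseudo_absences(): need at least one presence.",
          class = "petrelwind_input_error")
  }
  colony <- config$colony
  rmax <- buffer_scale * max(haversine_km(presences$lon, presences$lat,
                                          colony["lon"], colony["lat"]))
  bbox <- bbox %||% list(lon = range(config$lon), lat = range(config$lat))
  n_target <- ratio * nrow(presences)
  got <- tibble(lon = numeric(0), lat = numeric(0))
  with_subseed(seed, salt = 131L, {
    for (i in seq_len(max_tries)) {
      m <- max(2L * (n_target - nrow(got)), 64L)
      cand <- tibble(lon = runif(m, bbox$lon[1], bbox$lon[2]),
                     lat = runif(m, bbox$lat[1], bbox$lat[2]))
      d <- haversine_km(cand$lon, cand$lat, colony["lon"], colony["lat"])
      ok <- d <= rmax & !is_land(config, cand$lon, cand$lat)
      got <- bind_rows(got, cand[ok, , drop = FALSE])
      if (nrow(got) >= n_target) break
    }
  })
  if (nrow(got) < n_target) {
    abort("draw_pseudo_absences(): buffer appears to contain no available sea area.",
          class = "petrelwind_generation_error")
  }
  got[seq_len(n_target), , drop = FALSE]
}

#' Environmental covariates of the synthetic world
#'
#' Extracts, at each point (and optional time), the synthetic covariate set
#' used by the habitat models: SST (deg C), distance to the colony (km),
#' distance to the nearest seamount (km), 10-m wind speed (m/s, when a wind
#' field is supplied) and bathymetric depth (m).
#'
#' @param points Tibble with `lon`, `lat` and optionally `timestamp`.
#' @param config A [world_config()].
#' @param field Optional `wind_field` for the wind-speed covariate.
#' @return `points` with covariate columns appended.
#' @export
habitat_covariates <- function(points, config, field = NULL) {
  stopifnot_cols(points, c("lon", "lat"), "points")
  tm <- if ("timestamp" %in% names(points)) points$timestamp else
    rep(config$time_origin + config$n_days / 2 * 86400, nrow(points))
  out <- points
  out$sst <- sst_at(config, points$lon, points$lat, tm)
  out$dist_colony_km <- haversine_km(points$lon, points$lat,
                                     config$colony["lon"],
                                     config$colony["lat"])
  dsm <- sapply(seq_len(nrow(config$seamounts)), function(k) {
    haversine_km(points$lon, points$lat, config$seamounts[k, 1],
                 config$seamounts[k, 2])
  })
  out$dist_seamount_km <- if (is.matrix(dsm)) apply(dsm, 1, min) else min(dsm)
  if (!is.null(field)) {
    w <- sample_wind(field, points$lon, points$lat, tm)
    out$wind_speed <- sqrt(w$u^2 + w$v^2)
  }
  out$depth <- depth_at(config, points$lon, points$lat)
  out
}

# fast rank AUC (probability a presence outscores an absence)
rank_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                 direction = "<", levels = c(0, 1))))
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# grow a boosted ensemble on (X, y) from an offset f0; returns list of trees
# and the fitted score path needed for staged prediction
boost_trees <- function(data, covariates, y, f0, n_trees, learning_rate,
                        tree_complexity, bag_fraction) {
  ctrl <- rpart::rpart.control(maxdepth = tree_complexity, cp = 0,
                               minsplit = max(4, nrow(data) %/% 50),
                               minbucket = max(2, nrow(data) %/% 100),
                               maxsurrogate = 0, maxcompete = 0, xval = 0)
  f <- rep(f0, nrow(data))
  trees <- vector("list", n_trees)
  fd <- data[covariates]
  for (m in seq_len(n_trees)) {
    p <- plogis(f)
    r <- y - p # negative gradient of the bernoulli deviance
    bag <- sample.int(nrow(data), max(2, round(bag_fraction * nrow(data))))
    df <- fd[bag, , drop = FALSE]
    df$.r <- r[bag]
    tr <- rpart::rpart(.r ~ ., data = df, method = "anova", control = ctrl)
    trees[[m]] <- tr
    f <- f + learning_rate * predict(tr, newdata = fd)
  }
  trees
}

# staged predictions: score after each block of trees
staged_scores <- function(trees, newdata, f0, learning_rate, eval_at) {
  f <- rep(f0, nrow(newdata))
  out <- matrix(NA_real_, nrow(newdata), length(eval_at))
  k <- 0
  for (m in seq_along(trees)) {
    f <- f + learning_rate * predict(trees[[m]], newdata = newdata)
    if (m %in% eval_at) {
      k <- k + 1
      out[, k] <- f
    }
  }
  out
}

#' Fit a boosted-regression-tree habitat model with CV-selected size
#'
#' Stagewise gradient boosting of small regression trees on the negative
#' gradient of the binomial (bernoulli) deviance, with the ensemble size
#' chosen where the mean K-fold cross-validated predictive deviance is
#' minimal (the `gbm.step` procedure), then refit on all data at that size.
#'
#' @param data Tibble with a 0/1 `label` column and covariate columns.
#' @param covariates Character vector of covariate column names (default:
#'   every column except `label`).
#' @param learning_rate Shrinkage per tree.
#' @param tree_complexity Maximum tree depth.
#' @param bag_fraction Row subsample fraction per tree.
#' @param n_folds CV folds used to pick the ensemble size.
#' @param max_trees Upper bound on ensemble size.
#' @param step_size CV deviance is evaluated every `step_size` trees.
#' @param seed RNG seed (fold assignment + bagging).
#' @return A `brt_fit`: trees, `n_trees`, CV curve, fold-wise AUC and
#'   deviance at the selected size, relative importance.
#' @export
fit_brt <- function(data, covariates = NULL, learning_rate = 0.005,
                    tree_complexity = 3, bag_fraction = 0.75, n_folds = 5,
                    max_trees = 1000, step_size = 25, seed = 1L) {
  stopifnot_cols(data, "label", "habitat data")
  covariates <- covariates %||% setdiff(names(data), "label")
  y <- data$label
  if (!all(y %in% 0:1) || length(unique(y)) < 2) {
    abort("fit_brt(): label must contain both 0s and 1s.",
          class = "petrelwind_input_error")
  }
  if (!all(purrr::map_lgl(data[covariates], ~all(is.finite(.x))))) {
    abort("fit_brt(): covariates must be finite.",
          class = "petrelwind_input_error")
  }
  f0 <- qlogis(mean(y))
  eval_at <- seq(step_size, max_trees, by = step_size)
  with_subseed(seed, salt = 151L, {
    folds <- sample(rep_len(seq_len(n_folds), nrow(data)))
    cv_scores <- map(seq_len(n_folds), function(k) {
      tr_idx <- folds != k
      trees_k <- boost_trees(data[tr_idx, , drop = FALSE], covariates,
                             y[tr_idx], f0, max_trees, learning_rate,
                             tree_complexity, bag_fraction)
      staged_scores(trees_k, data[!tr_idx, covariates, drop = FALSE], f0,
                    learning_rate, eval_at)
    })
    cv_dev <- sapply(seq_along(eval_at), function(j) {
      mean(map_dbl(seq_len(n_folds), function(k) {
        binomial_deviance(y[folds == k], plogis(cv_scores[[k]][, j]))
      }))
    })
    if (which.min(cv_dev) == length(eval_at) && length(eval_at) > 2 &&
        all(diff(cv_dev) < 0) && max_trees >= 200) {
      inform("fit_brt(): CV deviance still decreasing at max_trees; consider raising max_trees.")
    }
    if (all(diff(cv_dev) >= 0)) {
      inform("fit_brt(): CV deviance never improved on the first block; learning rate may be too high.")
    }
    best_j <- which.min(cv_dev)
    n_trees <- eval_at[best_j]
    cv_auc <- map_dbl(seq_len(n_folds), function(k) {
      yk <- y[folds == k]
      if (length(unique(yk)) < 2) return(NA_real_)
      rank_auc(yk, cv_scores[[k]][, best_j])
    })
    cv_dev_folds <- map_dbl(seq_len(n_folds), function(k) {
      binomial_deviance(y[folds == k], plogis(cv_scores[[k]][, best_j]))
    })
    trees <- boost_trees(data, covariates, y, f0, n_trees, learning_rate,
                         tree_complexity, bag_fraction)
    structure(list(
      trees = trees, f0 = f0, covariates = covariates,
      learning_rate = learning_rate, tree_complexity = tree_complexity,
      bag_fraction = bag_fraction, n_trees = n_trees,
      cv_curve = tibble(n_trees = eval_at, cv_deviance = cv_dev),
      cv_auc = cv_auc, cv_deviance = cv_dev_folds,
      n_folds = n_folds, n_obs = nrow(data), data = data
    ), class = "brt_fit")
  })
}

#' @export
print.brt_fit <- function(x, ...) {
  cat(sprintf(
    "<brt_fit> %d trees (lr %g, depth %d, bag %g), %d obs, %d covariates\n",
    x$n_trees, x$learning_rate, x$tree_complexity, x$bag_fraction, x$n_obs,
    length(x$covariates)))
  cat(sprintf("  CV (K=%d): AUC %.3f +- %.3f, deviance %.3f\n",
              x$n_folds, mean(x$cv_auc, na.rm = TRUE),
              sd(x$cv_auc, na.rm = TRUE), mean(x$cv_deviance)))
  invisible(x)
}

#' Predict presence probability from a BRT fit
#'
#' @param object A `brt_fit`.
#' @param newdata Tibble with the fit's covariate columns (default:
#'   training data).
#' @param type `"response"` (probability) or `"link"` (logit score).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.brt_fit <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  newdata <- newdata %||% object$data
  f <- rep(object$f0, nrow(newdata))
  nd <- newdata[object$covariates]
  for (tr in object$trees) f <- f + object$learning_rate * predict(tr, nd)
  if (type == "response") plogis(f) else f
}

#' Relative variable importance of a BRT fit
#'
#' Per-covariate sum, across every tree in the ensemble, of the squared
#' improvement attributable to its primary splits, normalized so the
#' importances are non-negative and sum to 100.
#'
#' @param fit A `brt_fit`.
#' @return Tibble `covariate`, `importance` (percent, descending).
#' @export
variable_importance <- function(fit) {
  stopifnot(inherits(fit, "brt_fit"))
  acc <- setNames(numeric(length(fit$covariates)), fit$covariates)
  for (tr in fit$trees) {
    vi <- tr$variable.importance
    if (!is.null(vi)) {
      vi <- vi[names(vi) %in% names(acc)]
      acc[names(vi)] <- acc[names(vi)] + vi
    }
  }
  tot <- sum(acc)
  imp <- if (tot > 0) 100 * acc / tot else
    rep(100 / length(acc), length(acc))
  tibble(covariate = names(acc), importance = as.numeric(imp)) |>
    arrange(dplyr::desc(.data$importance))
}

#' Partial dependence of a BRT fit on one covariate
#'
#' Averages the ensemble prediction over the training rows with the chosen
#' covariate clamped to each grid value (the marginal effect after
#' integrating out the other covariates empirically).
#'
#' @param fit A `brt_fit`.
#' @param covariate Covariate name.
#' @param grid Numeric grid; default 50 values across the training range.
#' @param type `"response"` or `"link"`.
#' @return Tibble `value`, `partial`.
#' @export
partial_dependence <- function(fit, covariate, grid = NULL,
                               type = c("response", "link")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "brt_fit"), covariate %in% fit$covariates)
  x <- fit$data[[covariate]]
  grid <- grid %||% seq(min(x), max(x), length.out = 50)
  partial <- map_dbl(grid, function(g) {
    nd <- fit$data
    nd[[covariate]] <- g
    mean(predict(fit, nd, type = type))
  })
  tibble(value = grid, partial = partial)
}

#' K-fold cross-validation metrics for a BRT configuration
#'
#' Refits the ensemble (at the fit's selected size) on K-1 folds and scores
#' the held-out fold, reporting fold-wise AUC and predictive deviance.
#' Metrics are invariant to row order up to the fold RNG seed.
#'
#' @param fit A `brt_fit`.
#' @param K Folds (default: the fit's `n_folds`).
#' @param seed Fold-assignment seed.
#' @return List with tibble `folds` and one-row `summary`.
#' @export
cv_evaluate <- function(fit, K = NULL, seed = 2L) {
  stopifnot(inherits(fit, "brt_fit"))
  K <- K %||% fit$n_folds
  data <- fit$data
  y <- data$label
  # fold assignment follows a canonical row ordering, so the metrics are
  # invariant to the row order of the training data
  canon <- do.call(order, unname(as.list(data)))
  with_subseed(seed, salt = 163L, {
    folds <- integer(nrow(data))
    folds[canon] <- sample(rep_len(seq_len(K), nrow(data)))
    rows <- map(seq_len(K), function(k) {
      tr <- data[folds != k, , drop = FALSE]
      trees_k <- boost_trees(tr, fit$covariates, tr$label, fit$f0,
                             fit$n_trees, fit$learning_rate,
                             fit$tree_complexity, fit$bag_fraction)
      f <- rep(fit$f0, sum(folds == k))
      nd <- data[folds == k, fit$covariates, drop = FALSE]
      for (t in trees_k) f <- f + fit$learning_rate * predict(t, nd)
      yk <- y[folds == k]
      tibble(fold = k,
             auc = if (length(unique(yk)) > 1) rank_auc(yk, f) else NA_real_,
             deviance = binomial_deviance(yk, plogis(f)))
    })
    folds_tbl <- list_rbind(rows)
    list(folds = folds_tbl,
         summary = summarise(folds_tbl,
                             auc_mean = mean(.data$auc, na.rm = TRUE),
                             auc_sd = sd(.data$auc, na.rm = TRUE),
                             deviance_mean = mean(.data$deviance),
                             deviance_sd = sd(.data$deviance)))
  })
}
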