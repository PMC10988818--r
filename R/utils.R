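#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across bind_rows bind_cols left_join n lag lead first last pull rename
#'   distinct count if_else row_number
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_lgl map2 pmap imap list_rbind
#' @importFrom stats dgamma rgamma rnorm runif rbinom optim plogis qlogis
#'   sd var cor median quantile approx setNames predict kmeans t.test lm
#'   anova complete.cases dnorm fitted residuals coef logLik
#' @importFrom utils head tail
NULL

# mean Earth radius used throughout (spherical model)
EARTH_RADIUS_KM <- 6371
KM_PER_DEG <- pi * EARTH_RADIUS_KM / 180 # 111.1949 km per degree of latitude

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised and
#' recycling over its arguments.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84 lon/lat).
#' @return Numeric vector of distances in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

#' Initial great-circle bearing between two points
#'
#' @inheritParams haversine_km
#' @return Bearing in degrees clockwise from north, in `[0, 360)`.
#' @export
step_bearing <- function(lon1, lat1, lon2, lat2) {
  same <- abs(lon1 - lon2) < 1e-12 & abs(lat1 - lat2) < 1e-12
  anti <- abs(lat1 + lat2) < 1e-9 & abs(((lon1 - lon2) %% 360) - 180) < 1e-9
  if (any(anti, na.rm = TRUE)) {
    abort("step_bearing(): antipodal points have no defined initial bearing.",
          class = "petrelwind_geometry_error")
  }
  b <- geosphere::bearing(cbind(lon1, lat1), cbind(lon2, lat2))
  b <- b %% 360
  b[same] <- NA_real_
  b
}

# displace (lon, lat) by d_km along bearing (deg); equirectangular step,
# adequate for the sub-degree hops used by the generators
move_point <- function(lon, lat, bearing_deg, d_km) {
  th <- bearing_deg * pi / 180
  dlat <- d_km * cos(th) / KM_PER_DEG
  lat2 <- lat + dlat
  dlon <- d_km * sin(th) / (KM_PER_DEG * cos((lat + lat2) / 2 * pi / 180))
  list(lon = lon + dlon, lat = lat2)
}

# wrap an angle in degrees to [0, 360)
wrap360 <- function(x) x %% 360

# wrap to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# wrap radians to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

# log density of a von Mises distribution centred at mu (radians)
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  lI0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  ld <- kappa * cos(x - mu) - log(2 * pi) - lI0
  if (log) ld else exp(ld)
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- min(length(th), m)
    if (take > 0) out[(got + 1):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  wrap_pi(out + mu)
}

# gamma (mean, sd) <-> (shape, rate)
gamma_shape <- function(mean, sd) (mean / sd)^2
gamma_rate <- function(mean, sd) mean / sd^2

# run code under a derived RNG seed without disturbing the caller's stream;
# `salt` splits one user seed into independent sub-streams per purpose
with_subseed <- function(seed, salt, code) {
  if (is.null(seed)) return(force(code))
  sub <- (as.double(seed) * 7919 + salt) %% 2147483647
  withr::with_seed(as.integer(sub), code)
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")),
          class = "petrelwind_input_error")
  }
  invisible(df)
}
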