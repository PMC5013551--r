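#' Simulate one speed profile of the layered kick model
#'
#' Draws the piecewise-constant speed trajectory of a single trip. Upward
#' kicks arrive as a Poisson process with per-phase rate `p = 2 * p_half` on
#' the first half of the trip, each raising the layer by one (capped at the
#' highest layer fully below `v_max`). The default construction reflects the
#' ascending half about the midpoint (`mode = "mirror"`), which guarantees
#' the profile returns to the base speed at the destination and realises the
#' symmetric accelerate/decelerate shape seen in free-flow speed profiles.
#' The alternative `mode = "independent"` draws descending kicks as a second
#' Poisson process at the same rate, floored at the base layer; it does not
#' enforce the terminal condition and is provided for sensitivity checks.
#'
#' @param t Trip duration in hours, positive.
#' @param params A [kick_params()] object.
#' @param mode `"mirror"` (default) or `"independent"`.
#' @return An object of class `speed_profile`: list with `kick_times`
#'   (sorted, within `[0, t]`), `speeds` (km/h, one per inter-kick
#'   interval, `length(kick_times) + 1` values), and `duration`.
#' @examples
#' set.seed(1)
#' simulate_kick_profile(1, kick_params(17.9, 20.9, 1.06))
#' @export
simulate_kick_profile <- function(t, params, mode = c("mirror", "independent")) {
  stopifnot(inherits(params, "kick_params"), is.numeric(t), length(t) == 1L)
  if (t <= 0) stop("'t' must be positive")
  mode <- match.arg(mode)
  n_cap <- params$n_layers
  n_up <- stats::rpois(1L, params$p * t / 2)
  up <- sort(stats::runif(n_up, 0, t / 2))
  if (mode == "mirror") {
    times <- c(up, rev(t - up))
    lev <- c(0L, seq_len(n_up), rev(seq_len(n_up) - 1L))
  } else {
    ## ascending kicks live in the first half, descending in the second, so
    ## the level path is 0..n_up then stepwise down, floored at the base layer
    n_dn <- stats::rpois(1L, params$p * t / 2)
    dn <- sort(stats::runif(n_dn, t / 2, t))
    times <- c(up, dn)
    lev <- c(0L, seq_len(n_up), pmax(n_up - seq_len(n_dn), 0L))
  }
  speeds <- params$v0 + pmin(lev, n_cap) * params$dv
  structure(list(kick_times = times, speeds = speeds, duration = t),
            class = "speed_profile")
}

#' Speed of a profile at given instants
#'
#' @param profile A [simulate_kick_profile()] result.
#' @param theta Time(s) within `[0, duration]`.
#' @return Speed(s) in km/h (right-continuous step function).
#' @export
profile_speed <- function(profile, theta) {
  stopifnot(inherits(profile, "speed_profile"), is.numeric(theta))
  if (any(theta < 0 | theta > profile$duration))
    stop("'theta' outside the trip duration")
  profile$speeds[findInterval(theta, profile$kick_times) + 1L]
}

#' Reduce a speed profile to a trip record
#'
#' The path length is the exact time integral of the piecewise-constant
#' speed (the area under the step function) and the mean speed is path
#' length over duration.
#'
#' @param profile A [simulate_kick_profile()] result.
#' @param vehicle_id Optional vehicle label.
#' @param t_start Optional trip start time (ISO 8601 string or `NA`).
#' @return One-row trip data.frame with columns `vehicle_id`, `t_start`,
#'   `duration_h`, `mean_speed_kmh`, `path_length_km`.
#' @export
trip_from_profile <- function(profile, vehicle_id = NA_character_,
                              t_start = NA_character_) {
  stopifnot(inherits(profile, "speed_profile"))
  widths <- diff(c(0, profile$kick_times, profile$duration))
  path <- sum(profile$speeds * widths)
  data.frame(vehicle_id = vehicle_id, t_start = t_start,
             duration_h = profile$duration,
             mean_speed_kmh = path / profile$duration,
             path_length_km = path,
             stringsAsFactors = FALSE)
}

#' Reduced sampler of the conditional speed law
#'
#' Samples mean trip speeds directly from the Poisson jump-count
#' representation: `k ~ Poisson(p_half * t)` and
#' `vbar = v0 + k * dv_half`, clipped at `v_max`. This is the generative
#' form whose binned statistics the fitting pipeline inverts; it omits the
#' kick-time spread of the full profile construction (the triangle
#' approximation made exact).
#'
#' @param t Trip duration(s) in hours, positive; one speed is drawn per
#'   element.
#' @param params A [kick_params()] object.
#' @return Mean speed(s) in km/h.
#' @examples
#' set.seed(1)
#' sample_mean_speed(rep(1, 5), kick_params(17.9, 20.9, 1.06))
#' @export
sample_mean_speed <- function(t, params) {
  stopifnot(inherits(params, "kick_params"), is.numeric(t))
  if (any(t <= 0)) stop("'t' must be positive")
  k <- stats::rpois(length(t), params$p_half * t)
  pmin(params$v0 + k * params$dv_half, params$v_max)
}

#' Simulate a population of kick-model trips
#'
#' Durations are drawn from the exponential travel-time law conditioned on
#' exceeding the trip filter threshold `t_min`: by memorylessness this is
#' `t_min + Exp(mean = t_bar - t_min)`, so the mean of the retained sample
#' is exactly `t_bar` (the quantity the travel-time fit reports). Per-trip
#' mean speeds come either from the reduced Poisson sampler
#' (`mode = "reduced"`, fast, the fitting pipeline's reference) or from full
#' mirror profiles (`mode = "profile"`).
#'
#' @param n Number of trips, at least 1.
#' @param params A [kick_params()] object.
#' @param mode `"reduced"` (default) or `"profile"`.
#' @param t_min Duration truncation threshold in hours (default 5 min);
#'   set 0 for the untruncated exponential law.
#' @param seed Optional integer seed for reproducibility.
#' @return Trip data.frame (`vehicle_id`, `t_start`, `duration_h`,
#'   `mean_speed_kmh`, `path_length_km`), with
#'   `path_length_km = mean_speed_kmh * duration_h`.
#' @examples
#' simulate_population(5, kick_params(17.9, 20.9, 1.06), seed = 1)
#' @export
simulate_population <- function(n, params, mode = c("reduced", "profile"),
                                t_min = 5 / 60, seed = NULL) {
  stopifnot(inherits(params, "kick_params"), is.numeric(n), length(n) == 1L)
  if (n < 1) stop("'n' must be at least 1")
  n <- as.integer(n)
  mode <- match.arg(mode)
  if (t_min < 0 || t_min >= params$t_bar)
    stop("'t_min' must lie in [0, t_bar)")
  if (!is.null(seed)) set.seed(seed)
  tt <- t_min + stats::rexp(n, 1 / (params$t_bar - t_min))
  if (mode == "reduced") {
    v <- sample_mean_speed(tt, params)
    data.frame(vehicle_id = sprintf("sim-%06d", seq_len(n)),
               t_start = NA_character_,
               duration_h = tt, mean_speed_kmh = v,
               path_length_km = v * tt, stringsAsFactors = FALSE)
  } else {
    rows <- lapply(seq_len(n), function(i) {
      trip_from_profile(simulate_kick_profile(tt[i], params),
                        vehicle_id = sprintf("sim-%06d", i))
    })
    do.call(rbind, rows)
  }
}

#' Simulate one trip of the Brownian-velocity null model
#'
#' Euler--Maruyama integration of the velocity random walk
#' \eqn{dv = \sqrt{D}\, d\xi} started at `v_drift`; the displacement is the
#' left-endpoint Riemann sum of the velocity path.
#'
#' @param t Trip duration in hours, positive.
#' @param params A [null_params()] object.
#' @param dt Integration step in hours; must satisfy `dt <= t / 100`.
#' @return List with `duration`, `displacement` (signed, km),
#'   `mean_velocity` (signed, km/h) and `mean_speed`
#'   (`abs(mean_velocity)`).
#' @examples
#' set.seed(1)
#' simulate_null_trip(1, null_params(D = 500))
#' @export
simulate_null_trip <- function(t, params, dt = t / 1e4) {
  stopifnot(inherits(params, "null_params"), is.numeric(t), length(t) == 1L)
  if (t <= 0) stop("'t' must be positive")
  if (dt > t / 100)
    stop("'dt' too coarse: use dt <= t/100 (got dt = ", dt, ")")
  n <- as.integer(ceiling(t / dt))
  dt <- t / n
  incr <- stats::rnorm(n, 0, sqrt(params$D * dt))
  v <- params$v_drift + c(0, cumsum(incr[-n]))
  x <- sum(v) * dt
  list(duration = t, displacement = x, mean_velocity = x / t,
       mean_speed = abs(x / t))
}

#' Simulate many null-model trips of a common duration
#'
#' Vectorised Euler--Maruyama over trips (one loop over time steps), used
#' for Monte-Carlo checks of the integrated-Brownian closed forms and the
#' \eqn{t^{1/2}} speed scaling.
#'
#' @param n Number of trips.
#' @param t Common trip duration in hours.
#' @param params A [null_params()] object.
#' @param n_steps Number of Euler steps (default 500).
#' @return data.frame with `displacement`, `mean_velocity`, `mean_speed`.
#' @export
simulate_null_population <- function(n, t, params, n_steps = 500L) {
  stopifnot(inherits(params, "null_params"), n >= 1, t > 0, n_steps >= 100)
  n <- as.integer(n); n_steps <- as.integer(n_steps)
  dt <- t / n_steps
  sd_i <- sqrt(params$D * dt)
  v <- rep(params$v_drift, n)
  x <- numeric(n)
  for (j in seq_len(n_steps)) {
    x <- x + v * dt
    v <- v + stats::rnorm(n, 0, sd_i)
  }
  data.frame(displacement = x, mean_velocity = x / t, mean_speed = abs(x / t))
}
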