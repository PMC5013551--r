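#' Describe a synthetic GPS fleet scenario
#'
#' Bundles everything the fleet generator needs: the kick-model parameters
#' driving trip durations and speed profiles, the rest-time law between
#' trips (5 min plus a lognormal, so every true stop exceeds the trip-end
#' threshold), position noise, artifact injection rates, and the fix
#' sampling rule (a fix at most every `max_fix_km` kilometres, or every
#' `highway_fix_s` seconds on roads at or above `highway_speed_kmh`).
#' The generator emulates the *structure* of insurance-device GPS logs --
#' engine events, sparse fixes, noise, micro-stops, signal loss -- not any
#' real road network.
#'
#' @param n_vehicles Number of vehicles.
#' @param days Number of simulated days per vehicle.
#' @param kick_params A [kick_params()] object (trip durations use its
#'   `t_bar` with the 5-min truncation).
#' @param rest_meanlog,rest_sdlog Lognormal parameters of the rest-time law
#'   in hours (defaults `log(0.75)` and 0.6); rests are 5 min plus this
#'   lognormal.
#' @param noise_sd_km Gaussian position noise s.d. in km (default 0.02,
#'   inside the 10--30 m device accuracy band; set 0 for exact round-trip
#'   tests).
#' @param micro_stop_rate,signal_loss_rate Per-trip artifact injection
#'   probabilities in `[0, 1]`.
#' @param micro_stop_s Duration of injected micro-stops in seconds
#'   (default 20, under the 30-s continuation rule).
#' @param max_fix_km,highway_fix_s,highway_speed_kmh Fix sampling rule.
#' @param t_min Trip duration truncation in hours (default 5 min).
#' @param area_tile_km Width of the square municipality tiles labelled
#'   A, B, C, ... along the route axis.
#' @param t0_s Epoch of the first day in seconds (default midnight
#'   2011-05-01 UTC).
#' @param seed Integer seed.
#' @return An object of class `synthetic_scenario`.
#' @examples
#' synthetic_scenario(n_vehicles = 3, seed = 7)
#' @export
synthetic_scenario <- function(n_vehicles = 10L, days = 1L,
                               kick_params = accelwalk::kick_params(
                                 17.9, 20.9, 1.06, t_bar = 0.30),
                               rest_meanlog = log(0.75), rest_sdlog = 0.6,
                               noise_sd_km = 0.02,
                               micro_stop_rate = 0, signal_loss_rate = 0,
                               micro_stop_s = 20,
                               max_fix_km = 2, highway_fix_s = 30,
                               highway_speed_kmh = 90,
                               t_min = 5 / 60, area_tile_km = 10,
                               t0_s = 1304208000, seed = 1L) {
  stopifnot(n_vehicles >= 1, days >= 1,
            inherits(kick_params, "kick_params"),
            micro_stop_rate >= 0, micro_stop_rate <= 1,
            signal_loss_rate >= 0, signal_loss_rate <= 1,
            noise_sd_km >= 0, max_fix_km > 0, highway_fix_s > 0)
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "Synthetic fleet scenario: %d vehicle(s) x %d day(s), noise %.0f m, micro-stop rate %.2f, signal-loss rate %.2f, seed %d\n",
    x$n_vehicles, x$days, 1000 * x$noise_sd_km, x$micro_stop_rate,
    x$signal_loss_rate, x$seed))
  invisible(x)
}

.area_label <- function(x, tile) LETTERS[(floor(x / tile) %% 26) + 1L]

## fix emission times for one profile under the sampling rule: at most
## `max_fix_km` of path or, at highway speeds, `highway_s` seconds between
## consecutive fixes (tracked across kick boundaries)
.profile_fix_times <- function(profile, max_fix_km, highway_s,
                               highway_speed) {
  bounds <- c(0, profile$kick_times, profile$duration)
  out_t <- numeric(0)
  d_since <- 0; t_since <- 0
  for (i in seq_along(profile$speeds)) {
    v <- profile$speeds[i]
    theta <- bounds[i]
    t_end <- bounds[i + 1L]
    repeat {
      dt_d <- (max_fix_km - d_since) / v
      dt_t <- if (v >= highway_speed) highway_s / 3600 - t_since else Inf
      dt <- min(dt_d, dt_t)
      if (theta + dt >= t_end - 1e-12) {
        d_since <- d_since + v * (t_end - theta)
        t_since <- t_since + (t_end - theta)
        break
      }
      theta <- theta + dt
      out_t <- c(out_t, theta)
      d_since <- 0; t_since <- 0
    }
  }
  out_t
}

## path distance along the profile at given instants
.profile_distance <- function(profile, theta) {
  bounds <- c(0, profile$kick_times, profile$duration)
  cum_d <- c(0, cumsum(profile$speeds * diff(bounds)))
  i <- findInterval(theta, bounds, rightmost.closed = TRUE)
  i <- pmin(i, length(profile$speeds))
  cum_d[i] + profile$speeds[i] * (theta - bounds[i])
}

#' Generate a ground-truthed synthetic GPS fleet log
#'
#' Simulates each vehicle as an alternation of kick-model trips and rests.
#' Trips run along a straight 1-D route (outbound on odd trips, inbound on
#' even ones); the route carries distance-parameterised road labels, one
#' per speed layer, so free-flow estimation has shared roads to aggregate.
#' Fixes are emitted under the sampling rule, Gaussian position noise is
#' added, and micro-stop / signal-loss artifacts are injected at the
#' configured per-trip rates. Every trip, rest and injected artifact is
#' recorded in the ground-truth tables, so extraction quality can be scored
#' exactly.
#'
#' @param scenario A [synthetic_scenario()] object.
#' @return List with `events` (the event-log data.frame, including
#'   `road_id` and `area_id` columns) and `truth`, itself a list of
#'   `trips` (per-trip wall-clock duration in hours -- including injected
#'   micro-stops -- path length, mean speed, start time), `rests`
#'   (planned rest intervals) and `artifacts` (type, vehicle, time of each
#'   injection).
#' @examples
#' fleet <- generate_fleet_log(synthetic_scenario(n_vehicles = 2, seed = 3))
#' table(fleet$events$kind)
#' @export
generate_fleet_log <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  set.seed(sc$seed)
  p <- sc$kick_params
  events <- list(); truth_trips <- list(); truth_rests <- list()
  artifacts <- list()
  horizon <- sc$days * 86400
  for (v in seq_len(sc$n_vehicles)) {
    vid <- sprintf("veh-%04d", v)
    home_x <- stats::runif(1, 1, 3 * sc$area_tile_km - 1)
    x <- home_x
    tcur <- sc$t0_s + 300 + stats::rlnorm(1, sc$rest_meanlog,
                                          sc$rest_sdlog) * 3600
    k <- 0L
    while (tcur < sc$t0_s + horizon) {
      k <- k + 1L
      dir <- if (k %% 2L == 1L) 1 else -1
      tt <- sc$t_min + stats::rexp(1, 1 / (p$t_bar - sc$t_min))
      prof <- simulate_kick_profile(tt, p)
      fix_t <- .profile_fix_times(prof, sc$max_fix_km, sc$highway_fix_s,
                                  sc$highway_speed_kmh)
      fix_d <- .profile_distance(prof, fix_t)
      path <- .profile_distance(prof, tt)
      spd <- profile_speed(prof, fix_t)
      layer <- round((spd - p$v0) / p$dv)
      ## event skeleton in trip-relative seconds
      rel_s <- c(0, fix_t * 3600, tt * 3600)
      xs <- x + dir * c(0, fix_d, path)
      kind <- c("engine_start", rep("fix", length(fix_t)), "engine_stop")
      road <- c(sprintf("L%d-road", 0L), sprintf("L%d-road", layer),
                sprintf("L%d-road", 0L))
      wall_h <- tt
      ## micro-stop artifact: a short mid-trip engine-off pause
      if (stats::runif(1) < sc$micro_stop_rate) {
        t_ms <- tt * 3600 / 2
        d_ms <- .profile_distance(prof, t_ms / 3600)
        l_ms <- round((profile_speed(prof, t_ms / 3600) - p$v0) / p$dv)
        after <- rel_s > t_ms
        rel_s <- c(rel_s[!after], t_ms, t_ms + sc$micro_stop_s,
                   rel_s[after] + sc$micro_stop_s)
        xs <- c(xs[!after], x + dir * d_ms, x + dir * d_ms, xs[after])
        kind <- c(kind[!after], "engine_stop", "engine_start", kind[after])
        road <- c(road[!after], rep(sprintf("L%d-road", l_ms), 2),
                  road[after])
        wall_h <- tt + sc$micro_stop_s / 3600
        artifacts[[length(artifacts) + 1L]] <- data.frame(
          vehicle_id = vid, type = "micro_stop",
          time_s = tcur + t_ms, stringsAsFactors = FALSE)
      }
      ys <- numeric(length(xs))
      ## signal-loss artifact: the recorded ignition position is stale
      ## (needs a previous stop to correct against, so not on trip 1)
      if (k > 1L && stats::runif(1) < sc$signal_loss_rate) {
        off <- stats::runif(1, 0.3, 1)
        ang <- stats::runif(1, 0, 2 * pi)
        xs[1] <- xs[1] + off * cos(ang)
        ys[1] <- ys[1] + off * sin(ang)
        artifacts[[length(artifacts) + 1L]] <- data.frame(
          vehicle_id = vid, type = "signal_loss", time_s = tcur,
          stringsAsFactors = FALSE)
      }
      if (sc$noise_sd_km > 0) {
        xs <- xs + stats::rnorm(length(xs), 0, sc$noise_sd_km)
        ys <- ys + stats::rnorm(length(ys), 0, sc$noise_sd_km)
      }
      events[[length(events) + 1L]] <- data.frame(
        vehicle_id = vid, time_s = tcur + rel_s, x_km = xs, y_km = ys,
        kind = kind, road_id = road,
        area_id = .area_label(xs, sc$area_tile_km),
        stringsAsFactors = FALSE)
      truth_trips[[length(truth_trips) + 1L]] <- data.frame(
        vehicle_id = vid, trip_index = k, t_start_s = tcur,
        duration_h = wall_h, path_length_km = path,
        mean_speed_kmh = path / tt, stringsAsFactors = FALSE)
      x <- x + dir * path
      t_end <- tcur + wall_h * 3600
      rest <- 300 + stats::rlnorm(1, sc$rest_meanlog, sc$rest_sdlog) * 3600
      truth_rests[[length(truth_rests) + 1L]] <- data.frame(
        vehicle_id = vid, t_off_s = t_end, t_on_s = t_end + rest,
        rest_s = rest, stringsAsFactors = FALSE)
      tcur <- t_end + rest
    }
  }
  list(events = do.call(rbind, c(events, make.row.names = FALSE)),
       truth = list(
         trips = do.call(rbind, c(truth_trips, make.row.names = FALSE)),
         rests = do.call(rbind, c(truth_rests, make.row.names = FALSE)),
         artifacts = if (length(artifacts))
           do.call(rbind, c(artifacts, make.row.names = FALSE))
         else data.frame(vehicle_id = character(), type = character(),
                         time_s = numeric(), stringsAsFactors = FALSE)))
}

#' Generate a trip-table fixture
#'
#' Thin wrapper around [simulate_population()] that optionally writes the
#' canonical trip CSV; the direct trip-level fixture for the fitting
#' pipeline.
#'
#' @param n Number of trips.
#' @param params A [kick_params()] object.
#' @param t_min Duration truncation in hours (default 5 min).
#' @param seed Integer seed.
#' @param path Optional CSV output path.
#' @return The trip data.frame (invisibly when `path` is given).
#' @export
generate_trip_table <- function(n, params, t_min = 5 / 60, seed = 1L,
                                path = NULL) {
  trips <- simulate_population(n, params, mode = "reduced", t_min = t_min,
                               seed = seed)
  if (!is.null(path)) {
    write_trips_csv(trips, path)
    return(invisible(trips))
  }
  trips
}
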