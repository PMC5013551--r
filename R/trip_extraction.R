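## Internal event-log conventions: a data.frame with columns
##   vehicle_id, time_s (numeric seconds), x_km, y_km,
##   kind in {engine_start, fix, engine_stop}, road_id (optional), quality
## Distances are Euclidean in planar km; lon/lat files are projected at the
## I/O boundary (see read_events_csv).

.dist2d <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

.check_event_log <- function(events) {
  need <- c("vehicle_id", "time_s", "x_km", "y_km", "kind")
  if (!all(need %in% names(events)))
    stop("event log must have columns: ", paste(need, collapse = ", "))
  if (!"road_id" %in% names(events)) events$road_id <- NA_character_
  bad <- !events$kind %in% c("engine_start", "fix", "engine_stop")
  if (any(bad)) stop("unknown event kind: ", events$kind[which(bad)[1]])
  events
}

## split one vehicle's chronological events into engine-on segments
## (engine_start ... fixes ... engine_stop); errors name the vehicle and
## the offending timestamp
.vehicle_segments <- function(ev, vid) {
  if (is.unsorted(ev$time_s, strictly = TRUE))
    stop("events not strictly increasing in time for vehicle ", vid,
         " at t = ", ev$time_s[which(diff(ev$time_s) <= 0)[1] + 1L])
  starts <- which(ev$kind == "engine_start")
  stops <- which(ev$kind == "engine_stop")
  if (length(starts) != length(stops) || any(stops < starts))
    stop("engine events do not alternate start/stop for vehicle ", vid)
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:stops[i]
    if (any(ev$kind[idx[-c(1, length(idx))]] != "fix"))
      stop("interleaved engine events for vehicle ", vid,
           " at t = ", ev$time_s[starts[i]])
    ev[idx, , drop = FALSE]
  })
}

## TRUE if the motion after a short gap heads back toward the origin of the
## pre-gap trip: displacement bearing within `angle_deg` of the bearing to
## the origin AND origin distance decreasing over the first `n_probe` fixes
.back_toward_origin <- function(seg, origin_xy, angle_deg = 30,
                                n_probe = 3L) {
  pts <- seg[, c("x_km", "y_km"), drop = FALSE]
  if (nrow(pts) < 2) return(FALSE)
  n <- min(n_probe + 1L, nrow(pts))
  dx <- pts$x_km[n] - pts$x_km[1]
  dy <- pts$y_km[n] - pts$y_km[1]
  if (dx == 0 && dy == 0) return(FALSE)
  ox <- origin_xy[1] - pts$x_km[1]
  oy <- origin_xy[2] - pts$y_km[1]
  if (ox == 0 && oy == 0) return(FALSE)
  cosang <- (dx * ox + dy * oy) /
    (sqrt(dx^2 + dy^2) * sqrt(ox^2 + oy^2))
  d_orig <- .dist2d(pts$x_km[1:n], pts$y_km[1:n], origin_xy[1], origin_xy[2])
  cosang >= cos(angle_deg * pi / 180) && all(diff(d_orig) < 0)
}

#' Segment an engine-event log into trips and stops
#'
#' Applies the trip-definition rules to a per-vehicle stream of engine
#' starts/stops and position fixes. An engine-off interval of at least
#' `stop_threshold` (default 5 min) ends a trip and becomes a stop; shorter
#' intervals merge the surrounding driving segments into one trip -- for
#' gaps under `micro_stop` (default 30 s) the merge is unconditional unless
#' the post-gap motion heads back toward the origin of the pre-gap segment
#' (bearing within `back_angle` degrees of the origin direction and origin
#' distance decreasing over the first three fixes), in which case the trip
#' is split. Trip duration is wall-clock from the first engine start to the
#' final engine stop of the merged run (merged micro-gaps count as driving
#' time and are totalled in the output); path length sums fix-to-fix
#' Euclidean distances, including across merged gaps.
#'
#' @param events Event-log data.frame (see [read_events_csv()]); must be
#'   chronologically sorted within vehicle.
#' @param stop_threshold Trip-ending engine-off threshold in seconds
#'   (default 300).
#' @param micro_stop Unconditional-merge threshold in seconds (default 30).
#' @param back_angle Half-angle in degrees of the "back toward origin"
#'   cone (default 30).
#' @return List with `trips` (one row per trip: `vehicle_id`, `trip_id`,
#'   `t_start_s`, `t_end_s`, `duration_h`, `path_length_km`,
#'   `straight_line_km`, `mean_speed_kmh`, `n_merged_gaps`,
#'   `merged_gap_s`, origin and destination coordinates), `stops` (one row
#'   per engine-off interval of at least `stop_threshold`: `vehicle_id`,
#'   `t_off_s`, `t_on_s`, `x_km`, `y_km`, `area_id` if present in the
#'   events), and `fixes` (per-trip position stream with `trip_id`,
#'   `time_s`, `x_km`, `y_km`, `road_id`, used by the free-flow profile).
#' @examples
#' log <- generate_fleet_log(synthetic_scenario(n_vehicles = 2, seed = 1))
#' seg <- segment_trips(log$events)
#' head(seg$trips)
#' @export
segment_trips <- function(events, stop_threshold = 300, micro_stop = 30,
                          back_angle = 30) {
  events <- .check_event_log(events)
  trips <- list(); stops <- list(); fixes <- list()
  for (vid in unique(events$vehicle_id)) {
    ev <- events[events$vehicle_id == vid, , drop = FALSE]
    segs <- .vehicle_segments(ev, vid)
    if (!length(segs)) next
    ## decide, for each inter-segment gap, whether it splits the trip
    n_seg <- length(segs)
    split_after <- logical(max(n_seg - 1L, 0L))
    run_origin <- c(segs[[1]]$x_km[1], segs[[1]]$y_km[1])
    for (i in seq_len(n_seg - 1L)) {
      gap <- segs[[i + 1L]]$time_s[1] - segs[[i]]$time_s[nrow(segs[[i]])]
      split_after[i] <-
        if (gap >= stop_threshold) TRUE
        else if (gap < micro_stop)
          .back_toward_origin(segs[[i + 1L]], run_origin, back_angle)
        else FALSE
      if (split_after[i])
        run_origin <- c(segs[[i + 1L]]$x_km[1], segs[[i + 1L]]$y_km[1])
    }
    run_id <- cumsum(c(0L, split_after)) + 1L
    for (r in unique(run_id)) {
      ss <- segs[run_id == r]
      pts <- do.call(rbind, lapply(ss, function(s)
        s[, c("time_s", "x_km", "y_km", "road_id"), drop = FALSE]))
      t0 <- ss[[1]]$time_s[1]
      t1 <- ss[[length(ss)]]$time_s[nrow(ss[[length(ss)]])]
      path <- sum(.dist2d(pts$x_km[-nrow(pts)], pts$y_km[-nrow(pts)],
                          pts$x_km[-1], pts$y_km[-1]))
      gaps_s <- if (length(ss) > 1)
        sum(vapply(seq_len(length(ss) - 1L), function(i)
          ss[[i + 1L]]$time_s[1] - ss[[i]]$time_s[nrow(ss[[i]])],
          numeric(1)))
      else 0
      tid <- sprintf("%s-%03d", vid, r)
      trips[[tid]] <- data.frame(
        vehicle_id = vid, trip_id = tid, t_start_s = t0, t_end_s = t1,
        duration_h = (t1 - t0) / 3600, path_length_km = path,
        straight_line_km = .dist2d(pts$x_km[1], pts$y_km[1],
                                   pts$x_km[nrow(pts)], pts$y_km[nrow(pts)]),
        mean_speed_kmh = path / ((t1 - t0) / 3600),
        n_merged_gaps = length(ss) - 1L, merged_gap_s = gaps_s,
        x_origin_km = pts$x_km[1], y_origin_km = pts$y_km[1],
        x_dest_km = pts$x_km[nrow(pts)], y_dest_km = pts$y_km[nrow(pts)],
        stringsAsFactors = FALSE)
      pts$vehicle_id <- vid; pts$trip_id <- tid
      fixes[[tid]] <- pts
    }
    ## stops: trip-ending engine-off intervals
    if (n_seg > 1) for (i in which(split_after)) {
      off <- segs[[i]][nrow(segs[[i]]), ]
      on <- segs[[i + 1L]][1, ]
      gap <- on$time_s - off$time_s
      if (gap < stop_threshold) next  # back-toward-origin split, not a rest
      stops[[length(stops) + 1L]] <- data.frame(
        vehicle_id = vid, t_off_s = off$time_s, t_on_s = on$time_s,
        x_km = off$x_km, y_km = off$y_km,
        area_id = if ("area_id" %in% names(off)) off$area_id
                  else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  list(trips = if (length(trips)) do.call(rbind, c(trips, make.row.names = FALSE))
               else NULL,
       stops = if (length(stops)) do.call(rbind, c(stops, make.row.names = FALSE))
               else NULL,
       fixes = if (length(fixes)) do.call(rbind, c(fixes, make.row.names = FALSE))
               else NULL)
}

#' Correct signal-loss artifacts at trip starts
#'
#' When the GPS fix is acquired some distance into a trip (signal loss at
#' ignition, underground parking), the recorded trip origin is wrong but
#' redundant information is available: the vehicle necessarily starts where
#' it last stopped. For every engine start lying farther than
#' `snap_threshold` from the previous engine stop of the same vehicle, the
#' start position is replaced by the previous stop position; subsequent
#' segmentation then recovers the missing initial path. Corrections are
#' counted.
#'
#' @param events Event-log data.frame, chronologically sorted per vehicle.
#' @param snap_threshold Distance in km beyond which an origin is snapped
#'   (default 0.1 km, well above the 10--30 m position noise).
#' @return List with `events` (corrected log) and `n_corrected`.
#' @export
correct_signal_loss <- function(events, snap_threshold = 0.1) {
  events <- .check_event_log(events)
  n_corrected <- 0L
  for (vid in unique(events$vehicle_id)) {
    idx <- which(events$vehicle_id == vid)
    ev <- events[idx, ]
    last_stop <- NA_integer_
    for (j in seq_len(nrow(ev))) {
      if (ev$kind[j] == "engine_stop") last_stop <- j
      if (ev$kind[j] == "engine_start" && !is.na(last_stop)) {
        d <- .dist2d(ev$x_km[j], ev$y_km[j],
                     ev$x_km[last_stop], ev$y_km[last_stop])
        if (d > snap_threshold) {
          events$x_km[idx[j]] <- ev$x_km[last_stop]
          events$y_km[idx[j]] <- ev$y_km[last_stop]
          n_corrected <- n_corrected + 1L
        }
      }
    }
  }
  list(events = events, n_corrected = n_corrected)
}

#' Filter trips by minimum length and duration
#'
#' Keeps trips strictly longer than `min_length` km and strictly longer
#' than `min_duration` hours (very short trips never reach the base speed
#' the model assumes). Survivors are returned unchanged.
#'
#' @param trips Trip data.frame with `path_length_km` and `duration_h`.
#' @param min_length Minimum path length in km (default 1).
#' @param min_duration Minimum duration in hours (default 5 min).
#' @return The surviving rows of `trips`.
#' @export
filter_trips <- function(trips, min_length = 1, min_duration = 5 / 60) {
  stopifnot(is.data.frame(trips),
            all(c("path_length_km", "duration_h") %in% names(trips)))
  trips[trips$path_length_km > min_length &
          trips$duration_h > min_duration, , drop = FALSE]
}

#' Free-flow speed of each road
#'
#' The free-flow (uncongested) speed of a road is estimated as the 85th
#' percentile of the observed travel speeds on it, computed with linear
#' interpolation between order statistics (R quantile type 7). Roads with
#' fewer than `min_n` samples are reported but flagged low-confidence.
#'
#' @param samples data.frame with `road_id` and `speed_kmh` (one row per
#'   traversal speed observation).
#' @param prob Percentile (default 0.85).
#' @param min_n Minimum sample count for a confident estimate (default 20).
#' @return data.frame with `road_id`, `free_flow_kmh`, `n`,
#'   `low_confidence`.
#' @examples
#' s <- data.frame(road_id = "a", speed_kmh = 1:100)
#' free_flow_speed(s)$free_flow_kmh # 85.15
#' @export
free_flow_speed <- function(samples, prob = 0.85, min_n = 20L) {
  stopifnot(is.data.frame(samples),
            all(c("road_id", "speed_kmh") %in% names(samples)))
  if (any(samples$speed_kmh <= 0)) stop("speeds must be positive")
  ids <- unique(samples$road_id)
  out <- do.call(rbind, lapply(ids, function(r) {
    sp <- samples$speed_kmh[samples$road_id == r]
    data.frame(road_id = r,
               free_flow_kmh = unname(stats::quantile(sp, prob, type = 7)),
               n = length(sp), low_confidence = length(sp) < min_n,
               stringsAsFactors = FALSE)
  }))
  if (any(out$low_confidence))
    warning(sum(out$low_confidence),
            " road(s) have fewer than ", min_n, " samples")
  out
}

#' Aggregated free-flow speed profile over relative trip time
#'
#' For each trip in a duration band, looks up the free-flow speed of the
#' road under each fix, resamples the resulting step series to relative
#' trip time theta/t in `[0, 1]`, averages across trips and normalizes by
#' the maximum. A mid-trip peak of this curve is the signature of the
#' accelerate-then-decelerate use of the road hierarchy.
#'
#' @param fixes Per-trip fix data.frame from [segment_trips()] (`trip_id`,
#'   `time_s`, `road_id`).
#' @param trips Matching trip data.frame (`trip_id`, `t_start_s`,
#'   `t_end_s`, `duration_h`).
#' @param ff_table [free_flow_speed()] output.
#' @param duration_center_h Centre of the duration band in hours.
#' @param duration_halfwidth_h Half-width of the band (default 0.1 h).
#' @param n_rel Number of relative-time grid points (default 51).
#' @return data.frame with `rel_time` and `rel_speed` (max = 1); the
#'   number of trips lacking road annotations is attached as attribute
#'   `n_skipped`.
#' @export
free_flow_profile <- function(fixes, trips, ff_table, duration_center_h,
                              duration_halfwidth_h = 0.1, n_rel = 51L) {
  stopifnot(is.data.frame(fixes), is.data.frame(trips),
            is.data.frame(ff_table))
  band <- trips[abs(trips$duration_h - duration_center_h) <=
                  duration_halfwidth_h, , drop = FALSE]
  if (!nrow(band)) stop("no trips in the requested duration band")
  grid <- seq(0, 1, length.out = n_rel)
  acc <- matrix(NA_real_, nrow(band), n_rel)
  skipped <- 0L
  for (i in seq_len(nrow(band))) {
    fx <- fixes[fixes$trip_id == band$trip_id[i], , drop = FALSE]
    ff <- ff_table$free_flow_kmh[match(fx$road_id, ff_table$road_id)]
    ok <- !is.na(ff)
    if (sum(ok) < 2) { skipped <- skipped + 1L; next }
    rel <- (fx$time_s[ok] - band$t_start_s[i]) /
      (band$t_end_s[i] - band$t_start_s[i])
    acc[i, ] <- stats::approx(rel, ff[ok], xout = grid, method = "constant",
                              rule = 2, ties = "ordered")$y
  }
  prof <- colMeans(acc, na.rm = TRUE)
  if (all(is.na(prof))) stop("no annotated trips in the duration band")
  out <- data.frame(rel_time = grid, rel_speed = prof / max(prof))
  attr(out, "n_skipped") <- skipped
  out
}

#' Assign a residence area to each vehicle
#'
#' A vehicle is assigned to the area where it spends the largest share of
#' its total parking time. Ties are broken toward the area observed
#' earliest in the stop stream, with a warning.
#'
#' @param stops Stop data.frame (`vehicle_id`, `t_off_s`, `t_on_s`,
#'   `area_id`); stops with missing `area_id` are ignored.
#' @return data.frame with `vehicle_id`, `area_id` (`NA` when no labelled
#'   stop exists), `hours_in_area`, `share`.
#' @export
assign_residence <- function(stops) {
  stopifnot(is.data.frame(stops),
            all(c("vehicle_id", "t_off_s", "t_on_s", "area_id") %in%
                  names(stops)))
  if (any(stops$t_on_s <= stops$t_off_s, na.rm = TRUE))
    stop("stop intervals must have t_on > t_off")
  out <- lapply(unique(stops$vehicle_id), function(vid) {
    st <- stops[stops$vehicle_id == vid & !is.na(stops$area_id), ,
                drop = FALSE]
    if (!nrow(st))
      return(data.frame(vehicle_id = vid, area_id = NA_character_,
                        hours_in_area = 0, share = NA_real_,
                        stringsAsFactors = FALSE))
    dur <- (st$t_on_s - st$t_off_s) / 3600
    ## keep first-observed order for the tie rule
    areas <- unique(st$area_id)
    tot <- vapply(areas, function(a) sum(dur[st$area_id == a]), numeric(1))
    best <- which(tot == max(tot))
    if (length(best) > 1)
      warning("residence tie for vehicle ", vid,
              "; keeping first-observed area ", areas[best[1]])
    data.frame(vehicle_id = vid, area_id = areas[best[1]],
               hours_in_area = tot[best[1]], share = tot[best[1]] / sum(dur),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}
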