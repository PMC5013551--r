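## CSV dialects. Trip tables: vehicle_id, t_start_iso, duration_h,
## mean_speed_kmh, path_length_km. Event logs: vehicle_id, timestamp_iso,
## x_km, y_km (or lon, lat), kind, road_id, quality. Timestamps are ISO 8601
## UTC at second resolution; internal time is numeric seconds.

.iso_to_s <- function(x) {
  out <- as.numeric(as.POSIXct(x, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%S"))
  if (any(is.na(out) & !is.na(x)))
    stop("unparseable ISO 8601 timestamp: ", x[which(is.na(out) & !is.na(x))[1]])
  out
}

.s_to_iso <- function(x)
  format(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%S")

#' Write / read trip tables as CSV
#'
#' Canonical trip CSV columns: `vehicle_id`, `t_start_iso`, `duration_h`,
#' `mean_speed_kmh`, `path_length_km`. Extra columns present in the
#' data.frame are preserved.
#'
#' @param trips Trip data.frame.
#' @param path CSV path.
#' @return `write_trips_csv` returns `path` invisibly; `read_trips_csv` a
#'   trip data.frame.
#' @export
write_trips_csv <- function(trips, path) {
  stopifnot(is.data.frame(trips))
  need <- c("vehicle_id", "duration_h", "mean_speed_kmh", "path_length_km")
  if (!all(need %in% names(trips)))
    stop("trip table must have columns: ", paste(need, collapse = ", "))
  if (!"t_start" %in% names(trips) && !"t_start_iso" %in% names(trips))
    trips$t_start_iso <- NA_character_
  if ("t_start" %in% names(trips)) {
    names(trips)[names(trips) == "t_start"] <- "t_start_iso"
  }
  first <- c("vehicle_id", "t_start_iso", "duration_h", "mean_speed_kmh",
             "path_length_km")
  trips <- trips[, c(first, setdiff(names(trips), first)), drop = FALSE]
  utils::write.csv(trips, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trips_csv
#' @export
read_trips_csv <- function(path) {
  if (!file.exists(path)) stop("no such trip table: ", path)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vehicle_id", "duration_h", "mean_speed_kmh", "path_length_km")
  if (!all(need %in% names(tr)))
    stop("malformed trip CSV (", path, "): need columns ",
         paste(need, collapse = ", "))
  tr
}

#' Write / read GPS event logs as CSV
#'
#' Event CSV columns: `vehicle_id`, `timestamp_iso`, `x_km`, `y_km` (planar
#' kilometres) or `lon`, `lat` (degrees; converted to a local planar frame
#' about the mean coordinate on read, using the spherical-earth metric),
#' `kind` (`engine_start`/`fix`/`engine_stop`), and optional `road_id`,
#' `quality`, `area_id`.
#'
#' @param events Event data.frame with internal `time_s` column.
#' @param path CSV path.
#' @return `write_events_csv` returns `path` invisibly; `read_events_csv`
#'   the internal event data.frame (`time_s` in seconds, planar km).
#' @export
write_events_csv <- function(events, path) {
  events <- .check_event_log(events)
  out <- events
  out$timestamp_iso <- .s_to_iso(out$time_s)
  out$time_s <- NULL
  first <- c("vehicle_id", "timestamp_iso", "x_km", "y_km", "kind")
  out <- out[, c(first, setdiff(names(out), first)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("no such event log: ", path)
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"timestamp_iso" %in% names(ev))
    stop("malformed event CSV (", path, "): missing timestamp_iso")
  ev$time_s <- .iso_to_s(ev$timestamp_iso)
  ev$timestamp_iso <- NULL
  if (all(c("lon", "lat") %in% names(ev))) {
    r_earth <- 6371.0088
    lat0 <- mean(ev$lat) * pi / 180
    lon0 <- mean(ev$lon) * pi / 180
    ev$x_km <- r_earth * cos(lat0) * (ev$lon * pi / 180 - lon0)
    ev$y_km <- r_earth * (ev$lat * pi / 180 - lat0)
    ev$lon <- NULL; ev$lat <- NULL
  }
  .check_event_log(ev)
}
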