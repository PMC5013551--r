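test_that("engine-off gaps split or merge trips according to the two thresholds", {
  ## 4-min gap: merged into one trip whose duration includes the gap
  a <- toy_segment("v1", 0, c(0, 0), 30, 600)
  b <- toy_segment("v1", 600 + 240, c(5, 0), 30, 600)
  seg <- segment_trips(rbind(a, b))
  expect_equal(nrow(seg$trips), 1)
  expect_equal(seg$trips$duration_h, 1440 / 3600)
  expect_equal(seg$trips$n_merged_gaps, 1L)
  expect_equal(seg$trips$merged_gap_s, 240)
  expect_null(seg$stops)
  ## engine-on time conservation: duration = on-time + merged gaps
  expect_equal(seg$trips$duration_h * 3600, 1200 + seg$trips$merged_gap_s)

  ## 6-min gap: two trips and one 6-min stop
  b2 <- toy_segment("v1", 600 + 360, c(5, 0), 30, 600)
  seg2 <- segment_trips(rbind(a, b2))
  expect_equal(nrow(seg2$trips), 2)
  expect_equal(nrow(seg2$stops), 1)
  expect_equal(seg2$stops$t_on_s - seg2$stops$t_off_s, 360)
  expect_equal(seg2$trips$duration_h, c(600, 600) / 3600)
})

test_that("a sub-30-s gap splits only when motion turns back toward the origin", {
  a <- toy_segment("v2", 0, c(0, 0), 30, 600)
  ## forward continuation: unconditional merge
  fwd <- toy_segment("v2", 620, c(5, 0), 30, 600)
  expect_equal(nrow(segment_trips(rbind(a, fwd))$trips), 1)
  ## reversal toward the origin of the previous segment: split
  back <- toy_segment("v2", 620, c(5, 0), 30, 600, dir = c(-1, 0))
  seg <- segment_trips(rbind(a, back))
  expect_equal(nrow(seg$trips), 2)
  ## a reversal split is not a rest: no stop interval is recorded
  expect_null(seg$stops)
  ## sideways motion (perpendicular to the origin bearing): merge
  side <- toy_segment("v2", 620, c(5, 0), 30, 600, dir = c(0, 1))
  expect_equal(nrow(segment_trips(rbind(a, side))$trips), 1)
})

test_that("malformed logs are rejected with the vehicle named", {
  a <- toy_segment("v3", 0, c(0, 0), 30, 600)
  bad <- a[c(2, 1, 3:nrow(a)), ]
  expect_error(segment_trips(bad), "v3")
  nostop <- a[-nrow(a), ]
  expect_error(segment_trips(nostop), "alternate")
})

test_that("signal-loss correction snaps trip origins to the previous stop", {
  a <- toy_segment("v4", 0, c(0, 0), 30, 600) # ends at (5, 0)
  ## next ignition recorded 0.5 km away from where the vehicle stopped
  b <- toy_segment("v4", 1200, c(5.5, 0), 30, 600)
  log <- rbind(a, b)
  corr <- correct_signal_loss(log, snap_threshold = 0.1)
  expect_equal(corr$n_corrected, 1L)
  path_raw <- segment_trips(log)$trips$path_length_km
  path_fix <- segment_trips(corr$events)$trips$path_length_km
  expect_equal(path_fix[2] - path_raw[2], 0.5, tolerance = 1e-9)
  ## coincident origin: nothing to correct
  b0 <- toy_segment("v4", 1200, c(5, 0), 30, 600)
  expect_equal(correct_signal_loss(rbind(a, b0))$n_corrected, 0L)
})

test_that("signal-loss corrections match the injected artifacts exactly", {
  sc <- synthetic_scenario(n_vehicles = 4, days = 1, noise_sd_km = 0,
                           signal_loss_rate = 0.5, seed = 41)
  fleet <- generate_fleet_log(sc)
  injected <- sum(fleet$truth$artifacts$type == "signal_loss")
  expect_gt(injected, 0)
  corr <- correct_signal_loss(fleet$events)
  expect_equal(corr$n_corrected, injected)
})

test_that("the trip filter keeps exactly the qualifying trips", {
  expect_equal(nrow(filter_trips(
    data.frame(path_length_km = 0.9, duration_h = 10 / 60))), 0)
  expect_equal(nrow(filter_trips(
    data.frame(path_length_km = 1.5, duration_h = 4 / 60))), 0)
  fixture <- read_trips_csv(system.file("extdata",
                                        "filter_fixture_trips.csv",
                                        package = "accelwalk"))
  expect_equal(nrow(fixture), 7)
  expect_equal(nrow(filter_trips(fixture)), 3)
})

test_that("free-flow speed is the interpolated 85th percentile", {
  s <- data.frame(road_id = "a", speed_kmh = 1:100)
  expect_equal(free_flow_speed(s, min_n = 10)$free_flow_kmh, 85.15)
  same <- data.frame(road_id = "b", speed_kmh = rep(64, 30))
  expect_equal(free_flow_speed(same)$free_flow_kmh, 64)
  expect_warning(free_flow_speed(data.frame(road_id = "c",
                                            speed_kmh = runif(5, 10, 20))),
                 "fewer")
})

test_that("free-flow speed equals a sort-based oracle on random multisets", {
  ## independent oracle: linear interpolation between order statistics
  oracle <- function(x, p = 0.85) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(5:50, 1)
    x <- round(runif(n, 5, 130), 3)
    got <- suppressWarnings(
      free_flow_speed(data.frame(road_id = "r", speed_kmh = x)))
    expect_equal(got$free_flow_kmh, oracle(x), tolerance = 1e-9)
  }
})

test_that("free-flow profiles are symmetric for symmetric road sequences", {
  n_rel <- 51L
  tt <- seq(0, 3600, length.out = n_rel)
  ## symmetric slow-fast-slow road sequence along the trip
  road <- rep("slow", n_rel)
  road[tt / 3600 > 0.267 & tt / 3600 < 0.733] <- "fast"
  fixes <- data.frame(vehicle_id = "v5", trip_id = "v5-001", time_s = tt,
                      x_km = 0, y_km = 0, road_id = road,
                      stringsAsFactors = FALSE)
  trips <- data.frame(trip_id = "v5-001", t_start_s = 0, t_end_s = 3600,
                      duration_h = 1, stringsAsFactors = FALSE)
  ff <- data.frame(road_id = c("slow", "fast"), free_flow_kmh = c(40, 100))
  prof <- free_flow_profile(fixes, trips, ff, duration_center_h = 1,
                            n_rel = n_rel)
  expect_equal(max(prof$rel_speed), 1)
  expect_equal(prof$rel_speed, rev(prof$rel_speed), tolerance = 1e-6)
})

test_that("mirror-model fleets peak mid-trip in the free-flow profile", {
  sc <- synthetic_scenario(n_vehicles = 20, days = 1, noise_sd_km = 0,
                           seed = 43)
  fleet <- generate_fleet_log(sc)
  seg <- segment_trips(fleet$events)
  p <- sc$kick_params
  ff <- data.frame(road_id = sprintf("L%d-road", 0:p$n_layers),
                   free_flow_kmh = p$v0 + (0:p$n_layers) * p$dv)
  prof <- free_flow_profile(seg$fixes, seg$trips, ff,
                            duration_center_h = 1,
                            duration_halfwidth_h = 0.25)
  peak <- prof$rel_time[which.max(prof$rel_speed)]
  expect_gte(peak, 0.45)
  expect_lte(peak, 0.55)
})

test_that("residence is the area holding most parking time", {
  st <- data.frame(vehicle_id = "v6",
                   t_off_s = c(0, 40000), t_on_s = c(36000, 47200),
                   area_id = c("A", "B"), stringsAsFactors = FALSE)
  expect_identical(assign_residence(st)$area_id, "A")
  tie <- data.frame(vehicle_id = "v7",
                    t_off_s = c(0, 10000), t_on_s = c(3600, 13600),
                    area_id = c("B", "A"), stringsAsFactors = FALSE)
  expect_warning(res <- assign_residence(tie), "tie")
  expect_identical(res$area_id, "B") # first-observed wins
  none <- data.frame(vehicle_id = "v8", t_off_s = 0, t_on_s = 100,
                     area_id = NA_character_, stringsAsFactors = FALSE)
  expect_true(is.na(assign_residence(none)$area_id))
})

test_that("planted residences are fully recovered when their share exceeds half", {
  set.seed(44)
  stops <- do.call(rbind, lapply(1:20, function(v) {
    home <- LETTERS[(v %% 4) + 1]
    others <- sample(setdiff(LETTERS[1:6], home), 5, replace = TRUE)
    data.frame(vehicle_id = sprintf("v%02d", v),
               t_off_s = seq(0, by = 50000, length.out = 6),
               t_on_s = seq(0, by = 50000, length.out = 6) +
                 c(40000, rep(2000, 5)), # 40000 s at home > half the total
               area_id = c(home, others), stringsAsFactors = FALSE)
  }))
  res <- assign_residence(stops)
  expect_identical(res$area_id, LETTERS[(1:20 %% 4) + 1])
})

test_that("extraction round-trips an artifact-free synthetic fleet exactly", {
  sc <- synthetic_scenario(n_vehicles = 5, days = 1, noise_sd_km = 0,
                           seed = 45)
  fleet <- generate_fleet_log(sc)
  seg <- segment_trips(fleet$events)
  truth <- fleet$truth$trips
  expect_equal(nrow(seg$trips), nrow(truth))
  o1 <- order(seg$trips$vehicle_id, seg$trips$t_start_s)
  o2 <- order(truth$vehicle_id, truth$t_start_s)
  expect_lt(max(abs(seg$trips$duration_h[o1] - truth$duration_h[o2])) * 3600,
            1) # within one second
  expect_lt(max(abs(seg$trips$path_length_km[o1] - truth$path_length_km[o2]) /
                  truth$path_length_km[o2]), 0.01)
  ## and through the CSV dialect (timestamps truncated to seconds)
  csv <- tempfile(fileext = ".csv")
  write_events_csv(fleet$events, csv)
  seg2 <- segment_trips(read_events_csv(csv))
  expect_equal(nrow(seg2$trips), nrow(truth))
  expect_lt(max(abs(sort(seg2$trips$duration_h) - sort(truth$duration_h))) *
              3600, 1.5)
})
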