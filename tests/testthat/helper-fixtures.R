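## Shared fixtures: the headline parameter set (base speed 17.9 km/h,
## half-gap 20.9 km/h, half-rate 1.06 /h, cap 130 km/h, mean travel time
## 0.30 h) and small hand-built event logs for the segmentation rules.

headline_params <- function(t_bar = 0.30)
  kick_params(v0 = 17.9, dv_half = 20.9, p_half = 1.06, v_max = 130,
              t_bar = t_bar)

## one vehicle driving along +x at constant speed, emitting a fix every
## `fix_s` seconds; returns rows of an event log
toy_segment <- function(vid, t0, x0, speed_kmh, dur_s, fix_s = 60,
                        dir = c(1, 0)) {
  tt <- seq(0, dur_s, by = fix_s)
  if (tt[length(tt)] < dur_s) tt <- c(tt, dur_s)
  d <- speed_kmh * tt / 3600
  data.frame(
    vehicle_id = vid, time_s = t0 + tt,
    x_km = x0[1] + dir[1] * d, y_km = x0[2] + dir[2] * d,
    kind = c("engine_start", rep("fix", length(tt) - 2L), "engine_stop"),
    road_id = NA_character_, stringsAsFactors = FALSE)
}
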