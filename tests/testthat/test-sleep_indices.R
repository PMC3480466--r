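test_that("supine episodes require 50 s and interruptions are not supine time", {
  th <- default_thresholds()
  # 9 lying windows (45 s): below the 50 s minimum -> no episode
  w9 <- mk_windows(data.frame(n = 9, posture = "lying", activity = 0))
  expect_equal(nrow(detect_supine_episodes(w9, th)), 0)
  # 10 lying windows (50 s): boundary inclusive -> one episode
  w10 <- mk_windows(data.frame(n = 10, posture = "lying", activity = 0))
  ep <- detect_supine_episodes(w10, th)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$duration_s, 50)

  # lying 4 h, sitting 10 min, lying 3 h -> time supine 7.0 h
  w <- mk_windows(data.frame(n = c(4 * 720, 120, 3 * 720),
                             posture = c("lying", "sitting", "lying"),
                             activity = 0))
  ep <- detect_supine_episodes(w, th)
  expect_equal(nrow(ep), 2)
  expect_equal(ep$interrupting_nonlying_s, c(0, 600))
  expect_equal(time_supine(w, ep, th), 7.0)
  expect_equal(diff(in_bed_span(ep)), 7 * 3600 + 600, ignore_attr = TRUE)
})

test_that("a non-lying gap beyond 30 min splits bouts; the largest wins", {
  th <- default_thresholds()
  w <- mk_windows(data.frame(n = c(120, 500, 720),
                             posture = c("lying", "upright", "lying"),
                             activity = 0))
  ep <- detect_supine_episodes(w, th)   # 41.7 min standing gap
  expect_equal(ep$bout, c(0, 1))
  expect_equal(ep$principal, c(FALSE, TRUE))
  expect_equal(time_supine(w, ep, th), 1.0)  # only the 1 h principal bout
})

test_that("total sleep time applies the strict 0.15 g stillness rule", {
  th <- default_thresholds()
  all_quiet <- mk_windows(data.frame(n = 720, posture = "lying", activity = 0.01))
  ep <- detect_supine_episodes(all_quiet, th)
  expect_equal(total_sleep_time(all_quiet, ep, th),
               time_supine(all_quiet, ep, th))

  half <- mk_windows(data.frame(n = c(360, 360), posture = "lying",
                                activity = c(0.2, 0.01)))
  ep <- detect_supine_episodes(half, th)
  expect_equal(total_sleep_time(half, ep, th), time_supine(half, ep, th) / 2)

  boundary <- mk_windows(data.frame(n = 720, posture = "lying", activity = 0.15))
  ep <- detect_supine_episodes(boundary, th)
  expect_equal(total_sleep_time(boundary, ep, th), 0)  # exactly 0.15 excluded
})

test_that("still-position latency finds the first sustained quiet run", {
  th <- default_thresholds()
  quiet <- mk_windows(data.frame(n = 720, posture = "lying", activity = 0.01))
  ep <- detect_supine_episodes(quiet, th)
  expect_equal(as.numeric(still_position_latency(quiet, ep, th)), 0)

  # 4 min active, then quiet >= 3 min -> latency 4 min
  lat4 <- mk_windows(data.frame(n = c(48, 672), posture = "lying",
                                activity = c(0.3, 0.01)))
  ep <- detect_supine_episodes(lat4, th)
  l <- still_position_latency(lat4, ep, th)
  expect_equal(as.numeric(l), 4)
  expect_true(attr(l, "onset_found"))

  # quiet runs never reach 3 consecutive minutes -> flagged, = supine duration
  restless <- mk_windows(data.frame(n = rep(c(24, 12), 20),
                                    posture = "lying",
                                    activity = rep(c(0.01, 0.4), 20)))
  ep <- detect_supine_episodes(restless, th)
  l <- still_position_latency(restless, ep, th)
  expect_false(attr(l, "onset_found"))
  expect_equal(as.numeric(l), time_supine(restless, ep, th) * 60)
})

test_that("rises count maximal non-lying runs inside the span", {
  th <- default_thresholds()
  w <- mk_windows(data.frame(n = c(720, 24, 720),
                             posture = c("lying", "upright", "lying"),
                             activity = 0))
  ep <- detect_supine_episodes(w, th)
  r <- detect_rises(w, ep, th)
  expect_equal(r$total, 1L)
  expect_equal(r$first_hour, 0L)  # rise starts 1 h after onset exactly? 720*5s=1h
  none <- mk_windows(data.frame(n = 720, posture = "lying", activity = 0))
  epn <- detect_supine_episodes(none, th)
  expect_equal(detect_rises(none, epn, th)$total, 0L)

  # 3 rises over 7.5 h supine (4 x 1.875 h lying) -> 0.4 per hour
  w3 <- mk_windows(data.frame(
    n = c(1350, 12, 1350, 12, 1350, 12, 1350),
    posture = c("lying", "upright", "lying", "sitting", "lying", "upright", "lying"),
    activity = 0))
  ep3 <- detect_supine_episodes(w3, th)
  r3 <- detect_rises(w3, ep3, th)
  expect_equal(r3$total, 3L)
  expect_equal(r3$first_hour, 0L)
  expect_equal(r3$per_hour, 3 / time_supine(w3, ep3, th))
  expect_equal(r3$per_hour, 0.4, tolerance = 1e-9)
})

test_that("posture-change statistics match the single-segment hand case", {
  th <- default_thresholds()
  seg <- data.frame(start_s = 0, end_s = 8 * 3600, duration_s = 8 * 3600,
                    mean_angle_deg = 180, label = "dorsal", episode = 1)
  rises <- list(total = 0L, first_hour = 0L, per_hour = 0)
  p <- posture_change_stats(seg, rises, 8, th)
  expect_equal(p$changes_per_hour, 0)
  expect_equal(p$mean_duration_min, 480)
  expect_equal(p$gt15_per_hour, 1 / 8)
  expect_equal(p$fractions[["dorsal"]], 1)
  expect_equal(sum(p$fractions), 1)
  expect_equal(p$first_posture, "dorsal")
})

test_that("sleep efficiency follows the turning/rise definition", {
  th <- default_thresholds()
  # no turns, no rises -> 1.0
  quiet <- mk_windows(data.frame(n = 720, posture = "lying", activity = 0.01))
  ep <- detect_supine_episodes(quiet, th)
  seg <- supine_segments(quiet, ep, th)
  expect_equal(as.numeric(sleep_efficiency_turning(quiet, seg, ep, th)), 1.0)

  # 30 min of rises inside an 8.5 h span (8 h lying), no turning -> 8.0 / 8.5
  w <- mk_windows(data.frame(
    n = c(1920, 180, 1920, 180, 1920),
    posture = c("lying", "upright", "lying", "upright", "lying"),
    activity = 0.01))
  ep <- detect_supine_episodes(w, th)
  seg <- supine_segments(w, ep, th)
  eff <- sleep_efficiency_turning(w, seg, ep, th)
  expect_equal(as.numeric(eff), 8.0 / 8.5, tolerance = 1e-9)
  expect_equal(attr(eff, "supine_denominator"), 1.0)

  # a turn plus adjacent active windows is charged as turning time
  turn <- mk_windows(data.frame(
    n = c(360, 1, 1, 1, 360), posture = "lying",
    activity = c(0.01, 0.3, 0.3, 0.3, 0.01),
    angle_deg = c(0, 0, 45, 90, 90)))
  ep <- detect_supine_episodes(turn, th)
  seg <- supine_segments(turn, ep, th)
  expect_equal(nrow(seg), 2)
  eff <- sleep_efficiency_turning(turn, seg, ep, th)
  expect_equal(attr(eff, "turning_s"), 15)  # boundary window + 2 active neighbours
})

test_that("undefined rates are NA, never zero, on an empty night", {
  rec <- const_recording(-1, 0.05, 0, 0.05, seconds = 1800,
                         start_time = "2026-01-01 22:00:00")  # standing all night
  s <- summarize_night(rec)
  expect_equal(s$time_supine_h, 0)
  expect_equal(s$total_sleep_time_h, 0)
  expect_true(is.na(s$rises_per_hour))
  expect_true(is.na(s$posture_changes_per_hour))
  expect_true(is.na(s$sleep_efficiency))
  expect_true(is.na(s$first_posture))
})

test_that("conservation invariants hold on randomized window sequences", {
  th <- default_thresholds()
  set.seed(71)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    spec <- data.frame(
      n = sample(30:600, k, replace = TRUE),
      posture = sample(c("lying", "lying", "lying", "upright", "sitting"), k,
                       replace = TRUE),
      activity = runif(k, 0, 0.3),
      angle_deg = runif(k, -179, 180))
    w <- mk_windows(spec)
    ep <- detect_supine_episodes(w, th)
    ts <- time_supine(w, ep, th)
    tst <- total_sleep_time(w, ep, th)
    span <- diff(in_bed_span(ep))
    expect_lte(tst, ts + 1e-12)
    if (!is.na(span)) expect_lte(ts * 3600, span + 1e-9)
    seg <- supine_segments(w, ep, th)
    if (nrow(seg)) {
      # segments tile the principal episodes exactly
      expect_equal(sum(seg$duration_s),
                   sum(ep$duration_s[ep$principal]))
      p <- posture_change_stats(seg, detect_rises(w, ep, th), ts, th)
      expect_equal(sum(p$fractions), 1, tolerance = 1e-9)
    }
  }
})

test_that("night-window gating makes indices invariant to out-of-night padding", {
  th <- default_thresholds()
  rate <- 16
  lying <- function(sec) data.frame(
    sternum_vertical = rep(0, sec * rate), sternum_ap = rep(-1, sec * rate),
    sternum_lat = rep(0, sec * rate), thigh_ap = rep(0.1, sec * rate))
  standing <- function(sec) data.frame(
    sternum_vertical = rep(-1, sec * rate), sternum_ap = rep(0.05, sec * rate),
    sternum_lat = rep(0, sec * rate), thigh_ap = rep(0.05, sec * rate))
  core <- accel_recording(lying(3600), rate, "2026-01-01 20:00:00", "core")
  padded <- accel_recording(rbind(standing(1800), lying(3600)), rate,
                            "2026-01-01 19:30:00", "padded")
  a <- summarize_night(core, th)
  b <- summarize_night(padded, th)
  for (nm in c("time_supine_h", "total_sleep_time_h", "rises_total",
               "posture_changes_per_hour", "first_posture"))
    expect_equal(b[[nm]], a[[nm]], label = nm)
})

test_that("doubling the sampling rate shifts no index by more than one window", {
  sc64 <- night_scenario(seed = 9, bedtime_min = 20, latency_min = 4,
                         posture_schedule = data.frame(
                           angle_deg = c(180, 90, -90),
                           duration_min = c(30, 25, 35)),
                         rise_events = data.frame(at_min = 40, duration_min = 2),
                         tail_min = 10, sampling_rate = 64)
  sc128 <- sc64; sc128$sampling_rate <- 128
  s64 <- summarize_night(simulate_night(sc64)$recording)
  s128 <- summarize_night(simulate_night(sc128)$recording)
  expect_equal(s128$rises_total, s64$rises_total)
  expect_lte(abs(s128$time_supine_h - s64$time_supine_h) * 3600, 5)
  expect_lte(abs(s128$total_sleep_time_h - s64$total_sleep_time_h) * 3600, 5)
  expect_lte(abs(s128$still_position_latency_min - s64$still_position_latency_min), 5 / 60)
})
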