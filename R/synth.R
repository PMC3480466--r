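#' Night scenario for the synthetic-recording simulator
#'
#' A scenario states a full night as a ground-truth script: when the
#' subject sits down in view of the sensors, goes to bed, how long they
#' toss before settling (latency), the schedule of sleeping postures
#' (torso rotation angles about the longitudinal axis), rises out of bed,
#' and the movement/noise model. [simulate_night] renders it into a
#' four-channel recording plus analytic ground-truth indices.
#'
#' Timing conventions (all aligned to the 5-s window grid): posture
#' transitions are constant-rate rotations occupying the first
#' `transition_duration_s` seconds of the new block; a transition into or
#' out of lying reads as upright (the window median sits at ~45 degrees of
#' tilt), so lying begins `transition_duration_s` after `bedtime` and ends
#' exactly at the final rise.
#'
#' @param seed integer seed driving all randomness of the render.
#' @param recording_start clock time `"HH:MM"` of the first sample.
#' @param bedtime_min minutes after recording start at which the subject
#'   lies down (pre-bed time is spent sitting).
#' @param latency_min minutes of restless (active) lying after supine onset
#'   before the first quiet period.
#' @param posture_schedule data.frame `angle_deg`, `duration_min`: the
#'   sequence of sleeping postures; consecutive angles should differ by
#'   more than the segmentation threshold to be recoverable.
#' @param rise_events data.frame `at_min` (minutes after bedtime),
#'   `duration_min`: episodes out of bed (standing).
#' @param movement_burst_rate expected movement bursts per hour of quiet
#'   sleep (Poisson-timed, aligned to whole windows).
#' @param burst_amplitude_g amplitude of burst oscillations (default 0.4 g,
#'   well above the 0.15 g stillness threshold).
#' @param latency_activity_g oscillation amplitude during the latency
#'   period (default 0.25 g).
#' @param sensor_noise_sd_g additive Gaussian sensor noise SD (default
#'   0.002 g, which puts quiet-window activity near the 0.004 g scale of
#'   real supine recordings).
#' @param transition_duration_s duration of posture transitions (default 5).
#' @param tail_min minutes of standing after the final rise.
#' @param sampling_rate Hz (default 64).
#' @param subject_id identifier for the rendered recording.
#' @return an object of class `night_scenario`.
#' @export
night_scenario <- function(seed = 1,
                           recording_start = "21:00",
                           bedtime_min = 105,
                           latency_min = 10,
                           posture_schedule = data.frame(
                             angle_deg = c(180, 90, 180, -90, 0, -90),
                             duration_min = c(35, 40, 90, 120, 80, 120)),
                           rise_events = data.frame(at_min = 200, duration_min = 3),
                           movement_burst_rate = 4,
                           burst_amplitude_g = 0.4,
                           latency_activity_g = 0.25,
                           sensor_noise_sd_g = 0.002,
                           transition_duration_s = 5,
                           tail_min = 30,
                           sampling_rate = 64,
                           subject_id = sprintf("sim%04d", seed)) {
  sc <- structure(as.list(environment()), class = "night_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc, thresholds = default_thresholds()) {
  stopifnot(inherits(sc, "night_scenario"))
  if (nrow(sc$posture_schedule) < 1L || any(sc$posture_schedule$duration_min <= 0))
    stop("posture schedule must be nonempty with positive durations")
  if (nrow(sc$rise_events)) {
    if (any(sc$rise_events$duration_min <= 0)) stop("rise durations must be positive")
    tot <- sum(sc$posture_schedule$duration_min)
    if (any(sc$rise_events$at_min <= 0 | sc$rise_events$at_min +
            sc$rise_events$duration_min >= tot))
      stop("rise events must fall strictly inside the posture schedule")
  }
  total_s <- scenario_total_s(sc)
  clock <- (parse_clock(sc$recording_start) + c(0, total_s)) %% 86400
  if (!all(in_night_window(clock, thresholds$night_start, thresholds$night_end)))
    stop("scenario exceeds the night window ", thresholds$night_start, "-",
         thresholds$night_end)
  invisible(sc)
}

scenario_total_s <- function(sc) {
  (sc$bedtime_min + sum(sc$posture_schedule$duration_min) + sc$tail_min) * 60
}

#' @export
print.night_scenario <- function(x, ...) {
  cat(sprintf("<night_scenario> seed %d: %d postures, %d rise(s), %.1f h in bed\n",
              x$seed, nrow(x$posture_schedule), nrow(x$rise_events),
              sum(x$posture_schedule$duration_min) / 60))
  invisible(x)
}

#' Draw a realistic random night scenario
#'
#' Samples a night compatible with published ambulatory norms: bedtime
#' 1.5-2 h after a 21:00 recording start, 4-12 min latency, 6.5-9.6 h
#' supine split into 5-40 min postures (never exactly 15 min, so the
#' "longer than 15 min" count is unambiguous), consecutive posture angles
#' on different quarter-turn categories (turns of at least 60 degrees,
#' at least 5 min apart), 0-2 rises of 2-4 min placed away from turns,
#' the latency period and the first-hour boundary, and sensor noise drawn
#' from 0.002-0.05 g.
#'
#' @param seed integer seed (drives both the draw and the render).
#' @return a [night_scenario].
#' @export
random_night_scenario <- function(seed = 1) {
  local_seed(seed, {
    latency_min <- sample(4:12, 1)
    allowed <- setdiff(5:40, 15)
    durations <- integer(0)
    while (sum(durations) < 390) durations <- c(durations, sample(allowed, 1))
    first_min <- latency_min + 6
    if (durations[1] < first_min)
      durations[1] <- first_min + (first_min == 15)
    canon <- c(0, 90, 180, -90)
    lab_idx <- integer(length(durations))
    lab_idx[1] <- sample(4, 1)
    for (k in seq_along(durations)[-1])
      lab_idx[k] <- sample(setdiff(1:4, lab_idx[k - 1]), 1)
    angles <- wrap_deg(canon[lab_idx] + stats::runif(length(durations), -15, 15))

    n_rise <- sample(0:2, 1)
    rise <- data.frame(at_min = numeric(0), duration_min = numeric(0))
    if (n_rise > 0) {
      cum <- cumsum(c(0, durations))
      big <- which(durations >= 14)[-1]              # never the first segment
      big <- big[big < length(durations)]
      big <- utils::head(sample(big), n_rise)
      for (j in big) {
        d <- sample(2:4, 1)
        off_ok <- setdiff(4:(durations[j] - d - 4), c(14, 15, 16))
        off_ok <- off_ok[!(durations[j] - off_ok - d) %in% c(14, 15, 16)]
        at <- cum[j] + sample(off_ok, 1)
        if (abs(at - 60) <= 2) next                  # keep first-hour count sharp
        rise <- rbind(rise, data.frame(at_min = at, duration_min = d))
      }
      rise <- rise[order(rise$at_min), , drop = FALSE]
    }
    night_scenario(
      seed = seed,
      bedtime_min = sample(90:120, 1),
      latency_min = latency_min,
      posture_schedule = data.frame(angle_deg = angles, duration_min = durations),
      rise_events = rise,
      sensor_noise_sd_g = stats::runif(1, 0.002, 0.05))
  })
}

# ---------------------------------------------------------------------------
# rendering

# Block table: contiguous [start_s, end_s) blocks of type sit/stand/lie with
# a roll angle for lying blocks. All boundaries are multiples of 60 s.
scenario_blocks <- function(sc) {
  B <- sc$bedtime_min * 60
  sched <- sc$posture_schedule
  cuts <- B + cumsum(c(0, sched$duration_min)) * 60
  W <- cuts[length(cuts)]
  blocks <- data.frame(start_s = 0, end_s = B, type = "sit", angle = NA_real_)
  for (k in seq_len(nrow(sched)))
    blocks <- rbind(blocks, data.frame(start_s = cuts[k], end_s = cuts[k + 1],
                                       type = "lie", angle = sched$angle_deg[k]))
  blocks <- rbind(blocks, data.frame(start_s = W, end_s = W + sc$tail_min * 60,
                                     type = "stand", angle = NA_real_))
  # overlay rises: carve standing intervals out of the lying blocks
  for (j in seq_len(nrow(sc$rise_events))) {
    t0 <- B + sc$rise_events$at_min[j] * 60
    t1 <- t0 + sc$rise_events$duration_min[j] * 60
    new <- list()
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      if (b$end_s <= t0 || b$start_s >= t1) { new[[length(new) + 1]] <- b; next }
      if (b$start_s < t0) new[[length(new) + 1]] <-
          transform(b, end_s = t0)
      new[[length(new) + 1]] <- data.frame(start_s = max(b$start_s, t0),
                                           end_s = min(b$end_s, t1),
                                           type = "stand", angle = NA_real_)
      if (b$end_s > t1) new[[length(new) + 1]] <- transform(b, start_s = t1)
    }
    blocks <- do.call(rbind, new)
  }
  blocks <- blocks[order(blocks$start_s), ]
  rownames(blocks) <- NULL
  blocks
}

block_orientation <- function(type, angle) {
  # torso tilt psi (0 upright, 90 lying) and roll theta; thigh gravity
  psi <- ifelse(type == "lie", 90, 0)
  theta <- ifelse(type == "lie", angle, 0)
  thigh <- c(sit = 0.95, stand = 0.05, lie = 0.15)[type]
  list(psi = psi, theta = theta, thigh = unname(thigh))
}

#' Render a scenario into a recording with ground truth
#'
#' Channel values are the projection of the unit gravity vector for the
#' scheduled orientation (torso tilt and roll), with constant-rate
#' rotations over `transition_duration_s` at block changes, additive
#' Gaussian sensor noise, an oscillatory "restless" component during the
#' latency period, and Poisson-timed zero-mean movement bursts during
#' quiet sleep (kept clear of turns, rises, the latency tail and the final
#' minutes so that ground-truth indices remain exact). All randomness
#' comes from `scenario$seed`.
#'
#' @param scenario a [night_scenario].
#' @param date calendar date for the recording start (the clock time comes
#'   from the scenario).
#' @return list with `recording` (an [accel_recording]) and `truth`, a list
#'   holding `summary` (the analytic ground-truth `night_summary`),
#'   `windows` (per-window true posture and angle), `turn_times_s`,
#'   `burst_s` and the scenario.
#' @export
simulate_night <- function(scenario, date = "2026-01-01") {
  validate_scenario(scenario)
  sc <- scenario
  rate <- sc$sampling_rate
  trans <- sc$transition_duration_s
  blocks <- scenario_blocks(sc)
  total_s <- scenario_total_s(sc)
  n <- as.integer(round(total_s * rate))
  tt <- (seq_len(n) - 1) / rate

  ori <- block_orientation(blocks$type, blocks$angle)
  len <- as.integer(round((blocks$end_s - blocks$start_s) * rate))
  psi <- rep(ori$psi, len)
  theta <- rep(ori$theta, len)
  thigh <- rep(ori$thigh, len)
  theta[is.na(theta)] <- 0

  # constant-rate transitions over the first `trans` s of each new block
  ntr <- as.integer(round(trans * rate))
  frac <- (seq_len(ntr) - 0.5) / ntr
  for (i in seq_len(nrow(blocks))[-1]) {
    i0 <- as.integer(round(blocks$start_s[i] * rate))
    idx <- i0 + seq_len(ntr)
    p0 <- ori$psi[i - 1]; p1 <- ori$psi[i]
    th0 <- theta[i0]; th1 <- ori$theta[i]; if (is.na(th1)) th1 <- th0
    g0 <- ori$thigh[i - 1]; g1 <- ori$thigh[i]
    psi[idx] <- p0 + (p1 - p0) * frac
    theta[idx] <- th0 + circular_diff(th1, th0) * frac
    thigh[idx] <- g0 + (g1 - g0) * frac
  }

  deg <- pi / 180
  v <- -cos(psi * deg)
  ap <- sin(psi * deg) * cos(theta * deg)
  lat <- sin(psi * deg) * sin(theta * deg)

  onset <- sc$bedtime_min * 60 + trans
  turn_times <- sc$bedtime_min * 60 +
    cumsum(sc$posture_schedule$duration_min[-nrow(sc$posture_schedule)]) * 60

  burst_windows <- integer(0)
  local_seed(sc$seed, {
    # restless latency period: quadrature oscillation on the planar axes
    li <- seq.int(round(onset * rate) + 1,
                  min(n, round((onset + sc$latency_min * 60) * rate)))
    if (length(li)) {
      ph <- stats::runif(1, 0, 2 * pi)
      ap[li] <- ap[li] + sc$latency_activity_g * sin(2 * pi * 2 * tt[li] + ph)
      lat[li] <- lat[li] + sc$latency_activity_g * cos(2 * pi * 2 * tt[li] + ph)
    }
    # movement bursts on whole quiet windows
    wstart <- seq(0, total_s - 5, by = 5)
    eligible <- burst_eligible(wstart, sc, blocks, onset, turn_times)
    quiet_h <- length(eligible) * 5 / 3600
    n_burst <- stats::rpois(1, sc$movement_burst_rate * quiet_h)
    if (n_burst > 0 && length(eligible)) {
      pick <- sample(eligible, min(n_burst, length(eligible)))
      for (p in pick) {
        extra <- sample(0:1, 1)              # 5 s or 10 s bursts
        wins <- p + 0:extra
        wins <- wins[wins %in% eligible]
        burst_windows <- union(burst_windows, wins)
        bi <- seq.int(round(wstart[wins[1]] * rate) + 1,
                      round((wstart[wins[length(wins)]] + 5) * rate))
        f <- stats::runif(1, 2, 5)
        for (chan in 1:4) {
          phs <- stats::runif(1, 0, 2 * pi)
          osc <- sc$burst_amplitude_g * sin(2 * pi * f * tt[bi] + phs)
          if (chan == 1) v[bi] <- v[bi] + osc
          else if (chan == 2) ap[bi] <- ap[bi] + osc
          else if (chan == 3) lat[bi] <- lat[bi] + osc
          else thigh[bi] <- thigh[bi] + osc
        }
      }
    }
    v <- v + stats::rnorm(n, 0, sc$sensor_noise_sd_g)
    ap <- ap + stats::rnorm(n, 0, sc$sensor_noise_sd_g)
    lat <- lat + stats::rnorm(n, 0, sc$sensor_noise_sd_g)
    thigh <- thigh + stats::rnorm(n, 0, sc$sensor_noise_sd_g)
  })

  rec <- accel_recording(
    data.frame(sternum_vertical = v, sternum_ap = ap,
               sternum_lat = lat, thigh_ap = thigh),
    sampling_rate = rate,
    start_time = paste0(date, " ",
                        sprintf("%02.0f:%02.0f:00",
                                parse_clock(sc$recording_start) %/% 3600,
                                parse_clock(sc$recording_start) %% 3600 %/% 60)),
    subject_id = sc$subject_id)

  burst_s <- length(burst_windows) * 5
  truth <- list(summary = truth_summary(sc, burst_s),
                windows = truth_windows(sc, blocks, total_s),
                turn_times_s = turn_times,
                burst_s = burst_s,
                burst_start_s = (burst_windows - 1) * 5,
                scenario = sc)
  list(recording = rec, truth = truth)
}

# window indices (1-based into the 5-s grid) where a burst may be placed
# without disturbing any ground-truth index
burst_eligible <- function(wstart, sc, blocks, onset, turn_times) {
  B <- sc$bedtime_min * 60
  W <- B + sum(sc$posture_schedule$duration_min) * 60
  lie <- rep(FALSE, length(wstart))
  for (i in which(blocks$type == "lie"))
    lie <- lie | (wstart >= blocks$start_s[i] & wstart < blocks$end_s[i])
  ok <- lie &
    wstart >= onset + (sc$latency_min + still_buffer_min()) * 60 &
    wstart < W - 15
  guard <- function(t0, t1) ok[wstart >= t0 & wstart < t1] <<- FALSE
  for (T in turn_times) guard(T - 15, T + 20)
  for (j in seq_len(nrow(sc$rise_events))) {
    t0 <- B + sc$rise_events$at_min[j] * 60
    t1 <- t0 + sc$rise_events$duration_min[j] * 60
    guard(t0 - 15, t1 + 20)
  }
  which(ok)
}

# minutes of guaranteed quiet after the latency period (protects the
# still-position-latency ground truth)
still_buffer_min <- function() 4

# analytic ground-truth summary, straight arithmetic on the scenario
truth_summary <- function(sc, burst_s) {
  trans <- sc$transition_duration_s
  B <- sc$bedtime_min * 60
  onset <- B + trans
  W <- B + sum(sc$posture_schedule$duration_min) * 60
  span_s <- W - onset
  rise_nonlying <- if (nrow(sc$rise_events))
    sc$rise_events$duration_min * 60 + trans else numeric(0)
  ts_s <- span_s - sum(rise_nonlying)
  n_turn <- nrow(sc$posture_schedule) - 1L
  dtheta <- abs(circular_diff(sc$posture_schedule$angle_deg[-1],
                              sc$posture_schedule$angle_deg[-(n_turn + 1L)]))
  tst_s <- ts_s - sc$latency_min * 60 - trans * n_turn - burst_s
  turning_s <- if (n_turn > 0) sum(ifelse(dtheta > 60, trans, 2 * trans)) else 0
  seg <- truth_segments(sc)
  rise_abs <- if (nrow(sc$rise_events)) B + sc$rise_events$at_min * 60 else numeric(0)
  tsh <- ts_s / 3600
  fr <- vapply(posture_labels(), function(l)
    sum(seg$duration_s[seg$label == l]) / sum(seg$duration_s), numeric(1))
  out <- list(
    subject_id = sc$subject_id,
    time_supine_h = tsh,
    in_bed_span_h = span_s / 3600,
    total_sleep_time_h = tst_s / 3600,
    average_activity_g = NA_real_,
    still_position_latency_min = sc$latency_min,
    sleep_onset_found = TRUE,
    sleep_efficiency = (ts_s - turning_s) / span_s,
    sleep_efficiency_supine = (ts_s - turning_s) / ts_s,
    rises_total = nrow(sc$rise_events),
    rises_first_hour = sum(rise_abs < onset + 3600),
    rises_per_hour = nrow(sc$rise_events) / tsh,
    posture_changes_per_hour = (n_turn + nrow(sc$rise_events)) / tsh,
    mean_posture_duration_min = mean(seg$duration_s) / 60,
    postures_gt15_per_hour = sum(seg$duration_s > 900) / tsh,
    posture_fractions = fr,
    first_posture = label_from_angle(sc$posture_schedule$angle_deg[1]))
  class(out) <- "night_summary"
  out
}

# ground-truth orientation segments: schedule pieces cut by rises, with the
# transition conventions of the renderer (lying starts trans s after each
# entry into bed and resumes trans s after each rise)
truth_segments <- function(sc) {
  trans <- sc$transition_duration_s
  B <- sc$bedtime_min * 60
  sched <- sc$posture_schedule
  cuts <- B + cumsum(c(0, sched$duration_min)) * 60
  seg <- data.frame(start_s = cuts[-length(cuts)], end_s = cuts[-1],
                    angle = sched$angle_deg)
  seg$start_s[1] <- seg$start_s[1] + trans
  out <- list()
  for (i in seq_len(nrow(seg))) {
    piece <- seg[i, ]
    for (j in seq_len(nrow(sc$rise_events))) {
      t0 <- B + sc$rise_events$at_min[j] * 60
      t1 <- t0 + sc$rise_events$duration_min[j] * 60 + trans
      if (t0 > piece$start_s && t0 < piece$end_s) {
        out[[length(out) + 1]] <- transform(piece, end_s = t0)
        piece$start_s <- t1
      }
    }
    out[[length(out) + 1]] <- piece
  }
  seg <- do.call(rbind, out)
  seg$duration_s <- seg$end_s - seg$start_s
  seg$label <- label_from_angle(wrap_deg(seg$angle))
  seg
}

# per-window true coarse posture and rotation angle
truth_windows <- function(sc, blocks, total_s) {
  wstart <- seq(0, total_s - 5, by = 5)
  bi <- findInterval(wstart, blocks$start_s)
  type <- blocks$type[bi]
  angle <- blocks$angle[bi]
  posture <- c(sit = "sitting", stand = "upright", lie = "lying")[type]
  first_win <- wstart %in% blocks$start_s
  prev_type <- blocks$type[pmax(bi - 1, 1)]
  # a transition window into lying reads upright; lie->lie turns read lying
  into_lying <- first_win & type == "lie" & prev_type != "lie" & bi > 1
  posture[into_lying] <- "upright"
  turn <- first_win & type == "lie" & prev_type == "lie" & bi > 1
  if (any(turn)) {
    a0 <- blocks$angle[bi[turn] - 1]
    angle[turn] <- wrap_deg(a0 + circular_diff(blocks$angle[bi[turn]], a0) / 2)
  }
  angle[posture != "lying"] <- NA_real_
  data.frame(start_s = wstart, posture = posture, angle_deg = wrap_deg(angle))
}

#' Simulate the laboratory calibration protocol
#'
#' Renders the standardized labeled motion sequence used to derive the tree
#' thresholds: 40 s walking at normal pace, 50 s walking up stairs, 40 s
#' walking down stairs, 40 s walking at fast pace, 40 s standing, 40 s
#' sitting, 40 s lying on the right side, 40 s lying on the left side and
#' 180 s lying on the back (510 s total). Walking intervals carry an
#' oscillatory dynamic component; posture switches are instantaneous on
#' the window grid so every 5-s window has a unique true label.
#'
#' @param seed integer seed.
#' @param noise_sd_g additive Gaussian sensor noise SD (default 0.05 g).
#' @param sampling_rate Hz.
#' @return list with `recording` and `intervals` (data.frame `label`,
#'   `coarse`, `start_s`, `end_s`).
#' @export
simulate_protocol <- function(seed = 1, noise_sd_g = 0.05, sampling_rate = 64) {
  spec <- data.frame(
    label = c("walk_normal", "stairs_up", "stairs_down", "walk_fast",
              "stand", "sit", "lie_right", "lie_left", "lie_back"),
    coarse = c("upright", "upright", "upright", "upright",
               "upright", "sitting", "lying", "lying", "lying"),
    dur = c(40, 50, 40, 40, 40, 40, 40, 40, 180),
    v = c(-1, -1, -1, -1, -1, -0.95, 0, 0, 0),
    ap = c(0.1, 0.15, 0.15, 0.1, 0.05, 0.2, 0, 0, -1),
    lat = c(0, 0, 0, 0, 0, 0, 1, -1, 0),
    thigh = c(0, 0.05, 0.05, 0, 0.05, 0.95, 0.15, 0.15, 0.9),
    amp = c(0.3, 0.4, 0.4, 0.5, 0, 0, 0, 0, 0),
    freq = c(2, 1.6, 1.8, 2.4, 0, 0, 0, 0, 0))
  rate <- sampling_rate
  n <- sum(spec$dur) * rate
  tt <- (seq_len(n) - 1) / rate
  rep_i <- rep(seq_len(nrow(spec)), spec$dur * rate)
  v <- spec$v[rep_i]; ap <- spec$ap[rep_i]
  lat <- spec$lat[rep_i]; thigh <- spec$thigh[rep_i]
  local_seed(seed, {
    for (i in which(spec$amp > 0)) {
      idx <- which(rep_i == i)
      ph <- stats::runif(3, 0, 2 * pi)
      v[idx] <- v[idx] + spec$amp[i] * sin(2 * pi * spec$freq[i] * tt[idx] + ph[1])
      ap[idx] <- ap[idx] + 0.6 * spec$amp[i] * sin(2 * pi * spec$freq[i] * tt[idx] + ph[2])
      thigh[idx] <- thigh[idx] + spec$amp[i] * sin(2 * pi * spec$freq[i] * tt[idx] + ph[3])
    }
    if (noise_sd_g > 0) {
      v <- v + stats::rnorm(n, 0, noise_sd_g)
      ap <- ap + stats::rnorm(n, 0, noise_sd_g)
      lat <- lat + stats::rnorm(n, 0, noise_sd_g)
      thigh <- thigh + stats::rnorm(n, 0, noise_sd_g)
    }
  })
  ends <- cumsum(spec$dur)
  list(recording = accel_recording(
         data.frame(sternum_vertical = v, sternum_ap = ap,
                    sternum_lat = lat, thigh_ap = thigh),
         sampling_rate = rate, start_time = "2026-01-01 15:00:00",
         subject_id = sprintf("protocol%04d", seed)),
       intervals = data.frame(label = spec$label, coarse = spec$coarse,
                              start_s = c(0, ends[-length(ends)]),
                              end_s = ends))
}
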