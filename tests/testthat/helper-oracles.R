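# Independent oracles and fixture builders used across the suite.

# Circular mean via complex arithmetic (independent of the package's
# sin/cos-sum implementation).
oracle_circular_mean <- function(angles_deg) {
  z <- sum(exp(1i * angles_deg * pi / 180))
  d <- Arg(z) * 180 / pi
  if (d <= -180) d <- d + 360
  d
}

oracle_circular_diff <- function(a, b) {
  d <- Arg(exp(1i * (a - b) * pi / 180)) * 180 / pi
  if (d <= -180) d <- d + 360
  d
}

# Offline brute-force segmentation: same rule as segment_supine (running
# circular mean anchored to the current segment, strict > threshold,
# stub-merge into the following segment), recomputed from scratch at every
# step via the complex-arithmetic oracle.
oracle_segment <- function(angle_deg, start_s, thr = 30, window_s = 5,
                           min_segment_s = window_s) {
  n <- length(angle_deg)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  seg_start <- 1L
  starts <- integer(0); ends <- integer(0)
  if (n > 1L) for (i in 2:n) {
    m <- oracle_circular_mean(angle_deg[seg_start:(i - 1L)])
    if (abs(oracle_circular_diff(angle_deg[i], m)) > thr) {
      starts <- c(starts, seg_start); ends <- c(ends, i - 1L)
      seg_start <- i
    }
  }
  starts <- c(starts, seg_start); ends <- c(ends, n)
  dur <- function(k) start_s[ends[k]] + window_s - start_s[starts[k]]
  k <- 1L
  while (k <= length(starts) && length(starts) > 1L) {
    if (dur(k) < min_segment_s + 1e-9) {
      if (k < length(starts)) {
        starts[k + 1L] <- starts[k]
      } else {
        ends[k - 1L] <- ends[k]
      }
      starts <- starts[-k]; ends <- ends[-k]
    } else k <- k + 1L
  }
  data.frame(
    start_s = start_s[starts],
    end_s = start_s[ends] + window_s,
    mean_angle_deg = vapply(seq_along(starts), function(j)
      oracle_circular_mean(angle_deg[starts[j]:ends[j]]), numeric(1)))
}

# Random supine angle trace: slow wobble plus occasional large turns.
random_angle_trace <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(50:400, 1)
  ang <- numeric(n)
  ang[1] <- runif(1, -180, 180)
  for (i in 2:n) {
    step <- rnorm(1, 0, 5)
    if (runif(1) < 0.02) step <- sample(c(-1, 1), 1) * runif(1, 40, 180)
    ang[i] <- ang[i - 1] + step
  }
  data.frame(start_s = (seq_len(n) - 1) * 5,
             angle_deg = ((ang + 180) %% 360) - 180)
}

# Constant-posture recording builder.
const_recording <- function(v, ap, lat, thigh, seconds = 10, rate = 64,
                            start_time = "2026-01-01 23:00:00",
                            subject_id = "fixture") {
  n <- seconds * rate
  accel_recording(
    data.frame(sternum_vertical = rep(v, n), sternum_ap = rep(ap, n),
               sternum_lat = rep(lat, n), thigh_ap = rep(thigh, n)),
    sampling_rate = rate, start_time = start_time, subject_id = subject_id)
}

# Classified-window fixture builder for the index module. `spec` is a
# data.frame with columns n (window count), posture, activity and
# optionally angle_deg (for lying windows).
mk_windows <- function(spec, window_s = 5) {
  if (is.null(spec$angle_deg)) spec$angle_deg <- 180
  rows <- do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    r <- spec[i, ]
    lying <- r$posture == "lying"
    data.frame(
      posture = rep(r$posture, r$n),
      activity = rep(r$activity, r$n),
      median_v = rep(if (lying) 0 else -1, r$n),
      median_ap = rep(if (lying) cospi(r$angle_deg / 180) else 0, r$n),
      median_lat = rep(if (lying) sinpi(r$angle_deg / 180) else 0, r$n),
      median_thigh = rep(if (r$posture == "sitting") 0.9 else 0.1, r$n))
  }))
  rows$posture <- factor(rows$posture, levels = c("lying", "sitting", "upright"))
  rows <- cbind(start_s = (seq_len(nrow(rows)) - 1) * window_s, rows)
  attr(rows, "window_s") <- window_s
  rows
}
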