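#' Supine episodes and the in-bed span
#'
#' A supine episode is a maximal run of lying windows lasting at least
#' `supine_min_s` (default 50 s, ten 5-s windows). Episodes separated by
#' non-lying gaps of at most `max_rise_min` minutes belong to one in-bed
#' bout; a longer gap ends the bout (getting up for the day). The principal
#' bout (largest total lying time) defines the in-bed span used by all
#' indices: from the first episode's start to the last episode's end, with
#' interior sitting/standing counted as interruptions, not supine time.
#'
#' @param windows classified window features ([classify_recording] output):
#'   contiguous rows with `start_s`, `posture`, `activity`.
#' @param thresholds a [default_thresholds] object.
#' @return data.frame with one row per episode: `start_s`, `end_s`,
#'   `duration_s`, `interrupting_nonlying_s` (non-lying seconds separating
#'   it from the previous episode of the same bout), `bout`, `principal`.
#' @export
detect_supine_episodes <- function(windows, thresholds = default_thresholds()) {
  w <- window_step(windows)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0),
                      interrupting_nonlying_s = numeric(0),
                      bout = integer(0), principal = logical(0))
  if (nrow(windows) == 0L) return(empty)
  lying <- windows$posture == "lying"
  r <- rle(as.vector(lying))
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  keep <- r$values & r$lengths * w >= thresholds$supine_min_s
  if (!any(keep)) return(empty)
  ep <- data.frame(start_s = windows$start_s[starts_i[keep]],
                   end_s = windows$start_s[ends_i[keep]] + w)
  ep$duration_s <- ep$end_s - ep$start_s
  gap <- c(0, ep$start_s[-1] - ep$end_s[-nrow(ep)])
  ep$interrupting_nonlying_s <- gap
  ep$bout <- cumsum(gap > thresholds$max_rise_min * 60)
  ep$interrupting_nonlying_s[c(TRUE, diff(ep$bout) > 0)] <- 0
  tot <- tapply(ep$duration_s, ep$bout, sum)
  ep$principal <- ep$bout == as.integer(names(tot)[which.max(tot)])
  ep
}

# seconds per window, from the attribute or the time grid
window_step <- function(windows) {
  ws <- attr(windows, "window_s")
  if (!is.null(ws)) return(ws)
  if (nrow(windows) > 1L) return(stats::median(diff(windows$start_s)))
  5
}

#' In-bed span of the principal bout
#' @param episodes output of [detect_supine_episodes].
#' @return numeric `c(start_s, end_s)`, or `c(NA, NA)` without episodes.
#' @export
in_bed_span <- function(episodes) {
  ep <- episodes[episodes$principal, , drop = FALSE]
  if (nrow(ep) == 0L) return(c(NA_real_, NA_real_))
  c(ep$start_s[1], ep$end_s[nrow(ep)])
}

span_window_idx <- function(windows, span) {
  which(windows$start_s >= span[1] & windows$start_s < span[2])
}

#' Time supine (hours)
#'
#' Total lying time inside the in-bed span: the span duration minus interior
#' sitting/standing time.
#'
#' @inheritParams detect_supine_episodes
#' @param episodes output of [detect_supine_episodes].
#' @return hours; 0 without episodes.
#' @export
time_supine <- function(windows, episodes, thresholds = default_thresholds()) {
  span <- in_bed_span(episodes)
  if (anyNA(span)) return(0)
  w <- window_step(windows)
  i <- span_window_idx(windows, span)
  sum(windows$posture[i] == "lying") * w / 3600
}

#' Total sleep time (hours)
#'
#' Lying time inside the in-bed span whose window activity is strictly below
#' `sleep_activity_g` (default 0.15 g, the average minimum activity while
#' lying supine in the laboratory).
#'
#' @inheritParams time_supine
#' @export
total_sleep_time <- function(windows, episodes, thresholds = default_thresholds()) {
  span <- in_bed_span(episodes)
  if (anyNA(span)) return(0)
  w <- window_step(windows)
  i <- span_window_idx(windows, span)
  sum(windows$posture[i] == "lying" &
        windows$activity[i] < thresholds$sleep_activity_g) * w / 3600
}

#' Still-position latency (minutes)
#'
#' Time from the onset of the in-bed span to the start of the first run of
#' at least `still_min_min` consecutive minutes of quiet lying (activity
#' strictly below `sleep_activity_g`). When no such run exists the latency
#' equals the full supine duration and the result carries
#' `attr(, "onset_found") = FALSE`.
#'
#' @inheritParams time_supine
#' @export
still_position_latency <- function(windows, episodes,
                                   thresholds = default_thresholds()) {
  span <- in_bed_span(episodes)
  if (anyNA(span)) return(structure(0, onset_found = FALSE))
  w <- window_step(windows)
  i <- span_window_idx(windows, span)
  quiet <- windows$posture[i] == "lying" &
    windows$activity[i] < thresholds$sleep_activity_g
  r <- rle(as.vector(quiet))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths * w >= thresholds$still_min_min * 60
  if (!any(ok)) {
    ts_min <- time_supine(windows, episodes, thresholds) * 60
    return(structure(ts_min, onset_found = FALSE))
  }
  first <- starts[which(ok)[1]]
  structure((windows$start_s[i][first] - span[1]) / 60, onset_found = TRUE)
}

#' Rises (awakenings out of the lying posture)
#'
#' A rise is a maximal run of non-lying (sitting or upright) windows inside
#' the in-bed span, i.e. after the first supine onset and before the final
#' lying end. Counts rises in total and within the first hour after supine
#' onset, plus the hourly rate relative to time supine.
#'
#' @inheritParams time_supine
#' @return list `total`, `first_hour`, `per_hour` (`per_hour` is `NA` when
#'   time supine is zero).
#' @export
detect_rises <- function(windows, episodes, thresholds = default_thresholds()) {
  span <- in_bed_span(episodes)
  if (anyNA(span)) return(list(total = 0L, first_hour = 0L, per_hour = NA_real_))
  i <- span_window_idx(windows, span)
  nonlying <- windows$posture[i] != "lying"
  r <- rle(as.vector(nonlying))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  rises_start <- windows$start_s[i][starts[r$values]]
  tsh <- time_supine(windows, episodes, thresholds)
  list(total = sum(r$values),
       first_hour = sum(rises_start < span[1] + 3600),
       per_hour = if (tsh > 0) sum(r$values) / tsh else NA_real_)
}

#' Orientation segments of all supine episodes
#'
#' Runs [supine_angle] and [segment_supine] over every principal-bout
#' episode and stacks the segments with an `episode` id. Segments tile each
#' episode exactly.
#'
#' @inheritParams time_supine
#' @param handedness passed to [supine_angle].
#' @return segment data.frame with an extra `episode` column.
#' @export
supine_segments <- function(windows, episodes,
                            thresholds = default_thresholds(),
                            handedness = 1) {
  w <- window_step(windows)
  ep <- episodes[episodes$principal, , drop = FALSE]
  out <- list()
  for (j in seq_len(nrow(ep))) {
    i <- which(windows$start_s >= ep$start_s[j] &
                 windows$start_s < ep$end_s[j] &
                 windows$posture == "lying")
    ang <- supine_angle(windows[i, , drop = FALSE], handedness = handedness)
    seg <- segment_supine(ang, thresholds, window_s = w)
    if (nrow(seg)) { seg$episode <- j; out[[length(out) + 1L]] <- seg }
  }
  if (!length(out))
    return(cbind(segment_supine(data.frame()), episode = integer(0)))
  do.call(rbind, out)
}

#' Posture-change statistics
#'
#' Posture changes per hour count internal segment boundaries plus rises
#' (getting up), divided by time supine. Also: the mean segment duration,
#' the hourly rate of segments longer than `long_posture_min` (default 15
#' minutes), the fraction of segmented supine time spent in each of the
#' four sleeping postures, and the first posture of the night.
#'
#' @param segments output of [supine_segments].
#' @param rises output of [detect_rises].
#' @param time_supine_h hours supine ([time_supine]).
#' @param thresholds a [default_thresholds] object.
#' @return list `changes_per_hour`, `mean_duration_min`, `gt15_per_hour`,
#'   `fractions` (named ventral/right/dorsal/left), `first_posture`. Rates
#'   are `NA` when time supine is zero.
#' @export
posture_change_stats <- function(segments, rises, time_supine_h,
                                 thresholds = default_thresholds()) {
  if (nrow(segments) == 0L)
    return(list(changes_per_hour = NA_real_, mean_duration_min = NA_real_,
                gt15_per_hour = NA_real_,
                fractions = setNames(rep(NA_real_, 4), posture_labels()),
                first_posture = NA_character_))
  boundaries <- nrow(segments) - length(unique(segments$episode))
  tot <- sum(segments$duration_s)
  fr <- vapply(posture_labels(), function(l)
    sum(segments$duration_s[segments$label == l]) / tot, numeric(1))
  rate <- function(x) if (time_supine_h > 0) x / time_supine_h else NA_real_
  list(changes_per_hour = rate(boundaries + rises$total),
       mean_duration_min = mean(segments$duration_s) / 60,
       gt15_per_hour = rate(sum(segments$duration_s > thresholds$long_posture_min * 60)),
       fractions = fr,
       first_posture = segments$label[which.min(segments$start_s)])
}

#' Sleep efficiency based on turning
#'
#' The fraction of the in-bed span spent supine and not turning. Turning
#' time charges one window per internal segment boundary plus the adjacent
#' contiguous lying windows whose activity is at or above
#' `sleep_activity_g`. The primary denominator is the in-bed span (which
#' includes rise time); `attr(, "supine_denominator")` carries the variant
#' with time supine as denominator. Clamped to `[0, 1]`.
#'
#' @inheritParams posture_change_stats
#' @param windows,episodes as in [time_supine].
#' @export
sleep_efficiency_turning <- function(windows, segments, episodes,
                                     thresholds = default_thresholds()) {
  span <- in_bed_span(episodes)
  if (anyNA(span)) return(structure(NA_real_, supine_denominator = NA_real_))
  w <- window_step(windows)
  ts_s <- time_supine(windows, episodes, thresholds) * 3600
  boundary_t <- segments$start_s[
    stats::ave(segments$start_s, segments$episode, FUN = seq_along) > 1]
  charged <- integer(0)
  active <- windows$activity >= thresholds$sleep_activity_g &
    windows$posture == "lying"
  for (b in boundary_t) {
    k <- which(abs(windows$start_s - b) < w / 2)
    if (!length(k)) next
    charged <- c(charged, k)
    j <- k - 1L
    while (j >= 1L && active[j]) { charged <- c(charged, j); j <- j - 1L }
    j <- k + 1L
    while (j <= nrow(windows) && active[j]) { charged <- c(charged, j); j <- j + 1L }
  }
  turning_s <- length(unique(charged)) * w
  span_s <- span[2] - span[1]
  clamp01 <- function(x) min(1, max(0, x))
  structure(clamp01((ts_s - turning_s) / span_s),
            supine_denominator = if (ts_s > 0) clamp01((ts_s - turning_s) / ts_s) else NA_real_,
            turning_s = turning_s)
}

#' Summarize one night
#'
#' Full pipeline: windowed gravity/activity features over the night window,
#' posture tree, supine episodes, adaptive orientation segmentation, and
#' every sleep duration / quality index. Deterministic for a fixed input
#' and threshold set.
#'
#' @param rec an [accel_recording].
#' @param thresholds a [default_thresholds] object.
#' @param window_s analysis window in seconds (default 5).
#' @param handedness orientation sign, see [supine_angle].
#' @return an object of class `night_summary`: a list with fields
#'   `subject_id`, `time_supine_h`, `in_bed_span_h`, `total_sleep_time_h`,
#'   `average_activity_g`, `still_position_latency_min`,
#'   `sleep_onset_found`, `sleep_efficiency`, `sleep_efficiency_supine`,
#'   `rises_total`, `rises_first_hour`, `rises_per_hour`,
#'   `posture_changes_per_hour`, `mean_posture_duration_min`,
#'   `postures_gt15_per_hour`, `posture_fractions`, `first_posture`.
#'   Undefined rates are `NA`, never 0.
#' @export
summarize_night <- function(rec, thresholds = default_thresholds(),
                            window_s = 5, handedness = 1) {
  windows <- classify_recording(rec, thresholds, window_s)
  episodes <- detect_supine_episodes(windows, thresholds)
  tsh <- time_supine(windows, episodes, thresholds)
  span <- in_bed_span(episodes)
  if (anyNA(span)) {
    out <- list(subject_id = rec$subject_id, time_supine_h = 0,
                in_bed_span_h = 0, total_sleep_time_h = 0,
                average_activity_g = NA_real_,
                still_position_latency_min = 0, sleep_onset_found = FALSE,
                sleep_efficiency = NA_real_, sleep_efficiency_supine = NA_real_,
                rises_total = 0L, rises_first_hour = 0L,
                rises_per_hour = NA_real_,
                posture_changes_per_hour = NA_real_,
                mean_posture_duration_min = NA_real_,
                postures_gt15_per_hour = NA_real_,
                posture_fractions = setNames(rep(NA_real_, 4), posture_labels()),
                first_posture = NA_character_)
    class(out) <- "night_summary"
    return(out)
  }
  rises <- detect_rises(windows, episodes, thresholds)
  segments <- supine_segments(windows, episodes, thresholds, handedness)
  pcs <- posture_change_stats(segments, rises, tsh, thresholds)
  lat <- still_position_latency(windows, episodes, thresholds)
  eff <- sleep_efficiency_turning(windows, segments, episodes, thresholds)
  i <- span_window_idx(windows, span)
  supine_i <- i[windows$posture[i] == "lying"]
  out <- list(
    subject_id = rec$subject_id,
    time_supine_h = tsh,
    in_bed_span_h = (span[2] - span[1]) / 3600,
    total_sleep_time_h = total_sleep_time(windows, episodes, thresholds),
    average_activity_g = mean(windows$activity[supine_i]),
    still_position_latency_min = as.numeric(lat),
    sleep_onset_found = attr(lat, "onset_found"),
    sleep_efficiency = as.numeric(eff),
    sleep_efficiency_supine = attr(eff, "supine_denominator"),
    rises_total = as.integer(rises$total),
    rises_first_hour = as.integer(rises$first_hour),
    rises_per_hour = rises$per_hour,
    posture_changes_per_hour = pcs$changes_per_hour,
    mean_posture_duration_min = pcs$mean_duration_min,
    postures_gt15_per_hour = pcs$gt15_per_hour,
    posture_fractions = pcs$fractions,
    first_posture = pcs$first_posture)
  class(out) <- "night_summary"
  out
}

#' @export
print.night_summary <- function(x, ...) {
  cat(sprintf("<night_summary> subject '%s'\n", x$subject_id))
  fmt <- function(v) if (is.numeric(v)) sprintf("%.3f", v) else as.character(v)
  for (nm in setdiff(names(x), c("subject_id", "posture_fractions")))
    cat(sprintf("  %-28s %s\n", nm, fmt(x[[nm]])))
  cat("  posture_fractions          ",
      paste(sprintf("%s=%.3f", names(x$posture_fractions), x$posture_fractions),
            collapse = " "), "\n")
  invisible(x)
}
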