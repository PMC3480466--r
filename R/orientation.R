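#' Circular statistics for orientation angles
#'
#' `circular_mean` is the direction of the summed unit vectors of the
#' angles; `circular_diff` is the signed smallest difference `a - b`. Both
#' work in degrees and return values in `(-180, 180]`.
#'
#' @param angles numeric vector of angles in degrees (any range).
#' @return `circular_mean`: a single angle in `(-180, 180]`; an error when
#'   the resultant length is below 1e-12 (antipodal cancellation).
#' @export
#' @examples
#' circular_mean(c(10, 20, 30))   # 20
#' circular_mean(c(350, 10))      # 0
#' circular_diff(170, -170)       # -20 (wraps)
circular_mean <- function(angles) {
  if (length(angles) == 0L) stop("circular_mean of an empty set")
  r <- angles * pi / 180
  s <- mean(sin(r)); c <- mean(cos(r))
  if (sqrt(s^2 + c^2) < 1e-12)
    stop("circular mean undefined: resultant length ~ 0 (antipodal angles)")
  wrap_deg(atan2(s, c) * 180 / pi)
}

#' @rdname circular_mean
#' @param a,b angles in degrees.
#' @export
circular_diff <- function(a, b) {
  wrap_deg(a - b)
}

# map any angle(s) to (-180, 180]; NA passes through
wrap_deg <- function(x) {
  y <- x %% 360
  y[!is.na(y) & y > 180] <- y[!is.na(y) & y > 180] - 360
  # %% can return 360 - eps artifacts; also map -180 -> 180
  y[!is.na(y) & y <= -180] <- y[!is.na(y) & y <= -180] + 360
  y
}

#' Torso rotation angle of supine windows
#'
#' For windows classified lying, the rotation of the torso about the
#' longitudinal body axis is the direction of the gravity projection in the
#' antero-posterior / medio-lateral plane of the sternum sensor:
#' `atan2(median_lat, median_ap)` in degrees, with the convention
#' 0 deg = ventral (lying on the stomach, gravity on the chest),
#' +90 deg = right side, 180 deg = dorsal (on the back), -90 deg = left
#' side. Set `handedness = -1` to mirror the left/right sign.
#'
#' Windows whose planar gravity magnitude `sqrt(ap^2 + lat^2)` does not
#' exceed `min_planar_g` have an ill-defined angle; they are flagged
#' (`defined = FALSE`) and carry the last valid angle forward (the first
#' windows inherit the first valid angle).
#'
#' @param features classified `window_features` rows (lying windows).
#' @param min_planar_g minimal planar gravity magnitude (default 0.2 g).
#' @param handedness +1 (default) or -1; sign of the medio-lateral axis.
#' @return data.frame `start_s`, `angle_deg`, `defined`.
#' @export
#' @examples
#' f <- data.frame(start_s = 0, median_ap = 1, median_lat = 0)
#' supine_angle(f)$angle_deg   # 0: ventral
supine_angle <- function(features, min_planar_g = 0.2, handedness = 1) {
  ap <- features$median_ap
  lat <- handedness * features$median_lat
  planar <- sqrt(ap^2 + lat^2)
  ang <- wrap_deg(atan2(lat, ap) * 180 / pi)
  defined <- planar > min_planar_g
  if (!any(defined) && length(ang))
    stop("no window has a well-defined supine angle (planar gravity <= ",
         min_planar_g, " g)")
  if (length(ang) && !all(defined)) {
    idx <- ifelse(defined, seq_along(ang), NA_integer_)
    # carry last valid forward; leading undefined inherit first valid
    idx <- cummax_na(idx)
    first_ok <- which(defined)[1]
    idx[is.na(idx)] <- first_ok
    ang <- ang[idx]
  }
  data.frame(start_s = features$start_s, angle_deg = ang, defined = defined)
}

cummax_na <- function(idx) {
  last <- NA_integer_
  for (i in seq_along(idx)) {
    if (!is.na(idx[i])) last <- idx[i] else idx[i] <- last
  }
  idx
}

#' Sleeping-posture label of a rotation angle
#'
#' Partitions `(-180, 180]`: ventral for `|angle| < 45`, right for
#' `[45, 135)`, left for `(-135, -45]`, dorsal otherwise (beyond +-135).
#' The half-open boundaries make the four categories an exact partition.
#'
#' @param angle angle(s) in degrees in `(-180, 180]`.
#' @return character vector of labels.
#' @export
#' @examples
#' label_from_angle(c(0, 90, 180, -90))  # ventral right dorsal left
label_from_angle <- function(angle) {
  if (any(angle <= -180 | angle > 180)) stop("angle out of (-180, 180]")
  ifelse(abs(angle) < 45, "ventral",
         ifelse(angle >= 45 & angle < 135, "right",
                ifelse(angle > -135 & angle <= -45, "left", "dorsal")))
}

posture_labels <- function() c("ventral", "right", "dorsal", "left")

#' Adaptive angle-based segmentation of a supine period
#'
#' Streams over the per-window orientation angles of one contiguous lying
#' run, maintaining the running circular mean of the current segment. A
#' segment boundary is set when the current angle deviates by more than
#' `angle_change_deg` (default 30 degrees) from that running mean; the
#' deviating window starts the next segment. Because the reference is the
#' segment's own mean rather than fixed category borders, slow wobble
#' around a border (e.g. oscillating across the 45-degree ventral/right
#' line) stays one segment, while genuine turns are detected however the
#' segment sits relative to the category grid.
#'
#' Segments no longer than `min_segment_s` (default one analysis window;
#' such stubs arise when a large turn's transition window is itself more
#' than the threshold away from both flanking postures) are merged into
#' the following segment, so each physical turn yields one boundary. Set
#' `min_segment_s = 0` to disable merging.
#'
#' Each segment is labeled via [label_from_angle] of the circular mean over
#' all its windows. Segments exactly tile the supplied run.
#'
#' @param angles data.frame from [supine_angle] (`start_s`, `angle_deg`),
#'   time-ordered, from one contiguous lying run.
#' @param thresholds a [default_thresholds] object.
#' @param window_s duration of one angle sample in seconds (default 5).
#' @param min_segment_s minimal segment duration before stub-merging;
#'   defaults to `window_s`.
#' @return data.frame with `start_s`, `end_s`, `duration_s`,
#'   `mean_angle_deg`, `label`; zero rows for empty input.
#' @export
#' @examples
#' a <- data.frame(start_s = seq(0, 595, by = 5), angle_deg = 90)
#' segment_supine(a)  # one 600 s segment, label "right"
segment_supine <- function(angles, thresholds = default_thresholds(),
                           window_s = 5, min_segment_s = window_s) {
  n <- nrow(angles)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), mean_angle_deg = numeric(0),
                      label = character(0))
  if (is.null(n) || n == 0L) return(empty)
  ang <- wrap_deg(angles$angle_deg)
  t0 <- angles$start_s
  thr <- thresholds$angle_change_deg
  rad <- ang * pi / 180
  sn <- sin(rad); cs <- cos(rad)

  seg_start <- 1L
  ssin <- sn[1]; scos <- cs[1]
  starts <- integer(0); ends <- integer(0)
  if (n > 1L) for (i in 2:n) {
    mean_ang <- atan2(ssin, scos) * 180 / pi
    if (abs(circular_diff(ang[i], mean_ang)) > thr) {
      starts <- c(starts, seg_start); ends <- c(ends, i - 1L)
      seg_start <- i
      ssin <- sn[i]; scos <- cs[i]
    } else {
      ssin <- ssin + sn[i]; scos <- scos + cs[i]
    }
  }
  starts <- c(starts, seg_start); ends <- c(ends, n)

  # stub-merge: segments shorter than min_segment_s join the next segment
  # (the last stub, if any, joins the previous one)
  dur_of <- function(s, e) seg_end_time(t0, e, window_s) - t0[s]
  k <- 1L
  while (k <= length(starts) && length(starts) > 1L) {
    if (dur_of(starts[k], ends[k]) < min_segment_s + 1e-9) {
      if (k < length(starts)) {
        starts[k + 1L] <- starts[k]
        starts <- starts[-k]; ends <- ends[-k]
      } else {
        ends[k - 1L] <- ends[k]
        starts <- starts[-k]; ends <- ends[-k]
      }
    } else k <- k + 1L
  }

  mean_angle <- vapply(seq_along(starts), function(j)
    circular_mean(ang[starts[j]:ends[j]]), numeric(1))
  data.frame(
    start_s = t0[starts],
    end_s = seg_end_time(t0, ends, window_s),
    duration_s = seg_end_time(t0, ends, window_s) - t0[starts],
    mean_angle_deg = mean_angle,
    label = label_from_angle(mean_angle))
}

# end time of the window at index i: its start plus one window duration
seg_end_time <- function(t0, i, window_s) t0[i] + window_s
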