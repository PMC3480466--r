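#' Windowed gravity / activity features
#'
#' Separates gravitational from dynamic acceleration: over consecutive
#' windows (default 5 s, tiling the recording) the per-channel median
#' estimates the gravity projection, the per-channel SD the movement
#' variability, and the *activity* is the mean magnitude of the
#' median-subtracted sample vectors,
#' `mean_i sqrt(sum_c (x[i,c] - median_c)^2)`.
#'
#' The trailing partial window is dropped (never padded); a recording
#' shorter than one window yields zero rows. The default step equals the
#' window (non-overlapping tiling, which the duration-based indices assume);
#' a smaller step gives the sliding variant.
#'
#' @param rec an [accel_recording].
#' @param window_s window length in seconds (default 5).
#' @param step_s hop between window starts in seconds (default `window_s`).
#' @return a data.frame of class `window_features` with one row per window:
#'   `start_s` (seconds from recording start), `median_*`, `sd_*` for the
#'   four channels, and `activity` (g). Attributes: `window_s`, `step_s`,
#'   `sampling_rate`, `start_time`.
#' @export
#' @examples
#' ch <- data.frame(sternum_vertical = rep(0, 640), sternum_ap = rep(-1, 640),
#'                  sternum_lat = rep(0, 640), thigh_ap = rep(0, 640))
#' wf <- window_features(accel_recording(ch, 64))
#' nrow(wf)        # 2 windows from 10 s
#' wf$activity     # all zero: constant signal
window_features <- function(rec, window_s = 5, step_s = window_s) {
  validate_recording(rec)
  rate <- rec$sampling_rate
  win <- window_s * rate
  step <- step_s * rate
  if (abs(win - round(win)) > 1e-9 || abs(step - round(step)) > 1e-9)
    stop("window_s and step_s must align with the sample grid")
  win <- as.integer(round(win)); step <- as.integer(round(step))
  if (win < 2L) stop("window must span at least 2 samples")
  if (step < 1L) stop("step must be positive")
  x <- as.matrix(rec$channels[channel_names()])
  if (nrow(x) < win) {
    out <- empty_features()
  } else {
    st <- window_stats_cpp(x, win, step)
    m <- nrow(st$median)
    out <- data.frame(start_s = (seq_len(m) - 1L) * step / rate)
    colnames(st$median) <- paste0("median_", short_names())
    colnames(st$sd) <- paste0("sd_", short_names())
    out <- cbind(out, as.data.frame(st$median), as.data.frame(st$sd),
                 activity = st$activity)
  }
  structure(out, window_s = window_s, step_s = step_s,
            sampling_rate = rate, start_time = rec$start_time,
            class = c("window_features", "data.frame"))
}

short_names <- function() c("v", "ap", "lat", "thigh")

empty_features <- function() {
  nm <- c("start_s", paste0("median_", short_names()),
          paste0("sd_", short_names()), "activity")
  out <- as.data.frame(setNames(rep(list(numeric(0)), length(nm)), nm))
  out
}

#' Dynamic-activity magnitude of one sample block
#'
#' Reference (pure-R) evaluation of the activity formula: the mean over the
#' block's samples of the Euclidean norm of the four median-subtracted
#' channel values. [window_features] computes the same quantity per window
#' in compiled code.
#'
#' @param samples numeric matrix, samples x 4 channels, in g.
#' @param medians numeric 4-vector of per-channel medians (gravity), in g.
#' @return non-negative scalar in g.
#' @export
#' @examples
#' x <- matrix(0, nrow = 10, ncol = 4)
#' x[1, 2] <- 0.5
#' window_activity(x, c(0, 0, 0, 0))  # 0.5 / 10 = 0.05
window_activity <- function(samples, medians) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stop("block must be nonempty")
  if (ncol(samples) != length(medians)) stop("medians length must match channels")
  dev <- sweep(samples, 2L, as.numeric(medians))
  mean(sqrt(rowSums(dev^2)))
}
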