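#' Decision constants of the posture / sleep-index method
#'
#' Bundles every threshold the pipeline uses into one validated object.
#' Defaults are the published decision constants of the method:
#' \describe{
#'   \item{vertical_g}{0.66 g. A window is *lying* when the absolute median
#'     gravity on the sternum vertical axis falls below this value
#'     (equivalently the torso deviates more than ~49 degrees from upright;
#'     the descriptive "40 degrees" figure corresponds to ~0.77 g and is not
#'     the operative constant).}
#'   \item{thigh_g}{0.5 g. Among non-lying windows, *sitting* when the
#'     absolute median thigh antero-posterior gravity exceeds this value,
#'     otherwise *upright* (standing/walking).}
#'   \item{angle_change_deg}{30 degrees. Adaptive segmentation closes a
#'     supine segment when the current orientation angle deviates more than
#'     this from the running circular mean of the segment.}
#'   \item{supine_min_s}{50 s (ten 5-s windows). Minimal duration of a lying
#'     run to count as a supine episode.}
#'   \item{sleep_activity_g}{0.15 g. Supine windows with dynamic activity
#'     strictly below this count as asleep.}
#'   \item{still_min_min}{3 minutes. Minimal quiet run defining sleep onset
#'     for the still-position latency.}
#'   \item{long_posture_min}{15 minutes. Segments longer than this count as
#'     long, settled postures.}
#'   \item{night_start, night_end}{"20:00" and "10:00". Clock window the
#'     analysis is restricted to (spans midnight).}
#'   \item{max_rise_min}{30 minutes. A non-lying gap between supine episodes
#'     longer than this ends the in-bed span (treated as getting up for the
#'     day rather than a rise).}
#'   \item{vertical_sign}{0 (magnitude rule). Set to +1 or -1 to pin a signed
#'     convention for the vertical axis instead of using |median|.}
#' }
#'
#' @param ... named overrides of the defaults listed above.
#' @return an object of class `sleep_thresholds` (a named list).
#' @export
#' @examples
#' th <- default_thresholds(sleep_activity_g = 0.2)
#' th$vertical_g
default_thresholds <- function(...) {
  th <- list(
    vertical_g       = 0.66,
    thigh_g          = 0.50,
    angle_change_deg = 30,
    supine_min_s     = 50,
    sleep_activity_g = 0.15,
    still_min_min    = 3,
    long_posture_min = 15,
    night_start      = "20:00",
    night_end        = "10:00",
    max_rise_min     = 30,
    vertical_sign    = 0
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(th))
    if (length(bad)) stop("unknown threshold field(s): ", paste(bad, collapse = ", "))
    th[names(dots)] <- dots
  }
  class(th) <- "sleep_thresholds"
  validate_thresholds(th)
  th
}

#' @export
print.sleep_thresholds <- function(x, ...) {
  cat("<sleep_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

validate_thresholds <- function(th) {
  num <- c("vertical_g", "thigh_g", "angle_change_deg", "supine_min_s",
           "sleep_activity_g", "still_min_min", "long_posture_min",
           "max_rise_min")
  for (nm in num) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("threshold '", nm, "' must be a single positive number")
  }
  for (nm in c("night_start", "night_end")) parse_clock(th[[nm]])
  if (!th$vertical_sign %in% c(-1, 0, 1))
    stop("vertical_sign must be -1, 0 or 1")
  invisible(th)
}

#' Read / write a threshold configuration
#'
#' Thresholds are stored as a flat JSON object so that calibration output can
#' be fed back into `classify`/`summarize` runs.
#'
#' @param th a `sleep_thresholds` object.
#' @param path file path.
#' @return `read_thresholds` returns a `sleep_thresholds` object.
#' @export
write_thresholds <- function(th, path) {
  stopifnot(inherits(th, "sleep_thresholds"))
  jsonlite::write_json(unclass(th), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_thresholds, x)
}
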