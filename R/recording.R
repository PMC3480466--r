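#' Four-channel accelerometer recording
#'
#' A recording holds four synchronized acceleration channels in units of g
#' (standard gravity, 9.81 m/s^2): the three sternum axes (vertical,
#' antero-posterior, medio-lateral) and the thigh antero-posterior axis,
#' sampled on a regular grid `start_time + i / sampling_rate`.
#'
#' @param channels a data.frame (or matrix) with the four canonical columns
#'   `sternum_vertical`, `sternum_ap`, `sternum_lat`, `thigh_ap`, one sample
#'   per row, values in g.
#' @param sampling_rate samples per second (Hz), default 64.
#' @param start_time clock timestamp of the first sample (POSIXct or an
#'   ISO-8601 string, interpreted as UTC).
#' @param subject_id free-text identifier.
#' @return an object of class `accel_recording`.
#' @export
#' @examples
#' ch <- data.frame(sternum_vertical = rep(0, 640), sternum_ap = rep(-1, 640),
#'                  sternum_lat = rep(0, 640), thigh_ap = rep(0.2, 640))
#' rec <- accel_recording(ch, 64, "2026-01-01 23:00:00", "demo")
#' duration_s(rec)  # 10 s
accel_recording <- function(channels, sampling_rate = 64,
                            start_time = "2000-01-01 00:00:00",
                            subject_id = "anonymous") {
  channels <- as.data.frame(channels)
  rec <- structure(
    list(subject_id = as.character(subject_id),
         start_time = parse_start_time(start_time),
         sampling_rate = as.numeric(sampling_rate),
         channels = channels),
    class = "accel_recording")
  validate_recording(rec)
  rec
}

#' Canonical channel names
#' @return character vector of the four channel names in canonical order.
#' @export
channel_names <- function() c("sternum_vertical", "sternum_ap", "sternum_lat", "thigh_ap")

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording> subject '%s'\n", x$subject_id))
  cat(sprintf("  start    %s UTC\n", format_iso(x$start_time)))
  cat(sprintf("  rate     %g Hz\n", x$sampling_rate))
  cat(sprintf("  samples  %d (%.1f s)\n", nrow(x$channels), duration_s(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `accel_recording`.
#' @export
duration_s <- function(rec) nrow(rec$channels) / rec$sampling_rate

#' Validate a recording against its invariants
#'
#' Checks: the four canonical channels are present, equal length >= 1,
#' all values finite with |value| <= 16 g, and sampling_rate > 0.
#'
#' @param rec an `accel_recording`.
#' @return the recording, invisibly; otherwise an error.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "accel_recording")) stop("not an accel_recording")
  missing <- setdiff(channel_names(), names(rec$channels))
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  rec$channels <- rec$channels[channel_names()]
  if (!is.numeric(rec$sampling_rate) || length(rec$sampling_rate) != 1L ||
      !is.finite(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  n <- nrow(rec$channels)
  if (n < 1L) stop("recording must contain at least one sample")
  for (nm in channel_names()) {
    v <- rec$channels[[nm]]
    if (!is.numeric(v)) stop("channel '", nm, "' is not numeric")
    if (anyNA(v) || any(!is.finite(v)))
      stop("channel '", nm, "' contains non-finite values (first at row ",
           which(!is.finite(v))[1], ")")
    if (any(abs(v) > 16))
      stop("channel '", nm, "' exceeds the sensor range of 16 g (row ",
           which(abs(v) > 16)[1], ")")
  }
  invisible(rec)
}

#' Read a recording from disk
#'
#' The canonical storage is a comma-separated table with one sample per row,
#' a required header naming the four canonical channels, and `#`-prefixed
#' metadata lines before the header:
#' \preformatted{
#' # subject_id=S001
#' # start_time=2026-01-01T22:30:00
#' # sampling_rate=64
#' sternum_vertical,sternum_ap,sternum_lat,thigh_ap
#' -0.98,0.01,-0.02,0.05
#' }
#' Values are in g; dot decimal separator. An optional metadata line
#' `# units=ms2` declares values in m/s^2, which are converted to g on read
#' (readers never rescale silently otherwise).
#'
#' @param path file path.
#' @param format only `"csv"` is supported in this build; `"edf"` is reserved
#'   and raises an informative error (no EDF backend is available offline).
#' @return a validated `accel_recording`.
#' @export
read_recording <- function(path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (format == "edf")
    stop("EDF input is not supported in this build; convert to the CSV channel table")
  if (!file.exists(path)) stop("no such file: ", path)
  head_lines <- readLines(path, n = 100L)
  meta_idx <- grep("^#", head_lines)
  meta_idx <- meta_idx[meta_idx == seq_along(meta_idx)]  # leading block only
  meta <- parse_meta(head_lines[meta_idx])
  skip <- length(meta_idx)
  dt <- data.table::fread(path, skip = skip, header = TRUE, sep = ",",
                          colClasses = "character", data.table = FALSE)
  missing <- setdiff(channel_names(), names(dt))
  if (length(missing))
    stop("recording file lacks channel(s): ", paste(missing, collapse = ", "))
  dt <- dt[channel_names()]
  for (nm in channel_names()) {
    v <- suppressWarnings(as.numeric(dt[[nm]]))
    bad <- which(is.na(v) & !is.na(dt[[nm]]) | is.na(dt[[nm]]))
    if (length(bad))
      stop("non-numeric value in channel '", nm, "' at data row ", bad[1])
    dt[[nm]] <- v
  }
  rate <- meta$sampling_rate
  if (is.null(rate)) stop("metadata header lacks 'sampling_rate'")
  units <- if (is.null(meta$units)) "g" else meta$units
  if (identical(units, "ms2")) dt[channel_names()] <- dt[channel_names()] / 9.81
  else if (!identical(units, "g")) stop("unknown units: ", units)
  accel_recording(dt,
                  sampling_rate = as.numeric(rate),
                  start_time = if (is.null(meta$start_time)) "2000-01-01 00:00:00" else meta$start_time,
                  subject_id = if (is.null(meta$subject_id)) "anonymous" else meta$subject_id)
}

parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      out[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  out
}

#' Write a recording to the canonical CSV channel table
#'
#' @param rec an `accel_recording`.
#' @param path destination path.
#' @param digits significant digits for the values (default keeps full
#'   double precision round-trips well under 1e-9 g).
#' @export
write_recording <- function(rec, path, digits = 15) {
  validate_recording(rec)
  writeLines(c(
    paste0("# subject_id=", rec$subject_id),
    paste0("# start_time=", format_iso(rec$start_time)),
    paste0("# sampling_rate=", format(rec$sampling_rate, digits = 15)),
    "# units=g"), path)
  ch <- rec$channels[channel_names()]
  for (nm in channel_names()) ch[[nm]] <- signif(ch[[nm]], digits)
  data.table::fwrite(ch, path, sep = ",", row.names = FALSE, append = TRUE,
                     col.names = TRUE)
  invisible(path)
}
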