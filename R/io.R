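#' Write / read a posture-segment table
#'
#' Segments are stored as a comma-separated table with ISO-8601 timestamps
#' and angles in degrees: columns `start`, `end`, `duration_s`,
#' `mean_angle_deg`, `label`. An empty segment list yields a valid file
#' with only the header.
#'
#' @param segments a segment data.frame ([supine_segments] /
#'   [segment_supine] output, or one already carrying POSIXct `start`,
#'   `end` columns).
#' @param path destination path.
#' @param start_time recording start (POSIXct or string); required to turn
#'   relative `start_s`/`end_s` columns into timestamps.
#' @return `read_segments` returns the table with POSIXct `start`, `end`.
#' @export
write_segments <- function(segments, path, start_time = NULL) {
  if (!is.null(segments$start_s)) {
    if (is.null(start_time)) stop("start_time needed to timestamp relative segments")
    t0 <- parse_start_time(start_time)
    segments$start <- t0 + segments$start_s
    segments$end <- t0 + segments$end_s
  }
  if (nrow(segments)) {
    if (any(segments$start >= segments$end)) stop("segments must satisfy start < end")
    if (any(diff(as.numeric(segments$start)) < 0)) stop("segments must be ordered")
    if (any(as.numeric(segments$end[-nrow(segments)]) >
            as.numeric(segments$start[-1]) + 1e-9))
      stop("segments must be non-overlapping")
  }
  out <- data.frame(start = format_iso(segments$start),
                    end = format_iso(segments$end),
                    duration_s = as.numeric(segments$end) - as.numeric(segments$start),
                    mean_angle_deg = segments$mean_angle_deg,
                    label = segments$label)
  data.table::fwrite(out, path, sep = ",")
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  dt <- data.table::fread(path, sep = ",", data.table = FALSE,
                          colClasses = list(character = c("start", "end", "label")))
  dt$start <- parse_start_time_vec(dt$start)
  dt$end <- parse_start_time_vec(dt$end)
  dt
}

parse_start_time_vec <- function(x) {
  as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
}

#' Write / read a night summary
#'
#' JSON stores the summary as one object with the posture fractions
#' nested; CSV flattens to a single row with `posture_fraction_<label>`
#' columns.
#'
#' @param summary a `night_summary` ([summarize_night] output).
#' @param path destination path.
#' @param format `"json"` (default) or `"csv"`.
#' @return `read_summary` returns a `night_summary`.
#' @export
write_summary <- function(summary, path, format = c("json", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "night_summary"))
  x <- unclass(summary)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    flat <- x
    fr <- flat$posture_fractions
    flat$posture_fractions <- NULL
    for (nm in names(fr)) flat[[paste0("posture_fraction_", nm)]] <- unname(fr[nm])
    data.table::fwrite(as.data.frame(flat), path, sep = ",")
  }
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    x$posture_fractions <- unlist(x$posture_fractions)
  } else {
    row <- data.table::fread(path, sep = ",", data.table = FALSE)
    x <- as.list(row)
    fr_cols <- grep("^posture_fraction_", names(x), value = TRUE)
    fr <- unlist(x[fr_cols])
    names(fr) <- sub("^posture_fraction_", "", fr_cols)
    x[fr_cols] <- NULL
    x$posture_fractions <- fr[posture_labels()]
  }
  x$rises_total <- as.integer(x$rises_total)
  x$rises_first_hour <- as.integer(x$rises_first_hour)
  class(x) <- "night_summary"
  x
}
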