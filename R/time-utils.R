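# Clock / timestamp helpers. The recording time grid is
# start_time + i / sampling_rate, with half-open windows [start, end).

#' Parse a clock time of day
#'
#' @param x a string `"HH:MM"` or `"HH:MM:SS"`.
#' @return seconds since midnight (numeric scalar).
#' @keywords internal
parse_clock <- function(x) {
  if (is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x < 86400)
    return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L)
    stop("clock time must be a single \"HH:MM[:SS]\" string")
  p <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (!length(p) %in% 2:3 || anyNA(suppressWarnings(as.numeric(p))))
    stop("malformed clock time: ", x)
  p <- as.numeric(p)
  if (length(p) == 2L) p <- c(p, 0)
  if (p[1] < 0 || p[1] > 23 || p[2] < 0 || p[2] > 59 || p[3] < 0 || p[3] >= 60)
    stop("malformed clock time: ", x)
  sum(p * c(3600, 60, 1))
}

#' Seconds since midnight of POSIXct timestamps
#' @keywords internal
clock_seconds <- function(time) {
  as.numeric(time) %% 86400 + 0 # POSIXct assumed UTC throughout the package
}

#' Is a clock time inside the (possibly midnight-spanning) night window?
#'
#' @param clock_s seconds since midnight.
#' @param night_start,night_end clock strings or seconds since midnight.
#' @return logical vector; half-open convention `[start, end)`.
#' @keywords internal
in_night_window <- function(clock_s, night_start, night_end) {
  ns <- parse_clock(night_start)
  ne <- parse_clock(night_end)
  if (ns == ne) return(rep(TRUE, length(clock_s)))   # degenerate: full day
  if (ns < ne) clock_s >= ns & clock_s < ne
  else         clock_s >= ns | clock_s < ne          # spans midnight
}

parse_start_time <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC"))
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  if (is.na(t)) stop("cannot parse start time: ", x)
  t
}

format_iso <- function(time) format(time, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
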