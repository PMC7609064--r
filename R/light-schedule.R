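#' Define a light:dark schedule
#'
#' A light schedule anchors Zeitgeber time (ZT): ZT 0 is lights-on, and under
#' the default 12 hr:12 hr light:dark cycle ZT 0-12 is day and ZT 12-24 is
#' night. Phase assignment uses half-open intervals, so the minute starting
#' exactly at lights-off belongs to the night.
#'
#' @param lights_on Clock time of lights-on, as \code{"HH:MM:SS"} (or
#'   \code{"HH:MM"}).
#' @param photoperiod_hours Hours of light per cycle; must lie strictly
#'   between 0 and \code{period_hours}.
#' @param period_hours Cycle length in hours; fixed at 24 for LD experiments.
#' @return An object of class \code{light_schedule}.
#' @examples
#' light_schedule("09:00:00")
#' @export
light_schedule <- function(lights_on = "09:00:00", photoperiod_hours = 12,
                           period_hours = 24) {
  if (period_hours != 24) stop2("period_hours is fixed at 24")
  if (!(photoperiod_hours > 0 && photoperiod_hours < period_hours)) {
    stop2("photoperiod_hours must lie in (0, ", period_hours, ")")
  }
  secs <- parse_clock_time(lights_on)
  structure(
    list(lights_on = lights_on, lights_on_s = secs,
         photoperiod_hours = photoperiod_hours, period_hours = period_hours),
    class = "light_schedule")
}

parse_clock_time <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (!length(parts) %in% 2:3) stop2("clock time must be HH:MM or HH:MM:SS")
  parts <- as.numeric(parts)
  if (anyNA(parts)) stop2("unparseable clock time: ", x)
  s <- parts[1] * 3600 + parts[2] * 60 + if (length(parts) == 3) parts[3] else 0
  if (s < 0 || s >= 86400) stop2("clock time out of range: ", x)
  s
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("Light schedule: lights on %s, %g:%g LD\n", x$lights_on,
              x$photoperiod_hours, x$period_hours - x$photoperiod_hours))
  invisible(x)
}

#' Zeitgeber-time labels for every minute of a recording
#'
#' Maps each minute of an activity recording to ZT minutes (0-1439) and a
#' day/night phase tag. Day is the half-open interval [ZT0, lights-off);
#' the minute at lights-off itself is night.
#'
#' @param recording A \code{dam_recording}, or a POSIXct/character start
#'   datetime (in which case \code{n_minutes} must be given).
#' @param schedule A \code{\link{light_schedule}}.
#' @param n_minutes Number of minutes to label when \code{recording} is a
#'   start datetime.
#' @return A data frame with columns \code{minute} (0-based index),
#'   \code{zt_min} (minutes since lights-on, in [0, 1440)) and \code{phase}
#'   (\code{"day"} or \code{"night"}).
#' @examples
#' sched <- light_schedule("09:00:00")
#' zt <- to_zt("2026-01-05 09:00:00", sched, n_minutes = 10)
#' zt$zt_min[1]  # 0: recording starts at lights-on
#' @export
to_zt <- function(recording, schedule, n_minutes = NULL) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (inherits(recording, "dam_recording")) {
    start <- recording$start_datetime
    n_minutes <- length(recording$minutes)
  } else {
    start <- recording
    if (is.null(n_minutes)) stop2("n_minutes required when recording is a datetime")
  }
  start <- as.POSIXct(start, tz = "UTC")
  if (is.na(start)) stop2("unparseable start datetime")
  sec_of_day <- as.numeric(start) %% 86400
  offset_min <- ((sec_of_day - schedule$lights_on_s) / 60) %% 1440
  minute <- seq_len(n_minutes) - 1L
  zt_min <- (offset_min + minute) %% 1440
  day_len <- schedule$photoperiod_hours * 60
  data.frame(minute = minute, zt_min = zt_min,
             phase = ifelse(zt_min < day_len, "day", "night"),
             stringsAsFactors = FALSE)
}
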