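#' @title Activity-monitor file dialect
#' @description
#' Tab-separated text, one row per minute, no header. Columns 1-8 are
#' metadata: row index (1-based), date (\code{DD Mmm YY}, English month
#' abbreviation), time (\code{HH:MM:SS}), status code (1 = valid reading),
#' and four reserved columns. Reserved column 5 of the \emph{first} row may
#' carry a 32-character 0/1 occupancy mask distinguishing empty channels
#' from channels housing an (possibly inactive) fly; all other reserved
#' cells are 0.
#'
#' Single-beam files append 32 channel-count columns (columns 9-40), the
#' per-minute beam-break counts of channels 1-32.
#'
#' Multi-beam files append, for each of the 32 channels, 19 columns: the
#' per-minute break counts at the 17 beam positions, then the precomputed
#' \code{moves} (adjacent inter-beam transitions; a jump over b beams in one
#' tick counts b) and \code{counts} (moves plus intra-beam movements)
#' columns. At every minute \code{counts >= moves}.
#' @name dam_dialect
#' @keywords internal
NULL

DAM_CHANNELS <- 32L
DAM_BEAMS <- 17L

month_num <- function(mmm) match(mmm, month.abb)

format_dam_date <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  sprintf("%02d %s %02d", lt$mday, month.abb[lt$mon + 1L], lt$year %% 100L)
}

parse_dam_datetime <- function(date, time) {
  parts <- strsplit(date, " ", fixed = TRUE)
  d <- vapply(parts, `[`, "", 1L)
  m <- month_num(vapply(parts, `[`, "", 2L))
  y <- vapply(parts, `[`, "", 3L)
  if (anyNA(m)) stop2("unparseable month in monitor file date column")
  as.POSIXct(sprintf("20%s-%02d-%s %s", y, m, d, time), tz = "UTC")
}

#' Construct a single-fly activity recording
#'
#' @param fly_id Opaque identifier.
#' @param minutes Integer vector of per-minute activity counts (>= 0).
#' @param start_datetime Wall-clock time of the first minute.
#' @param channel Monitor channel, 1-32.
#' @param beam_mode One of \code{"single"}, \code{"multibeam_moves"},
#'   \code{"multibeam_counts"}.
#' @param condition Named list or character vector of condition labels
#'   (sex pairing, diet, genotype, ...).
#' @param temperature_schedule Optional \code{\link{temperature_epochs}}
#'   table.
#' @param occupied Whether the channel housed a fly (\code{FALSE} marks an
#'   empty tube written as all-zero).
#' @return An object of class \code{dam_recording}.
#' @export
dam_recording <- function(fly_id, minutes, start_datetime, channel = 1L,
                          beam_mode = c("single", "multibeam_moves", "multibeam_counts"),
                          condition = list(), temperature_schedule = NULL,
                          occupied = TRUE) {
  beam_mode <- match.arg(beam_mode)
  if (!is_count_vector(minutes)) {
    stop2("minutes must be nonnegative integer counts without gaps")
  }
  channel <- as.integer(channel)
  if (channel < 1L || channel > DAM_CHANNELS) stop2("channel must be in 1..32")
  start_datetime <- as.POSIXct(start_datetime, tz = "UTC")
  if (is.na(start_datetime)) stop2("unparseable start_datetime")
  if (!is.null(temperature_schedule)) {
    validate_temperature_epochs(temperature_schedule, length(minutes))
  }
  structure(
    list(fly_id = as.character(fly_id), channel = channel,
         condition = condition, start_datetime = start_datetime,
         minutes = as.integer(minutes), beam_mode = beam_mode,
         temperature_schedule = temperature_schedule,
         occupied = isTRUE(occupied)),
    class = "dam_recording")
}

#' @export
print.dam_recording <- function(x, ...) {
  cat(sprintf("<dam_recording> fly %s, channel %d, %s mode, %d min (%.1f days)\n",
              x$fly_id, x$channel, x$beam_mode, length(x$minutes),
              length(x$minutes) / 1440))
  if (!x$occupied) cat("  (empty channel)\n")
  invisible(x)
}

#' Temperature epochs tiling a recording
#'
#' Epochs are half-open minute intervals \code{[start_minute, end_minute)}
#' that must be ordered, non-overlapping and tile the recording. Used for
#' thermogenetic (TrpA1) designs with baseline / activation / recovery
#' phases; the activation temperature must exceed the baseline temperature.
#'
#' @param label Character vector over \code{baseline}, \code{activation},
#'   \code{recovery}.
#' @param start_minute,end_minute Integer epoch bounds (half-open).
#' @param temperature_C Temperature per epoch.
#' @return A data frame of class \code{temperature_epochs}.
#' @export
temperature_epochs <- function(label, start_minute, end_minute, temperature_C) {
  label <- match.arg(label, c("baseline", "activation", "recovery"),
                     several.ok = TRUE)
  df <- data.frame(label = label, start_minute = as.integer(start_minute),
                   end_minute = as.integer(end_minute),
                   temperature_C = as.numeric(temperature_C),
                   stringsAsFactors = FALSE)
  class(df) <- c("temperature_epochs", "data.frame")
  df
}

validate_temperature_epochs <- function(ep, n_minutes) {
  if (nrow(ep) == 0L) stop2("temperature schedule is empty")
  if (ep$start_minute[1] != 0L || ep$end_minute[nrow(ep)] != n_minutes ||
      any(ep$start_minute[-1] != ep$end_minute[-nrow(ep)])) {
    stop2("temperature epochs must tile the recording without gaps or overlap")
  }
  if (any(ep$end_minute <= ep$start_minute)) stop2("empty temperature epoch")
  base <- ep$temperature_C[ep$label == "baseline"]
  act <- ep$temperature_C[ep$label == "activation"]
  if (length(base) && length(act) && any(act <= max(base))) {
    stop2("activation temperature must exceed baseline temperature")
  }
  invisible(ep)
}

check_timestamps <- function(times) {
  if (length(times) > 1L) {
    d <- as.numeric(diff(times), units = "mins")
    if (any(d <= 0)) stop2("non-monotonic timestamps in monitor file")
    gap <- which(d > 1.000001)
    if (length(gap)) {
      stop2("gap in monitor file timestamps: minute after ",
            format(times[gap[1]], "%Y-%m-%d %H:%M:%S", tz = "UTC"),
            " is missing")
    }
    if (any(abs(d - 1) > 1e-6)) stop2("monitor rows are not at 1-min spacing")
  }
  invisible(times)
}

#' Read an activity-monitor text file
#'
#' Parses the tab-separated monitor dialect (see \link{dam_dialect}) into
#' one \code{\link{dam_recording}} per populated channel. Timestamps must be
#' chronological at exactly 1-minute spacing; a gap or a negative count is a
#' hard error, never silently repaired.
#'
#' @param path File path.
#' @param beam_mode \code{"single"} for single-beam files; for multi-beam
#'   files, \code{"multibeam_moves"} selects the adjacent-beam-transition
#'   column and \code{"multibeam_counts"} the column that also includes
#'   intra-beam movements.
#' @param condition Optional condition labels attached to every recording.
#' @param fly_ids Optional character vector of 32 fly ids; defaults to
#'   \code{<file>_ch<channel>}.
#' @return A list of \code{dam_recording} (class \code{dam_recording_set})
#'   for populated channels, with attribute \code{empty_channels} listing
#'   channels the occupancy mask marks empty.
#' @export
read_monitor_file <- function(path, beam_mode = c("single", "multibeam_moves",
                                                  "multibeam_counts"),
                              condition = list(), fly_ids = NULL) {
  beam_mode <- match.arg(beam_mode)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  expected <- if (beam_mode == "single") 8L + DAM_CHANNELS else
    8L + DAM_CHANNELS * (DAM_BEAMS + 2L)
  if (ncol(raw) != expected) {
    stop2("monitor file has ", ncol(raw), " columns; expected ", expected,
          " for beam_mode ", beam_mode)
  }
  times <- parse_dam_datetime(raw[[2]], raw[[3]])
  if (anyNA(times)) stop2("unparseable timestamp in monitor file")
  check_timestamps(times)

  mask <- rep(TRUE, DAM_CHANNELS)
  if (grepl("^[01]{32}$", raw[[5]][1])) {
    mask <- strsplit(raw[[5]][1], "")[[1]] == "1"
  }
  counts_for_channel <- function(ch) {
    if (beam_mode == "single") {
      col <- 8L + ch
      as.numeric(raw[[col]])
    } else {
      base <- 8L + (ch - 1L) * (DAM_BEAMS + 2L)
      moves <- as.numeric(raw[[base + DAM_BEAMS + 1L]])
      counts <- as.numeric(raw[[base + DAM_BEAMS + 2L]])
      if (any(counts < moves)) {
        stop2("multi-beam channel ", ch, ": counts column < moves column")
      }
      if (beam_mode == "multibeam_moves") moves else counts
    }
  }
  if (is.null(fly_ids)) {
    stem <- sub("\\.[^.]*$", "", basename(path))
    fly_ids <- sprintf("%s_ch%02d", stem, seq_len(DAM_CHANNELS))
  }
  recs <- list()
  for (ch in seq_len(DAM_CHANNELS)) {
    if (!mask[ch]) next
    m <- counts_for_channel(ch)
    if (any(m < 0)) stop2("negative count in channel ", ch)
    if (any(m != floor(m))) stop2("non-integer count in channel ", ch)
    recs[[length(recs) + 1L]] <- dam_recording(
      fly_id = fly_ids[ch], minutes = as.integer(m),
      start_datetime = times[1], channel = ch, beam_mode = beam_mode,
      condition = condition)
  }
  structure(recs, class = "dam_recording_set",
            empty_channels = which(!mask))
}

#' @export
print.dam_recording_set <- function(x, ...) {
  cat(sprintf("<dam_recording_set> %d populated channels, %d empty\n",
              length(x), length(attr(x, "empty_channels"))))
  invisible(x)
}

#' Write recordings to an activity-monitor text file
#'
#' Emits the single-beam dialect (see \link{dam_dialect}). All recordings
#' must share a start time and length; channels not present in the set are
#' written as all-zero and marked empty in the occupancy mask, so an empty
#' tube is never mistaken for an inactive fly.
#'
#' @param recordings A \code{dam_recording_set}, list of
#'   \code{dam_recording}, or a single recording.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_monitor_file <- function(recordings, path) {
  if (inherits(recordings, "dam_recording")) recordings <- list(recordings)
  if (length(recordings) == 0L) stop2("no recordings to write")
  lens <- vapply(recordings, function(r) length(r$minutes), 0L)
  if (length(unique(lens)) != 1L) stop2("recordings have mixed lengths")
  starts <- vapply(recordings, function(r) as.numeric(r$start_datetime), 0)
  if (length(unique(starts)) != 1L) stop2("recordings have mixed start times")
  chans <- vapply(recordings, function(r) r$channel, 0L)
  if (anyDuplicated(chans)) stop2("duplicate channel numbers")
  n <- lens[1]
  start <- recordings[[1]]$start_datetime
  times <- start + 60 * (seq_len(n) - 1)
  mat <- matrix(0L, nrow = n, ncol = DAM_CHANNELS)
  mask <- rep("0", DAM_CHANNELS)
  for (r in recordings) {
    mat[, r$channel] <- r$minutes
    mask[r$channel] <- if (r$occupied) "1" else "0"
  }
  reserved5 <- c(paste(mask, collapse = ""), rep("0", n - 1L))
  meta <- data.frame(seq_len(n), format_dam_date(times),
                     format(times, "%H:%M:%S", tz = "UTC"), 1L,
                     reserved5, 0L, 0L, 0L, stringsAsFactors = FALSE)
  utils::write.table(cbind(meta, as.data.frame(mat)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a multi-beam activity-monitor text file
#'
#' @param flies List of multi-beam simulations (elements with \code{beams}
#'   matrix and \code{moves}/\code{counts} vectors, as returned by
#'   \code{\link{simulate_multibeam}}), each with a \code{channel}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_multibeam_file <- function(flies, path) {
  if (length(flies) == 0L) stop2("no recordings to write")
  n <- length(flies[[1]]$moves$minutes)
  start <- flies[[1]]$moves$start_datetime
  times <- start + 60 * (seq_len(n) - 1)
  mat <- matrix(0L, nrow = n, ncol = DAM_CHANNELS * (DAM_BEAMS + 2L))
  mask <- rep("0", DAM_CHANNELS)
  for (f in flies) {
    ch <- f$moves$channel
    base <- (ch - 1L) * (DAM_BEAMS + 2L)
    mat[, base + seq_len(DAM_BEAMS)] <- f$beams
    mat[, base + DAM_BEAMS + 1L] <- f$moves$minutes
    mat[, base + DAM_BEAMS + 2L] <- f$counts$minutes
    mask[ch] <- "1"
  }
  reserved5 <- c(paste(mask, collapse = ""), rep("0", n - 1L))
  meta <- data.frame(seq_len(n), format_dam_date(times),
                     format(times, "%H:%M:%S", tz = "UTC"), 1L,
                     reserved5, 0L, 0L, 0L, stringsAsFactors = FALSE)
  utils::write.table(cbind(meta, as.data.frame(mat)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export per-minute series as CSV
#'
#' Writes the documented per-minute CSV with header
#' \code{fly_id,zt_min,phase,count}.
#'
#' @param recordings A \code{dam_recording} or list of them.
#' @param schedule A \code{\link{light_schedule}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
export_minutes_csv <- function(recordings, schedule, path) {
  if (inherits(recordings, "dam_recording")) recordings <- list(recordings)
  tabs <- lapply(recordings, function(r) {
    zt <- to_zt(r, schedule)
    data.frame(fly_id = r$fly_id, zt_min = zt$zt_min, phase = zt$phase,
               count = r$minutes, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
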