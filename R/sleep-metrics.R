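#' Score sleep from per-minute activity
#'
#' Sleep is a period of inactivity (zero counts) lasting at least
#' \code{min_bout} minutes; maximal zero-count runs of at least that length
#' become sleep bouts, shorter runs contribute no sleep. A run truncated by
#' the recording boundary counts if its observed length qualifies.
#'
#' @param x A \code{\link{dam_recording}} or a nonnegative integer vector of
#'   per-minute counts.
#' @param min_bout Minimum bout length in minutes (default 5, the standard
#'   operational definition).
#' @return An object of class \code{sleep_series}: per-minute logical
#'   \code{asleep}, a \code{bouts} data frame (\code{start_minute}, 0-based,
#'   and \code{duration_min}), \code{fly_id} and \code{source_beam_mode}.
#' @examples
#' s <- score_sleep(c(0, 0, 0, 0, 0, 3, 0, 0, 0, 0))
#' s$bouts            # one 5-min bout at minute 0; trailing 4-zero run is not sleep
#' sum(s$asleep)
#' @export
score_sleep <- function(x, min_bout = 5L) {
  if (inherits(x, "dam_recording")) {
    counts <- x$minutes; fly_id <- x$fly_id; mode <- x$beam_mode
  } else {
    counts <- x; fly_id <- NA_character_; mode <- NA_character_
  }
  if (length(counts) == 0L) stop2("minutes vector is empty")
  if (!is_count_vector(counts)) stop2("counts must be nonnegative integers")
  r <- rle(counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_bout
  bouts <- data.frame(start_minute = starts[keep], duration_min = r$lengths[keep])
  asleep <- rep(FALSE, length(counts))
  for (i in seq_len(nrow(bouts))) {
    asleep[bouts$start_minute[i] + seq_len(bouts$duration_min[i])] <- TRUE
  }
  structure(list(fly_id = fly_id, asleep = asleep, bouts = bouts,
                 source_beam_mode = mode, min_bout = as.integer(min_bout)),
            class = "sleep_series")
}

#' @export
print.sleep_series <- function(x, ...) {
  cat(sprintf("<sleep_series> %d min, %d asleep, %d bouts (mean %.1f min)\n",
              length(x$asleep), sum(x$asleep), nrow(x$bouts),
              if (nrow(x$bouts)) mean(x$bouts$duration_min) else NA_real_))
  invisible(x)
}

# Complete ZT cycles: returns for each minute the 1-based index of the
# complete 24-h ZT window (lights-on to lights-on) it falls in, or NA for
# minutes outside any complete window.
zt_window_index <- function(zt) {
  abs_zt <- zt$zt_min[1] + zt$minute  # minutes since the lights-on before start
  win <- abs_zt %/% 1440 + ifelse(zt$zt_min[1] > 0, 0L, 1L)
  # window w is complete iff all 1440 of its minutes are in the recording
  first_zt0 <- if (zt$zt_min[1] == 0) 0L else 1440L - zt$zt_min[1]
  w_of <- (abs_zt - (first_zt0 + zt$zt_min[1])) %/% 1440 + 1L
  w_of[zt$minute < first_zt0] <- NA_integer_
  n_complete <- (length(zt$minute) - first_zt0) %/% 1440
  w_of[!is.na(w_of) & w_of > n_complete] <- NA_integer_
  w_of
}

#' Summarize a sleep series over a 24-h Zeitgeber window
#'
#' Computes daytime, nighttime and total sleep minutes, the 30-min sleep
#' profile, and per-night sleep across all complete nights of the
#' recording. A bout spanning the day/night boundary contributes its
#' minutes to each phase by membership.
#'
#' @param series A \code{\link{sleep_series}}.
#' @param zt ZT labels from \code{\link{to_zt}} covering the same minutes.
#' @param window 1-based index of the complete 24-h ZT window (lights-on to
#'   lights-on) to summarize.
#' @return An object of class \code{sleep_summary} with fields
#'   \code{daytime_sleep_min}, \code{nighttime_sleep_min},
#'   \code{total_sleep_min}, \code{profile_30min} (48 bins; bin b covers
#'   ZT [30(b-1), 30b) minutes), \code{per_night_sleep}, \code{n_bouts} and
#'   \code{mean_bout_min} (bouts overlapping the window).
#' @export
sleep_summary <- function(series, zt, window = 1L) {
  stopifnot(inherits(series, "sleep_series"))
  if (length(series$asleep) != nrow(zt)) stop2("series and zt lengths differ")
  w_of <- zt_window_index(zt)
  sel <- !is.na(w_of) & w_of == window
  if (sum(sel) != 1440L) {
    stop2("window ", window, " is not fully covered by the recording")
  }
  asleep <- series$asleep[sel]
  zt_min <- zt$zt_min[sel]
  night <- zt$phase[sel] == "night"
  daytime <- sum(asleep & !night)
  nighttime <- sum(asleep & night)
  bin <- zt_min %/% 30 + 1L
  profile <- vapply(seq_len(48), function(b) sum(asleep[bin == b]), 0L)
  # per-night sleep across every complete night in the recording
  night_all <- zt$phase == "night"
  w_all <- zt_window_index(zt)
  nights_avail <- sort(unique(w_all[!is.na(w_all)]))
  per_night <- vapply(nights_avail, function(w) {
    sum(series$asleep[!is.na(w_all) & w_all == w & night_all])
  }, 0L)
  in_window <- which(sel) - 1L
  b <- series$bouts
  overlap <- b$start_minute <= max(in_window) &
    (b$start_minute + b$duration_min - 1L) >= min(in_window)
  structure(list(fly_id = series$fly_id,
                 window = window,
                 daytime_sleep_min = daytime,
                 nighttime_sleep_min = nighttime,
                 total_sleep_min = daytime + nighttime,
                 profile_30min = profile,
                 per_night_sleep = per_night,
                 n_bouts = sum(overlap),
                 mean_bout_min = if (any(overlap)) mean(b$duration_min[overlap]) else NA_real_),
            class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf("<sleep_summary> window %d: day %d min, night %d min, total %d min, %d bouts\n",
              x$window, x$daytime_sleep_min, x$nighttime_sleep_min,
              x$total_sleep_min, x$n_bouts))
  invisible(x)
}

#' Plot a 30-min sleep profile
#'
#' @param x A \code{sleep_summary}.
#' @param ... Passed to \code{plot}.
#' @export
plot.sleep_summary <- function(x, ...) {
  mids <- seq(15, 1425, by = 30) / 60
  graphics::plot(mids, x$profile_30min, type = "o", pch = 16,
                 xlab = "ZT (h)", ylab = "Sleep (min / 30 min)",
                 ylim = c(0, 30), ...)
  graphics::rect(12, -2, 24, 32, col = grDevices::grey(0.2, 0.15), border = NA)
  invisible(x)
}

# Full phase instances: maximal runs of the given phase of at least
# full_len minutes (720 under 12:12), returned as half-open minute ranges.
phase_instances <- function(zt, phase, full_len) {
  is_ph <- zt$phase == phase
  r <- rle(is_ph)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values & r$lengths >= full_len
  data.frame(start = starts[keep], end = starts[keep] + full_len)  # half-open
}

#' Sleep change between temperature epochs
#'
#' Implements the thermogenetic-activation comparison: sleep during an
#' activation-epoch phase instance minus sleep during the last full
#' baseline-epoch instance of the same phase (activation minus baseline, in
#' minutes).
#'
#' @param series A \code{\link{sleep_series}}.
#' @param zt ZT labels from \code{\link{to_zt}}.
#' @param epochs A \code{\link{temperature_epochs}} table.
#' @param phase \code{"nighttime"} or \code{"daytime"}.
#' @param night_selector Ordinal of the full phase instance inside the
#'   activation epoch to use; \code{NULL} (default) takes the second when
#'   present, else the first.
#' @param phase_len_min Full phase length in minutes (720 under 12:12).
#' @return An object of class \code{sleep_change} with
#'   \code{baseline_sleep_min}, \code{activation_sleep_min} and
#'   \code{delta_min = activation - baseline}.
#' @export
sleep_change <- function(series, zt, epochs, phase = c("nighttime", "daytime"),
                         night_selector = NULL, phase_len_min = 720L) {
  phase <- match.arg(phase)
  ph <- if (phase == "nighttime") "night" else "day"
  stopifnot(inherits(series, "sleep_series"))
  inst <- phase_instances(zt, ph, phase_len_min)
  in_epoch <- function(label) {
    ep <- epochs[epochs$label == label, , drop = FALSE]
    if (nrow(ep) == 0L) stop2("no ", label, " epoch in schedule")
    ok <- rep(FALSE, nrow(inst))
    for (i in seq_len(nrow(ep))) {
      ok <- ok | (inst$start >= ep$start_minute[i] & inst$end <= ep$end_minute[i])
    }
    inst[ok, , drop = FALSE]
  }
  base_inst <- in_epoch("baseline")
  act_inst <- in_epoch("activation")
  if (nrow(base_inst) == 0L) stop2("baseline epoch contains no full ", phase, " instance")
  sel <- night_selector %||% min(2L, nrow(act_inst))
  if (nrow(act_inst) < sel) {
    stop2("activation epoch has no full ", phase, " instance #", sel)
  }
  sleep_in <- function(row) sum(series$asleep[(row$start + 1L):row$end])
  baseline <- sleep_in(base_inst[nrow(base_inst), ])
  activation <- sleep_in(act_inst[sel, ])
  structure(list(phase = phase,
                 baseline_sleep_min = baseline,
                 activation_sleep_min = activation,
                 delta_min = activation - baseline,
                 night_selector = sel),
            class = "sleep_change")
}

#' @export
print.sleep_change <- function(x, ...) {
  cat(sprintf("<sleep_change> %s: activation %d - baseline %d = %+d min\n",
              x$phase, x$activation_sleep_min, x$baseline_sleep_min, x$delta_min))
  invisible(x)
}

#' Flag dead flies by terminal inactivity
#'
#' A fly is flagged dead when its final run of zero counts extends to the
#' recording end and lasts at least \code{threshold_h} hours. Flagged flies
#' should be excluded from group summaries for windows overlapping
#' \code{[death_minute, end)}.
#'
#' @param recording A \code{\link{dam_recording}} or count vector.
#' @param threshold_h Terminal-inactivity threshold in hours (default 12).
#' @return A list with \code{dead} (logical) and \code{death_minute}
#'   (0-based start of the terminal run, or \code{NA}).
#' @export
flag_dead <- function(recording, threshold_h = 12) {
  counts <- if (inherits(recording, "dam_recording")) recording$minutes else recording
  n <- length(counts)
  nz <- which(counts > 0)
  run_start <- if (length(nz)) max(nz) else 0L  # terminal zero run starts after last nonzero
  terminal <- n - run_start
  if (terminal >= threshold_h * 60) {
    list(dead = TRUE, death_minute = run_start)
  } else {
    list(dead = FALSE, death_minute = NA_integer_)
  }
}

#' Tukey five-number boxplot summary
#'
#' Boxes extend from the 25th to 75th percentiles; whiskers extend to the
#' most extreme values within 1.5 interquartile ranges of the box, and
#' values beyond the whiskers are listed as outliers. Quartiles use linear
#' interpolation between order statistics (\code{stats::quantile} type 7).
#'
#' @param values Numeric vector (at least one value).
#' @return A list: \code{q1}, \code{median}, \code{q3}, \code{whisker_low},
#'   \code{whisker_high}, \code{outliers}.
#' @examples
#' tukey_box_summary(c(1, 2, 3, 4, 100))$outliers  # 100
#' @export
tukey_box_summary <- function(values) {
  if (length(values) == 0L || all(is.na(values))) stop2("no values")
  values <- values[!is.na(values)]
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Per-fly sleep summary table
#'
#' Convenience wrapper producing the documented per-fly CSV schema:
#' \code{fly_id}, condition columns, \code{daytime_sleep_min},
#' \code{nighttime_sleep_min}, \code{total_sleep_min}, \code{n_bouts},
#' \code{mean_bout_len}.
#'
#' @param recordings List of \code{\link{dam_recording}}.
#' @param schedule A \code{\link{light_schedule}}.
#' @param window 24-h window index passed to \code{\link{sleep_summary}}.
#' @param drop_dead Exclude flies flagged by \code{\link{flag_dead}}.
#' @return A data frame, one row per (surviving) fly.
#' @export
sleep_summary_table <- function(recordings, schedule, window = 1L,
                                drop_dead = TRUE) {
  rows <- lapply(recordings, function(r) {
    if (drop_dead && flag_dead(r)$dead) return(NULL)
    zt <- to_zt(r, schedule)
    s <- sleep_summary(score_sleep(r), zt, window)
    cond <- as.list(r$condition)
    cbind(data.frame(fly_id = r$fly_id, stringsAsFactors = FALSE),
          if (length(cond)) as.data.frame(cond, stringsAsFactors = FALSE),
          data.frame(daytime_sleep_min = s$daytime_sleep_min,
                     nighttime_sleep_min = s$nighttime_sleep_min,
                     total_sleep_min = s$total_sleep_min,
                     n_bouts = s$n_bouts, mean_bout_len = s$mean_bout_min))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
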