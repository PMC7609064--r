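ETHOGRAM_LABELS <- c("immobile", "courting", "other_active")

#' Construct a per-second ethogram track
#'
#' One behavior label per second over the three states used for nighttime
#' video scoring: \code{immobile}, \code{courting}, \code{other_active}
#' (locomotion, eating, grooming, brief inactivity).
#'
#' @param labels Character vector, one label per second.
#' @param zt_start_s ZT of the first second, in seconds since ZT0.
#' @param fly_id Identifier.
#' @return An object of class \code{ethogram_track}.
#' @export
ethogram_track <- function(labels, zt_start_s = 0, fly_id = "fly") {
  if (length(labels) == 0L) stop2("labels is empty")
  bad <- setdiff(unique(labels), ETHOGRAM_LABELS)
  if (length(bad)) stop2("unknown ethogram labels: ", paste(bad, collapse = ", "))
  structure(list(fly_id = as.character(fly_id), labels = as.character(labels),
                 zt_start_s = as.numeric(zt_start_s)),
            class = "ethogram_track")
}

#' @export
print.ethogram_track <- function(x, ...) {
  cat(sprintf("<ethogram_track> fly %s, %d s from ZT %.2f h\n", x$fly_id,
              length(x$labels), x$zt_start_s / 3600))
  invisible(x)
}

#' Score one analysis window of an ethogram track
#'
#' Implements the video-scoring rule for 5-min windows: an in-window
#' immobile second counts as sleep only if the immobility run it belongs to
#' (extended into the surrounding context beyond the window edges) lasts at
#' least \code{sleep_run_s} seconds in total; shorter immobility ("brief
#' inactivity") counts as wake-but-not-courting. Courting seconds count as
#' courting. Runs straddling either window edge are treated symmetrically.
#'
#' @param track An \code{\link{ethogram_track}}.
#' @param window_start_zt Window start, seconds since ZT0.
#' @param window_len_s Window length in seconds (default 300).
#' @param sleep_run_s Minimum total immobility-run length qualifying as
#'   sleep (default 300, i.e. the 5-min sleep definition).
#' @return An object of class \code{window_score} with
#'   \code{pct_sleep}, \code{pct_court}, \code{pct_wake_noncourt} (each in
#'   [0, 100], summing to 100).
#' @export
score_window <- function(track, window_start_zt, window_len_s = 300,
                         sleep_run_s = 300) {
  stopifnot(inherits(track, "ethogram_track"))
  n <- length(track$labels)
  i0 <- round(window_start_zt - track$zt_start_s) + 1L  # 1-based index of window start
  i1 <- i0 + window_len_s - 1L
  if (i0 < 1L || i1 > n) {
    stop2("window [", window_start_zt, ", ", window_start_zt + window_len_s,
          ") s extends beyond the track and its context")
  }
  lab <- track$labels
  imm <- lab == "immobile"
  r <- rle(imm)
  run_len <- rep(r$lengths, r$lengths)        # total run length at each second
  idx <- i0:i1
  in_win <- lab[idx]
  sleep_s <- sum(imm[idx] & run_len[idx] >= sleep_run_s)
  court_s <- sum(in_win == "courting")
  wake_s <- window_len_s - sleep_s - court_s
  structure(list(window_start_zt = window_start_zt,
                 window_len_s = window_len_s,
                 pct_sleep = 100 * sleep_s / window_len_s,
                 pct_court = 100 * court_s / window_len_s,
                 pct_wake_noncourt = 100 * wake_s / window_len_s),
            class = "window_score")
}

#' @export
print.window_score <- function(x, ...) {
  cat(sprintf("<window_score> ZT %.2f h: sleep %.1f%%, court %.1f%%, wake %.1f%%\n",
              x$window_start_zt / 3600, x$pct_sleep, x$pct_court,
              x$pct_wake_noncourt))
  invisible(x)
}

#' Score the six nightly ZT18-24 windows and aggregate
#'
#' Scores the first 5 minutes of each hour between ZT 18 and ZT 24 (windows
#' starting at ZT 18:00, 19:00, ..., 23:00) and returns the mean of each
#' percentage across the six windows.
#'
#' @param track An \code{\link{ethogram_track}} covering ZT 18-24.
#' @param window_len_s,sleep_run_s As in \code{\link{score_window}}.
#' @return A list with the aggregate \code{pct_sleep}, \code{pct_court},
#'   \code{pct_wake_noncourt} and a \code{windows} data frame of per-window
#'   scores.
#' @export
nightly_score <- function(track, window_len_s = 300, sleep_run_s = 300) {
  starts <- (18:23) * 3600
  scores <- lapply(starts, function(s)
    score_window(track, s, window_len_s, sleep_run_s))
  tab <- data.frame(
    window_start_zt = starts,
    pct_sleep = vapply(scores, `[[`, 0, "pct_sleep"),
    pct_court = vapply(scores, `[[`, 0, "pct_court"),
    pct_wake_noncourt = vapply(scores, `[[`, 0, "pct_wake_noncourt"))
  list(pct_sleep = mean(tab$pct_sleep), pct_court = mean(tab$pct_court),
       pct_wake_noncourt = mean(tab$pct_wake_noncourt), windows = tab)
}

#' Read / write per-second ethogram CSV
#'
#' The documented schema is \code{fly_id,zt_s,label}, one row per second in
#' chronological order.
#'
#' @param path CSV path.
#' @return For the reader, a list of \code{\link{ethogram_track}} (one per
#'   fly).
#' @export
read_ethogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("fly_id", "zt_s", "label") %in% names(df))) {
    stop2("ethogram CSV needs columns fly_id, zt_s, label")
  }
  lapply(split(df, df$fly_id), function(d) {
    d <- d[order(d$zt_s), ]
    if (any(diff(d$zt_s) != 1)) stop2("ethogram track for ", d$fly_id[1],
                                      " is not at 1-s spacing")
    ethogram_track(d$label, d$zt_s[1], d$fly_id[1])
  })
}

#' @rdname read_ethogram_csv
#' @param tracks List of \code{ethogram_track}.
#' @export
write_ethogram_csv <- function(tracks, path) {
  if (inherits(tracks, "ethogram_track")) tracks <- list(tracks)
  tabs <- lapply(tracks, function(tr) {
    data.frame(fly_id = tr$fly_id,
               zt_s = tr$zt_start_s + seq_along(tr$labels) - 1,
               label = tr$labels, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
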