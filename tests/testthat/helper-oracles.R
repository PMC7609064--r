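# Independent oracles, deliberately naive.

# Brute-force run-length sleep scanner: walks the vector minute by minute.
brute_force_sleep <- function(counts, min_bout = 5L) {
  n <- length(counts)
  asleep <- logical(n)
  starts <- integer(0)
  durs <- integer(0)
  i <- 1L
  while (i <= n) {
    if (counts[i] == 0L) {
      j <- i
      while (j < n && counts[j + 1L] == 0L) j <- j + 1L
      if (j - i + 1L >= min_bout) {
        asleep[i:j] <- TRUE
        starts <- c(starts, i - 1L)
        durs <- c(durs, j - i + 1L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(asleep = asleep, bouts = data.frame(start_minute = starts,
                                           duration_min = durs))
}

# Exact expected scored sleep of a homogeneous two-state chain by full
# enumeration of all state sequences (tiny n only).
enum_expected_scored <- function(s, w, n, min_bout = 5L) {
  tot <- 0
  for (i in 0:(2^n - 1)) {
    seq <- as.logical(bitwAnd(i, 2^(0:(n - 1))) > 0)
    p <- if (seq[1]) s / (s + w) else w / (s + w)
    for (t in 2:n) {
      p <- p * (if (seq[t - 1]) {
        if (seq[t]) 1 - w else w
      } else {
        if (seq[t]) s else 1 - s
      })
    }
    r <- rle(seq)
    tot <- tot + p * sum(r$lengths[r$values & r$lengths >= min_bout])
  }
  tot
}

# Build a single-beam monitor-file row set by hand (32 channel columns).
write_toy_monitor <- function(path, counts_by_channel, start = "2026-01-05 09:00:00") {
  n <- length(counts_by_channel[[1]])
  times <- as.POSIXct(start, tz = "UTC") + 60 * (seq_len(n) - 1)
  lt <- as.POSIXlt(times, tz = "UTC")
  rows <- vapply(seq_len(n), function(i) {
    ch <- vapply(1:32, function(c) {
      v <- counts_by_channel[[as.character(c)]]
      if (is.null(v)) 0L else v[i]
    }, 0L)
    paste(c(i, sprintf("%02d %s %02d", lt$mday[i], month.abb[lt$mon[i] + 1],
                       lt$year[i] %% 100),
            format(times[i], "%H:%M:%S", tz = "UTC"), 1, 0, 0, 0, 0, ch),
          collapse = "\t")
  }, "")
  writeLines(rows, path)
  path
}

default_schedule <- function() light_schedule("09:00:00")

# Simple deterministic ethogram builder from run-length encoding.
make_track <- function(..., zt_start_s = 18 * 3600, fly_id = "e1") {
  runs <- list(...)
  labels <- unlist(lapply(runs, function(r) rep(r[[1]], r[[2]])))
  ethogram_track(labels, zt_start_s = zt_start_s, fly_id = fly_id)
}
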