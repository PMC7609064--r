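test_that("single-beam monitor files are transcribed exactly", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_monitor(path, list(`1` = c(0L, 2L, 0L), `7` = c(5L, 0L, 1L)))
  recs <- read_monitor_file(path, "single")
  expect_length(recs, 32L)
  ch <- vapply(recs, `[[`, 0L, "channel")
  expect_identical(recs[[which(ch == 1)]]$minutes, c(0L, 2L, 0L))
  expect_identical(recs[[which(ch == 7)]]$minutes, c(5L, 0L, 1L))
  expect_identical(recs[[which(ch == 2)]]$minutes, c(0L, 0L, 0L))
  expect_equal(as.numeric(recs[[1]]$start_datetime),
               as.numeric(as.POSIXct("2026-01-05 09:00:00", tz = "UTC")))
})

test_that("multi-beam mode selects moves or counts columns", {
  # one minute: the fly crosses one adjacent-beam boundary (beams 8 -> 9)
  # and twitches once within beam 9: moves = 1, counts = 2
  beams <- integer(17); beams[8] <- 1L; beams[9] <- 2L
  ch1 <- c(beams, 1L, 2L)                      # 17 beams, moves, counts
  other <- rep(0L, 19)
  row <- paste(c(1, "05 Jan 26", "09:00:00", 1, 0, 0, 0, 0,
                 ch1, rep(other, 31)), collapse = "\t")
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(row, path)
  mv <- read_monitor_file(path, "multibeam_moves")
  ct <- read_monitor_file(path, "multibeam_counts")
  expect_identical(mv[[1]]$minutes, 1L)
  expect_identical(ct[[1]]$minutes, 2L)
  expect_identical(mv[[1]]$beam_mode, "multibeam_moves")
})

test_that("write -> read round trip is the identity on counts and channels", {
  set.seed(101)
  recs <- lapply(1:32, function(ch) {
    dam_recording(sprintf("f%02d", ch), stats::rpois(120, 0.7),
                  "2026-01-05 09:00:00", ch)
  })
  path <- withr::local_tempfile(fileext = ".txt")
  write_monitor_file(recs, path)
  back <- read_monitor_file(path, "single",
                            fly_ids = sprintf("f%02d", 1:32))
  expect_length(back, 32L)
  for (i in 1:32) {
    expect_identical(back[[i]]$minutes, recs[[i]]$minutes)
    expect_identical(back[[i]]$channel, recs[[i]]$channel)
    expect_identical(back[[i]]$fly_id, recs[[i]]$fly_id)
  }
})

test_that("multi-beam writer round-trips and enforces counts >= moves", {
  m <- fly_model()
  flies <- lapply(1:3, function(i) {
    sim <- simulate_multibeam(m, n_days = 1, seed = 5,
                              fly_id = paste0("mb", i), channel = i)
    sim
  })
  path <- withr::local_tempfile(fileext = ".txt")
  write_multibeam_file(flies, path)
  mv <- read_monitor_file(path, "multibeam_moves")
  ct <- read_monitor_file(path, "multibeam_counts")
  expect_length(mv, 3L)
  for (i in 1:3) {
    expect_identical(mv[[i]]$minutes, flies[[i]]$moves$minutes)
    expect_identical(ct[[i]]$minutes, flies[[i]]$counts$minutes)
    expect_true(all(ct[[i]]$minutes >= mv[[i]]$minutes))
  }
  # corrupt one counts cell below moves -> hard error
  raw <- strsplit(readLines(path), "\t")
  raw[[1]][8 + 19] <- "0"  # channel 1 counts column, first row
  raw[[1]][8 + 18] <- "3"  # moves column above it
  writeLines(vapply(raw, paste, "", collapse = "\t"), path)
  expect_error(read_monitor_file(path, "multibeam_counts"), "counts column < moves")
})

test_that("timestamp gaps, disorder and negative counts are hard errors", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_toy_monitor(path, list(`1` = c(1L, 1L, 1L, 1L)))
  rows <- readLines(path)
  writeLines(rows[-3], path)  # drop 09:02 -> gap
  expect_error(read_monitor_file(path, "single"), "09:01")
  writeLines(rows[c(1, 3, 2, 4)], path)
  expect_error(read_monitor_file(path, "single"), "non-monotonic")
  rows2 <- rows
  rows2[2] <- sub("\t0\t0\t0\t0\t1\t", "\t0\t0\t0\t0\t-1\t", rows2[2])
  writeLines(rows2, path)
  expect_error(read_monitor_file(path, "single"), "negative")
})

test_that("writer validates inputs and flags empty channels", {
  expect_error(write_monitor_file(list()), "no recordings")
  r1 <- dam_recording("a", c(0L, 0L, 5L), "2026-01-05 09:00:00", 1)
  r2 <- dam_recording("b", c(0L, 0L), "2026-01-05 09:00:00", 2)
  expect_error(write_monitor_file(list(r1, r2), tempfile()), "mixed lengths")
  path <- withr::local_tempfile(fileext = ".txt")
  write_monitor_file(list(r1), path)
  back <- read_monitor_file(path, "single")
  expect_length(back, 1L)                       # only the populated channel
  expect_identical(back[[1]]$minutes, c(0L, 0L, 5L))
  expect_identical(attr(back, "empty_channels"), 2:32)
})

test_that("Zeitgeber labeling follows the half-open day convention", {
  sch <- default_schedule()
  zt <- to_zt("2026-01-05 09:00:00", sch, n_minutes = 1441)
  expect_equal(zt$zt_min[1], 0)
  expect_identical(zt$phase[1], "day")
  expect_equal(zt$zt_min[721], 720)             # exactly lights-off
  expect_identical(zt$phase[721], "night")      # half-open: night
  expect_identical(zt$phase[720], "day")
  expect_equal(zt$zt_min[1441], 0)              # periodic with period 1440
  # start one hour before lights-off (20:00 with lights-on 09:00)
  zt2 <- to_zt("2026-01-05 20:00:00", sch, n_minutes = 2)
  expect_equal(zt2$zt_min[1], 660)
  expect_identical(zt2$phase[1], "day")
})

test_that("per-minute CSV export uses the documented schema", {
  r <- dam_recording("f1", c(0L, 3L), "2026-01-05 09:00:00", 1)
  path <- withr::local_tempfile(fileext = ".csv")
  export_minutes_csv(r, default_schedule(), path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("fly_id", "zt_min", "phase", "count"))
  expect_identical(df$count, c(0L, 3L))
})

test_that("light schedule rejects invalid photoperiods", {
  expect_error(light_schedule(photoperiod_hours = 0), "photoperiod")
  expect_error(light_schedule(photoperiod_hours = 24), "photoperiod")
  expect_error(light_schedule("25:00:00"), "out of range")
})
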