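test_that("sleep scoring applies the 5-min inactivity rule", {
  s <- score_sleep(c(0L, 0L, 0L, 0L, 0L, 3L, 0L, 0L, 0L, 0L))
  expect_equal(s$bouts, data.frame(start_minute = 0L, duration_min = 5L))
  expect_equal(sum(s$asleep), 5L)
  expect_false(any(s$asleep[7:10]))      # trailing 4-zero run is not sleep
  all_active <- score_sleep(rep(1L, 100))
  expect_equal(nrow(all_active$bouts), 0L)
  expect_equal(sum(all_active$asleep), 0L)
  all_zero <- score_sleep(rep(0L, 7))    # boundary-truncated run, length >= 5
  expect_equal(all_zero$bouts$duration_min, 7L)
  expect_error(score_sleep(integer(0)), "empty")
})

test_that("sleep scoring agrees with a brute-force run-length scanner", {
  set.seed(2024)
  for (i in 1:400) {
    v <- stats::rbinom(1440, 1, stats::runif(1, 0.05, 0.95))
    mine <- score_sleep(v)
    oracle <- brute_force_sleep(v)
    expect_identical(mine$asleep, oracle$asleep)
    expect_equal(mine$bouts, oracle$bouts)
  }
})

test_that("scoring is antitone in activity", {
  set.seed(7)
  for (i in 1:50) {
    v <- stats::rbinom(400, 1, 0.5)
    base <- sum(score_sleep(v)$asleep)
    z <- which(v == 0)
    if (!length(z)) next
    v[sample(z, 1)] <- 1L
    expect_lte(sum(score_sleep(v)$asleep), base)
  }
})

test_that("summaries split boundary bouts by minute membership and conserve", {
  sch <- default_schedule()
  # single bout ZT 716-730 (14 min): 4 day minutes + 10 night minutes
  v <- rep(1L, 1440)
  v[717:730] <- 0L                      # minute index 716..729 (0-based)
  zt <- to_zt("2026-01-05 09:00:00", sch, n_minutes = 1440)
  sm <- sleep_summary(score_sleep(v), zt, window = 1)
  expect_equal(sm$daytime_sleep_min, 4L)
  expect_equal(sm$nighttime_sleep_min, 10L)
  expect_equal(sm$total_sleep_min, 14L)
  # asleep all night saturates at 720 and fills the night-half profile
  v2 <- c(rep(1L, 720), rep(0L, 720))
  sm2 <- sleep_summary(score_sleep(v2), zt, window = 1)
  expect_equal(sm2$nighttime_sleep_min, 720L)
  expect_true(all(sm2$profile_30min[25:48] == 30L))
  expect_true(all(sm2$profile_30min[1:24] == 0L))
})

test_that("summary conservation identities hold on random series", {
  sch <- default_schedule()
  zt <- to_zt("2026-01-05 09:00:00", sch, n_minutes = 2880)
  set.seed(11)
  for (i in 1:25) {
    v <- stats::rbinom(2880, 1, 0.4)
    ss <- score_sleep(v)
    expect_equal(sum(ss$bouts$duration_min), sum(ss$asleep))
    for (w in 1:2) {
      sm <- sleep_summary(ss, zt, window = w)
      expect_equal(sm$daytime_sleep_min + sm$nighttime_sleep_min,
                   sm$total_sleep_min)
      expect_equal(sum(sm$profile_30min), sm$total_sleep_min)
      expect_true(all(sm$profile_30min >= 0 & sm$profile_30min <= 30))
    }
  }
  expect_error(sleep_summary(score_sleep(rep(0L, 2880)), zt, window = 3),
               "not fully covered")
})

test_that("windows align to lights-on for recordings starting mid-cycle", {
  sch <- default_schedule()
  # recording starts 1 h before lights-off: the first complete ZT window
  # starts 780 min in, so window 1 needs 780 + 1440 minutes of data
  zt <- to_zt("2026-01-05 20:00:00", sch, n_minutes = 2300)
  sm <- sleep_summary(score_sleep(rep(0L, 2300)), zt, window = 1)
  expect_equal(sm$total_sleep_min, 1440L)
  expect_error(sleep_summary(score_sleep(rep(0L, 2300)), zt, window = 2),
               "not fully covered")
  zt_short <- to_zt("2026-01-05 20:00:00", sch, n_minutes = 2100)
  expect_error(sleep_summary(score_sleep(rep(0L, 2100)), zt_short, window = 1),
               "not fully covered")
})

test_that("sleep change subtracts baseline from activation phase sleep", {
  sch <- default_schedule()
  n <- 5 * 1440
  epochs <- temperature_epochs(c("baseline", "activation", "recovery"),
                               c(0L, 2160L, 5040L), c(2160L, 5040L, n),
                               c(22, 29, 22))
  zt <- to_zt("2026-01-05 09:00:00", sch, n_minutes = n)
  # baseline night (night 1): 420 min asleep; activation night 2 of the
  # epoch (night 3 overall): 300 min asleep
  v <- rep(1L, n)
  v[721:1140] <- 0L              # ZT720.. of day 1: 420 min
  v[3601:3900] <- 0L             # night 3: 300 min
  sc <- sleep_change(score_sleep(v), zt, epochs, "nighttime")
  expect_equal(sc$baseline_sleep_min, 420L)
  expect_equal(sc$activation_sleep_min, 300L)
  expect_equal(sc$delta_min, -120L)
  expect_equal(sc$night_selector, 2L)
  # identical behavior in both epochs gives delta 0
  v2 <- rep(1L, n); v2[721:1140] <- 0L; v2[3601:4020] <- 0L
  expect_equal(sleep_change(score_sleep(v2), zt, epochs, "nighttime")$delta_min, 0L)
  # requesting a phase instance that is absent is a hard error
  epochs2 <- temperature_epochs(c("baseline", "activation"),
                                c(0L, 2160L), c(2160L, n), c(22, 29))
  expect_error(sleep_change(score_sleep(v), zt, epochs2, "nighttime",
                            night_selector = 5), "instance #5")
})

test_that("dead flies are flagged by >= 12 h terminal inactivity", {
  active <- c(rep(1L, 1000), rep(0L, 100))
  expect_false(flag_dead(active)$dead)
  dead <- c(rep(1L, 700), rep(0L, 13 * 60))
  fd <- flag_dead(dead)
  expect_true(fd$dead)
  expect_equal(fd$death_minute, 700L)
  below <- c(rep(1L, 700), rep(0L, 11.5 * 60))
  expect_false(flag_dead(below)$dead)
  # an interior 13-h gap followed by activity does not flag
  interior <- c(rep(0L, 13 * 60), rep(1L, 100))
  expect_false(flag_dead(interior)$dead)
})

test_that("Tukey box summaries follow the declared quantile rule", {
  b <- tukey_box_summary(1:9)
  expect_equal(b$q1, 3); expect_equal(b$median, 5); expect_equal(b$q3, 7)
  expect_equal(b$whisker_low, 1); expect_equal(b$whisker_high, 9)
  expect_length(b$outliers, 0L)
  same <- tukey_box_summary(rep(4.2, 6))
  expect_equal(same$whisker_low, 4.2)
  expect_equal(same$whisker_high, 4.2)
  out <- tukey_box_summary(c(1, 2, 3, 4, 100))
  expect_equal(out$outliers, 100)
  expect_equal(out$whisker_high, 4)
  expect_error(tukey_box_summary(numeric(0)), "no values")
  # sorting-based oracle under the same (type 7) rule
  set.seed(3)
  for (i in 1:20) {
    x <- stats::rnorm(25)
    b <- tukey_box_summary(x)
    q <- stats::quantile(x, c(.25, .75), type = 7, names = FALSE)
    fence <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
    expect_equal(sort(b$outliers), sort(x[x < fence[1] | x > fence[2]]))
  }
})

test_that("per-fly summary table reports the documented columns", {
  m <- fly_model_preset("MM_fed")
  sims <- lapply(1:3, function(i) simulate_fly(m, 2, seed = 21,
                                               fly_id = paste0("t", i)))
  tab <- sleep_summary_table(lapply(sims, `[[`, "recording"),
                             default_schedule(), window = 2)
  expect_true(all(c("fly_id", "sex_pairing", "diet", "daytime_sleep_min",
                    "nighttime_sleep_min", "total_sleep_min", "n_bouts",
                    "mean_bout_len") %in% names(tab)))
  expect_equal(nrow(tab), 3L)
})
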