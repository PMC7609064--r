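test_that("simulation is bit-reproducible from the seed", {
  m <- fly_model_preset("MF_fed")
  a <- simulate_fly(m, 2, seed = 9, fly_id = "r1")
  b <- simulate_fly(m, 2, seed = 9, fly_id = "r1")
  expect_identical(a$recording$minutes, b$recording$minutes)
  expect_identical(a$truth$asleep_state, b$truth$asleep_state)
  c <- simulate_fly(m, 2, seed = 10, fly_id = "r1")
  expect_false(identical(a$recording$minutes, c$recording$minutes))
  g1 <- simulate_gcamp(seed = 3); g2 <- simulate_gcamp(seed = 3)
  expect_identical(g1$trace$raw_F, g2$trace$raw_F)
})

test_that("emissions respect the state: awake >= 1 count, asleep 0", {
  m <- fly_model(wake_activity_rate = 2.5)
  sim <- simulate_fly(m, 2, seed = 4)
  expect_true(all(sim$recording$minutes[!sim$truth$asleep_state] >= 1L))
  expect_true(all(sim$recording$minutes[sim$truth$asleep_state] == 0L))
  # mean awake-minute count matches the configured (zero-truncated) rate
  awake_counts <- unlist(lapply(1:40, function(i) {
    s <- simulate_fly(m, 1, seed = 100 + i, fly_id = paste0("e", i))
    s$recording$minutes[!s$truth$asleep_state]
  }))
  expect_equal(mean(awake_counts), 2.5,
               tolerance = 3 * stats::sd(awake_counts) / sqrt(length(awake_counts)) / 2.5)
  expect_error(fly_model(wake_activity_rate = 0.5), "exceed 1")
  expect_error(fly_model(p_wake_day = 1), "in \\(0, 1\\)")
})

test_that("scored sleep fraction matches the geometric run-length law", {
  # symmetric chain: stationary sleep fraction 1/2; the fraction of sleep
  # minutes scored under the 5-min rule is q^4 (5w + q), q = 1 - w
  m <- fly_model(p_fall_asleep_day = 0.1, p_fall_asleep_night = 0.1,
                 p_wake_day = 0.1, p_wake_night = 0.1)
  tot <- vapply(1:800, function(i) {
    sum(score_sleep(simulate_fly(m, 1, seed = 50, fly_id = paste0("g", i))$recording)$asleep)
  }, 0)
  q <- 0.9
  analytic <- 1440 * 0.5 * q^4 * (5 * 0.1 + q)
  expect_lt(abs(mean(tot) - analytic),
            4 * stats::sd(tot) / sqrt(800) + 1)  # +1 for recording-edge effects
  # scored sleep never exceeds true sleep-state minutes
  for (i in 1:20) {
    s <- simulate_fly(m, 1, seed = 60, fly_id = paste0("h", i))
    expect_lte(sum(score_sleep(s$recording)$asleep), sum(s$truth$asleep_state))
  }
})

test_that("the exact DP expectation matches brute-force enumeration", {
  # tiny chain, full enumeration over all 2^12 state sequences
  s <- 0.2; w <- 0.3
  m <- fly_model(p_fall_asleep_day = s, p_fall_asleep_night = s,
                 p_wake_day = w, p_wake_night = w)
  dp <- expected_scored_sleep(m, n_days = 12 / 1440)
  expect_equal(dp$expected_total, enum_expected_scored(s, w, 12),
               tolerance = 1e-10)
  s2 <- 0.5; w2 <- 0.15
  m2 <- fly_model(p_fall_asleep_day = s2, p_fall_asleep_night = s2,
                  p_wake_day = w2, p_wake_night = w2)
  dp2 <- expected_scored_sleep(m2, n_days = 10 / 1440)
  expect_equal(dp2$expected_total, enum_expected_scored(s2, w2, 10),
               tolerance = 1e-10)
})

test_that("high wake pressure abolishes scored sleep", {
  m <- fly_model(p_fall_asleep_day = 0.01, p_fall_asleep_night = 0.01,
                 p_wake_day = 0.95, p_wake_night = 0.95)
  sim <- simulate_fly(m, 1, seed = 2)
  expect_lt(sum(score_sleep(sim$recording)$asleep), 30)
  expect_lt(expected_scored_sleep(m, 1)$expected_total, 10)
})

test_that("multi-beam simulation keeps counts >= moves and orders sleep", {
  m <- fly_model_preset("MM_fed")
  sl_counts <- sl_moves <- numeric(30)
  for (i in 1:30) {
    sim <- simulate_multibeam(m, 1, seed = 30, fly_id = paste0("mb", i),
                              twitch_prob = 0.3)
    expect_true(all(sim$counts$minutes >= sim$moves$minutes))
    expect_true(all(sim$moves$minutes[!sim$truth$asleep_state] >= 1L))
    sl_moves[i] <- sum(score_sleep(sim$moves)$asleep)
    sl_counts[i] <- sum(score_sleep(sim$counts)$asleep)
  }
  expect_true(all(sl_counts <= sl_moves))
  # no twitches, no micro-movements: the two modes coincide
  sim0 <- simulate_multibeam(m, 1, seed = 31, micro_rate = 0,
                             twitch_prob = 0)
  expect_identical(sim0$moves$minutes, sim0$counts$minutes)
})

test_that("latency trials respect rates, censoring and the target CI", {
  none <- simulate_latency_trials(0, 1 / 600, 20, seed = 8)
  surv <- to_survival(none, "initiation")
  expect_true(all(surv$event == 0L))
  expect_true(all(surv$time == 7200))
  some <- simulate_latency_trials(1 / 900, 1 / 600, 200, seed = 9,
                                  target_ci = 0.4)
  ci <- vapply(some, courtship_index, 0)
  expect_equal(mean(ci, na.rm = TRUE), 0.4, tolerance = 1e-6)
  init <- to_survival(some, "initiation")
  obs <- init$time[init$event == 1L]
  expect_equal(mean(obs), 900, tolerance = 0.15 * 900)  # censored-mean sanity
})

test_that("gcamp generator places the transient inside its window", {
  prot <- perfusion_protocol()
  sim <- simulate_gcamp(100, 0.5, 0.002, 0.4, 0, prot, seed = 12)
  t <- sim$trace$times_s
  pure <- 100 + 50 * exp(-0.002 * t)
  dev <- sim$trace$raw_F - pure
  expect_true(all(dev[t < 60 | t > 180] == 0))
  expect_equal(max(dev), 100 * 0.4, tolerance = 1e-9)
  expect_equal(sim$truth$peak_true, 0.4)
})
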