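#' Two-state fly behavior model
#'
#' Per-minute two-state (wake/sleep) Markov chain with phase-dependent
#' transition probabilities, matching the 1-minute measurement grid of the
#' activity monitors. Run lengths are geometric, which gives closed-form
#' expectations for scored sleep (see \code{\link{expected_scored_sleep}}).
#' Awake minutes emit zero-truncated Poisson counts (always >= 1), asleep
#' minutes emit 0, so scored sleep can undercount but never invent sleep.
#'
#' @param p_fall_asleep_day,p_fall_asleep_night Per-minute wake-to-sleep
#'   transition probabilities, in (0, 1).
#' @param p_wake_day,p_wake_night Per-minute sleep-to-wake transition
#'   probabilities, in (0, 1); mean sleep-bout dwell is \code{1/p_wake}
#'   minutes.
#' @param wake_activity_rate Mean counts per awake minute (> 1; the
#'   zero-truncated Poisson rate is solved to match this mean).
#' @param condition Named list of condition labels.
#' @return An object of class \code{fly_model}.
#' @export
fly_model <- function(p_fall_asleep_day = 0.08, p_fall_asleep_night = 0.1,
                      p_wake_day = 0.12, p_wake_night = 0.05,
                      wake_activity_rate = 2, condition = list()) {
  p <- c(p_fall_asleep_day, p_fall_asleep_night, p_wake_day, p_wake_night)
  if (any(p <= 0 | p >= 1)) stop2("transition probabilities must lie in (0, 1)")
  structure(list(p_fall_asleep_day = p_fall_asleep_day,
                 p_fall_asleep_night = p_fall_asleep_night,
                 p_wake_day = p_wake_day, p_wake_night = p_wake_night,
                 wake_activity_rate = wake_activity_rate,
                 lambda = ztpois_lambda(wake_activity_rate),
                 condition = condition),
            class = "fly_model")
}

#' @export
print.fly_model <- function(x, ...) {
  cat(sprintf(paste0("<fly_model> fall asleep day/night %.3f/%.3f, ",
                     "wake day/night %.3f/%.3f, %.1f counts/awake min\n"),
              x$p_fall_asleep_day, x$p_fall_asleep_night,
              x$p_wake_day, x$p_wake_night, x$wake_activity_rate))
  invisible(x)
}

#' Condition presets for the sleep-courtship study structure
#'
#' Parameter sets mimicking the observed structure: male-female (MF) pairs
#' on normal food court at night and sleep little; yeast-deprived MF pairs
#' sleep much more; male-male (MM) pairs sleep a lot regardless of diet.
#' Nighttime sleep-bout dwell times are tens of minutes for high sleepers
#' and a few minutes for courting males.
#'
#' @param name One of \code{"MF_fed"}, \code{"MF_deprived"},
#'   \code{"MM_fed"}, \code{"MM_deprived"}, \code{"single_male"}.
#' @return A \code{\link{fly_model}}.
#' @export
fly_model_preset <- function(name = c("MF_fed", "MF_deprived", "MM_fed",
                                      "MM_deprived", "single_male")) {
  name <- match.arg(name)
  pairing <- if (grepl("^MF", name)) "MF" else if (grepl("^MM", name)) "MM" else "single-male"
  diet <- if (grepl("deprived", name)) "yeast_deprived" else "fed"
  cond <- list(sex_pairing = pairing, diet = diet)
  switch(name,
    MF_fed = fly_model(0.08, 0.05, 0.12, 0.30, condition = cond),
    MF_deprived = fly_model(0.08, 0.12, 0.12, 0.045, condition = cond),
    MM_fed = fly_model(0.08, 0.15, 0.12, 0.03, condition = cond),
    MM_deprived = fly_model(0.08, 0.13, 0.12, 0.035, condition = cond),
    single_male = fly_model(0.08, 0.14, 0.12, 0.032, condition = cond))
}

# Exact sampling of the two-state chain by geometric dwell times. The
# transition into minute t uses minute t's parameters; parameters are
# piecewise constant (phase/epoch segments), and a dwell crossing a
# segment boundary is continued under the new segment's parameter, which
# by memorylessness is an exact simulation of the per-minute chain.
markov_states <- function(s, w) {
  n <- length(s)
  seg_end <- c(which(diff(s) != 0 | diff(w) != 0), n)
  asleep <- logical(n)
  state <- stats::runif(1) < s[1] / (s[1] + w[1])  # stationary start
  asleep[1] <- state
  t <- 2L            # transitions into minutes t.. are not yet drawn
  si <- 1L
  while (t <= n) {
    while (seg_end[si] < t) si <- si + 1L
    b <- seg_end[si]
    p <- if (state) w[t] else s[t]
    g <- stats::rgeom(1L, p) + 1L        # flip lands on minute t + g - 1
    flip_at <- t + g - 1L
    if (flip_at > b) {                   # flip falls beyond the segment:
      asleep[t:b] <- state               # persist and redraw under the new
      t <- b + 1L                        # segment's parameter (memoryless)
    } else {
      if (flip_at > t) asleep[t:(flip_at - 1L)] <- state
      state <- !state
      asleep[flip_at] <- state
      t <- flip_at + 1L
    }
  }
  asleep
}

# Per-minute transition-probability vectors for a recording that starts at
# lights-on. Minute t's transition (from t-1) uses minute t's parameters.
minute_params <- function(model, n_minutes, epochs = NULL,
                          activation_model = NULL, day_len = 720L) {
  m <- seq_len(n_minutes) - 1L
  night <- (m %% 1440L) >= day_len
  s <- ifelse(night, model$p_fall_asleep_night, model$p_fall_asleep_day)
  w <- ifelse(night, model$p_wake_night, model$p_wake_day)
  if (!is.null(epochs) && !is.null(activation_model)) {
    act <- rep(FALSE, n_minutes)
    ep <- epochs[epochs$label == "activation", , drop = FALSE]
    for (i in seq_len(nrow(ep))) {
      act[(ep$start_minute[i] + 1L):ep$end_minute[i]] <- TRUE
    }
    s[act & night] <- activation_model$p_fall_asleep_night
    s[act & !night] <- activation_model$p_fall_asleep_day
    w[act & night] <- activation_model$p_wake_night
    w[act & !night] <- activation_model$p_wake_day
  }
  list(s = s, w = w, night = night)
}

#' Simulate one fly's activity recording
#'
#' Runs the per-minute two-state chain (stationary initial state for the
#' starting phase), emits zero-truncated Poisson counts in awake minutes
#' and zeros in asleep minutes, and returns the recording together with the
#' hidden ground truth. Deterministic given \code{seed}: the fly's RNG
#' stream is seeded with \code{mix_seed(seed, fly_id)}.
#'
#' @param model A \code{\link{fly_model}} (used outside activation epochs).
#' @param n_days Number of 24-h days (recording starts at lights-on).
#' @param seed Base integer seed.
#' @param fly_id Identifier (also enters the per-fly seed).
#' @param channel Monitor channel.
#' @param epochs Optional \code{\link{temperature_epochs}}.
#' @param activation_model Optional \code{fly_model} used during activation
#'   epochs (thermogenetic activation).
#' @param start_date Calendar date of the first lights-on.
#' @param schedule A \code{\link{light_schedule}}.
#' @return A list: \code{recording} (a \code{\link{dam_recording}}) and
#'   \code{truth} (hidden state sequence, per-phase true sleep-state
#'   minutes, parameters, seed).
#' @export
simulate_fly <- function(model, n_days = 1, seed = 1, fly_id = "fly1",
                         channel = 1L, epochs = NULL, activation_model = NULL,
                         start_date = "2026-01-05",
                         schedule = light_schedule("09:00:00")) {
  stopifnot(inherits(model, "fly_model"))
  if (n_days < 1) stop2("n_days must be >= 1")
  n <- as.integer(1440 * n_days)
  day_len <- as.integer(schedule$photoperiod_hours * 60)
  mp <- minute_params(model, n, epochs, activation_model, day_len)
  set.seed(mix_seed(seed, fly_id))
  asleep <- markov_states(mp$s, mp$w)
  counts <- integer(n)
  awake <- which(!asleep)
  counts[awake] <- rztpois(length(awake), model$lambda)
  start_dt <- as.POSIXct(paste(start_date, schedule$lights_on), tz = "UTC")
  rec <- dam_recording(fly_id, counts, start_dt, channel, "single",
                       condition = model$condition,
                       temperature_schedule = epochs)
  truth <- list(asleep_state = asleep,
                true_day_sleep_min = sum(asleep & !mp$night),
                true_night_sleep_min = sum(asleep & mp$night),
                model = model, activation_model = activation_model,
                seed = seed, fly_id = fly_id)
  list(recording = rec, truth = truth)
}

#' Simulate a multi-beam recording (moves and counts modes)
#'
#' While awake the fly performs a 17-position random walk with adjacent
#' steps (inter-beam "moves", always >= 1 per awake minute) plus
#' intra-beam micro-movements; while asleep, occasional twitches register
#' in the counts channel only. Per-minute \code{counts >= moves} holds by
#' construction and is asserted.
#'
#' @inheritParams simulate_fly
#' @param move_rate Mean inter-beam moves per awake minute (> 1).
#' @param micro_rate Mean intra-beam movements per awake minute (Poisson).
#' @param twitch_prob Probability an asleep minute registers one twitch in
#'   counts mode.
#' @return A list: \code{moves} and \code{counts} (two
#'   \code{\link{dam_recording}}s of the same fly), \code{beams}
#'   (minutes x 17 break-count matrix), and \code{truth}.
#' @export
simulate_multibeam <- function(model, n_days = 1, seed = 1, fly_id = "fly1",
                               channel = 1L, move_rate = 2, micro_rate = 1,
                               twitch_prob = 0.05,
                               start_date = "2026-01-05",
                               schedule = light_schedule("09:00:00")) {
  base <- simulate_fly(model, n_days, seed, fly_id, channel,
                       start_date = start_date, schedule = schedule)
  asleep <- base$truth$asleep_state
  n <- length(asleep)
  set.seed(mix_seed(seed, paste0(fly_id, "::multibeam")))
  moves <- counts <- integer(n)
  awake <- which(!asleep)
  moves[awake] <- rztpois(length(awake), ztpois_lambda(max(move_rate, 1.01)))
  counts[awake] <- moves[awake] + stats::rpois(length(awake), micro_rate)
  sleeping <- which(asleep)
  twitch <- stats::rbinom(length(sleeping), 1L, twitch_prob)
  counts[sleeping] <- twitch
  stopifnot(all(counts >= moves))
  # coarse positional bookkeeping for the per-beam columns
  beams <- matrix(0L, nrow = n, ncol = DAM_BEAMS)
  pos <- sample.int(DAM_BEAMS, 1L)
  for (t in seq_len(n)) {
    if (moves[t] > 0L) {
      step <- sum(sample(c(-1L, 1L), moves[t], replace = TRUE))
      pos <- 1L + (abs(pos - 1L + step) %% (2L * (DAM_BEAMS - 1L)))
      if (pos > DAM_BEAMS) pos <- 2L * DAM_BEAMS - pos  # reflect
    }
    beams[t, pos] <- counts[t]
  }
  mk <- function(m, mode) dam_recording(fly_id, m, base$recording$start_datetime,
                                        channel, mode, model$condition)
  list(moves = mk(moves, "multibeam_moves"),
       counts = mk(counts, "multibeam_counts"),
       beams = beams,
       truth = c(base$truth, list(twitch_prob = twitch_prob,
                                  move_rate = move_rate,
                                  micro_rate = micro_rate)))
}

#' Exact expected scored sleep of the two-state model
#'
#' For every minute m, computes the probability that m lies inside a
#' sleep-state run of total length at least \code{min_bout} minutes -- the
#' event that the 5-min rule scores minute m as sleep, given that awake
#' minutes always emit counts. The computation is an exact dynamic program
#' over run starts (no Monte-Carlo), valid with phase- and epoch-dependent
#' transition probabilities; run qualification uses total run length, so
#' phase boundaries need no special handling, and runs truncated by the
#' recording end qualify only if the observed part does.
#'
#' @inheritParams simulate_fly
#' @param min_bout Scoring threshold, minutes.
#' @return A list: \code{p_scored} (per-minute probability the minute is
#'   scored as sleep), \code{p_sleep_state} (marginal sleep-state
#'   probability), \code{night} (phase indicator),
#'   \code{expected_night_sleep} and \code{expected_day_sleep} per 24-h
#'   day (matrices day x 1), and totals.
#' @export
expected_scored_sleep <- function(model, n_days = 1, epochs = NULL,
                                  activation_model = NULL, min_bout = 5L,
                                  schedule = light_schedule("09:00:00")) {
  n <- as.integer(1440 * n_days)
  day_len <- as.integer(schedule$photoperiod_hours * 60)
  mp <- minute_params(model, n, epochs, activation_model, day_len)
  s <- mp$s; w <- mp$w
  # forward marginal P(asleep at t)
  pS <- numeric(n)
  pS[1] <- s[1] / (s[1] + w[1])
  for (t in 2:n) pS[t] <- pS[t - 1L] * (1 - w[t]) + (1 - pS[t - 1L]) * s[t]
  # run-start probabilities and persistence log-products
  f <- c(pS[1], (1 - pS[-n]) * s[-1])
  log_stay <- log(1 - w)          # stay-asleep prob at minute t (t >= 2 used)
  Lp <- c(0, cumsum(log_stay[-1]))  # Lp[t] = sum_{u=2..t} log_stay[u]
  max_stay <- max(1 - w)
  L <- min(n - 1L, ceiling(-27.7 / log(max_stay)))  # tail < 1e-12
  p <- numeric(n)
  k <- as.integer(min_bout) - 1L
  for (d in 0:L) {
    m <- (1L + d):n
    sidx <- m - d
    if (d >= k) {
      term <- f[sidx] * exp(Lp[m] - Lp[sidx])
    } else {
      e <- sidx + k
      ok <- e <= n
      m <- m[ok]; sidx <- sidx[ok]; e <- e[ok]
      if (!length(m)) next
      term <- f[sidx] * exp(Lp[e] - Lp[sidx])
    }
    p[m] <- p[m] + term
  }
  day_idx <- (seq_len(n) - 1L) %/% 1440L + 1L
  list(p_scored = p, p_sleep_state = pS, night = mp$night,
       expected_night_sleep = tapply(p * mp$night, day_idx, sum),
       expected_day_sleep = tapply(p * !mp$night, day_idx, sum),
       expected_total = sum(p))
}

#' Calibrate nighttime sleep by adjusting the wake rate
#'
#' Adjusts \code{p_wake_night} so the model's expected scored nighttime
#' sleep (per \code{\link{expected_scored_sleep}}, second day of a 2-day
#' recording to wash out initial conditions) hits a target.
#'
#' @param model A \code{\link{fly_model}}.
#' @param target_night_sleep_min Target expected scored sleep per night,
#'   minutes.
#' @return The model with \code{p_wake_night} recalibrated.
#' @export
calibrate_night_sleep <- function(model, target_night_sleep_min) {
  obj <- function(logit_w) {
    m <- model
    m$p_wake_night <- stats::plogis(logit_w)
    expected_scored_sleep(m, n_days = 2)$expected_night_sleep[[2]] -
      target_night_sleep_min
  }
  root <- stats::uniroot(obj, stats::qlogis(c(1e-4, 0.9)), tol = 1e-8)
  model$p_wake_night <- stats::plogis(root$root)
  model
}

#' Simulate censored courtship/copulation latency trials
#'
#' Exponential latency to courtship initiation and an exponential
#' initiation-to-copulation gap, censored at the end of the 2-h
#' observation. Courting intervals are filled to a target courtship index.
#'
#' @param rate_court Initiation rate, events/s (0 gives all-censored).
#' @param rate_cop Initiation-to-copulation rate, events/s.
#' @param n Number of trials.
#' @param censor_s Observation length, s.
#' @param group Group label.
#' @param target_ci Courtship index used to fill courting intervals.
#' @param seed Integer seed.
#' @return A list of \code{\link{courtship_trial}}.
#' @export
simulate_latency_trials <- function(rate_court, rate_cop, n, censor_s = 7200,
                                    group = "group", target_ci = 0.6, seed = 1) {
  set.seed(mix_seed(seed, paste0("trials::", group)))
  lapply(seq_len(n), function(i) {
    t_init <- if (rate_court > 0) stats::rexp(1, rate_court) else Inf
    if (t_init > censor_s) {
      return(courtship_trial(sprintf("%s_%03d", group, i), group, 0,
                             NA, NA, NULL, censor_s))
    }
    t_cop <- t_init + if (rate_cop > 0) stats::rexp(1, rate_cop) else Inf
    if (t_cop > censor_s) t_cop <- NA
    d <- if (is.na(t_cop)) 600 else min(600, t_cop - t_init)
    ci <- if (d > 0) cbind(t_init, t_init + target_ci * d) else NULL
    courtship_trial(sprintf("%s_%03d", group, i), group, 0, t_init, t_cop,
                    ci, censor_s)
  })
}

#' Simulate a GCaMP perfusion trace with ground truth
#'
#' The raw trace is a stable fluorophore baseline C carrying the evoked
#' transient, plus an exponentially bleaching component and Gaussian frame
#' noise:
#' \deqn{F(t) = C (1 + a s(t)) + A e^{-kt} + \epsilon_t,}
#' where s(t) is a ramp-plateau-decay waveform confined to
#' \code{[atp_start, atp_end + 60]} (10-s ramp, plateau, 30-s decay).
#' Because the transient scales the stable baseline, the ground-truth
#' peak \eqn{\Delta F/F_0} equals the amplitude \code{a} exactly.
#'
#' @param C Stable baseline intensity.
#' @param A_over_C Bleaching amplitude relative to C.
#' @param k Bleach rate, 1/s.
#' @param transient_amplitude Evoked amplitude a (fractional).
#' @param noise_sigma_over_C Gaussian frame noise SD relative to C.
#' @param protocol A \code{\link{perfusion_protocol}}.
#' @param seed Integer seed.
#' @return A list: \code{trace} (a \code{\link{fluorescence_trace}}) and
#'   \code{truth} (parameters, waveform, true peak).
#' @export
simulate_gcamp <- function(C = 100, A_over_C = 0.5, k = 0.005,
                           transient_amplitude = 0.3,
                           noise_sigma_over_C = 0.01,
                           protocol = perfusion_protocol(), seed = 1) {
  set.seed(mix_seed(seed, "gcamp"))
  t <- seq(0, protocol$total_duration_s, by = protocol$sample_interval_s)
  s <- transient_waveform(t, protocol)
  a <- transient_amplitude
  raw <- C * (1 + a * s) + (A_over_C * C) * exp(-k * t) +
    stats::rnorm(length(t), 0, noise_sigma_over_C * C)
  list(trace = fluorescence_trace(t, raw),
       truth = list(transient_amplitude = a, peak_true = a, C = C,
                    A = A_over_C * C, k = k,
                    sigma = noise_sigma_over_C * C, s = s, seed = seed))
}

# Ramp (10 s) - plateau - decay (30 s) waveform in [0, 1], nonzero only in
# [atp_start, atp_end + 60].
transient_waveform <- function(t, protocol, ramp_s = 10, decay_s = 30) {
  on <- protocol$atp_start_s
  off <- protocol$atp_end_s + 60
  plateau_end <- off - decay_s
  s <- numeric(length(t))
  rising <- t >= on & t < on + ramp_s
  s[rising] <- (t[rising] - on) / ramp_s
  s[t >= on + ramp_s & t <= plateau_end] <- 1
  falling <- t > plateau_end & t <= off
  s[falling] <- (off - t[falling]) / decay_s
  s
}
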