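#' Construct a courtship trial record
#'
#' Event times are in seconds on the recording clock. Unobserved events are
#' \code{NA} and are censored at \code{observation_end} (2 h after
#' introduction by default, matching the standard 2-h recording).
#'
#' @param trial_id Identifier.
#' @param group Group label.
#' @param t_intro Introduction time (divider removal), s.
#' @param t_court_init Courtship-initiation time, s, or \code{NA} if never
#'   observed.
#' @param t_copulation Copulation time, s, or \code{NA}.
#' @param courting_intervals Two-column matrix or data frame of disjoint
#'   half-open \code{[start, end)} courting intervals, s.
#' @param observation_end End of observation, s (default
#'   \code{t_intro + 7200}).
#' @return An object of class \code{courtship_trial}.
#' @export
courtship_trial <- function(trial_id, group = "group", t_intro = 0,
                            t_court_init = NA, t_copulation = NA,
                            courting_intervals = NULL,
                            observation_end = t_intro + 7200) {
  if (!is.na(t_court_init) && t_court_init < t_intro) {
    stop2("t_court_init precedes t_intro")
  }
  if (!is.na(t_copulation)) {
    if (is.na(t_court_init)) stop2("copulation without courtship initiation")
    if (t_copulation < t_court_init) stop2("t_copulation precedes t_court_init")
  }
  ci <- courting_intervals
  if (!is.null(ci)) {
    ci <- as.matrix(ci)
    if (ncol(ci) != 2L) stop2("courting_intervals needs two columns")
    ci <- ci[order(ci[, 1]), , drop = FALSE]
    if (any(ci[, 2] <= ci[, 1])) stop2("empty or reversed courting interval")
    if (nrow(ci) > 1L && any(ci[-1, 1] < ci[-nrow(ci), 2])) {
      stop2("courting intervals overlap")
    }
  }
  structure(list(trial_id = as.character(trial_id), group = as.character(group),
                 t_intro = t_intro, t_court_init = t_court_init,
                 t_copulation = t_copulation, courting_intervals = ci,
                 observation_end = observation_end),
            class = "courtship_trial")
}

#' Courtship index
#'
#' Fraction of time a male is engaged in courtship during the 10 minutes
#' following courtship initiation, or until copulation if that occurs
#' sooner: the denominator is \code{D = min(600, t_copulation -
#' t_court_init)} seconds and the numerator is the courting time inside
#' \code{[t_court_init, t_court_init + D)}. Undefined (\code{NA}, distinct
#' from 0) for males that never initiate courtship.
#'
#' @param trial A \code{\link{courtship_trial}}.
#' @return Courtship index in [0, 1], or \code{NA} if courtship was never
#'   initiated.
#' @examples
#' tr <- courtship_trial("t1", t_court_init = 300, t_copulation = 660,
#'                       courting_intervals = cbind(300, 540))
#' courtship_index(tr)  # 240 s courting / 360 s denominator = 0.667
#' @export
courtship_index <- function(trial) {
  stopifnot(inherits(trial, "courtship_trial"))
  if (is.na(trial$t_court_init)) return(NA_real_)
  d <- if (is.na(trial$t_copulation)) 600 else
    min(600, trial$t_copulation - trial$t_court_init)
  if (d <= 0) return(NA_real_)
  lo <- trial$t_court_init
  hi <- lo + d
  ci <- trial$courting_intervals
  if (is.null(ci)) return(0)
  overlap <- pmax(0, pmin(ci[, 2], hi) - pmax(ci[, 1], lo))
  sum(overlap) / d
}

#' Convert trials to censored latency samples
#'
#' Latency is measured from introduction; trials without the endpoint are
#' censored at the end of observation.
#'
#' @param trials List of \code{\link{courtship_trial}}.
#' @param endpoint \code{"initiation"} or \code{"copulation"}.
#' @return A data frame with columns \code{trial_id}, \code{group},
#'   \code{time} (s) and \code{event} (1 observed, 0 censored).
#' @export
to_survival <- function(trials, endpoint = c("initiation", "copulation")) {
  endpoint <- match.arg(endpoint)
  if (inherits(trials, "courtship_trial")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    t_ev <- if (endpoint == "initiation") tr$t_court_init else tr$t_copulation
    if (is.na(t_ev) || t_ev > tr$observation_end) {
      time <- tr$observation_end - tr$t_intro; event <- 0L
    } else {
      time <- t_ev - tr$t_intro; event <- 1L
    }
    data.frame(trial_id = tr$trial_id, group = tr$group, time = time,
               event = event, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-group log-rank test
#'
#' Implemented from the standard formula: at each distinct event time the
#' expected number of events in group A is allocated from the risk-set
#' proportions, ties use the hypergeometric variance, and the statistic is
#' \eqn{(\sum O_A - \sum E_A)^2 / \sum V} referred to a chi-square
#' distribution with one degree of freedom. Censoring ties at an event time
#' follow the standard convention that events precede censorings.
#'
#' @param time_a,time_b Latency samples (s) for groups A and B.
#' @param event_a,event_b Event indicators (1 observed, 0 censored).
#' @return An object of class \code{logrank_test}: \code{chisq}, \code{df},
#'   \code{p_value}, \code{observed} and \code{expected} per group.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L) {
    stop2("each group needs at least one sample")
  }
  stopifnot(length(time_a) == length(event_a), length(time_b) == length(event_b))
  if (any(c(time_a, time_b) <= 0)) stop2("times must be positive")
  event_a <- as.integer(event_a); event_b <- as.integer(event_b)
  if (sum(event_a) + sum(event_b) == 0L) {
    stop2("no observed events: log-rank test carries no information")
  }
  ev_times <- sort(unique(c(time_a[event_a == 1L], time_b[event_b == 1L])))
  o_a <- e_a <- v <- 0
  for (t in ev_times) {
    n_a <- sum(time_a >= t)          # at risk (events at t still at risk)
    n_b <- sum(time_b >= t)
    d_a <- sum(time_a == t & event_a == 1L)
    d_b <- sum(time_b == t & event_b == 1L)
    n <- n_a + n_b
    d <- d_a + d_b
    if (n < 2 || d == 0) next
    o_a <- o_a + d_a
    e_a <- e_a + d * n_a / n
    v <- v + d * (n_a / n) * (n_b / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (o_a - e_a)^2 / v else 0
  structure(list(chisq = chisq, df = 1L,
                 p_value = stats::pchisq(chisq, 1L, lower.tail = FALSE),
                 observed = c(A = o_a, B = sum(event_b)),
                 expected = c(A = e_a, B = o_a + sum(event_b) - e_a)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  cat(sprintf("  observed A = %g, expected A = %.3f\n",
              x$observed["A"], x$expected["A"]))
  invisible(x)
}

#' Compare two groups of trials by latency
#'
#' Convenience wrapper: converts trials to censored samples for the chosen
#' endpoint and runs \code{\link{logrank_test}} between two group labels.
#'
#' @param trials List of \code{\link{courtship_trial}}.
#' @param endpoint \code{"initiation"} or \code{"copulation"}.
#' @param groups Optional two group labels; defaults to the two labels
#'   present.
#' @return A \code{logrank_test}.
#' @export
compare_latency <- function(trials, endpoint = c("initiation", "copulation"),
                            groups = NULL) {
  surv <- to_survival(trials, endpoint)
  g <- groups %||% unique(surv$group)
  if (length(g) != 2L) stop2("exactly two groups required")
  a <- surv[surv$group == g[1], ]
  b <- surv[surv$group == g[2], ]
  logrank_test(a$time, a$event, b$time, b$event)
}

#' Read / write courtship trial CSV
#'
#' Schema: \code{trial_id,group,t_intro,t_court_init,t_copulation,
#' observation_end,courting_intervals}; the intervals column encodes
#' disjoint \code{start-end} pairs separated by \code{";"} (empty when
#' none). Times in seconds; empty cells are censored events.
#'
#' @param path CSV path.
#' @return For the reader, a list of \code{\link{courtship_trial}}.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    iv <- df$courting_intervals[i]
    ci <- NULL
    if (!is.na(iv) && nzchar(iv)) {
      pairs <- strsplit(strsplit(iv, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
      ci <- do.call(rbind, lapply(pairs, as.numeric))
    }
    courtship_trial(df$trial_id[i], df$group[i], df$t_intro[i],
                    if (is.na(df$t_court_init[i])) NA else df$t_court_init[i],
                    if (is.na(df$t_copulation[i])) NA else df$t_copulation[i],
                    ci, df$observation_end[i])
  })
}

#' @rdname read_trials_csv
#' @param trials List of \code{courtship_trial}.
#' @export
write_trials_csv <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    iv <- ""
    if (!is.null(tr$courting_intervals)) {
      iv <- paste(apply(tr$courting_intervals, 1,
                        function(p) paste0(p[1], "-", p[2])), collapse = ";")
    }
    data.frame(trial_id = tr$trial_id, group = tr$group, t_intro = tr$t_intro,
               t_court_init = tr$t_court_init, t_copulation = tr$t_copulation,
               observation_end = tr$observation_end, courting_intervals = iv,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
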