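#' ATP perfusion protocol
#'
#' Timing metadata for a perfusion imaging run. The default matches the
#' standard protocol: frames every 5 s for 5 min, with 2.5 mM ATP delivered
#' for 1 min after 1 min of baseline, so ATP runs from 60 s to 120 s.
#'
#' @param sample_interval_s Frame interval, s.
#' @param baseline_duration_s Baseline before ATP onset, s; ATP starts at
#'   the end of the baseline.
#' @param atp_duration_s Duration of ATP perfusion, s.
#' @param total_duration_s Total recording length, s.
#' @return An object of class \code{perfusion_protocol} with derived
#'   \code{atp_start_s} and \code{atp_end_s}.
#' @export
perfusion_protocol <- function(sample_interval_s = 5, baseline_duration_s = 60,
                               atp_duration_s = 60, total_duration_s = 300) {
  atp_start <- baseline_duration_s
  atp_end <- atp_start + atp_duration_s
  if (!(atp_start > 0 && atp_end > atp_start && atp_end <= total_duration_s)) {
    stop2("require 0 < atp_start < atp_end <= total_duration")
  }
  structure(list(sample_interval_s = sample_interval_s,
                 baseline_duration_s = baseline_duration_s,
                 atp_start_s = atp_start, atp_end_s = atp_end,
                 total_duration_s = total_duration_s),
            class = "perfusion_protocol")
}

#' Construct a fluorescence trace
#'
#' @param times_s Strictly increasing, evenly spaced frame times, s.
#' @param raw_F Raw ROI intensities (arbitrary units).
#' @return An object of class \code{fluorescence_trace}; \code{detrended_F}
#'   and \code{dFF} are filled in by \code{\link{detrend}} and
#'   \code{\link{normalize_and_peak}}.
#' @export
fluorescence_trace <- function(times_s, raw_F) {
  if (length(times_s) != length(raw_F)) stop2("times and intensities differ in length")
  d <- diff(times_s)
  if (length(d) && (any(d <= 0) || max(abs(d - d[1])) > 1e-8)) {
    stop2("times must be strictly increasing at constant spacing")
  }
  structure(list(times_s = as.numeric(times_s), raw_F = as.numeric(raw_F),
                 detrended_F = NULL, dFF = NULL),
            class = "fluorescence_trace")
}

in_window <- function(t, lo, hi) t >= lo & t < hi  # half-open

bleach_windows <- function(protocol) {
  list(pre = c(protocol$atp_start_s - 60, protocol$atp_start_s - 30),
       post = c(protocol$atp_end_s + 150, protocol$atp_end_s + 180))
}

#' Fit the photobleaching decay
#'
#' Least-squares fit of \eqn{F(t) = A e^{-kt} + C} (k >= 0, t from trace
#' start) restricted to the transient-free frames: those acquired 30-60 s
#' before ATP onset and 150-180 s after the end of ATP perfusion. Windows
#' are half-open; a frame is used iff its timestamp lies inside. On
#' non-convergence of the nonlinear fit, falls back to a log-linear fit
#' with a warning.
#'
#' @param trace A \code{\link{fluorescence_trace}}.
#' @param protocol A \code{\link{perfusion_protocol}}.
#' @return An object of class \code{bleach_fit}: \code{A}, \code{k},
#'   \code{C}, \code{fit_window_times}, \code{method}.
#' @export
fit_bleach <- function(trace, protocol) {
  stopifnot(inherits(trace, "fluorescence_trace"),
            inherits(protocol, "perfusion_protocol"))
  w <- bleach_windows(protocol)
  t <- trace$times_s
  pre <- in_window(t, w$pre[1], w$pre[2])
  post <- in_window(t, w$post[1], w$post[2])
  if (w$pre[1] < min(t) - 1e-9 || w$post[2] > max(t) + protocol$sample_interval_s) {
    stop2("bleach-fit windows fall outside the trace")
  }
  if (sum(pre) < 2L || sum(post) < 2L) {
    stop2("each bleach-fit window needs at least 2 frames")
  }
  sel <- pre | post
  tf <- t[sel]; Ff <- trace$raw_F[sel]
  out <- function(A, k, C, method) {
    structure(list(A = A, k = k, C = C, fit_window_times = w, method = method),
              class = "bleach_fit")
  }
  if (max(Ff) - min(Ff) < 1e-12) {
    return(out(0, 0, mean(Ff), "degenerate"))
  }
  # Exact least squares by profiling the nonlinear rate: for each k the
  # model is linear in (A, C), so solve that subproblem in closed form and
  # minimize the residual sum of squares over k >= 0. This avoids the
  # instability of a free 3-parameter exponential when the decay is nearly
  # flat (A and C then trade off along a ridge).
  t_span <- diff(range(tf))
  lin_fit <- function(k) {
    z <- exp(-k * tf)
    co <- stats::lm.fit(cbind(C = 1, A = z), Ff)$coefficients
    A <- unname(co["A"]); C <- unname(co["C"])
    # plausibility: a bleaching decay has A >= 0 and an asymptote that is
    # nonnegative; project onto the constraint when violated
    if (!is.finite(A) || A < 0) { A <- 0; C <- mean(Ff) }
    if (C < 0) { C <- 0; A <- sum(Ff * z) / sum(z * z) }
    list(A = A, C = C, rss = sum((Ff - C - A * z)^2))
  }
  # profile over a rate range where the regressor is distinguishable from
  # the intercept (k * span in [0.02, 20]), plus the no-decay candidate
  ks <- exp(seq(log(0.02 / t_span), log(20 / t_span), length.out = 80))
  rss <- vapply(ks, function(k) lin_fit(k)$rss, 0)
  i <- which.min(rss)
  lo <- ks[max(i - 1L, 1L)]; hi <- ks[min(i + 1L, length(ks))]
  k_hat <- stats::optimize(function(k) lin_fit(k)$rss, c(lo, hi),
                           tol = 1e-10)$minimum
  if (rss[i] < lin_fit(k_hat)$rss) k_hat <- ks[i]
  cf <- lin_fit(k_hat)
  if (sum((Ff - mean(Ff))^2) <= cf$rss) {  # no-decay model fits as well
    k_hat <- 0; cf <- list(A = 0, C = mean(Ff))
  }
  if (is.finite(cf$A) && is.finite(cf$C)) {
    return(out(cf$A, max(0, k_hat), cf$C, "profile_ls"))
  }
  warning("profiled bleach fit failed; using log-linear fallback",
          call. = FALSE)
  m1 <- mean(trace$raw_F[pre]); m2 <- mean(trace$raw_F[post])
  C0 <- min(m1, m2) - 1e-3 * max(abs(c(m1, m2, 1)))
  y <- pmax(Ff - C0, 1e-9)
  lf <- stats::lm(log(y) ~ tf)
  out(exp(unname(stats::coef(lf)[1])), max(0, -unname(stats::coef(lf)[2])),
      C0, "loglinear")
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf("<bleach_fit> F(t) = %.4g * exp(-%.5g t) + %.4g  [%s]\n",
              x$A, x$k, x$C, x$method))
  invisible(x)
}

#' Remove the photobleaching trend
#'
#' Subtracts the fitted decaying component \eqn{A e^{-kt}} from the raw
#' trace, preserving the offset \eqn{C} so the baseline stays on the
#' intensity scale that the \eqn{\Delta F/F_0} normalization presumes. Set
#' \code{subtract_offset = TRUE} to subtract the full fitted curve instead
#' (the literal reading; it drives the baseline toward zero and usually
#' makes F0 invalid).
#'
#' @param trace A \code{\link{fluorescence_trace}}.
#' @param fit A \code{\link{bleach_fit}} from the same trace.
#' @param subtract_offset Subtract the fitted offset C as well.
#' @return The trace with \code{detrended_F} filled in.
#' @export
detrend <- function(trace, fit, subtract_offset = FALSE) {
  stopifnot(inherits(trace, "fluorescence_trace"), inherits(fit, "bleach_fit"))
  dec <- fit$A * exp(-fit$k * trace$times_s)
  trace$detrended_F <- trace$raw_F - dec - if (subtract_offset) fit$C else 0
  trace
}

#' Baseline fluorescence F0
#'
#' Mean detrended intensity over the 30 s immediately preceding ATP onset
#' (half-open window \code{[atp_start - 30, atp_start)}).
#'
#' @param trace A detrended \code{\link{fluorescence_trace}}.
#' @param protocol A \code{\link{perfusion_protocol}}.
#' @return F0 (scalar).
#' @export
compute_f0 <- function(trace, protocol) {
  if (is.null(trace$detrended_F)) stop2("trace has not been detrended")
  sel <- in_window(trace$times_s, protocol$atp_start_s - 30, protocol$atp_start_s)
  if (!any(sel)) stop2("F0 window contains no frames")
  f0 <- mean(trace$detrended_F[sel])
  if (f0 <= 0) {
    stop2("F0 <= 0: normalization undefined. If the full fitted curve was ",
          "subtracted, detrend with subtract_offset = FALSE so the baseline ",
          "keeps its intensity scale.")
  }
  f0
}

#' Normalize to delta-F/F0 and extract the peak response
#'
#' Computes \eqn{\Delta F/F_0 = (F - F_0)/F_0} per frame on the detrended
#' trace. The peak response is the maximum of the \eqn{\Delta F/F_0} series
#' after a centered moving-average smooth of \code{smooth_s} seconds,
#' evaluated over the response window (default \code{[atp_start,
#' atp_end + 60)}, perfusion plus washout onset). Smoothing reflects the
#' sustained (about a minute) time course of the ATP response and keeps the
#' maximum from tracking single-frame noise.
#'
#' @param trace A detrended \code{\link{fluorescence_trace}}.
#' @param f0 Baseline from \code{\link{compute_f0}}.
#' @param protocol A \code{\link{perfusion_protocol}}.
#' @param peak_window Two-element numeric, response window in s (half-open);
#'   \code{NULL} for the default.
#' @param smooth_s Moving-average width, s (0 disables smoothing).
#' @return A list: the trace with \code{dFF} filled in, \code{peak_response}
#'   and \code{peak_time_s}.
#' @export
normalize_and_peak <- function(trace, f0, protocol, peak_window = NULL,
                               smooth_s = 45) {
  if (is.null(trace$detrended_F)) stop2("trace has not been detrended")
  if (f0 <= 0) stop2("F0 must be positive")
  trace$dFF <- (trace$detrended_F - f0) / f0
  pw <- peak_window %||% c(protocol$atp_start_s, protocol$atp_end_s + 60)
  width <- max(1L, round(smooth_s / protocol$sample_interval_s))
  if (width %% 2L == 0L) width <- width + 1L
  smoothed <- moving_average(trace$dFF, width)
  sel <- which(in_window(trace$times_s, pw[1], pw[2]))
  if (!length(sel)) stop2("peak window contains no frames")
  i <- sel[which.max(smoothed[sel])]
  list(trace = trace, peak_response = smoothed[i],
       peak_time_s = trace$times_s[i])
}

#' Full delta-F/F0 pipeline for one trace
#'
#' Bleach fit, detrend, F0, normalization and peak extraction in one call.
#'
#' @inheritParams normalize_and_peak
#' @param trace A \code{\link{fluorescence_trace}} (raw).
#' @param subtract_offset Passed to \code{\link{detrend}}.
#' @return An object of class \code{dff_result}: \code{trace} (with
#'   \code{detrended_F} and \code{dFF}), \code{fit}, \code{f0},
#'   \code{peak_response}, \code{peak_time_s}.
#' @examples
#' prot <- perfusion_protocol()
#' sim <- simulate_gcamp(C = 100, A_over_C = 0.5, k = 0.005,
#'                       transient_amplitude = 0.3, noise_sigma_over_C = 0,
#'                       protocol = prot, seed = 1)
#' res <- dff_pipeline(sim$trace, prot)
#' round(res$peak_response, 3)
#' @export
dff_pipeline <- function(trace, protocol, peak_window = NULL, smooth_s = 45,
                         subtract_offset = FALSE) {
  fit <- fit_bleach(trace, protocol)
  tr <- detrend(trace, fit, subtract_offset)
  f0 <- compute_f0(tr, protocol)
  np <- normalize_and_peak(tr, f0, protocol, peak_window, smooth_s)
  structure(list(trace = np$trace, fit = fit, f0 = f0,
                 peak_response = np$peak_response,
                 peak_time_s = np$peak_time_s, protocol = protocol),
            class = "dff_result")
}

#' @export
print.dff_result <- function(x, ...) {
  cat(sprintf("<dff_result> F0 = %.3f, peak dF/F0 = %.4f at t = %g s\n",
              x$f0, x$peak_response, x$peak_time_s))
  invisible(x)
}

#' @export
plot.dff_result <- function(x, ...) {
  graphics::plot(x$trace$times_s, x$trace$dFF, type = "l",
                 xlab = "Time (s)", ylab = expression(Delta * F / F[0]), ...)
  graphics::rect(x$protocol$atp_start_s, graphics::par("usr")[3],
                 x$protocol$atp_end_s, graphics::par("usr")[4],
                 col = grDevices::grey(0.5, 0.2), border = NA)
  graphics::points(x$peak_time_s, x$peak_response, pch = 16, col = 2)
  invisible(x)
}

#' Read ROI trace CSV
#'
#' Schema: a \code{time_s} column plus one intensity column per ROI.
#'
#' @param path CSV path.
#' @return Named list of \code{\link{fluorescence_trace}}, one per ROI
#'   column.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df)) stop2("trace CSV needs a time_s column")
  rois <- setdiff(names(df), "time_s")
  stats::setNames(lapply(rois, function(r) fluorescence_trace(df$time_s, df[[r]])),
                  rois)
}
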