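#' @title In vitro event analysis
#' @description Detection and quantification of slice-physiology events:
#'   spontaneous extracellular field potentials (threshold rule: deflection
#'   3 SD beyond baseline noise lasting more than 20 ms), fEPSP slopes
#'   (10-90% of the initial rising phase) and long-term potentiation time
#'   courses (% of baseline, late window 40-60 min), and dF/F calcium
#'   transients.
#' @name invitro-events
NULL

#' Robust noise SD of a trace
#'
#' Median absolute deviation (scaled to the Gaussian SD) over a baseline
#' window, robust to sparse residual events.
#'
#' @param trace Numeric vector.
#' @param rate Sampling rate (Hz).
#' @param window `c(start, end)` in seconds (default: whole trace).
#' @return Estimated noise SD in native units.
#' @export
estimate_noise_sd <- function(trace, rate, window = NULL) {
  if (is.null(window)) window <- c(0, (length(trace) - 1) / rate)
  i0 <- max(1L, floor(window[1] * rate) + 1L)
  i1 <- min(length(trace), floor(window[2] * rate) + 1L)
  if ((i1 - i0 + 1L) < rate) stop("noise window shorter than 1 s", call. = FALSE)
  seg <- trace[i0:i1]
  stats::mad(seg, constant = 1.4826)
}

#' Detect spontaneous extracellular field potentials
#'
#' An event is a contiguous excursion of the (baseline-subtracted) trace
#' beyond +/- `threshold_sd` times the noise SD lasting more than
#' `min_duration` ms; onset and offset are at the threshold crossings.
#' Excursions separated by less than `merge_gap` ms are merged before the
#' duration rule is applied. Detection is invariant under amplitude
#' rescaling because all thresholds are in SD units.
#'
#' @param trace Numeric vector (uV).
#' @param rate Sampling rate (Hz).
#' @param noise_sd Noise SD; estimated with [estimate_noise_sd()] if `NULL`.
#' @param threshold_sd Amplitude threshold in SD units (default 3).
#' @param min_duration Minimum event duration (ms, default 20; strict `>`).
#' @param merge_gap Sub-threshold gaps shorter than this are merged (ms,
#'   default 10).
#' @return An `event_list` data frame: onset_s, duration_ms, peak_sd,
#'   peak_native; with `attr(, "frequency_per_min")`.
#' @export
detect_sefp <- function(trace, rate, noise_sd = NULL, threshold_sd = 3,
                        min_duration = 20, merge_gap = 10) {
  if (is.null(noise_sd)) noise_sd <- estimate_noise_sd(trace, rate)
  if (is.na(noise_sd)) stop("noise SD unavailable", call. = FALSE)
  x <- trace - stats::median(trace)
  total_min <- length(x) / rate / 60
  empty <- data.frame(onset_s = numeric(0), duration_ms = numeric(0),
                      peak_sd = numeric(0), peak_native = numeric(0))
  if (noise_sd == 0) {
    attr(empty, "frequency_per_min") <- 0
    class(empty) <- c("event_list", "data.frame")
    return(empty)
  }
  over <- abs(x) >= threshold_sd * noise_sd
  runs <- logical_runs(over)
  if (!length(runs)) {
    attr(empty, "frequency_per_min") <- 0
    class(empty) <- c("event_list", "data.frame")
    return(empty)
  }
  # merge excursions separated by short sub-threshold gaps
  gap_samp <- merge_gap / 1000 * rate
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (r in 2:nrow(runs)) {
      if (runs[r, 1L] - merged[nrow(merged), 2L] - 1L < gap_samp) {
        merged[nrow(merged), 2L] <- runs[r, 2L]
      } else {
        merged <- rbind(merged, runs[r, , drop = FALSE])
      }
    }
  }
  dur_ms <- (merged[, 2L] - merged[, 1L] + 1L) / rate * 1000
  keep <- dur_ms > min_duration
  merged <- merged[keep, , drop = FALSE]
  dur_ms <- dur_ms[keep]
  if (!nrow(merged)) {
    attr(empty, "frequency_per_min") <- 0
    class(empty) <- c("event_list", "data.frame")
    return(empty)
  }
  peak <- vapply(seq_len(nrow(merged)), function(r) {
    seg <- x[merged[r, 1L]:merged[r, 2L]]
    seg[which.max(abs(seg))]
  }, 0)
  out <- data.frame(onset_s = (merged[, 1L] - 1L) / rate,
                    duration_ms = dur_ms,
                    peak_sd = peak / noise_sd,
                    peak_native = peak)
  attr(out, "frequency_per_min") <- nrow(out) / total_min
  class(out) <- c("event_list", "data.frame")
  out
}

#' @export
print.event_list <- function(x, ...) {
  fpm <- attr(x, "frequency_per_min")
  cat("Detected events: ", nrow(x),
      if (!is.null(fpm)) paste0(" (", signif(fpm, 4), " events/min)"),
      "\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}

#' Slope of the initial fEPSP component (10-90%)
#'
#' After blanking the stimulus artifact, the initial monophasic deflection is
#' located (dominant extremum; polarity auto-detected), the 10% and 90%
#' amplitude crossings on its rising phase are found by linear interpolation,
#' and a least-squares line is fit to the samples between them.
#'
#' @param sweep Numeric vector (mV), one evoked sweep, stimulus at time 0.
#' @param rate Sampling rate (Hz).
#' @param blank Stimulus-artifact blanking window (ms, default 2).
#' @return Slope in native units per ms (signed).
#' @export
fepsp_slope <- function(sweep, rate, blank = 2) {
  i0 <- floor(blank / 1000 * rate) + 1L
  if (i0 >= length(sweep)) stop("blanking window covers the sweep", call. = FALSE)
  x <- sweep[i0:length(sweep)]
  x <- x - x[1]
  ipk <- which.max(abs(x))
  amp <- x[ipk]
  if (amp == 0) stop("no identifiable deflection", call. = FALSE)
  sgn <- sign(amp)
  xr <- x * sgn                      # rising phase is now positive-going
  apk <- xr[ipk]
  crossing <- function(level) {
    below <- which(xr[seq_len(ipk)] <= level)
    if (!length(below)) return(1)
    i <- max(below)
    if (i == ipk) return(ipk)
    i + (level - xr[i]) / (xr[i + 1L] - xr[i])
  }
  c10 <- crossing(0.1 * apk)
  c90 <- crossing(0.9 * apk)
  lo <- ceiling(c10); hi <- floor(c90)
  tms <- (seq_along(xr) - 1) / rate * 1000
  if (hi - lo < 2L) {                # too few samples: chord through crossings
    t10 <- (c10 - 1) / rate * 1000; t90 <- (c90 - 1) / rate * 1000
    return(sgn * (0.9 * apk - 0.1 * apk) / (t90 - t10))
  }
  fit <- stats::lm.fit(cbind(1, tms[lo:hi]), xr[lo:hi])
  sgn * unname(fit$coefficients[2])
}

#' Normalize and summarize an LTP time course
#'
#' Sweep slopes are expressed as percent of the mean baseline slope (sweeps
#' at time < 0, induction at 0); the late-phase potentiation is the mean of
#' the normalized slope inside `window` (minutes after induction, default
#' 40-60 min). Requires at least `min_baseline` minutes of baseline.
#'
#' @param time_min Numeric vector of sweep times (minutes, 0 = induction).
#' @param slopes fEPSP slope per sweep (native units).
#' @param window Late analysis window in minutes (default `c(40, 60)`).
#' @param min_baseline Minimum baseline span (min, default 15).
#' @return An `ltp_series` list: `time_min`, `norm_slope` (%),
#'   `mean_potentiation` (%), `window`, `baseline_mean`.
#' @export
ltp_analyze <- function(time_min, slopes, window = c(40, 60), min_baseline = 15) {
  stopifnot(length(time_min) == length(slopes))
  bl <- time_min < 0
  if (!any(bl) || -min(time_min[bl]) < min_baseline - 1e-9) {
    stop("baseline epoch shorter than ", min_baseline, " min", call. = FALSE)
  }
  if (window[1] > max(time_min)) stop("analysis window outside recording", call. = FALSE)
  base_mean <- mean(slopes[bl])
  norm <- 100 * slopes / base_mean
  inw <- time_min >= window[1] & time_min <= window[2]
  if (!any(inw)) stop("no sweeps inside the analysis window", call. = FALSE)
  structure(list(time_min = time_min, norm_slope = norm,
                 mean_potentiation = mean(norm[inw]),
                 window = window, baseline_mean = base_mean),
            class = "ltp_series")
}

#' @export
print.ltp_series <- function(x, ...) {
  cat("LTP time course: ", length(x$time_min), " sweeps, baseline mean slope ",
      signif(x$baseline_mean, 4), "\n  mean potentiation ",
      x$window[1], "-", x$window[2], " min: ",
      round(x$mean_potentiation, 1), "% of baseline\n", sep = "")
  invisible(x)
}

#' @export
plot.ltp_series <- function(x, ...) {
  graphics::plot(x$time_min, x$norm_slope, xlab = "time (min)",
                 ylab = "fEPSP slope (% baseline)", pch = 16, cex = 0.5, ...)
  graphics::abline(h = 100, lty = 2)
  graphics::abline(v = 0, col = "grey60")
  invisible(x)
}

#' Group comparison of LTP experiments
#'
#' Between-group ANOVA on the normalized time-course profiles (subject-mean
#' summary) plus a Welch t-test on the late-window mean potentiation.
#'
#' @param series_a,series_b Lists of `ltp_series` per group.
#' @return List with `anova` (a `test_result`) and `window_test`
#'   (Welch t on mean potentiation).
#' @export
ltp_compare <- function(series_a, series_b) {
  prof <- function(s) s$norm_slope[s$time_min >= 0]
  pot <- function(s) s$mean_potentiation
  list(anova = profile_anova(lapply(series_a, prof), lapply(series_b, prof)),
       window_test = welch_ttest(vapply(series_a, pot, 0),
                                 vapply(series_b, pot, 0)))
}

#' Percent fluorescence change (dF/F)
#'
#' dF/F = 100 (F - F0) / (F0 - B), with B either a scalar, a background
#' trace, or a list/matrix of background-ROI traces that are averaged
#' pointwise first.
#'
#' @param f Fluorescence trace (ROI mean).
#' @param f0 Baseline fluorescence (scalar).
#' @param b Background: scalar, vector (same length as `f`), or list/matrix
#'   of background-ROI traces (averaged).
#' @return dF/F trace in percent.
#' @export
dff <- function(f, f0, b = 0) {
  if (is.list(b)) b <- rowMeans(do.call(cbind, b))
  if (is.matrix(b)) b <- rowMeans(b)
  denom <- f0 - b
  if (any(denom <= 0)) stop("F0 - B must be positive everywhere", call. = FALSE)
  100 * (f - f0) / denom
}
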