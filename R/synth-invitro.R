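#' @title Synthetic in vitro traces
#' @description Generators for the four slice-physiology inputs: traces with
#'   planted sEFP-like deflections, miniature-IPSC traces with
#'   difference-of-exponentials events, LTP slope-versus-time series with a
#'   baseline epoch and a post-induction plateau, and calcium fluorescence
#'   traces with known baseline and background. All noise is additive
#'   Gaussian of known SD and every planted event is enumerated in the
#'   returned ground truth.
#' @name synth-invitro
NULL

#' Generate a trace with planted sEFP-like deflections
#'
#' Events are flat-topped pulses with raised-cosine edges, amplitude given
#' in units of the noise SD, riding on Gaussian noise.
#'
#' @param duration_s Trace length (s, default 120).
#' @param rate Sampling rate (Hz, default 1000).
#' @param noise_sd Noise SD in native units (uV, default 10).
#' @param events Data frame `onset_s`, `duration_ms`, `amplitude_sd`
#'   (amplitude in noise-SD units; negative-going events use negative
#'   values). Empty/`NULL` plants nothing.
#' @param edge_ms Raised-cosine edge length (ms, default 3).
#' @param seed Integer seed.
#' @return List with `trace`, `rate`, `noise_sd` and `ground_truth`.
#' @export
gen_sefp_trace <- function(duration_s = 120, rate = 1000, noise_sd = 10,
                           events = NULL, edge_ms = 3, seed = 1L) {
  n <- round(duration_s * rate)
  with_seed(seed, {
    x <- stats::rnorm(n, sd = noise_sd)
    if (!is.null(events) && nrow(events)) {
      if (any(events$onset_s < 0 |
              events$onset_s + events$duration_ms / 1000 > duration_s)) {
        stop("planted event outside the trace", call. = FALSE)
      }
      o <- order(events$onset_s)
      gaps <- diff(events$onset_s[o]) * 1000 -
        events$duration_ms[o][-nrow(events)]
      if (any(gaps < 2 * edge_ms)) {
        stop("planted events overlap beyond the allowed limit", call. = FALSE)
      }
      for (r in seq_len(nrow(events))) {
        d_samp <- round(events$duration_ms[r] / 1000 * rate)
        e_samp <- round(edge_ms / 1000 * rate)
        shape <- rep(1, d_samp)
        up <- 0.5 * (1 - cos(pi * seq_len(e_samp) / e_samp))
        shape[seq_len(e_samp)] <- up
        shape[(d_samp - e_samp + 1L):d_samp] <- rev(up)
        i0 <- round(events$onset_s[r] * rate) + 1L
        ix <- i0:(i0 + d_samp - 1L)
        x[ix] <- x[ix] + events$amplitude_sd[r] * noise_sd * shape
      }
    }
    list(trace = x, rate = rate, noise_sd = noise_sd,
         ground_truth = list(modality = "sefp", events = events,
                             noise_sd = noise_sd, edge_ms = edge_ms,
                             seed = seed))
  })
}

#' Generate a miniature-IPSC trace with planted events
#'
#' Events have a difference-of-exponentials shape (fast rise,
#' single-exponential decay), inward (negative) polarity, Poisson arrival
#' times thinned to a minimum separation, and per-event Gaussian amplitudes.
#'
#' @param duration_s Trace length (s, default 180 - a 3 min recording).
#' @param rate Sampling rate (Hz, default 10000).
#' @param rate_hz Mean event rate (Hz, default 5).
#' @param amp_mean,amp_sd Event peak amplitude distribution (pA; defaults
#'   26.09 and 5).
#' @param tau_ms Decay constant (ms, default 9.5).
#' @param rise_ms Rise constant (ms, default 0.5).
#' @param noise_sd Noise SD (pA, default 3).
#' @param min_sep_ms Minimum inter-event separation; closer arrivals are
#'   thinned (ms, default 30). An error is raised when the requested density
#'   makes heavy overlap unavoidable (`rate_hz * min_sep_ms/1000 > 0.5`).
#' @param seed Integer seed.
#' @return List with `trace` (pA), `rate`, `noise_sd` and `ground_truth`
#'   (`events`: data frame onset_s, amplitude_pa kept after thinning).
#' @export
gen_mini_trace <- function(duration_s = 180, rate = 10000, rate_hz = 5,
                           amp_mean = 26.09, amp_sd = 5, tau_ms = 9.5,
                           rise_ms = 0.5, noise_sd = 3, min_sep_ms = 30,
                           seed = 1L) {
  stopifnot(amp_mean > 0, tau_ms > 0, rise_ms > 0)
  if (rate_hz * min_sep_ms / 1000 > 0.5) {
    stop("event density too high: events would overlap beyond the limit",
         call. = FALSE)
  }
  n <- round(duration_s * rate)
  with_seed(seed, {
    x <- stats::rnorm(n, sd = noise_sd)
    onsets <- cumsum(stats::rexp(ceiling(rate_hz * duration_s * 1.5) + 20L,
                                 rate = rate_hz))
    onsets <- onsets[onsets < duration_s - 10 * tau_ms / 1000]
    if (length(onsets) > 1L) {
      keep <- c(TRUE, diff(onsets) >= min_sep_ms / 1000)
      # iterate: thinning can re-expose short gaps
      while (!all(keep)) {
        onsets <- onsets[keep]
        keep <- c(TRUE, diff(onsets) >= min_sep_ms / 1000)
      }
    }
    amps <- pmax(stats::rnorm(length(onsets), amp_mean, amp_sd), 0.2 * amp_mean)
    span <- round(8 * tau_ms / 1000 * rate)
    t_ms <- (seq_len(span) - 1) / rate * 1000
    shape <- (1 - exp(-t_ms / rise_ms)) * exp(-t_ms / tau_ms)
    shape <- shape / max(shape)
    for (i in seq_along(onsets)) {
      i0 <- round(onsets[i] * rate) + 1L
      ix <- i0:min(n, i0 + span - 1L)
      x[ix] <- x[ix] - amps[i] * shape[seq_along(ix)]
    }
    list(trace = x, rate = rate, noise_sd = noise_sd,
         ground_truth = list(modality = "minis",
                             events = data.frame(onset_s = onsets,
                                                 amplitude_pa = amps),
                             tau_ms = tau_ms, rise_ms = rise_ms,
                             rate_hz = rate_hz, noise_sd = noise_sd,
                             seed = seed))
  })
}

#' Generate an LTP slope-versus-time series
#'
#' Baseline sweeps at a constant mean slope, then an exponential approach to
#' a plateau expressed as percent of baseline, with multiplicative Gaussian
#' sweep noise.
#'
#' @param baseline_min Baseline span before induction (min, default 15).
#' @param post_min Post-induction span (min, default 60).
#' @param sweep_interval_s Seconds between sweeps (default 15).
#' @param plateau_pct Plateau level as % of baseline (default 140).
#' @param rise_tau_min Time constant of the approach to plateau (default 5).
#' @param baseline_slope Baseline fEPSP slope (native units, default -0.2).
#' @param noise_cv Coefficient of variation of sweep noise (default 0.03).
#' @param seed Integer seed.
#' @return List with `time_min`, `slopes` and `ground_truth`.
#' @export
gen_ltp_series <- function(baseline_min = 15, post_min = 60,
                           sweep_interval_s = 15, plateau_pct = 140,
                           rise_tau_min = 5, baseline_slope = -0.2,
                           noise_cv = 0.03, seed = 1L) {
  dt <- sweep_interval_s / 60
  time_min <- seq(-baseline_min, post_min, by = dt)
  level <- ifelse(time_min < 0, 1,
                  1 + (plateau_pct / 100 - 1) * (1 - exp(-time_min / rise_tau_min)))
  slopes <- with_seed(seed, {
    baseline_slope * level * (1 + stats::rnorm(length(level), sd = noise_cv))
  })
  list(time_min = time_min, slopes = slopes,
       ground_truth = list(modality = "ltp", plateau_pct = plateau_pct,
                           rise_tau_min = rise_tau_min,
                           baseline_slope = baseline_slope,
                           noise_cv = noise_cv, seed = seed))
}

#' Generate a calcium fluorescence trace with background ROIs
#'
#' @param duration_s Trace length (s, default 30).
#' @param rate Frame rate (Hz, default 50).
#' @param f0 Baseline fluorescence (default 100).
#' @param background Background fluorescence level (default 20).
#' @param transients Data frame `onset_s`, `amplitude` (fluorescence units),
#'   `tau_s` (decay, s); `NULL` plants nothing.
#' @param n_background_rois Number of background ROI traces (default 4).
#' @param noise_sd Frame noise SD (default 0.5).
#' @param seed Integer seed.
#' @return List with `f` (ROI trace), `f0`, `background_rois` (matrix, one
#'   column per ROI), and `ground_truth` (planted peak dF/F per transient).
#' @export
gen_calcium_trace <- function(duration_s = 30, rate = 50, f0 = 100,
                              background = 20, transients = NULL,
                              n_background_rois = 4, noise_sd = 0.5,
                              seed = 1L) {
  n <- round(duration_s * rate)
  tt <- (seq_len(n) - 1) / rate
  with_seed(seed, {
    f <- rep(f0, n) + stats::rnorm(n, sd = noise_sd)
    if (!is.null(transients) && nrow(transients)) {
      for (r in seq_len(nrow(transients))) {
        on <- transients$onset_s[r]
        idx <- tt >= on
        f[idx] <- f[idx] + transients$amplitude[r] *
          exp(-(tt[idx] - on) / transients$tau_s[r])
      }
    }
    bg <- matrix(background + stats::rnorm(n * n_background_rois, sd = noise_sd),
                 nrow = n)
    peak_dff <- if (!is.null(transients) && nrow(transients)) {
      100 * transients$amplitude / (f0 - background)
    } else numeric(0)
    list(f = f, f0 = f0, background_rois = bg,
         ground_truth = list(modality = "calcium", transients = transients,
                             background = background, peak_dff = peak_dff,
                             seed = seed))
  })
}
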