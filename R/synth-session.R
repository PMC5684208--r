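#' @title Synthetic tracking, LFP and spiking sessions
#' @description Generates a paired position-tracking series (50 Hz) and LFP
#'   trace (250 Hz) on a common clock, plus sorted-unit spike trains with
#'   wide or narrow mean waveforms. The speed profile is piecewise constant
#'   over segments drawn from a stated speed set, so in-range (5-20 cm/s)
#'   and out-of-range epochs are known exactly; the LFP is a sum of
#'   band-limited Gaussian noise components with planted per-band power
#'   fractions; spike trains are homogeneous Poisson at stated rates.
#' @name synth-session
NULL

#' Default planted band power fractions
#' @return Named numeric vector over the default bands, summing to 1.
#' @export
default_band_fractions <- function() {
  c(delta = 0.25, theta = 0.35, beta = 0.15, low_gamma = 0.15, high_gamma = 0.10)
}

#' Generate a synthetic recording session
#'
#' @param duration Session length (s, default 600).
#' @param pos_rate Tracking rate (Hz, default 50).
#' @param lfp_rate LFP rate (Hz, default 250).
#' @param band_fractions Named fractions over `bands` (must sum to 1 within
#'   1e-6; default [default_band_fractions()]).
#' @param bands Band edges (default [default_bands()]).
#' @param speed_levels Speeds the piecewise-constant profile draws from
#'   (cm/s; default `c(2, 10, 30)` - one in the 5-20 cm/s range).
#' @param seg_dur Speed-segment duration (s, default 20).
#' @param lfp_amp Total LFP SD (uV, default 100).
#' @param unit_spec Optional data frame `n`, `rate_hz`, `width_us` describing
#'   unit populations (e.g. wide 450 us excitatory at 2.73 Hz).
#' @param wf_rate Waveform sampling rate (Hz, default 32000).
#' @param group Genotype label attached to units (default `"A"`).
#' @param seed Integer seed.
#' @return List with `tracking` (time, x, y), `lfp` (numeric vector),
#'   `lfp_rate`, `units` (list of unit records), and `ground_truth`
#'   (segment speeds, planted fractions, unit parameters, seed).
#' @export
gen_session <- function(duration = 600, pos_rate = 50, lfp_rate = 250,
                        band_fractions = default_band_fractions(),
                        bands = default_bands(),
                        speed_levels = c(2, 10, 30), seg_dur = 20,
                        lfp_amp = 100, unit_spec = NULL, wf_rate = 32000,
                        group = "A", seed = 1L) {
  stopifnot(duration > 0, pos_rate > 0, lfp_rate > 0)
  if (abs(sum(band_fractions) - 1) > 1e-6) {
    stop("band fractions must sum to 1", call. = FALSE)
  }
  stopifnot(all(names(band_fractions) %in% names(bands)))
  with_seed(seed, {
    n_pos <- round(duration * pos_rate)
    n_lfp <- round(duration * lfp_rate)
    t_pos <- (seq_len(n_pos) - 1L) / pos_rate

    # piecewise-constant speed profile; heading rotates slowly so the path
    # stays smooth under the boxcar filter
    # balanced allocation of levels over segments, randomly ordered, so every
    # session contains in-range locomotion whenever one level is in range
    n_seg <- ceiling(duration / seg_dur)
    seg_speed <- sample(rep_len(speed_levels, n_seg))
    seg_of <- pmin(floor(t_pos / seg_dur) + 1L, n_seg)
    speed <- seg_speed[seg_of]
    heading <- cumsum(stats::rnorm(n_pos, sd = 0.02))
    step <- speed / pos_rate
    x <- cumsum(c(0, step[-1] * cos(heading[-1])))
    y <- cumsum(c(0, step[-1] * sin(heading[-1])))
    tracking <- data.frame(time = t_pos, x = x, y = y)

    # LFP: sum of band-limited noise components with planted power fractions
    lfp <- numeric(n_lfp)
    for (b in names(band_fractions)) {
      comp <- fft_bandpass(stats::rnorm(n_lfp), lfp_rate,
                           bands[[b]][1], bands[[b]][2])
      comp <- comp / stats::sd(comp) * sqrt(band_fractions[[b]])
      lfp <- lfp + comp
    }
    lfp <- lfp * lfp_amp

    units <- list()
    if (!is.null(unit_spec)) {
      for (r in seq_len(nrow(unit_spec))) {
        for (j in seq_len(unit_spec$n[r])) {
          spikes <- cumsum(stats::rexp(ceiling(unit_spec$rate_hz[r] * duration * 1.5) + 20L,
                                       rate = unit_spec$rate_hz[r]))
          spikes <- spikes[spikes <= duration]
          units[[length(units) + 1L]] <-
            list(spikes = spikes,
                 waveform = spike_waveform(unit_spec$width_us[r], wf_rate),
                 wf_rate = wf_rate, duration = duration, group = group,
                 true_width_us = unit_spec$width_us[r],
                 true_rate_hz = unit_spec$rate_hz[r])
        }
      }
    }
    list(tracking = tracking, lfp = lfp, lfp_rate = lfp_rate,
         pos_rate = pos_rate, units = units,
         ground_truth = list(modality = "session",
                             segment_speeds = seg_speed, seg_dur = seg_dur,
                             band_fractions = band_fractions,
                             unit_spec = unit_spec, seed = seed))
  })
}

#' Biphasic mean spike waveform template
#'
#' A negative Gaussian trough followed by a positive Gaussian peak at the
#' requested trough-to-peak separation.
#'
#' @param width_us Trough-to-peak separation (microseconds).
#' @param wf_rate Sampling rate (Hz, default 32000).
#' @param span_us Total waveform span (default 2000 us).
#' @return Numeric waveform (uV, arbitrary scale).
#' @export
spike_waveform <- function(width_us, wf_rate = 32000, span_us = 2000) {
  t_us <- (seq_len(round(span_us * wf_rate / 1e6)) - 1) / wf_rate * 1e6
  t0 <- 500
  -100 * exp(-((t_us - t0) / 80)^2) + 55 * exp(-((t_us - t0 - width_us) / 140)^2)
}
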