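#' @title Miniature postsynaptic current detection and metrics
#' @description Sliding optimal-scaling template matching (the standard
#'   scheme for miniature-event detection): at each offset the template is
#'   fit to the trace by least squares with free scale and offset, and the
#'   detection criterion is the scale divided by its standard error. An event
#'   is accepted when the criterion reaches the threshold (3.5 by default)
#'   and the fitted peak also exceeds 3 times the baseline noise SD. Event
#'   amplitudes, instantaneous frequencies (1/interval to the previous
#'   event) and single-exponential decay constants are reported, and pooled
#'   group metrics use a seeded fixed-size subsample of events per cell.
#' @name minis
NULL

#' Difference-of-exponentials mini template
#'
#' `(1 - exp(-t/rise)) * exp(-t/decay)`, peak-normalized to 1.
#'
#' @param rate Sampling rate (Hz).
#' @param rise_ms,decay_ms Rise and decay time constants (ms; defaults 0.5
#'   and 9).
#' @param length_ms Template length (ms, default 30).
#' @return Numeric template vector with attributes `rise_ms`, `decay_ms`,
#'   `peak_index`.
#' @export
mini_template <- function(rate, rise_ms = 0.5, decay_ms = 9, length_ms = 30) {
  t_ms <- (seq_len(round(length_ms / 1000 * rate)) - 1) / rate * 1000
  shape <- (1 - exp(-t_ms / rise_ms)) * exp(-t_ms / decay_ms)
  shape <- shape / max(shape)
  structure(shape, rise_ms = rise_ms, decay_ms = decay_ms,
            peak_index = which.max(shape))
}

#' Detect miniature synaptic events by sliding template matching
#'
#' @param trace Current trace (pA). Inward (negative-going) events are the
#'   default; the trace is rectified internally and amplitudes are reported
#'   positive.
#' @param rate Sampling rate (Hz).
#' @param template Template vector (see [mini_template()]); built with
#'   defaults if `NULL`.
#' @param criterion Detection-criterion threshold (default 3.5).
#' @param noise_sd Baseline noise SD (pA); robustly estimated from the whole
#'   trace if `NULL`.
#' @param amp_sd_min Minimum fitted peak amplitude in noise-SD units
#'   (default 3).
#' @param direction `"negative"` (inward, default) or `"positive"`.
#' @return A `mini_events` data frame: time_s (event peak), amplitude_pa,
#'   inst_freq_hz (NA for each cell's first event), tau_ms, criterion.
#' @export
detect_minis <- function(trace, rate, template = NULL, criterion = 3.5,
                         noise_sd = NULL, amp_sd_min = 3,
                         direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (is.null(template)) template <- mini_template(rate)
  L <- length(template)
  if (L > length(trace)) stop("template longer than trace", call. = FALSE)
  x <- trace - stats::median(trace)
  if (direction == "negative") x <- -x
  if (is.null(noise_sd)) noise_sd <- stats::mad(x, constant = 1.4826)

  st <- sum(template); stt <- sum(template^2)
  s_tt <- stt - st^2 / L                       # centered template energy
  sd_run <- running_sum(x, L)
  sdd_run <- running_sum(x^2, L)
  sdt_run <- xcorr_valid(x, template)
  a <- (sdt_run - sd_run * st / L) / s_tt      # fitted scale
  b <- (sd_run - a * st) / L
  sse <- sdd_run - b * sd_run - a * sdt_run
  sse <- pmax(sse, 0)
  se_a <- sqrt(sse / (L - 2) / s_tt)
  crit <- ifelse(se_a > 0, a / se_a, 0)

  accept <- crit >= criterion & a >= amp_sd_min * noise_sd
  runs <- logical_runs(accept)
  if (!length(runs)) {
    out <- data.frame(time_s = numeric(0), amplitude_pa = numeric(0),
                      inst_freq_hz = numeric(0), tau_ms = numeric(0),
                      criterion = numeric(0))
    class(out) <- c("mini_events", "data.frame")
    attr(out, "noise_sd") <- noise_sd
    return(out)
  }
  pk_off <- attr(template, "peak_index") %||% which.max(template)
  onsets <- vapply(seq_len(nrow(runs)), function(r) {
    seg <- runs[r, 1L]:runs[r, 2L]
    seg[which.max(crit[seg])]
  }, 0L)
  # drop re-triggers within half a template of the previous event
  if (length(onsets) > 1L) {
    keep <- c(TRUE, diff(onsets) > L / 2)
    onsets <- onsets[keep]
  }
  peaks <- onsets + pk_off - 1L
  amp <- a[onsets]
  # decay fits stop short of the next event so overlap cannot inflate tau
  next_onset <- c(onsets[-1L], length(x) + 1L)
  # local baseline from the few ms preceding each onset (template-fit offset
  # is biased when the template decay mismatches the event)
  pre_w <- max(2L, round(0.002 * rate))
  base_loc <- vapply(onsets, function(o) {
    stats::median(x[max(1L, o - pre_w):max(1L, o - 1L)])
  }, 0)
  tau <- vapply(seq_along(onsets), function(i) {
    fit_decay_tau(x, peaks[i], amp[i], base_loc[i], rate,
                  rise_ms = attr(template, "rise_ms") %||% 0.5,
                  decay_guess = attr(template, "decay_ms") %||% 9,
                  limit = next_onset[i] - 1L)
  }, 0)
  times <- (peaks - 1L) / rate
  iff <- c(NA_real_, 1 / diff(times))
  out <- data.frame(time_s = times, amplitude_pa = amp, inst_freq_hz = iff,
                    tau_ms = tau, criterion = crit[onsets])
  class(out) <- c("mini_events", "data.frame")
  attr(out, "noise_sd") <- noise_sd
  attr(out, "duration_s") <- length(trace) / rate
  out
}

# Single-exponential decay fit from an event peak on the rectified trace.
# Starts a short delay after the peak (to let the rise component die away),
# seeds with a log-linear fit and refines with nls when it converges.
fit_decay_tau <- function(x, peak_idx, amp, baseline, rate,
                          rise_ms = 0.5, decay_guess = 9, limit = length(x)) {
  skip <- max(1, round(2 * rise_ms / 1000 * rate))
  span <- round(5 * decay_guess / 1000 * rate)
  i0 <- peak_idx + skip
  i1 <- min(length(x), peak_idx + span, limit)
  if (i1 - i0 < 4L) return(NA_real_)
  y <- x[i0:i1] - baseline
  t_ms <- (seq.int(i0, i1) - peak_idx) / rate * 1000
  pos <- y > 0.05 * amp
  if (sum(pos) < 4L) return(NA_real_)
  # a credible tau must be resolvable inside the fitted window
  tau_max <- 2 * 5 * decay_guess
  lfit <- stats::lm.fit(cbind(1, t_ms[pos]), log(y[pos]))
  tau0 <- -1 / lfit$coefficients[2]
  if (!is.finite(tau0) || tau0 <= 0 || tau0 > tau_max) return(NA_real_)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(y ~ A * exp(-t_ms / tau), start = list(A = amp, tau = tau0),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    tau <- stats::coef(fit)[["tau"]]
    if (is.finite(tau) && tau > 0 && tau <= tau_max) return(tau)
  }
  unname(tau0)
}

#' @export
print.mini_events <- function(x, ...) {
  nsd <- attr(x, "noise_sd")
  cat("Miniature events: ", nrow(x), " detected",
      if (!is.null(nsd)) paste0(" (noise SD ", signif(nsd, 3), " pA)"),
      "\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}

#' Pooled per-event mini metrics and group comparison
#'
#' For each cell a fixed number `k` of detected events is subsampled
#' uniformly without replacement (seeded); events are pooled within group
#' and per-group mean +/- SEM are reported for peak amplitude, instantaneous
#' frequency and decay constant, together with a pooled-variance per-event
#' t-test (df = k*(cells_a + cells_b) - 2) and a two-sample
#' Kolmogorov-Smirnov test with cumulative-probability curves.
#'
#' @param cells_a,cells_b Lists of `mini_events` data frames (one per cell).
#' @param k Events per cell (default 50).
#' @param seed Subsampling seed.
#' @return A `mini_metrics` list: `pooled` (data frame with group, cell and
#'   the three metrics), `summary` (per metric x group: mean, sem, n),
#'   `tests` (per metric: `t` and `ks` `test_result`s), `k`, `seed`.
#' @export
mini_metrics <- function(cells_a, cells_b, k = 50L, seed = 1L) {
  check <- function(cells, label) {
    bad <- which(vapply(cells, nrow, 0L) < k)
    if (length(bad)) {
      stop("cells with fewer than k = ", k, " events in group ", label, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  check(cells_a, "A"); check(cells_b, "B")
  pooled <- with_seed(seed, {
    take <- function(cells, group) {
      do.call(rbind, lapply(seq_along(cells), function(i) {
        ev <- cells[[i]]
        sel <- sort(sample.int(nrow(ev), k))
        data.frame(group = group, cell = i,
                   amplitude_pa = ev$amplitude_pa[sel],
                   inst_freq_hz = ev$inst_freq_hz[sel],
                   tau_ms = ev$tau_ms[sel])
      }))
    }
    rbind(take(cells_a, "A"), take(cells_b, "B"))
  })
  metrics <- c("amplitude_pa", "inst_freq_hz", "tau_ms")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(c("A", "B"), function(g) {
      v <- pooled[[m]][pooled$group == g]
      v <- v[!is.na(v)]
      data.frame(metric = m, group = g, mean = mean(v),
                 sem = stats::sd(v) / sqrt(length(v)), n = length(v))
    }))
  }))
  tests <- lapply(metrics, function(m) {
    va <- pooled[[m]][pooled$group == "A"]; va <- va[!is.na(va)]
    vb <- pooled[[m]][pooled$group == "B"]; vb <- vb[!is.na(vb)]
    tt <- pooled_ttest(va, vb)
    tt$test <- "pooled per-event t"
    list(t = tt, ks = ks_test(va, vb))
  })
  names(tests) <- metrics
  structure(list(pooled = pooled, summary = summ, tests = tests,
                 k = k, seed = seed),
            class = "mini_metrics")
}

#' @export
print.mini_metrics <- function(x, ...) {
  cat("Pooled mini metrics (k = ", x$k, " events/cell, seed ", x$seed, ")\n",
      sep = "")
  s <- x$summary
  s$mean <- signif(s$mean, 4); s$sem <- signif(s$sem, 3)
  print(s, row.names = FALSE)
  for (m in names(x$tests)) {
    tt <- x$tests[[m]]$t
    cat(sprintf("  %s: t(%d) = %.3f, p = %s\n", m, as.integer(tt$df),
                tt$statistic, format.pval(tt$p.value, digits = 3)))
  }
  invisible(x)
}
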