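#' @title Position tracking and LFP band power
#' @description Cleans head-position tracking (50 Hz), computes running
#'   speed, selects locomotion epochs in a speed range (5-20 cm/s by
#'   default), and quantifies the percent power of local field potential
#'   frequency bands (250 Hz LFP, 55-65 Hz notch) during those epochs.
#' @name tracking-lfp
NULL

#' Default LFP frequency bands (Hz)
#'
#' Delta 1-4, theta 4-12, beta 12-30, low gamma 30-55, high gamma 65-120 Hz.
#' The 55-65 Hz mains-notch band separates the gamma bands and is excluded
#' from both band and total power.
#' @return Named list of `c(lo, hi)` band edges.
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 12), beta = c(12, 30),
       low_gamma = c(30, 55), high_gamma = c(65, 120))
}

#' Clean a position-tracking series
#'
#' Tracking artifacts are removed by deleting samples implying speeds greater
#' than 100 cm/s; missing positions with total gap durations under 1 s are
#' linearly interpolated (longer gaps stay missing); and the path is smoothed
#' with a centered 21-sample boxcar window over each contiguous valid run
#' (shrinking symmetric window near run edges).
#'
#' @param track Data frame with columns `time` (s, strictly increasing),
#'   `x`, `y` (cm); `NA` positions mark missing samples.
#' @param max_speed Deletion threshold (cm/s, default 100).
#' @param max_gap Longest gap interpolated (s, default 1).
#' @param boxcar Boxcar length in samples (odd, default 21).
#' @return A data frame of the same shape with cleaned `x`, `y` and a logical
#'   `valid` column.
#' @export
clean_tracking <- function(track, max_speed = 100, max_gap = 1, boxcar = 21L) {
  stopifnot(all(c("time", "x", "y") %in% names(track)),
            all(diff(track$time) > 0), boxcar %% 2L == 1L)
  n <- nrow(track)
  x <- track$x; y <- track$y; tt <- track$time
  valid <- !(is.na(x) | is.na(y))
  if (sum(valid) < 2L) stop("fewer than 2 valid tracking samples", call. = FALSE)

  # delete samples reached at > max_speed from the previous surviving sample
  iv <- which(valid)
  prev <- iv[1]
  for (i in iv[-1]) {
    sp <- sqrt((x[i] - x[prev])^2 + (y[i] - y[prev])^2) / (tt[i] - tt[prev])
    if (sp > max_speed) valid[i] <- FALSE else prev <- i
  }
  x[!valid] <- NA_real_; y[!valid] <- NA_real_

  # interpolate interior gaps shorter than max_gap
  runs <- logical_runs(!valid)
  if (length(runs)) {
    for (r in seq_len(nrow(runs))) {
      a <- runs[r, 1L]; b <- runs[r, 2L]
      if (a == 1L || b == n) next                     # edge gaps stay missing
      gap_dur <- tt[b + 1L] - tt[a - 1L]
      if (gap_dur >= max_gap) next
      w <- (tt[a:b] - tt[a - 1L]) / gap_dur
      x[a:b] <- x[a - 1L] + w * (x[b + 1L] - x[a - 1L])
      y[a:b] <- y[a - 1L] + w * (y[b + 1L] - y[a - 1L])
      valid[a:b] <- TRUE
    }
  }

  # boxcar smoothing per valid run; symmetric window shrinks near run edges
  half <- (boxcar - 1L) %/% 2L
  smooth_run <- function(v) {
    m <- length(v)
    out <- v
    for (i in seq_len(m)) {
      h <- min(half, i - 1L, m - i)
      out[i] <- mean(v[(i - h):(i + h)])
    }
    out
  }
  runs <- logical_runs(valid)
  if (length(runs)) {
    for (r in seq_len(nrow(runs))) {
      a <- runs[r, 1L]; b <- runs[r, 2L]
      x[a:b] <- smooth_run(x[a:b])
      y[a:b] <- smooth_run(y[a:b])
    }
  }
  data.frame(time = tt, x = x, y = y, valid = valid)
}

#' Instantaneous running speed from cleaned tracking
#'
#' Speed at each sample is the Euclidean displacement from the previous valid
#' sample divided by the elapsed time; the first valid sample inherits the
#' speed of its successor so the trace is aligned to the tracking timestamps.
#'
#' @param track Cleaned tracking data frame (see [clean_tracking()]).
#' @return Data frame `time`, `speed` (cm/s, `NA` where tracking is invalid).
#' @export
compute_speed <- function(track) {
  valid <- if ("valid" %in% names(track)) track$valid else !is.na(track$x)
  iv <- which(valid)
  if (length(iv) < 2L) stop("fewer than 2 valid samples", call. = FALSE)
  sp <- rep(NA_real_, nrow(track))
  dx <- diff(track$x[iv]); dy <- diff(track$y[iv]); dt <- diff(track$time[iv])
  seg <- sqrt(dx^2 + dy^2) / dt
  # a segment speed is only meaningful between consecutive samples
  consec <- diff(iv) == 1L
  sp[iv[-1][consec]] <- seg[consec]
  first <- iv[1]
  nxt <- sp[iv[iv > first]]
  sp[first] <- nxt[!is.na(nxt)][1]
  data.frame(time = track$time, speed = sp)
}

#' Percent power of LFP frequency bands during in-range locomotion
#'
#' Each LFP sample inherits the speed of the nearest tracking sample; only
#' contiguous epochs whose speed lies inside `speed_range` (and lasting at
#' least `min_epoch` seconds) enter the analysis. Epochs are notch-filtered
#' (zero-phase Butterworth band-stop, 55-65 Hz by default), the power
#' spectral density is estimated by Welch's method (2 s Hann windows, 50%
#' overlap, periodograms averaged across epochs without concatenating across
#' discontinuities), power is integrated per band with the notch band excised
#' from both band and total power, and percentages of total analyzed-range
#' power are reported.
#'
#' @param lfp Numeric vector of LFP samples (uV).
#' @param lfp_rate LFP sampling rate (Hz, default 250).
#' @param speed Data frame `time`, `speed` from [compute_speed()].
#' @param lfp_start Time of the first LFP sample (s, default 0).
#' @param speed_range In-range locomotion speeds (cm/s, default `c(5, 20)`).
#' @param bands Named list of band edges (default [default_bands()]).
#' @param notch Notch band (Hz, default `c(55, 65)`); `NULL` disables.
#' @param min_epoch Shortest usable epoch (s, default 1).
#' @param window Welch window length (s, default 2).
#' @return A `band_power` data frame: band, lo, hi, power, percent
#'   (percent sums to 100 over the analyzed bands).
#' @export
band_percent_power <- function(lfp, lfp_rate = 250, speed, lfp_start = 0,
                               speed_range = c(5, 20), bands = default_bands(),
                               notch = c(55, 65), min_epoch = 1, window = 2) {
  nyq <- lfp_rate / 2
  edges <- do.call(rbind, bands)
  if (any(edges < 0) || any(edges > nyq)) {
    stop("band edges must lie within 0-", nyq, " Hz", call. = FALSE)
  }
  o <- order(edges[, 1])
  if (any(edges[o, 1][-1] < edges[o, 2][-nrow(edges)])) {
    stop("bands must be non-overlapping", call. = FALSE)
  }
  n <- length(lfp)
  t_lfp <- lfp_start + (seq_len(n) - 1L) / lfp_rate
  # nearest tracking sample per LFP sample
  ti <- findInterval(t_lfp, speed$time, all.inside = TRUE)
  use_next <- (speed$time[pmin(ti + 1L, nrow(speed))] - t_lfp) < (t_lfp - speed$time[ti])
  ti[use_next] <- pmin(ti[use_next] + 1L, nrow(speed))
  sp <- speed$speed[ti]
  in_range <- !is.na(sp) & sp >= speed_range[1] & sp <= speed_range[2]
  runs <- logical_runs(in_range)
  min_len <- ceiling(min_epoch * lfp_rate)
  epochs <- list()
  if (length(runs)) {
    for (r in seq_len(nrow(runs))) {
      if (runs[r, 2L] - runs[r, 1L] + 1L >= min_len) {
        epochs[[length(epochs) + 1L]] <- lfp[runs[r, 1L]:runs[r, 2L]]
      }
    }
  }
  if (length(epochs) == 0L) stop("no in-range epoch of at least ",
                                 min_epoch, " s", call. = FALSE)
  if (!is.null(notch)) {
    bf <- signal::butter(4, notch / nyq, type = "stop")
    epochs <- lapply(epochs, function(e) as.numeric(signal::filtfilt(bf, e)))
  }
  nper <- round(window * lfp_rate)
  est <- welch_psd(epochs, fs = lfp_rate, nper = nper, min_len = min_len)
  in_notch <- if (is.null(notch)) rep(FALSE, length(est$freq)) else
    est$freq >= notch[1] & est$freq < notch[2]
  band_power <- vapply(bands, function(b) {
    sel <- est$freq >= b[1] & est$freq < b[2] & !in_notch
    sum(est$psd[sel])
  }, 0)
  total <- sum(band_power)
  out <- data.frame(band = names(bands),
                    lo = vapply(bands, `[`, 0, 1L),
                    hi = vapply(bands, `[`, 0, 2L),
                    power = unname(band_power),
                    percent = unname(100 * band_power / total),
                    row.names = NULL)
  attr(out, "n_windows") <- est$n_windows
  attr(out, "notch") <- notch
  attr(out, "speed_range") <- speed_range
  class(out) <- c("band_power", "data.frame")
  out
}

#' @export
print.band_power <- function(x, ...) {
  cat("LFP band power (", attr(x, "n_windows"), " Welch windows, speeds ",
      paste(attr(x, "speed_range"), collapse = "-"), " cm/s)\n", sep = "")
  df <- as.data.frame(x)
  df$power <- signif(df$power, 4); df$percent <- round(df$percent, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Per-band Welch comparison between groups of band-power tables
#'
#' @param tables_a,tables_b Lists of `band_power` tables (one per session),
#'   at least two per group, identical band definitions.
#' @param value `"percent"` (default) or `"power"`.
#' @return Data frame with band, group means, Welch t, df and two-sided p.
#' @export
compare_bands <- function(tables_a, tables_b, value = c("percent", "power")) {
  value <- match.arg(value)
  stopifnot(length(tables_a) >= 2, length(tables_b) >= 2)
  bands <- tables_a[[1]]$band
  grab <- function(tabs) vapply(tabs, function(tb) {
    stopifnot(identical(tb$band, bands))
    tb[[value]]
  }, numeric(length(bands)))
  A <- grab(tables_a); B <- grab(tables_b)
  res <- lapply(seq_along(bands), function(i) {
    ht <- welch_ttest(A[i, ], B[i, ])
    data.frame(band = bands[i], mean_a = mean(A[i, ]), mean_b = mean(B[i, ]),
               t = ht$statistic, df = ht$df, p.value = ht$p.value)
  })
  do.call(rbind, res)
}
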