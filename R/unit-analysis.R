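#' @title Single-unit classification and firing rates
#' @description Sorted extracellular units are classified into putative
#'   excitatory neurons and putative interneurons by the width of the mean
#'   spike waveform (trough-to-peak interval, excitatory if > 300 us), and
#'   firing rates (spike count over whole-session duration) are compared
#'   between genotypes with a Welch t-test.
#' @name unit-analysis
NULL

#' Trough-to-peak width of a mean spike waveform
#'
#' Polarity is normalized so the principal extremum is a negative trough
#' (waveforms whose dominant extremum is positive are inverted). The width is
#' the interval from the principal trough to the subsequent positive peak,
#' with parabolic sub-sample interpolation at both extrema.
#'
#' @param waveform Numeric vector (>= 8 samples) of the mean spike waveform.
#' @param sample_rate Waveform sampling rate (Hz).
#' @return Width in microseconds.
#' @export
waveform_width <- function(waveform, sample_rate) {
  stopifnot(length(waveform) >= 8L, sample_rate > 0)
  w <- waveform - stats::median(waveform)
  if (max(w) > abs(min(w))) w <- -w        # enforce negative principal trough
  it <- which.min(w)
  if (it >= length(w) - 1L) {
    stop("no peak after the principal trough; waveform has no trough-to-peak structure",
         call. = FALSE)
  }
  post <- w[(it + 1L):length(w)]
  ip <- it + which.max(post)
  if (w[ip] <= w[it]) stop("monotone waveform; no trough-to-peak structure", call. = FALSE)
  refine <- function(i) {
    if (i <= 1L || i >= length(w)) return(i)
    y1 <- w[i - 1L]; y2 <- w[i]; y3 <- w[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (den == 0) return(i)
    i + 0.5 * (y1 - y3) / den
  }
  (refine(ip) - refine(it)) / sample_rate * 1e6
}

#' Classify units by waveform width
#'
#' Strict rule: width > 300 us is a putative excitatory neuron, otherwise a
#' putative interneuron (exactly 300 us falls to the interneuron side).
#'
#' @param units List of unit records; each a list with `waveform`,
#'   `wf_rate` (waveform sampling rate, Hz), and optionally `spikes`
#'   (timestamps, s), `duration` (s), `group`.
#' @param width_threshold Classification boundary in microseconds (default 300).
#' @return A `unit_class_table` data frame: unit, width_us, class, group;
#'   per-class counts in `attr(, "counts")`.
#' @export
classify_units <- function(units, width_threshold = 300) {
  widths <- vapply(units, function(u) waveform_width(u$waveform, u$wf_rate), 0)
  cls <- ifelse(widths > width_threshold, "putative_excitatory", "putative_interneuron")
  out <- data.frame(unit = seq_along(units),
                    width_us = widths,
                    class = cls,
                    group = vapply(units, function(u) u$group %||% NA_character_, ""),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(factor(cls, levels = c("putative_excitatory",
                                                      "putative_interneuron")))
  class(out) <- c("unit_class_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.unit_class_table <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("Unit classification (trough-to-peak width, > 300 us = excitatory):\n")
  cat("  putative excitatory: ", cnt[["putative_excitatory"]],
      ", putative interneurons: ", cnt[["putative_interneuron"]], "\n", sep = "")
  print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("  ... and", nrow(x) - 10, "more units\n")
  invisible(x)
}

#' Per-unit firing rates and group comparison
#'
#' Rate = spike count / whole-session duration (no speed filtering). When
#' two groups are present, rates are compared per class with a Welch t-test.
#'
#' @param units List of unit records with `spikes` (timestamps, s),
#'   `duration` (s), and optionally `group`; classification columns are taken
#'   from `classes` when given.
#' @param classes Optional `unit_class_table` from [classify_units()].
#' @return List with `rates` (data frame: unit, rate_hz, class, group),
#'   `summary` (per class x group mean, SEM, n) and `tests` (per-class Welch
#'   comparisons, if two groups).
#' @export
firing_rates <- function(units, classes = NULL) {
  durs <- vapply(units, function(u) u$duration, 0)
  if (any(durs <= 0)) stop("zero or negative session duration", call. = FALSE)
  rate <- vapply(units, function(u) length(u$spikes), 0) / durs
  df <- data.frame(unit = seq_along(units), rate_hz = rate,
                   class = if (!is.null(classes)) classes$class else "all",
                   group = vapply(units, function(u) u$group %||% NA_character_, ""),
                   stringsAsFactors = FALSE)
  summ <- NULL; tests <- NULL
  if (!all(is.na(df$group))) {
    agg <- stats::aggregate(rate_hz ~ class + group, data = df, function(v) {
      c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
    })
    summ <- do.call(data.frame, agg)
    names(summ) <- c("class", "group", "mean_hz", "sem_hz", "n")
    groups <- unique(df$group)
    if (length(groups) == 2L && !is.null(classes)) {
      tests <- lapply(unique(df$class), function(cl) {
        a <- df$rate_hz[df$class == cl & df$group == groups[1]]
        b <- df$rate_hz[df$class == cl & df$group == groups[2]]
        if (length(a) >= 2 && length(b) >= 2) {
          ht <- welch_ttest(a, b)
          data.frame(class = cl, t = ht$statistic, df = ht$df, p.value = ht$p.value)
        }
      })
      tests <- do.call(rbind, tests)
    }
  }
  list(rates = df, summary = summ, tests = tests)
}
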