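#' @title Shared statistical kernel
#' @description Thin, uniformly-shaped wrappers around the classical tests the
#'   pipeline relies on (Welch and pooled t, Mann-Whitney U, two-sample
#'   Kolmogorov-Smirnov, Benjamini-Hochberg step-up), plus the pooled
#'   per-event t-test used for miniature-IPSC metrics and a between-group
#'   ANOVA on subject-mean profiles used for LTP time courses. All location
#'   tests are two-sided and return a common `test_result` structure.
#' @name stats-util
NULL

test_result <- function(statistic, df, p, test, n1, n2, extra = list()) {
  out <- c(list(statistic = unname(statistic),
                df = if (is.null(df)) NA_real_ else unname(df),
                p.value = unname(p),
                test = test,
                n = c(n1, n2)),
           extra)
  class(out) <- "test_result"
  out
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4), sep = "")
  if (!is.na(x$df)) cat(", df = ", format(x$df, digits = 5), sep = "")
  cat(", p = ", format.pval(x$p.value, digits = 4),
      "  (n = ", x$n[1], ", ", x$n[2], ")\n", sep = "")
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unpaired Student's t-test with Welch's correction (Satterthwaite degrees of
#' freedom), the default between-genotype comparison for LFP band power and
#' unit firing rates. When both groups have zero variance and equal means the
#' statistic is reported as 0 with p = 1.
#'
#' @param a,b Numeric vectors of at least two observations each.
#' @return A `test_result` with the t statistic, Satterthwaite df and
#'   two-sided p-value.
#' @examples
#' welch_ttest(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(test_result(0, NA_real_, 1, "Welch two-sample t", length(a), length(b)))
    }
    return(test_result(sign(mean(a) - mean(b)) * Inf, NA_real_, 0,
                       "Welch two-sample t", length(a), length(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  test_result(ht$statistic, ht$parameter, ht$p.value,
              "Welch two-sample t", length(a), length(b))
}

#' Pooled-variance two-sample t-test
#'
#' Classical Student's t with pooled variance, used for voxelwise CBV group
#' contrasts and as the kernel of [pooled_event_test()].
#'
#' @inheritParams welch_ttest
#' @return A `test_result`; df = n1 + n2 - 2.
#' @export
pooled_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    return(test_result(t, length(a) + length(b) - 2, p,
                       "pooled two-sample t", length(a), length(b)))
  }
  ht <- stats::t.test(a, b, var.equal = TRUE)
  test_result(ht$statistic, ht$parameter, ht$p.value,
              "pooled two-sample t", length(a), length(b))
}

#' Pooled per-event t-test across cells
#'
#' For event-level metrics (e.g. mIPSC peak amplitudes) recorded from several
#' cells per group: a fixed number `k` of events is subsampled uniformly
#' without replacement from each cell (seeded), events are pooled within
#' group, and a pooled-variance two-sample t-test is run on the pooled
#' per-event values. With g1 and g2 cells the degrees of freedom are
#' k*(g1 + g2) - 2 (e.g. 7 + 8 cells at k = 50 gives df = 748).
#'
#' @param cells_a,cells_b Lists of numeric vectors, one vector of per-event
#'   values per cell.
#' @param k Events subsampled per cell (default 50).
#' @param seed Integer seed for the subsampling.
#' @return A `test_result` carrying the pooled samples in `$pooled`.
#' @export
pooled_event_test <- function(cells_a, cells_b, k = 50L, seed = 1L) {
  stopifnot(length(cells_a) >= 1, length(cells_b) >= 1)
  short_a <- which(vapply(cells_a, length, 1L) < k)
  short_b <- which(vapply(cells_b, length, 1L) < k)
  if (length(short_a) || length(short_b)) {
    stop("cells with fewer than k = ", k, " events: group A ",
         paste(short_a, collapse = ","), "; group B ",
         paste(short_b, collapse = ","), call. = FALSE)
  }
  pooled <- with_seed(seed, {
    pa <- unlist(lapply(cells_a, function(v) v[sample.int(length(v), k)]))
    pb <- unlist(lapply(cells_b, function(v) v[sample.int(length(v), k)]))
    list(a = pa, b = pb)
  })
  res <- pooled_ttest(pooled$a, pooled$b)
  res$test <- "pooled per-event t"
  res$pooled <- pooled
  res$k <- k
  res
}

#' Mann-Whitney U test
#'
#' Two-sided Wilcoxon rank-sum test: exact when the combined sample is small
#' (n1 + n2 <= 16) and tie-free, tie-corrected normal approximation with
#' continuity correction otherwise. All values tied across both groups gives
#' p = 1 by convention.
#'
#' @param a,b Numeric vectors of at least one observation each.
#' @return A `test_result` with the U statistic (number of (a, b) pairs with
#'   a < b, i.e. `wilcox.test`'s W for `a` first).
#' @export
mannwhitney_u <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1L) {
    return(test_result(length(a) * length(b) / 2, NA_real_, 1,
                       "Mann-Whitney U", length(a), length(b)))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 16L) && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  test_result(ht$statistic, NA_real_, ht$p.value,
              "Mann-Whitney U", length(a), length(b))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order (monotone, capped at 1).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Used for distribution-level comparisons of pooled mIPSC metrics; also
#' returns the two empirical cumulative distribution functions for
#' cumulative-probability plots.
#'
#' @inheritParams mannwhitney_u
#' @return A `test_result` with statistic D, asymptotic two-sided p, and
#'   `$ecdf_a`, `$ecdf_b` step functions.
#' @export
ks_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  ht <- suppressWarnings(stats::ks.test(a, b))
  test_result(ht$statistic, NA_real_, ht$p.value,
              "two-sample Kolmogorov-Smirnov", length(a), length(b),
              extra = list(ecdf_a = stats::ecdf(a), ecdf_b = stats::ecdf(b)))
}

#' Between-group ANOVA on subject-mean profiles
#'
#' A deliberately simple group-level summary for repeated time-course data
#' (e.g. normalized fEPSP slope curves): each subject's time series is reduced
#' to its mean over the analysis window and a one-way between-group ANOVA is
#' run on those subject means, giving F(1, n1 + n2 - 2). This is a
#' wrapper-level summary, not a full repeated-measures model.
#'
#' @param profiles_a,profiles_b Lists of numeric vectors (one per subject).
#' @return A `test_result` with the F statistic and numerator/denominator df
#'   in `$df_num`, `$df_den`.
#' @export
profile_anova <- function(profiles_a, profiles_b) {
  ma <- vapply(profiles_a, mean, 0)
  mb <- vapply(profiles_b, mean, 0)
  stopifnot(length(ma) >= 2, length(mb) >= 2)
  g <- factor(rep(c("A", "B"), c(length(ma), length(mb))))
  fit <- stats::aov(c(ma, mb) ~ g)
  s <- summary(fit)[[1]]
  test_result(s[["F value"]][1], s[["Df"]][2], s[["Pr(>F)"]][1],
              "between-group ANOVA on subject means", length(ma), length(mb),
              extra = list(df_num = s[["Df"]][1], df_den = s[["Df"]][2]))
}
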