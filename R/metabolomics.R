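#' @title Metabolomics differential abundance
#' @description Feature-table filtering (per ion mode: 600-ion-count
#'   abundance floor, top 2000 by maximum abundance), targeted annotation
#'   against a reference metabolite library (10 mDa mass and 1 min
#'   retention-time tolerances, nearest mass wins), and nonparametric
#'   differential abundance (two-sided Mann-Whitney per feature with
#'   Benjamini-Hochberg FDR control applied within each detection mode).
#' @name metabolomics
NULL

#' Filter a metabolite feature table
#'
#' Per ion detection mode: drop features whose maximum abundance across
#' samples is below `min_abund` ion counts (exactly `min_abund` is kept),
#' then keep the `top_n` features by maximum abundance.
#'
#' @param features Data frame with columns `feature_id`, `mode`
#'   (`"positive"`/`"negative"`), `mass` (Da), `rt` (min), and one numeric
#'   abundance column per sample (all remaining columns).
#' @param top_n Features kept per mode (default 2000).
#' @param min_abund Minimum maximum-abundance in ion counts (default 600).
#' @return The filtered feature table (possibly empty, with a warning).
#' @export
filter_features <- function(features, top_n = 2000L, min_abund = 600) {
  stopifnot(nrow(features) > 0)
  abund <- feature_abundances(features)
  mx <- apply(abund, 1L, max)
  keep <- mx >= min_abund
  out <- do.call(rbind, lapply(split(seq_len(nrow(features)), features$mode),
                               function(ix) {
    ix <- ix[keep[ix]]
    if (length(ix) > top_n) ix <- ix[order(mx[ix], decreasing = TRUE)[seq_len(top_n)]]
    features[sort(ix), , drop = FALSE]
  }))
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no feature survives filtering")
  out
}

# abundance matrix = all numeric sample columns
feature_abundances <- function(features) {
  meta <- c("feature_id", "mode", "mass", "rt")
  samp <- setdiff(names(features), meta)
  as.matrix(features[, samp, drop = FALSE])
}

#' Match features to a targeted metabolite library
#'
#' A feature matches a library entry of the same detection mode when the
#' absolute mass deviation is at most `mass_tol` Da and the retention-time
#' deviation at most `rt_tol` min. Among multiple candidates the smallest
#' mass deviation wins, ties broken by the smallest RT deviation.
#'
#' @param features Feature table (see [filter_features()]).
#' @param library_df Data frame with `name`, `mass`, `rt`, `mode`.
#' @param mass_tol Mass tolerance in Da (default 0.010 = 10 mDa).
#' @param rt_tol Retention-time tolerance in minutes (default 1).
#' @return Data frame: feature_id, metabolite (NA when unmatched),
#'   dmass_mda, drt_min.
#' @export
match_targeted <- function(features, library_df, mass_tol = 0.010, rt_tol = 1) {
  res <- lapply(seq_len(nrow(features)), function(i) {
    cand <- library_df[library_df$mode == features$mode[i], , drop = FALSE]
    if (nrow(cand)) {
      dm <- abs(cand$mass - features$mass[i])
      dr <- abs(cand$rt - features$rt[i])
      ok <- dm <= mass_tol & dr <= rt_tol
      if (any(ok)) {
        cand <- cand[ok, , drop = FALSE]; dm <- dm[ok]; dr <- dr[ok]
        j <- order(dm, dr)[1]
        return(data.frame(feature_id = features$feature_id[i],
                          metabolite = cand$name[j],
                          dmass_mda = dm[j] * 1000, drt_min = dr[j]))
      }
    }
    data.frame(feature_id = features$feature_id[i], metabolite = NA_character_,
               dmass_mda = NA_real_, drt_min = NA_real_)
  })
  do.call(rbind, res)
}

#' Nonparametric differential abundance between two genotype groups
#'
#' Per feature: a two-sided Mann-Whitney U test between the two groups, a
#' fold change reported as the ratio of the larger group mean to the smaller
#' (always >= 1) with the regulation direction in group B, and
#' Benjamini-Hochberg q-values computed within each detection mode (set
#' `pool_modes = TRUE` for one family). Features constant across all samples
#' get p = 1 and are flagged. Reporting conventions: untargeted hit lists
#' use q < `fdr`; targeted lists use raw p < `fdr`.
#'
#' @param features Feature table.
#' @param samples Data frame describing the sample columns: `sample`
#'   (column name), `genotype`.
#' @param group_a,group_b Genotype labels compared (defaults `"E3/3"` vs
#'   `"E4/4"`; direction is reported for `group_b`).
#' @param pool_modes Apply BH across both modes jointly (default `FALSE`).
#' @param fdr Significance level for the hit lists (default 0.05).
#' @return A `de_result` data frame: feature_id, mode, regulation
#'   (up/down in group B), fold_change, p.value, q.value, constant;
#'   attributes `untargeted_hits` and `targeted_hits` hold the feature ids
#'   passing q < fdr and p < fdr respectively.
#' @export
differential_abundance <- function(features, samples,
                                   group_a = "E3/3", group_b = "E4/4",
                                   pool_modes = FALSE, fdr = 0.05) {
  cols_a <- samples$sample[samples$genotype == group_a]
  cols_b <- samples$sample[samples$genotype == group_b]
  if (length(cols_a) < 3L || length(cols_b) < 3L) {
    stop("need at least 3 samples per group", call. = FALSE)
  }
  A <- as.matrix(features[, cols_a, drop = FALSE])
  B <- as.matrix(features[, cols_b, drop = FALSE])
  n <- nrow(features)
  p <- numeric(n); fc <- numeric(n); reg <- character(n); const <- logical(n)
  for (i in seq_len(n)) {
    a <- A[i, ]; b <- B[i, ]
    if (length(unique(c(a, b))) == 1L) {
      p[i] <- 1; fc[i] <- 1; reg[i] <- "none"; const[i] <- TRUE
      next
    }
    p[i] <- mannwhitney_u(a, b)$p.value
    ma <- mean(a); mb <- mean(b)
    if (mb >= ma) {
      fc[i] <- if (ma > 0) mb / ma else Inf
      reg[i] <- "up"
    } else {
      fc[i] <- if (mb > 0) ma / mb else Inf
      reg[i] <- "down"
    }
  }
  q <- numeric(n)
  if (pool_modes) {
    q <- bh_fdr(p)
  } else {
    for (m in unique(features$mode)) {
      ix <- features$mode == m
      q[ix] <- bh_fdr(p[ix])
    }
  }
  out <- data.frame(feature_id = features$feature_id, mode = features$mode,
                    regulation = reg, fold_change = fc,
                    p.value = p, q.value = q, constant = const,
                    stringsAsFactors = FALSE)
  attr(out, "untargeted_hits") <- out$feature_id[out$q.value < fdr & !out$constant]
  attr(out, "targeted_hits") <- out$feature_id[out$p.value < fdr & !out$constant]
  attr(out, "groups") <- c(group_a, group_b)
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  g <- attr(x, "groups")
  cat("Differential abundance, ", g[2], " vs ", g[1], ": ", nrow(x),
      " features\n  q < 0.05 (untargeted reporting): ",
      length(attr(x, "untargeted_hits")),
      "; raw p < 0.05 (targeted reporting): ",
      length(attr(x, "targeted_hits")), "\n", sep = "")
  top <- as.data.frame(x)[order(x$p.value), ][seq_len(min(8L, nrow(x))), ]
  top$fold_change <- signif(top$fold_change, 3)
  top$p.value <- signif(top$p.value, 3); top$q.value <- signif(top$q.value, 3)
  print(top, row.names = FALSE)
  invisible(x)
}
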