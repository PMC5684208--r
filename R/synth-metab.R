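#' @title Synthetic metabolomics feature tables
#' @description Generates a feature x sample abundance table mimicking
#'   recursive feature-extraction output: log-normal abundances across three
#'   genotype groups (8 E3/3, 9 E3/4, 7 E4/4 by default), a planted set of
#'   affected features scaled by known fold changes in the E4/4 group, a
#'   matching reference library with masses and retention times (some
#'   entries deliberately offset beyond the matching tolerance), and a few
#'   deliberately low-abundance features that the 600-ion-count filter must
#'   remove.
#' @name synth-metab
NULL

#' Generate a synthetic feature table, reference library and ground truth
#'
#' @param n_features Number of (normal-abundance) features (default 400).
#' @param n_per_group Named samples per genotype (default
#'   `c("E3/3" = 8, "E3/4" = 9, "E4/4" = 7)`).
#' @param affected Integer indices of affected features (default none).
#' @param fold_changes Fold change per affected feature (> 0; values < 1
#'   mean down-regulation in E4/4). Length 1 is recycled.
#' @param sdlog Log-normal within-group noise (default 0.25).
#' @param n_low Extra features with maximum abundance below 600 counts
#'   (default 10).
#' @param n_library Library entries tied to features within tolerance
#'   (default `min(n_features, 100)`).
#' @param n_offset Library entries tied to features but mass-shifted 15-30
#'   mDa outside tolerance (default 10).
#' @param seed Integer seed.
#' @return List with `features` (data frame: feature_id, mode, mass, rt,
#'   sample columns), `samples` (sample, genotype), `library` (name, mass,
#'   rt, mode), and `ground_truth` (affected ids, fold changes, matchable
#'   and offset library names, seed).
#' @export
gen_feature_table <- function(n_features = 400L,
                              n_per_group = c("E3/3" = 8L, "E3/4" = 9L, "E4/4" = 7L),
                              affected = integer(0), fold_changes = numeric(0),
                              sdlog = 0.25, n_low = 10L,
                              n_library = min(n_features, 100L),
                              n_offset = 10L, seed = 1L) {
  stopifnot(all(n_per_group >= 1L))
  if (length(affected)) {
    if (any(affected < 1L | affected > n_features)) {
      stop("affected set must be a subset of the features", call. = FALSE)
    }
    fold_changes <- rep_len(fold_changes, length(affected))
    if (any(fold_changes <= 0)) stop("fold changes must be positive", call. = FALSE)
  }
  with_seed(seed, {
    ntot <- n_features + n_low
    genotype <- rep(names(n_per_group), n_per_group)
    sample_ids <- paste0("S", sprintf("%02d", seq_along(genotype)))
    mode <- sample(c("positive", "negative"), ntot, replace = TRUE)
    mass <- stats::runif(ntot, 50, 1000)
    rt <- stats::runif(ntot, 0.5, 15)
    meanlog <- stats::runif(n_features, log(2000), log(50000))
    abund <- matrix(0, ntot, length(genotype))
    for (j in seq_along(genotype)) {
      abund[seq_len(n_features), j] <- exp(stats::rnorm(n_features, meanlog, sdlog))
    }
    if (length(affected)) {
      e44 <- genotype == "E4/4"
      abund[affected, e44] <- abund[affected, e44] * fold_changes
    }
    if (n_low > 0L) {
      abund[(n_features + 1L):ntot, ] <-
        matrix(stats::runif(n_low * length(genotype), 50, 500), n_low)
    }
    feature_id <- paste0("F", sprintf("%04d", seq_len(ntot)))
    features <- data.frame(feature_id = feature_id, mode = mode,
                           mass = mass, rt = rt, stringsAsFactors = FALSE)
    features[sample_ids] <- as.data.frame(abund)

    n_library <- min(n_library, n_features)
    n_offset <- min(n_offset, n_features - n_library)
    lib_src <- sort(sample.int(n_features, n_library))
    pool <- setdiff(seq_len(n_features), lib_src)
    off_src <- sort(pool[sample.int(length(pool), n_offset)])
    library_df <- data.frame(name = paste0("Met_", lib_src),
                             mass = mass[lib_src] + stats::runif(n_library, -0.004, 0.004),
                             rt = rt[lib_src] + stats::runif(n_library, -0.4, 0.4),
                             mode = mode[lib_src], stringsAsFactors = FALSE)
    if (n_offset > 0L) {
      library_df <- rbind(library_df,
        data.frame(name = paste0("Off_", off_src),
                   mass = mass[off_src] +
                     sample(c(-1, 1), n_offset, TRUE) * stats::runif(n_offset, 0.015, 0.030),
                   rt = rt[off_src] + stats::runif(n_offset, -0.4, 0.4),
                   mode = mode[off_src], stringsAsFactors = FALSE))
    }
    list(features = features,
         samples = data.frame(sample = sample_ids, genotype = genotype,
                              stringsAsFactors = FALSE),
         library = library_df,
         ground_truth = list(modality = "metabolomics",
                             affected_ids = feature_id[affected],
                             fold_changes = fold_changes,
                             low_ids = if (n_low) feature_id[(n_features + 1L):ntot]
                                       else character(0),
                             matchable = stats::setNames(paste0("Met_", lib_src),
                                                         feature_id[lib_src]),
                             offset_names = paste0("Off_", off_src),
                             sdlog = sdlog, seed = seed))
  })
}
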