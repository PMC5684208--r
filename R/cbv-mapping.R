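#' @title Relative cerebral blood volume mapping
#' @description Steady-state contrast-enhanced CBV mapping: the relative CBV
#'   of a voxel is proportional to the transverse relaxation change
#'   dR2 = ln(Spre/Spost)/TE, where Spre and Spost are the signals before and
#'   after the contrast agent reaches steady state and TE is the effective
#'   echo time. Maps are normalized to the mean dR2 in a reference-vessel
#'   (internal jugular vein) ROI, contrasted between groups with a voxelwise
#'   Student's t-test, and corrected for multiple comparisons at the cluster
#'   level with a Monte-Carlo cluster-extent simulation.
#' @name cbv-mapping
NULL

#' Compute a normalized relative CBV map
#'
#' Computes dR2 = ln(Spre/Spost)/TE voxelwise and divides by the mean dR2
#' over a reference-vessel ROI so that maps are comparable across subjects.
#'
#' @param spre,spost 3-D arrays of pre- and post-contrast signal (same grid,
#'   strictly positive on the analysis mask).
#' @param te Effective echo time (ms).
#' @param vein_roi Logical/0-1 array marking the reference-vessel ROI;
#'   `NULL` skips normalization.
#' @param brain_mask Optional logical array restricting the computation
#'   (defaults to all voxels).
#' @return A `cbv_map`: list with `values` (3-D array, NA outside the mask),
#'   `normalized`, `te`, `vein_mean`.
#' @export
compute_cbv_map <- function(spre, spost, te, vein_roi = NULL, brain_mask = NULL) {
  stopifnot(is.array(spre), is.array(spost), identical(dim(spre), dim(spost)),
            length(dim(spre)) == 3L, te > 0)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(spre))
  stopifnot(identical(dim(brain_mask), dim(spre)))
  brain_mask <- brain_mask & !is.na(spre) & !is.na(spost)
  bad <- sum(brain_mask & (spre <= 0 | spost <= 0))
  if (bad > 0) {
    stop("non-positive signal at ", bad, " masked voxel(s); cannot take log ratio",
         call. = FALSE)
  }
  vals <- array(NA_real_, dim(spre))
  vals[brain_mask] <- log(spre[brain_mask] / spost[brain_mask]) / te
  vein_mean <- NA_real_
  normalized <- FALSE
  if (!is.null(vein_roi)) {
    vein_roi <- as.logical(vein_roi) & brain_mask
    if (!any(vein_roi)) stop("vein ROI is empty", call. = FALSE)
    vein_mean <- mean(vals[vein_roi])
    if (vein_mean <= 0) stop("vein ROI mean dR2 is not positive", call. = FALSE)
    vals <- vals / vein_mean
    normalized <- TRUE
  }
  structure(list(values = vals, normalized = normalized, te = te,
                 vein_mean = vein_mean),
            class = "cbv_map")
}

#' @export
print.cbv_map <- function(x, ...) {
  cat("CBV map ", paste(dim(x$values), collapse = " x "),
      if (x$normalized) " (vein-normalized)" else " (unnormalized)",
      "; TE = ", x$te, " ms\n", sep = "")
  v <- x$values[!is.na(x$values)]
  cat("  masked voxels: ", length(v), ", mean = ", signif(mean(v), 4),
      ", sd = ", signif(stats::sd(v), 4), "\n", sep = "")
  invisible(x)
}

#' Voxelwise two-sample t map between groups of CBV maps
#'
#' @param maps_a,maps_b Lists of `cbv_map` objects (or 3-D arrays) per group;
#'   at least two per group, identical grids.
#' @param welch Use Welch's correction instead of pooled variance
#'   (default `FALSE`, matching a plain Student's t contrast).
#' @return A `stat_map`: list with `t` (3-D array), `df`, `n`, `welch`.
#'   Voxels with zero variance in both groups get t = 0 and are flagged in
#'   `zero_var` (excluded from clustering). Swapping the groups negates t.
#' @export
group_stat_map <- function(maps_a, maps_b, welch = FALSE) {
  get_vals <- function(m) if (inherits(m, "cbv_map")) m$values else m
  va <- lapply(maps_a, get_vals)
  vb <- lapply(maps_b, get_vals)
  stopifnot(length(va) >= 2, length(vb) >= 2)
  d <- dim(va[[1]])
  ok <- vapply(c(va, vb), function(x) identical(dim(x), d), TRUE)
  if (!all(ok)) stop("all maps must share one grid", call. = FALSE)
  A <- vapply(va, identity, va[[1]])        # d x n1 array
  B <- vapply(vb, identity, vb[[1]])
  n1 <- length(va); n2 <- length(vb)
  dim(A) <- c(prod(d), n1); dim(B) <- c(prod(d), n2)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    tval <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(tval))
  }
  zero_var <- (v1 + v2) == 0
  tval[zero_var] <- 0
  df[zero_var] <- n1 + n2 - 2
  tarr <- array(tval, d); dfarr <- array(df, d)
  # residual maps (per-subject deviations from group means) for smoothness
  resid <- c(lapply(seq_len(n1), function(i) array(A[, i] - m1, d)),
             lapply(seq_len(n2), function(i) array(B[, i] - m2, d)))
  structure(list(t = tarr, df = dfarr, n = c(n1, n2), welch = welch,
                 zero_var = array(zero_var, d), residuals = resid),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("Voxelwise ", if (x$welch) "Welch" else "pooled", " t map ",
      paste(dim(x$t), collapse = " x "), "; groups n = ", x$n[1], "/", x$n[2],
      "\n  max |t| = ", signif(max(abs(x$t), na.rm = TRUE), 4), "\n", sep = "")
  invisible(x)
}

# Two-sided |t| height threshold for a stat map at uncorrected p.
height_threshold <- function(stat, height_p) {
  stats::qt(1 - height_p / 2, df = stat$n[1] + stat$n[2] - 2)
}

#' Cluster-extent multiple-comparisons correction
#'
#' Thresholds the t map at a two-sided uncorrected height p, labels
#' suprathreshold voxels into 6-connected 3-D clusters, and determines the
#' critical cluster extent by Monte-Carlo simulation: null Gaussian fields
#' with smoothness matched to the residual maps (neighbour-autocorrelation
#' estimate) are thresholded at the same two-sided p, and the critical size
#' is the smallest k for which the proportion of simulations whose largest
#' cluster reaches k is at most `alpha`. A label-permutation null
#' (`null = "permutation"`) is available as an alternative.
#'
#' @param stat A `stat_map` from [group_stat_map()].
#' @param height_p Two-sided uncorrected voxel threshold (default 0.01).
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param alpha Corrected cluster-level alpha (default 0.05).
#' @param seed Seed for the simulation.
#' @param null `"gaussian"` (smoothness-matched random fields) or
#'   `"permutation"` (group-label permutation of the subject maps).
#' @param maps_a,maps_b Required for `null = "permutation"`: the original maps.
#' @return A `cluster_set`: surviving clusters (voxel indices, sizes, peak t),
#'   critical size, the null distribution of maximum cluster sizes, and the
#'   connectivity used.
#' @export
cluster_correct <- function(stat, height_p = 0.01, n_iter = 10000L,
                            alpha = 0.05, seed = 1L, null = c("gaussian", "permutation"),
                            maps_a = NULL, maps_b = NULL) {
  stopifnot(inherits(stat, "stat_map"), height_p > 0, height_p < 1, n_iter >= 100L)
  null <- match.arg(null)
  d <- dim(stat$t)
  tcrit <- height_threshold(stat, height_p)
  usable <- !stat$zero_var & !is.na(stat$t)
  if (!any(usable) || stats::sd(stat$t[usable]) == 0) {
    warning("degenerate (constant) statistic map; returning no clusters")
    return(structure(list(clusters = list(), sizes = integer(0),
                          critical_size = NA_integer_, alpha = alpha,
                          height_p = height_p, connectivity = "6-connected",
                          null_max_sizes = integer(0)),
                     class = "cluster_set"))
  }
  supra <- which(usable & abs(stat$t) >= tcrit)
  clusters <- label_clusters_6conn(supra, d)

  max_sizes <- integer(n_iter)
  if (null == "gaussian") {
    # simulate the group t-field under the null: per iteration, draw one
    # smoothness-matched Gaussian field per subject and form the same
    # two-sample t statistic thresholded at the same |t| height (a z-field
    # shortcut is conservative at low df because t-fields are rougher)
    fwhm <- rho_to_fwhm(field_neighbor_rho(stat$residuals))
    n1 <- stat$n[1]; n2 <- stat$n[2]
    nv <- prod(d)
    smooth_field <- if (any(fwhm > 0)) {
      kf <- gauss_kernel_fft(d, fwhm)
      function() Re(stats::fft(stats::fft(array(stats::rnorm(nv), d)) * kf,
                               inverse = TRUE)) / nv
    } else {
      function() stats::rnorm(nv)
    }
    max_sizes <- with_seed(seed, {
      vapply(seq_len(n_iter), function(i) {
        A <- vapply(seq_len(n1), function(j) as.numeric(smooth_field()),
                    numeric(nv))
        B <- vapply(seq_len(n2), function(j) as.numeric(smooth_field()),
                    numeric(nv))
        m1 <- rowMeans(A); m2 <- rowMeans(B)
        v1 <- rowSums((A - m1)^2) / (n1 - 1)
        v2 <- rowSums((B - m2)^2) / (n2 - 1)
        tv <- if (stat$welch) {
          (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
        } else {
          sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
          (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
        }
        idx <- which(abs(tv) >= tcrit)
        if (length(idx) == 0L) return(0L)
        max(lengths(label_clusters_6conn(idx, d)))
      }, 0L)
    })
  } else {
    if (is.null(maps_a) || is.null(maps_b)) {
      stop("permutation null requires maps_a and maps_b", call. = FALSE)
    }
    get_vals <- function(m) if (inherits(m, "cbv_map")) m$values else m
    all_maps <- c(lapply(maps_a, get_vals), lapply(maps_b, get_vals))
    n1 <- length(maps_a); ntot <- length(all_maps)
    max_sizes <- with_seed(seed, {
      vapply(seq_len(n_iter), function(i) {
        perm <- sample.int(ntot)
        sm <- group_stat_map(all_maps[perm[seq_len(n1)]],
                             all_maps[perm[(n1 + 1L):ntot]], welch = stat$welch)
        idx <- which(!sm$zero_var & abs(sm$t) >= tcrit)
        if (length(idx) == 0L) return(0L)
        max(lengths(label_clusters_6conn(idx, d)))
      }, 0L)
    })
  }
  # smallest k with P(max cluster >= k) <= alpha
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  sizes <- lengths(clusters)
  keep <- sizes >= k
  structure(list(clusters = clusters[keep], sizes = sizes[keep],
                 peak_t = vapply(clusters[keep], function(ix) {
                   tv <- stat$t[ix]; tv[which.max(abs(tv))]
                 }, 0),
                 all_cluster_sizes = sizes,
                 critical_size = k, alpha = alpha, height_p = height_p,
                 connectivity = "6-connected", null_max_sizes = max_sizes),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Cluster-corrected results (", x$connectivity, ", height p = ",
      x$height_p, ", alpha = ", x$alpha, ")\n", sep = "")
  cat("  critical cluster size: ", x$critical_size, " voxels\n", sep = "")
  if (length(x$sizes) == 0L) {
    cat("  no surviving clusters\n")
  } else {
    for (i in seq_along(x$sizes)) {
      cat(sprintf("  cluster %d: %d voxels, peak t = %.3f\n",
                  i, x$sizes[i], x$peak_t[i]))
    }
  }
  invisible(x)
}

#' Summary statistics of a CBV map over an ROI
#'
#' @param map A `cbv_map` or 3-D array.
#' @param roi Logical/0-1 array on the same grid.
#' @return List with `mean`, `sd`, `n_voxels`.
#' @export
roi_summary <- function(map, roi) {
  vals <- if (inherits(map, "cbv_map")) map$values else map
  stopifnot(identical(dim(vals), dim(roi)))
  roi <- as.logical(roi) & !is.na(vals)
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  v <- vals[roi]
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       n_voxels = length(v))
}
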