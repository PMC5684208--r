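#' @title Synthetic contrast-enhanced imaging volumes
#' @description Generates pre/post-contrast volume pairs for two genotype
#'   groups with a planted regional dR2 excess. The per-subject true dR2
#'   field is a baseline level plus (optionally spatially smoothed) Gaussian
#'   noise, plus the planted effect inside the effect-region mask for
#'   group B; signals are then constructed as Spre = s0 and
#'   Spost = s0 * exp(-dR2 * TE) so the mapping stage recovers the field
#'   exactly up to the planted noise. A reference-vessel ROI with unit mean
#'   dR2 is carved out so vein normalization is available.
#' @name synth-cbv
NULL

#' Cuboid mask helper
#'
#' @param dims Grid dimensions (length 3).
#' @param center Voxel coordinates of the cuboid center.
#' @param half Half-widths per axis (length 1 or 3).
#' @return Logical 3-D array.
#' @export
cube_mask <- function(dims, center, half) {
  half <- rep_len(half, 3L)
  m <- array(FALSE, dims)
  lo <- pmax(1L, round(center - half)); hi <- pmin(dims, round(center + half))
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  m
}

#' Generate synthetic pre/post-contrast volume pairs with a planted effect
#'
#' @param n_per_group Subjects per group (default `c(7, 8)`).
#' @param dims Grid dimensions (default `c(16, 16, 10)`).
#' @param effect_mask Logical array marking the affected region; default: a
#'   centered cuboid of half-width 2.
#' @param effect_size Planted dR2 excess in group B inside the mask
#'   (>= 0, default 0.2).
#' @param baseline Baseline true dR2 (default 1).
#' @param noise_sd SD of the per-subject dR2 noise field (default 0.1).
#' @param smooth_fwhm Spatial smoothing of the noise field in voxels
#'   (default 0 = white noise).
#' @param s0 Pre-contrast signal level (> 0, default 1000).
#' @param te Effective echo time (ms, default 1).
#' @param seed Integer seed.
#' @return List with `pairs` (per subject: `spre`, `spost`, `group`),
#'   `vein_roi`, `effect_mask`, `te`, and `ground_truth` (planted effect,
#'   baseline, noise model, seed).
#' @export
gen_cbv_volumes <- function(n_per_group = c(7L, 8L), dims = c(16L, 16L, 10L),
                            effect_mask = NULL, effect_size = 0.2,
                            baseline = 1, noise_sd = 0.1, smooth_fwhm = 0,
                            s0 = 1000, te = 1, seed = 1L) {
  stopifnot(length(n_per_group) == 2L, all(n_per_group >= 1L),
            effect_size >= 0, te > 0)
  if (s0 <= 0 || baseline <= 0) {
    stop("baseline signal and dR2 level must be positive", call. = FALSE)
  }
  # reference vessel: small block in the far corner
  vein <- cube_mask(dims, center = dims - c(1, 1, 1), half = c(1, 1, 0))
  if (is.null(effect_mask)) {
    effect_mask <- cube_mask(dims, center = dims / 2, half = 2) & !vein
  }
  if (!identical(dim(effect_mask), as.integer(dims)) &&
      !identical(dim(effect_mask), dims)) {
    stop("effect mask does not match the grid", call. = FALSE)
  }
  if (effect_size > 0 && any(vein & effect_mask)) {
    stop("effect mask overlaps the vein ROI", call. = FALSE)
  }
  groups <- rep(c("A", "B"), n_per_group)
  pairs <- with_seed(seed, lapply(groups, function(g) {
    noise <- array(stats::rnorm(prod(dims), sd = noise_sd), dims)
    if (smooth_fwhm > 0) {
      noise <- gauss_smooth3d(noise, smooth_fwhm)
      noise <- noise / stats::sd(noise) * noise_sd
    }
    r <- baseline + noise
    if (g == "B" && effect_size > 0) r[effect_mask] <- r[effect_mask] + effect_size
    r[vein] <- 1 + stats::rnorm(sum(vein), sd = noise_sd / 10)
    list(spre = array(s0, dims), spost = array(s0, dims) * exp(-r * te), group = g)
  }))
  list(pairs = pairs, vein_roi = vein, effect_mask = effect_mask, te = te,
       ground_truth = list(modality = "cbv", effect_size = effect_size,
                           baseline = baseline, noise_sd = noise_sd,
                           smooth_fwhm = smooth_fwhm, n_per_group = n_per_group,
                           seed = seed))
}
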