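# Small shared fixtures, built in code at test time.

# A session small enough for fast spectral tests but long enough for stable
# percent-power estimates.
small_session <- function(seed = 1L, duration = 120, ...) {
  gen_session(duration = duration, seed = seed, ...)
}

# Percent power recovered from a generated session through the full
# tracking -> speed -> band-power chain.
session_percents <- function(s) {
  tr <- clean_tracking(s$tracking)
  sp <- compute_speed(tr)
  bp <- band_percent_power(s$lfp, s$lfp_rate, sp)
  stats::setNames(bp$percent, bp$band)
}

# CBV maps for every subject of a generated volume set.
cbv_maps_by_group <- function(g, normalize = TRUE) {
  maps <- lapply(g$pairs, function(p) {
    compute_cbv_map(p$spre, p$spost, g$te,
                    vein_roi = if (normalize) g$vein_roi else NULL)
  })
  grp <- vapply(g$pairs, function(p) p$group, "")
  list(A = maps[grp == "A"], B = maps[grp == "B"])
}

# Match detected event times against planted ones within a tolerance (s);
# returns the fraction of planted events recovered.
recall_fraction <- function(planted_s, detected_s, tol_s) {
  if (length(planted_s) == 0L) return(NA_real_)
  hit <- vapply(planted_s, function(t0) any(abs(detected_s - t0) <= tol_s), TRUE)
  mean(hit)
}
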