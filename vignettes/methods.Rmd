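---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models behind each analysis stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generators do and do
not emulate, and the numerical decisions taken where the underlying
procedures leave room.

## CBV mapping

Steady-state contrast-enhanced imaging makes relative cerebral blood
volume proportional to the change in transverse relaxation rate,

$$\Delta R2 = \frac{\ln(S_\mathrm{pre}/S_\mathrm{post})}{TE},$$

where $S_\mathrm{pre}$ and $S_\mathrm{post}$ are voxel signals before and
after the contrast agent reaches steady state and $TE$ is the effective
echo time. Because only the ratio enters, the map is invariant under any
common positive rescaling of the two signals. Maps are divided by the mean
$\Delta R2$ of a reference-vessel (internal jugular vein) ROI, which
represents ~100% blood volume, making values comparable across subjects.

Group contrasts are plain voxelwise two-sample Student's t-tests (pooled
variance by default; Welch behind a flag). Voxels with zero variance in
both groups are set to $t = 0$ and excluded from clustering, avoiding
infinities. The inference model is a two-sample contrast with no
covariates; factorial designs with nuisance regressors are out of scope.

**Cluster-extent correction.** The t map is thresholded at a two-sided
uncorrected height $p$ (default 0.01 — a conventional cluster-forming
threshold; exposed as a parameter), suprathreshold voxels are grouped into
6-connected (face-adjacent) 3-D clusters, and the critical extent is
calibrated by Monte-Carlo simulation (default 10,000 iterations): the
critical size is the smallest $k$ such that the proportion of null
simulations whose largest cluster reaches $k$ is at most $\alpha$ (default
0.05). Two null models are provided:

* `"gaussian"` (default): Gaussian random fields whose smoothness is
  matched to the residual maps. Smoothness is estimated from the pooled
  lag-1 spatial autocorrelation of the residuals along each axis and
  converted to the FWHM of the white-noise-smoothing kernel that reproduces
  it ($\rho = e^{-1/(4\sigma_k^2)}$ for a Gaussian kernel of SD
  $\sigma_k$ voxels). Crucially, the null simulates the *group t-field*:
  one smoothness-matched field per subject, combined with the same t
  statistic and thresholded at the same $|t|$ height. A single-field
  z-approximation is measurably conservative at the small group sizes used
  here, because t-fields are rougher than their underlying Gaussian fields.
* `"permutation"`: group labels of the observed subject maps are permuted.
  Slightly slower per iteration, assumption-free under exchangeability.

Smoothing uses FFT-based separable Gaussian convolution with periodic
boundaries — appropriate for null-field synthesis, where only cluster-size
statistics matter.

## Tracking and LFP band power

Tracking (50 Hz nominal) is cleaned exactly in the order artifact deletion
→ interpolation → smoothing: samples implying speeds above 100 cm/s
relative to the previous surviving sample are deleted; interior gaps
shorter than 1 s are linearly interpolated while longer gaps stay missing;
and each contiguous valid run is smoothed with a centered 21-sample boxcar
(a symmetric window that shrinks near run edges, so runs are never
contaminated across gaps). Speed is the Euclidean displacement between
consecutive valid samples over elapsed time.

LFP (250 Hz) samples inherit the speed of the nearest tracking sample, and
only contiguous epochs with speeds inside 5–20 cm/s (and at least 1 s
long) are analyzed — locomotion at these speeds is the behavioural state
in which entorhinal oscillations are conventionally compared. Epochs are
notch-filtered (zero-phase 4th-order Butterworth band-stop, 55–65 Hz)
against mains noise, and the PSD is estimated by Welch's method: 2 s Hann
windows with 50% overlap *within* each epoch, periodograms averaged across
epochs. Epochs are deliberately not concatenated across discontinuities,
which would create spurious broadband edge power. Epochs between 1 and 2 s
are Hann-windowed whole and zero-padded onto the common frequency grid.

Band edges are not canonical and are exposed as a parameter; the defaults
(delta 1–4, theta 4–12, beta 12–30, low gamma 30–55, high gamma 65–120 Hz)
follow rodent entorhinal-cortex convention, with the 55–65 Hz notch
separating the gamma bands and the high-gamma edge capped at 120 Hz to
stay inside the 125 Hz Nyquist limit. The notch band is excised from both
band and total power, so reported percentages always sum to 100 over the
analyzed range. Percent power is computed per session and sessions are the
units of the group comparison (per-band Welch t-tests); pooling epochs
across sessions before normalization is a defensible alternative the
interface does not currently take.

## Unit classification and firing rates

"Waveform width" is implemented as the trough-to-peak interval of the mean
spike waveform — the standard extracellular measure for separating
putative excitatory cells from interneurons. Polarity is normalized so the
principal extremum is a negative trough, and both extrema are refined by
parabolic (three-point) interpolation for sub-sample precision, which makes
the measure stable under resampling. The classification rule is strict:
width > 300 µs ⇒ putative excitatory; exactly 300 µs falls to the
interneuron side, because the excitatory criterion is a strict inequality.

Firing rate is spike count over the whole-session duration. No speed
filter is applied to spikes — the locomotion filter belongs to the LFP
analysis, not to rate estimation. Group comparisons use Welch's t-test per
class.

## In vitro events

**Noise SD.** The threshold rules are stated in units of baseline noise
SD, but the estimation method is a free choice; the package uses the
median absolute deviation scaled by 1.4826 over a baseline window, which
stays within a few percent of the true SD even when sparse large events
contaminate the window.

**sEFPs.** An event is a contiguous excursion beyond ±3 SD lasting more
than 20 ms, with onset/offset at the threshold crossings. Excursions
separated by less than 10 ms are merged first (a config-exposed guard
against noise splitting one event in two). Because all thresholds are in
SD units, detection is invariant under amplitude rescaling of the trace.

**fEPSP slope and LTP.** The stimulus artifact is blanked (default 2 ms),
the initial deflection is identified as the dominant extremum with
auto-detected polarity, and the slope is a least-squares line over the
samples between the 10% and 90% amplitude crossings of the rising phase
(crossings located by linear interpolation; if fewer than three samples
lie between them, the chord through the crossings is used). LTP series are
normalized to the mean slope of a ≥15 min baseline and summarized as the
mean normalized slope over 40–60 min post-induction; group comparison
combines a between-group ANOVA on subject-mean profiles with a Welch
t-test on the window means. The profile ANOVA is a deliberately simple
subject-level summary, not a full repeated-measures model with sphericity
handling — equivalence to any particular mixed-model formulation is not
claimed.

**Miniature IPSCs.** Detection is the sliding optimal-scaling template
scheme: at every offset the template is fit to the trace by least squares
with free scale $a$ and offset $b$, and the detection criterion is
$a/\mathrm{SE}(a)$. An event is accepted when the criterion reaches 3.5
*and* the fitted peak exceeds 3× the noise SD — the joint rule is what
keeps the false-positive rate negligible, since on pure noise the
criterion alone crosses 3.5 occasionally but the amplitude condition is
then essentially never met. The default template has a 0.5 ms rise, 9 ms
decay and 30 ms length; mIPSCs are treated as inward (the trace is
rectified internally, amplitudes reported positive). Decay constants come
from a single-exponential fit starting 2× the rise constant after the peak
(letting the rise term die away), seeded by a log-linear fit and refined
by nonlinear least squares; fits are truncated at the next detected event,
and values that cannot be resolved inside the fitted window (τ beyond 10×
the template decay) are reported as NA rather than as numbers the data do
not support. Instantaneous frequency is the reciprocal interval to the
previous event; each cell's first event has none and is excluded.

Pooled metrics subsample exactly 50 events per cell with an explicit seed
recorded in the output, pool within group, and compare groups with a
pooled-variance per-event t-test — with $g_1$ and $g_2$ cells the degrees
of freedom are $50(g_1+g_2)-2$ (748 for 7 + 8 cells), which is what makes
pooled variance, not Welch, the matching choice. A two-sample KS test with
cumulative-probability curves is attached for distribution-level
comparisons; the pooled t is the default because mean-level differences
are the primary claim. Pooling events across cells treats events, not
cells, as the unit of inference and understates cell-level variability;
that is a property of the procedure itself, inherited deliberately.

**ΔF/F.** $\Delta F/F = 100\,(F - F_0)/(F_0 - B)$, with $B$ the pointwise
mean of four background-ROI traces when ROIs are supplied. $F_0 - B \le 0$
anywhere is an error, not a warning, since the normalization is undefined.

## Metabolomics

Filtering mirrors recursive feature extraction: per ion mode, features
whose maximum abundance is below 600 ion counts are dropped (exactly 600
is kept — the floor is a minimum), and the top 2000 by maximum abundance
survive. The filter is idempotent. Targeted annotation matches a feature
to a same-mode library entry when |Δmass| ≤ 10 mDa and |ΔRT| ≤ 1 min;
among multiple candidates the smallest mass deviation wins, ties broken by
RT deviation.

Differential abundance is a two-sided Mann-Whitney test per feature (exact
for small tie-free samples, tie-corrected normal approximation otherwise),
with fold change defined — since a definition must be chosen — as the
ratio of the larger group arithmetic mean to the smaller, reported ≥ 1
with an up/down regulation flag for the E4/4 group. BH q-values are
computed within each detection mode by default (modes are separate
acquisition families; a flag pools them). The conventional reporting split
is preserved: untargeted hit lists at q < 0.05, targeted lists at raw
p < 0.05. The default contrast is E4/4 vs E3/3, with heterozygous E3/4
samples carried in the table but excluded from it. Abundances are assumed
already normalized (e.g. to protein content) upstream; no re-normalization
is applied.

## Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical structure* the analyses assume,
with defaults set to the reported experimental conditions where those are stated:
two-genotype group structure (7 + 8 imaging subjects; 8/9/7 metabolomics
samples; 7 + 8 patched cells), a regional ΔR2 excess (default 0.2) against
additive Gaussian (optionally spatially smoothed) noise, piecewise-constant
speed profiles drawn from a stated level set so in-range epochs are known
exactly, LFP as a sum of band-limited Gaussian noise components with
planted power fractions, homogeneous Poisson spike trains at stated rates
(2.73 / 1.70 Hz) with wide (450 µs) or narrow (150 µs) waveform templates,
flat-topped sEFP pulses and difference-of-exponentials minis at stated
amplitudes (26.09 / 21.6 pA) and decay constants (~9.5 ms), LTP series
with plateaus at 140% / 190% of baseline, and log-normal metabolite
abundances with planted fold changes. Where no value is reported, a
single realistic choice was fixed once: e.g. 0.25 log-normal within-group
SD for metabolites, 3 pA mini noise SD, 5 Hz mini rate, a 3 pA/5 pA-class
per-event amplitude SD of 5 pA for trace generation (the event-level SDs
implied by the reported SEMs are used directly when simulating pooled
amplitude *samples* rather than traces). Cell-level and event-level mini
variability are exposed as separate parameters rather than fixed to any
particular split, since no within-group variance decomposition is stated.

Not emulated: biophysical neuron or MR physics, 1/f LFP background,
bursting or refractory spike statistics, chromatogram/raw-spectrum
structure, electrode drift, or any behaviourally induced coupling between
speed and oscillation content. Passing the closure tests therefore shows
that the estimators recover the quantities they claim from data satisfying
their assumptions — not that those assumptions hold in any given animal.

Determinism is a contract: every generator takes an explicit seed, runs in
a local RNG scope, restores the caller's random state, and produces
bit-identical output for identical configuration and seed.

## Problem sizes used by the test suite

The suite exercises every stage at desk scale: cluster-level family-wise
error is calibrated over 400 outer replicates of 12×12×8 grids with 200
Monte-Carlo iterations each; null p-value uniformity uses 200 replicates
per test family; mini-detector recall uses 30 s traces at 2 kHz and
false-positive rates are accumulated over 20–30 trace-minutes; fold-change
recovery uses 40-feature tables over 25–40 seeds. These sizes are the
package's choice of a thorough-but-quick default; every routine accepts
larger inputs unchanged, and `cluster_correct()` retains its 10,000
iteration default outside the tests.

## Known limitations

* The cluster null assumes stationary, axis-separable Gaussian smoothness;
  strongly non-stationary residual fields would need the permutation null.
* The Welch-flag path of `cluster_correct()` thresholds at the pooled-df
  height for both observed and simulated fields — consistent, but the
  height's nominal p is approximate for unequal variances.
* `mini_metrics()` requires every cell to reach the subsample size and
  fails loudly otherwise rather than imputing.
* The profile ANOVA for LTP curves is a subject-mean summary, not a full
  repeated-measures decomposition.
* Fold changes from small samples are ratio estimates with no shrinkage;
  the planted-truth tests quantify their spread under the generator's
  noise model only.
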