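# neuromodal

Quantitative pipeline for characterising basal hyperactivity of the
entorhinal cortex (EC) in APOE4 mouse models, spanning the five data
modalities such a study rests on — contrast-enhanced imaging, in vivo
electrophysiology, sorted single units, in vitro slice physiology, and
LC-MS metabolomics — together with a synthetic-data module that generates
every input with planted, recoverable ground truth. It is aimed at
neurophysiology and neuroimaging analysts who want each analysis stage as a
small, tested, scriptable function rather than a chain of GUI tools.

## What it computes

* **Relative CBV mapping.** Voxelwise ΔR2 = ln(S<sub>pre</sub>/S<sub>post</sub>)/TE
  from pre/post-contrast volumes, normalized to the mean ΔR2 of an internal
  jugular vein ROI (`compute_cbv_map()`); voxelwise two-sample Student's t
  contrasts between genotypes (`group_stat_map()`); and cluster-extent
  multiple-comparisons correction by Monte-Carlo simulation (10,000
  iterations by default) of smoothness-matched null fields, 6-connected 3-D
  clustering, corrected to p < 0.05 (`cluster_correct()`).
* **Speed-filtered LFP band power.** Tracking cleanup (samples > 100 cm/s
  deleted, gaps < 1 s interpolated, 21-sample boxcar; `clean_tracking()`),
  running speed (`compute_speed()`), and percent power of delta/theta/beta/
  low-gamma/high-gamma bands during 5–20 cm/s locomotion epochs with a
  55–65 Hz notch, via Welch's PSD (`band_percent_power()`), compared across
  genotypes with Welch's t-test (`compare_bands()`).
* **Unit classification and firing rates.** Trough-to-peak waveform width
  with sub-sample interpolation (`waveform_width()`); putative excitatory
  neurons are units wider than 300 µs (`classify_units()`); firing rate =
  spikes / session duration with per-class Welch comparisons
  (`firing_rates()`).
* **In vitro events.** sEFP detection by the 3-SD / >20 ms threshold rule
  (`detect_sefp()`); fEPSP 10–90% rising-phase slopes (`fepsp_slope()`) and
  LTP time courses normalized to a ≥15 min baseline with mean potentiation
  over 40–60 min post-induction (`ltp_analyze()`); miniature IPSC detection
  by sliding optimal-scaling template matching (criterion ≥ 3.5 and peak ≥
  3× noise SD; `detect_minis()`) with pooled 50-events-per-cell metrics and
  the pooled per-event t-test (`mini_metrics()`, `pooled_event_test()`);
  ΔF/F = 100(F−F0)/(F0−B) calcium transients (`dff()`).
* **Metabolomics differential abundance.** Per-mode top-2000 /
  600-ion-count feature filtering (`filter_features()`), targeted annotation
  at 10 mDa mass and 1 min RT tolerances (`match_targeted()`), and
  two-sided Mann-Whitney tests with Benjamini-Hochberg FDR per detection
  mode (`differential_abundance()`).

All shared statistics (Welch and pooled t, Mann-Whitney U, two-sample KS,
BH step-up) live behind one uniform `test_result` interface in the
stats-util module.

## Worked example

Generate a session with a planted theta fraction of 0.6, then recover it
through the full tracking → speed filter → band power chain:

```r
library(neuromodal)
s <- gen_session(duration = 180, seed = 42,
                 band_fractions = c(delta = 0.1, theta = 0.6, beta = 0.1,
                                    low_gamma = 0.1, high_gamma = 0.1))
track <- clean_tracking(s$tracking)
speed <- compute_speed(track)
band_percent_power(s$lfp, s$lfp_rate, speed)
#> LFP band power (57 Welch windows, speeds 5-20 cm/s)
#>        band lo  hi power percent
#>       delta  1   4  1897    9.50
#>       theta  4  12 11860   59.41
#>        beta 12  30  2302   11.53
#>   low_gamma 30  55  1910    9.57
#>  high_gamma 65 120  1993    9.98
```

The planted 60% theta fraction comes back as 59.4% of analyzed-range power;
the other four bands sit near their planted 10% shares.

Miniature IPSCs: two groups of cells generated at mean amplitudes
26.09 pA (7 cells) and 21.6 pA (8 cells), detected by template matching and
pooled at 50 events per cell:

```r
cells_a <- lapply(1:7, function(i) {
  g <- gen_mini_trace(duration_s = 30, rate = 2000, amp_mean = 26.09, seed = i)
  detect_minis(g$trace, g$rate)
})
cells_b <- lapply(11:18, function(i) {
  g <- gen_mini_trace(duration_s = 30, rate = 2000, amp_mean = 21.6, seed = i)
  detect_minis(g$trace, g$rate)
})
mini_metrics(cells_a, cells_b, k = 50, seed = 1)
#> Pooled mini metrics (k = 50 events/cell, seed 1)
#>        metric group   mean   sem   n
#>  amplitude_pa     A 26.120 0.280 350
#>  amplitude_pa     B 21.480 0.232 400
#>  inst_freq_hz     A  7.941 0.358 345
#>  inst_freq_hz     B  7.863 0.349 395
#>        tau_ms     A  9.857 0.148 350
#>        tau_ms     B 10.010 0.178 400
#>   amplitude_pa: t(748) = 12.853, p = <2e-16
#>   inst_freq_hz: t(738) = 0.157, p = 0.875
#>   tau_ms: t(748) = -0.632, p = 0.528
```

The pooled per-event test has 50 × (7 + 8) − 2 = 748 degrees of freedom;
amplitudes separate decisively while frequency and decay constant do not —
the planted configuration.

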