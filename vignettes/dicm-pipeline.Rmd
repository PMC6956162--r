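---
title: "Dominant intrinsic coupling modes and the flexibility index: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant intrinsic coupling modes and the flexibility index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicmflex)
```

## The model

Resting-state electrophysiological recordings express several qualitatively
different kinds of inter-regional coupling at once: correlated amplitude
envelopes, phase locking within a frequency band, modulation of a fast
rhythm's amplitude by a slow rhythm's phase, and lagged, directed
interactions. `dicmflex` treats these as competing hypotheses for every
sensor pair and every short time window, and asks which one — if any — is
statistically dominant there. The winning label per pair and window is the
*dominant intrinsic coupling mode* (dICM), and the temporal dynamics of
these labels carry the information the package ultimately summarises:
lobar subnetwork features (mean subgraph strength, MSS, and fractional
occupancy, FO) and a global *flexibility index* (FI), the rate at which a
pair's label changes between consecutive windows, averaged over the whole
array.

The pipeline has five stages:

1. **Preprocessing** (`downsample()`, `filterbank()`, `make_windows()`).
   Eight zero-phase Butterworth bands — delta 0.5–4, theta 4–8, alpha1
   8–10, alpha2 10–13, beta1 13–15, beta2 15–19, beta3 20–29, gamma
   30–45 Hz — with Hilbert envelope and phase per band and channel, cut
   into 2-s windows advanced by 0.2 s. Two seconds is two cycles of the
   slowest (delta) band, the shortest window in which delta-paced
   cross-frequency modulation is expressible.
2. **Candidate coupling estimators** (`estimate_all()`): amplitude envelope
   correlation (AEC, estimator id 1), same-frequency imaginary
   phase-locking value (iPLV, id 2), phase–amplitude coupling via
   cross-frequency iPLV (PAC, id 3), delay symbolic transfer entropy with
   neural-gas symbolisation (dSTE, id 4), and the directed phase lag index
   (dPLI, id 5). Frequency content is coded 1–36: codes 1–8 are the eight
   within-band codes in filterbank order, codes 9–36 the 28 ordered
   low < high band pairs in lexicographic order; code 0 means "no
   significant coupling". iPLV uses only the within-band codes, PAC only
   the cross-band codes, AEC/dSTE/dPLI both.
3. **Statistical filtering** (`run_dicm()`): per candidate, an empirical
   null from circular time-shift surrogates; per estimator, pair and
   window, Benjamini–Hochberg FDR at q = 0.01 across its frequency
   candidates; then `select_dicm()` keeps the representative mode(s) —
   the max-strength significant candidate when one estimator is
   significant, and, when several are, up to two records below the
   stricter multi-estimator threshold 0.01/4 = 0.0025, smallest p first.
4. **Topological filtering** (`omst_filter()`, `apply_omst()`): per-window
   orthogonal minimal spanning trees on the retained strength graph,
   keeping the edge-disjoint-tree union that maximises global efficiency
   minus wiring cost.
5. **Aggregation and modelling**: lobar dominance calls (a mode is
   characteristic of a lobe pair when it labels more than 75% of its
   sensor pairs in at least 50% of windows), MSS/FO feature vectors over
   the packaged 12-row subnetwork configuration, the flexibility index,
   growth-curve selection by AIC (`fit_fi_age()`), SVM/SVR age prediction
   and rank-sum group comparisons.

## Statistical choices

**Surrogates.** Each surrogate circularly shifts one member of the pair by
a random offset of at least one second and recomputes the statistic. The
shift preserves each signal's spectrum, envelope statistics and symbol
alphabet while destroying cross-signal alignment, which makes it a valid
null for all five estimators. Whole-recording analytic series (envelope,
phase phasor, envelope-phase phasor, symbol series) are computed once, so
a surrogate is just a shifted index into the same series.

**Empirical p-values.** p is the fraction of surrogate values *at or
above* the observed one. Ties count against significance: a bounded
statistic that saturates (dPLI reaches exactly 1 whenever the windowed
phase difference never changes sign, which slow narrowband drift produces
regularly even under the null) must not become significant merely by tying
its surrogates. Zero p-values are attainable and are handled correctly by
the BH step-up; this keeps the pipeline operational at desk-scale
surrogate counts (200 in the tests; 1000 by default; 10000 in the
reference profile), where any estimator whose minimum attainable p
exceeded q/36 could never retain anything.

**dSTE statistic.** Both directional transfer entropies are maximised over
the same delay grid (1–10 samples by default) for the observed window and
for every surrogate, and for cross-band codes over both orientations, so
observed and surrogate statistics are exchangeable under the null — the
surrogate scan is the computational bottleneck and is implemented in
compiled code. Net strength is |TE(a→b) − TE(b→a)| / max of the two, with
each TE normalised by log k. The embedding (dimension 3, lag 1, codebook
size k = 8 learned by neural gas on a pooled subsample of z-scored
delay-embedded state vectors, one codebook per recording) keeps the symbol
alphabet well sampled inside 300-sample windows; all of these are
config-exposed since no reference values exist for them.

**Cross-band conventions.** PAC filters the high-band Hilbert envelope
inside the low band and phase-locks it to the low-band phase; cross-band
dPLI applies the directed step statistic to the same pair of phase series;
cross-band AEC correlates the two bands' envelopes directly. For an
unordered sensor pair, cross-band candidates are evaluated in both
orientations and the larger strength kept, with the surrogate statistic
maximised the same way.

**Selection edge cases.** When two or more estimators are FDR-significant
but none passes 0.0025, the single max-strength candidate is kept; when
more than two pass, the two smallest p (ties broken by larger strength).
A record's slot-1 label defines the pair's dICM for dominance counts and
the FI, since those need a single label per pair and window.

## The synthetic-data generator

Because no reference recordings are distributable, every downstream claim
is exercised on synthetic multichannel recordings with planted structure
(`gen_recording()`, `gen_switching_recording()`, `gen_cohort()`). Each
channel is a 1/f-weighted (amplitude ∝ f^−1/2) sum of independent
band-limited noise components; plan entries then rewrite individual
(channel, band) components:

* **AEC**: the target channel keeps its band phase, its envelope becomes a
  strength-weighted mixture with the source channel's envelope. The
  realised window-level correlation is a monotone (not identity) function
  of the requested strength.
* **iPLV**: phase-only coupling — the target keeps its own envelope while
  its phase becomes a phasor mixture of the source's constant-lagged phase
  and its own. The default lag is π/2 because the imaginary-part statistic
  is deliberately blind to zero-lag coupling; a zero-lag plant would be
  invisible by design.
* **PAC / cross-band dSTE**: textbook narrowband synthesis — the source's
  low band becomes a phase-diffusing oscillator (centre frequency, ~1 Hz
  Lorentzian linewidth) whose phase multiplies a constant-envelope
  high-band carrier as 1 − depth + depth·(1 + cos(φ − lag))/2. The
  constant-envelope carrier makes the realised modulation depth equal the
  requested one; the phase diffusion makes circular-shift surrogates
  decorrelate while the in-window phase relation stays coherent.
* **dPLI / within-band dSTE**: delayed-copy injection mixed with
  independent noise.

What the generator does *not* emulate: sensor noise covariance and field
spread of real MEG systems, artefacts (cardiac, ocular, muscle), source
mixing, and 1/f slopes varying across the scalp. Passing tests therefore
demonstrate that the pipeline recovers the coupling structure it models,
at the SNR the plants produce — not that real recordings meet those
assumptions.

Cohorts use the fast path: ages sampled uniformly within the six age bins
8–12, 13–17, 18–27, 28–37, 38–50, 51–60 years (allocated proportionally
to the reference cohort sizes 24/26/43/43/28/14), FI = a·age² + b·age + c
plus Gaussian noise, clamped to [0, 1]. The defaults a = −2·10⁻⁴,
b = 0.016, c = 0.1, sd = 0.02 put the curve's peak near age 40 with a
clearly resolvable quadratic at n = 178.

## Numerical and scale choices

* The window step is not stated by the source ranking of the scheme; 0.2 s
  is adopted because it yields exactly T = 900 segments for a 180-s
  recording at both 170 Hz (step 34 samples) and 150 Hz (step 30).
  Windows overrunning the end (the last 9) are truncated, not wrapped;
  the small estimator bias on ≤1% of windows is accepted.
* "3rd-order Butterworth, zero-phase" is implemented as forward–backward
  filtering (effective order 6). Signals are demeaned before filtering;
  band edges are half-open [lo, hi).
* Downsampling uses a zero-phase anti-alias low-pass at 0.9× the target
  Nyquist followed by cubic-spline resampling, reproducing the 30,600 /
  27,000 sample counts exactly.
* OMST uses the distance transform d = 1/w; statistically rejected edges
  (w = 0) are ineligible; disconnected significant graphs are filtered per
  connected component, since spanning trees are undefined otherwise. OMST
  runs per window, consistent with the dynamic reading of the filter; FI
  is computed from the statistically filtered tensor.
* Within-hemisphere adaptations of the MSS/FO equations use the pairs
  internal to each hemisphere's sensors of the lobe, pooled over
  hemispheres; the pair-count is the normaliser, so both stay in [0, 1].
* The packaged 248- and 275-sensor lobe maps are deterministic synthetic
  partitions built from sensor-name blocks — the reference assignments are
  unpublished — and any user map can replace them. Band subscripts in the
  packaged subnetwork ranking that do not match the filterbank naming are
  mapped to the nearest bands (β → β2, γ1/γ2 → γ).
* Test problem sizes: planted-mode recovery uses 24-s two-channel
  recordings (T = 120) with 200 surrogates; null calibration uses four
  channels × 84 windows (504 window-pair tests); cohort simulations use
  n = 178 with 100 replicates. These sizes give stable pass/fail behaviour
  for the properties being checked while keeping the whole suite fast.

## Known limitations

* At 200 surrogates the attainable p-values are coarse; with BH at
  q = 0.01 across ≥28 candidates only p = 0 can survive, so each
  estimator spuriously retains *some* code in roughly 1/201 of
  window-candidates, and those flukes occasionally outrank a true mode in
  the two-record selection. The reference surrogate count (10,000) makes
  this negligible; the desk-scale property tests account for it by
  checking recovery fractions, not exact labels.
* Windowed phase statistics in slow, narrow bands (delta–alpha) have wide
  nulls over 2-s windows — slow relative phase drift mimics locking — so
  planted-mode recovery tests use faster bands, and real-data inferences
  about slow bands lean entirely on the surrogate calibration.
* dPLI saturates at 1 for any window in which the phase difference never
  changes sign; the tie-aware p-value keeps this honest but also makes
  dPLI conservative at small surrogate counts.
* The exponential and von Bertalanffy growth-curve fits are nonlinear
  least squares with fixed, deliberately generic starting values; on
  pathological cohorts they may fail to converge and are then excluded
  from the AIC comparison with a warning.
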