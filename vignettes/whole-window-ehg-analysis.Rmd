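---
title: "Whole-window EHG analysis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-window EHG analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The electrohysterogram (EHG) records uterine myoelectrical activity from
abdominal surface electrodes. Across the third trimester the myometrium
progressively prepares for labour: contraction amplitude rises as resting
membrane potentials depolarise and more myocytes recruit, electrical
activity becomes more coordinated (less random), and bursts become more
impulsive relative to baseline. Multiple (twin) gestations, a major risk
factor for preterm birth, are thought to enter this labour-preparatory
state earlier because of greater uterine distension.

`ehgtrends` implements a *whole-window* characterisation of these changes:
instead of detecting individual contraction bursts — unreliable early in
gestation when amplitudes are low — every recording is cut into fixed,
overlapping analysis windows, four features are computed per window, and
the median across windows represents the recording. Cohort-level trends
over gestational age (GA) are then estimated per gestation type.

## Pipeline and model

1. **Band-pass 0.1–4 Hz, zero phase.** The EHG fast-wave components live
   between the fast-wave-low band (FWL, 0.13–0.26 Hz, propagation-related)
   and the fast-wave-high band (FWH, 0.34–4 Hz, excitability-related);
   below 0.1 Hz is baseline drift and respiration, above 4 Hz is noise and
   cardiac residue. The filter is realised in the frequency domain by
   multiplying the spectrum with the *squared magnitude* of a 5th-order
   Butterworth band-pass. This is exactly the forward–backward (zero-phase)
   response of that filter, without the numerical fragility of a 10th-order
   IIR in coefficient form at a normalised edge of 0.1/500 Hz. Edge
   transients are confined to roughly the first/last 10 s, which analytic
   checks exclude.
2. **Resample to 20 Hz.** Fourier resampling with a raised-cosine
   anti-alias taper from 70% to 90% of the target Nyquist (7–9 Hz). The
   0.1–4 Hz band is untouched; a 9 Hz tone is suppressed below 1e-12 of
   its amplitude. This replaces the classical polyphase decimator with an
   equivalent-contract implementation that also handles non-integer
   ratios.
3. **Artifact exclusion.** Motion-artifact intervals come from an
   annotation file (half-open `[start_s, end_s)` seconds). Samples inside
   any interval are dropped and the remaining maximal clean stretches are
   kept. Windows are cut *inside* clean segments only — a window touching
   an artifact is discarded entirely, never patched, because interpolating
   across an artifact would invent signal.
4. **Windows.** 120 s with 50% overlap (2400 samples at 20 Hz; step 60 s).
   A segment of duration `D` yields `floor((D - 120)/60) + 1` windows; a
   30-minute clean recording yields 29.

### The four features

* **PPA** (peak-to-peak amplitude, 0.1–4 Hz): `max - min` per window;
  proxy for contraction intensity. Scales linearly with the signal; all
  other features are scale-invariant, so no amplitude calibration is
  assumed anywhere.
* **KHE** (kurtosis of the Hilbert envelope, 0.1–4 Hz): Pearson
  (non-excess) kurtosis of the analytic-signal magnitude; proxy for
  impulsiveness. Gaussian noise gives the Rayleigh-envelope value 3.245;
  isolated bursts push it far higher. The first/last 2 s of the envelope
  are discarded because the frequency-domain Hilbert transformer rings at
  window edges and inflates the fourth moment. The non-excess convention
  is a documented choice (the excess convention would only shift values
  by 3).
* **MDF** (median frequency, 0.2–1 Hz): the frequency splitting the
  in-band power spectral distribution into equal halves; the 0.2 Hz lower
  edge avoids maternal cardiac interference. The PSD is a Welch estimate
  with Hann taper, 50% overlap and 60-s segments (0.017 Hz resolution —
  a 12.8-s segment, sometimes used, cannot resolve the band to the 0.05 Hz
  the contract requires). The half-power crossing is interpolated within
  bins; when the cumulative spectrum plateaus at exactly half power (two
  equal tones), the *midpoint of the median interval* is returned, the
  usual convention for a distribution median with atoms.
* **SampEn** (sample entropy, FWH band, m = 2, r = 0.2): the window is
  re-filtered to 0.34–4 Hz, then `SampEn = -ln(A/B)` with Chebyshev
  tolerance `r = 0.2 × SD` of the re-filtered window (the universal
  reading of "r = 0.2"; applied per window, a documented choice since the
  source convention is unstated). Counting follows Richman–Moorman: both
  template lengths use the same `n - m` offsets, self-matches excluded.
  The hot loop is in C++; an O(N²) brute-force R oracle checks it to
  1e-12 in the tests.

Undefined features (constant window, zero in-band power, no matching
templates) propagate as `NA` and are excluded per feature at aggregation,
never imputed. The per-recording summary is the median over windows.

## Cohort statistics

* **Stage stratification:** routine check-up recordings split at the
  clinical thresholds into Early3T (`GA < 32` weeks) and Late3T
  (`32 ≤ GA < 37`), both half-open; term-not-in-labour (TNL) and
  active-phase-of-labour (APL) labels come from metadata, not GA.
* **GA balancing:** before any SG-vs-MG statistic, GA is segmented into
  1-week bins and the larger group is randomly downsampled to the smaller
  group's count per bin (seeded, without replacement, bins processed in
  ascending order). Bins with one empty group are dropped from both. The
  bin width is exposed; 1 week is the natural clinical unit. Strict
  per-bin equalisation is adopted for reproducibility even though the
  original dynamic-sampling technique is underspecified and need not
  produce exactly equal group sizes. Balancing applies to routine
  recordings only — term groups have no MG counterpart by design.
* **Trends:** per feature and group, `mgcv::gam(y ~ s(ga, bs = "cr",
  k = 10), method = "GCV.Cp")` — Gaussian response, penalized cubic
  regression splines, GCV-chosen smoothness — evaluated with 95%
  pointwise intervals on a 0.25-week grid. Separate SG and MG fits rather
  than an interaction model, matching independent per-group curves.
* **Correlations:** Spearman's rho via average ranks + Pearson, two-sided
  p by exact permutation enumeration for `n ≤ 7` and the t approximation
  above (a deterministic replacement for random-permutation p-values,
  which would depend on an RNG). The SG correlation optionally spans the
  full GA range including TNL/APL (`include_term`, default on); MG is
  restricted to routine recordings before 37 weeks.
* **Comparisons:** two-sided Wilcoxon rank-sum (`stats::wilcox.test`),
  exact when the combined n ≤ 20 without ties, else normal approximation
  with tie and continuity correction. Raw p-values at α = 0.05, no
  multiple-testing correction, following the reporting convention of this
  literature. Repeated recordings from the same woman are treated as
  independent (recording-level analysis); the analysis log records this
  caveat.

## The synthetic cohort generator

No EHG recordings are publicly deposited for this design, so the package
carries a seeded generator that emulates the statistical structure the
analysis assumes. One recording (default 30 min at 500 Hz) is:

* sparse contraction bursts — onsets from a Poisson process (0.6/min)
  thinned to forbid overlap, each a Gaussian-tapered (35 s) sum of an FWL
  oscillation (carrier ~0.19 Hz, mild jitter) and an FWH oscillation
  (carrier ~0.45–0.9 Hz), powers split 40/60;
* baseline drift below 0.1 Hz (three random slow sinusoids);
* band-limited Gaussian noise, normalised so `noise_sd` is the in-band
  noise floor (white noise at 500 Hz would be almost entirely removed by
  the 0.1–4 Hz filter, making the parameter meaningless downstream);
* a `regularity` knob in [0, 1] mapped to log-normal
  instantaneous-frequency jitter of the FWH oscillator
  (scale `1.2 × (1 - regularity)`, 0.4 s correlation time). Higher
  regularity means a purer tone and lower SampEn; the mapping is a
  monotone control, not a physiological claim. Mild fractional jitter was
  empirically too weak to move SampEn at 20 Hz, hence the wider
  log-normal law.

Cohort defaults state a plausible third-trimester study: 40 SG and 40 MG
routine women with 1–3 visits each, uniform in 26–37 weeks; 17 SG TNL
women near 39 weeks and 10 SG APL women beyond 40 weeks, one recording
each; a log-normal woman-level amplitude effect (SD 0.15). The programmed
trends encode the qualitative electrophysiology:

* SG burst amplitude `0.4 + 0.09 × (GA - 26)` — starting near the noise
  floor (0.3) so the burst-to-noise ratio, and with it envelope kurtosis,
  rises across gestation rather than saturating;
* SG regularity `0.25 + 0.03 × (GA - 26)` (capped at 0.95) — entropy
  falls;
* MG adds `+0.5 × (32 - GA)/6` to amplitude and `+0.25 × (32 - GA)/6` to
  regularity, both positive only before 32 weeks: earlier uterine
  activation that converges to the SG trajectory by 32 weeks, so group
  differences concentrate in the early third trimester and vanish later.

What the generator does **not** emulate: biophysical propagation,
electrode geometry, multichannel structure, maternal cardiac or
respiration residues, real artifact morphology (artifacts are clipped
ramps — irrelevant, since annotated intervals are excluded, not
repaired), or absolute amplitude units. A green end-to-end test therefore
establishes that the *pipeline* recovers programmed structure of this
kind — not that the physiological claims of any particular study are
true.

## Numerical choices and degenerate inputs

* Filter/resample linearity: the whole preprocessing chain is linear, so
  `pipeline(a·x) = a·pipeline(x)` to machine precision (tested).
* Artifact bounds are mapped to sample indices with a guarded ceiling so
  float noise at interval boundaries can never shift a cut by one sample;
  clean + annotated duration is conserved to within one sample period.
* MDF plateau tie-break tolerance: 1e-9 of total in-band power.
* SampEn tolerance uses the n−1 sample SD; with `B = 0` or `A = 0` the
  value is undefined (`NA`), as for constant windows.
* GAM: if fewer unique GA values than the basis size, the basis is
  shrunk; below 5 unique values the fit errors with guidance.
* Windows shorter than 120 s yield zero windows, and recordings with zero
  windows are excluded with a warning.

## Known limitations

* The balancing rule is a reproducible approximation of an
  underspecified "dynamic sampling" procedure; other rules satisfying the
  same per-bin contract exist.
* Recording-level (not woman-level) units throughout; no mixed-effects
  handling of repeated visits.
* Features are fixed to the four implemented; no burst
  detection/segmentation is provided by design.
* The simulator's effect sizes are stated defaults, not estimates fitted
  to any clinical data; only directions and significance patterns of the
  synthetic world are meaningful.
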