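---
title: "Methods: repertoire features, forest validation and soundscape metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repertoire features, forest validation and soundscape metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sealscape)
```

# Scope and model

`sealscape` analyses an underwater pinniped vocal repertoire from
labelled single-channel recordings, and characterizes the surrounding
soundscape. The repertoire model is a catalogue of 18 call types in
three structural categories:

* **harmonic** calls (12 types): a fundamental frequency `f0` with a
  stack of harmonics, possibly degraded to one or two visible bands
  (scream, whine, whoo), and always carrying some frequency modulation;
* **noisy** calls (3 types): broadband energy without harmonic
  structure, summarized by the spectral peak and energy quartiles;
* **pulsative** calls (3 types): series of short units at a steady rate
  (clap, knock) or continuous calls with fast amplitude modulation
  (rumble), summarized chiefly by the pulse rate `PR`.

Moans exist in the catalogue but are too faint to be measured; they are
carried in the registry with `measurable = FALSE` and the feature stage
refuses them with an explicit reason, as it refuses any segment not
flagged good-quality.

All spectral measurements are band-limited — 20 Hz–1 kHz by default,
because snapping shrimp dominate the band above ~1.5 kHz; growls and
knocks, which carry energy above 1 kHz and are louder than the shrimp
background, are analysed to 3 kHz, and high-pitched screams to 2 kHz.

# Feature definitions and estimator design

The measured variables mirror standard bioacoustic practice:

| variable | definition | estimator |
|---|---|---|
| `dur` | total duration, s | first/last crossing of the amplitude envelope at −20 dB below its peak |
| `f0` | fundamental frequency, Hz | harmonic-comb score on the average spectrum, refined by the mean of a per-frame fundamental track |
| `excF` | excursion of the fundamental contour, Hz | highest minus lowest tracked fundamental (2%/98% track quantiles) |
| `Fmax` | frequency of the highest spectral peak, Hz | argmax of the (lightly smoothed) average spectrum; on harmonic calls, argmax over the harmonics of `f0` |
| `Q25/Q50/Q75` | energy quartiles, Hz | lowest frequency at which cumulative in-band power reaches 25/50/75% |
| `PR` | pulse rate, pulses/s | `(n_pulses − 1)/(t_last − t_first)` from envelope segmentation, or the envelope-spectrum peak for AM calls |

Design notes, in decreasing order of consequence:

* **f0 under frequency modulation.** The original measurement was a
  manual harmonic cursor on the average spectrum. A purely spectral
  automation is biased for modulated calls: a contour dwells longest at
  its extremes (the derivative vanishes there), so the average-spectrum
  peak sits near a contour extreme rather than at the contour mean. The
  estimator therefore uses the comb score only for coarse localization
  and returns the mean of a per-frame fundamental track. The track
  scores every frame with a fixed-length log harmonic comb (six teeth,
  `1/k` weights, out-of-band teeth read a floor value). The fixed tooth
  count is what makes candidate scores comparable: without it, a lone
  strong harmonic above half the band edge outscores the full stack,
  and an exact subharmonic of a pure tone ties with it. Frame length
  adapts to cover ≥ 6 fundamental cycles; half-frame zero-padding keeps
  frame centers covering the call edges, where the contour extremes of
  an arch-shaped modulation live. A 3-point running median removes
  isolated mis-tracked frames (the half-empty edge frames are the usual
  offenders).
* **Fmax on harmonic stacks.** The raw argmax smears across the
  modulation plateau of the dominant harmonic; instead the band power
  around each harmonic `k·f0` (±0.45·f0) is compared directly and the
  winning harmonic reported. On noisy/pulsative spectra a ~30 Hz moving
  average stabilizes the argmax against single-realization χ²
  fluctuation; quartiles always use the raw cumulative spectrum.
* **Duration.** Envelope = full-wave rectification + zero-phase FFT
  low-pass, default 5 ms smoothing for duration (short enough not to
  bias an 0.18 s hiccup) and 20 ms for pulse segmentation (long enough
  to fuse a click, short enough to separate knocks at ~7 pulses/s). The
  −20 dB threshold is configurable; the original oscillogram reading
  states none.
* **Per-type f0 search ranges.** A fixed 40–400 Hz window contradicts
  the published statistics for whoo (439 ± 154 Hz), cry and wop; search
  ranges are therefore mean ± 3.5 SD clipped to the analysis band
  (screams keep 500–2000 Hz).
* **Quartile definition.** Cumulative summation is on linear power; the
  original instrument's weighting is unstated.
* **Average spectrum.** 1024-point Hamming frames, 75% overlap, linear
  power averaging over frames; power is normalized so a full-scale,
  bin-centered sine reads its mean-square power (0.5) independent of
  FFT size — the calibration chain depends on this normalization.

# The synthetic world

The generator's defaults are the published per-type statistics
(`repertoire_params()`): truncated-normal marginals for every variable,
sampled independently because only marginals are published. Consequences
worth stating plainly:

* **No covariances.** Real calls correlate duration, pitch and spectral
  shape; sampled tables cannot. Classifier accuracies on synthetic
  tables are therefore *not* expected to match the published
  percentages — only the qualitative structure (every class above
  chance, `PR` dominating the pulsative ranking) is asserted, and even
  that has one honest failure mode, below.
* **Truncation shifts means.** Where the printed SD is large relative
  to the mean (knock duration 1.922 ± 1.828 s), positive truncation
  necessarily raises the sampled mean (analytically ≈ 2.43 s for the
  knock). Tests compare draws against the truncated-normal expectation,
  not the raw printed mean.
* **Harmonic-grid quantization of Fmax.** The harmonic generator places
  the spectral peak on the harmonic nearest the sampled target
  (`k* = round(Fmax/f0)`, amplitudes rolling off at −6 dB per harmonic
  step away from `k*`). For types whose `Fmax/f0` ratio is ~1.3 with a
  wide SD (gloo, whine), `E[max(1, round(r))·f0]` exceeds the printed
  mean by construction; no extractor can undo that. Parameter-recovery
  tests therefore compare extraction against the recorded per-call
  ground truth.
* **Contours.** The f0 contour is a single raised-cosine arch centered
  on the sampled `f0` and spanning exactly the sampled `excF` — the
  simplest shape consistent with the described modulation. Types whose
  excursion is unreported (gloogloo, groan) are synthesized unmodulated.
* **Noisy spectra.** Piecewise-flat density with 25% of the energy
  between successive quartile targets, plus a Gaussian bump at the
  `Fmax` target whose mass is folded into the piecewise solution so the
  quartiles still land exactly on target; the bump's height adapts to
  2× the tallest plateau so the argmax is the bump even when sampled
  quartiles fall close together.
* **Pulsative calls.** Discrete series place clicks at exactly `1/PR`
  spacing (`floor(dur·PR)+1` clicks), so the realized rate is exact and
  the realized duration is the click span — recorded as ground truth.
  Rumbles are shaped-noise carriers under a sinusoidal envelope
  (modulation index 0.8).
* **Background.** Snapping-shrimp crackle: Poisson snaps (default
  60 s⁻¹), 2.5 ms decaying transients band-passed to 1.5–5.5 kHz.
  Vessel noise: 20–200 Hz band noise plus engine tonals (60/120/180 Hz
  defaults). Flow noise: < 30 Hz. Component gains are RMS dB re full
  scale; defaults (−26/−30/−36) keep the mix realistic for a busy
  coastal site without clipping.
* Calls are tapered with 5 ms raised-cosine edges (synthesis hygiene);
  the default corpus rate is 11,025 Hz, mirroring the subsampled
  day-files the screening workflow uses, and halving test runtime
  relative to the 22,050 Hz recorder rate.

A green synthetic test therefore establishes that the estimators recover
the stated marginal structure and that the pipeline's bookkeeping is
exact; it does not establish performance on real, reverberant,
noise-masked recordings.

# Random-Forest validation

The environment ships no R random-forest package, so the package
implements the standard algorithm in C++ (Rcpp): bagged CART trees grown
to purity, Gini splits, `mtry` features per split (2 harmonic, 2 noisy,
1 pulsative), 500 trees, out-of-bag majority-vote predictions, and Gini
importance as the per-tree-averaged impurity decrease. On identical
feature tables its OOB error tracks scikit-learn's
`RandomForestClassifier` within about one percentage point.

The harmonic variable set is `{dur, f0, Fmax, Q25, Q50, Q75}`: the six
variables measurable for every type of the category. `excF` is dropped
because it is unavailable for two types, while the quartiles — reported
as "--" for the single-band types in repertoire tables — must have been
available internally for the classifier; the package computes them for
single-band types but masks them out of report-style output. For sampled
tables the single-band quartiles are synthesized as small jitter around
`f0`, mirroring spectra whose energy sits in the fundamental band.

**A known honest red.** With independent marginals, croak (n = 32)
overlaps bark (n = 294) so strongly that its out-of-bag recall sits at
or below its 4.3% chance rate on roughly two seeds in five — confirmed
with an independent implementation on identical tables. The acceptance
test asserts the above-chance property for every class as specified and
is left red when croak fails it; weakening the assertion would hide a
real property of the marginals-only world. (On the real data croak
recall was 44% — covariance structure the published marginals cannot
carry.)

# Soundscape metrics

Calibration: counts → volts via the ADC full scale, volts → µPa via
`10^(−(sensitivity + gain)/20)`; a 1 V-rms tone at −168.5 dB re V/µPa
reads 168.5 dB re 1 µPa by definition.

* **PSD percentiles**: Hann-windowed periodograms (1 s windows, 50%
  overlap, 1 Hz bins — standard soundscape practice; the metric's
  original estimator settings are unstated), per-frequency percentiles
  {10, 25, 50, 75, 90} in dB re 1 µPa²/Hz. Note the median of
  single-window periodogram bins sits `10·log10(ln 2) ≈ −1.6 dB` below
  the mean density for Gaussian noise; tests use that closed form.
* **Band levels**: mean-square pressure integrated over half-open
  `[lo, hi)` bands per time bin — half-open so disjoint covering bands
  sum exactly to the broadband level (20 Hz–5.5 kHz). Octave bands are
  base-2 (`fc/√2` to `fc·√2`) at 125/500/2000 Hz: vessel noise, seal
  vocalizations, snapping shrimp respectively.
* **LTSA**: spectrogram frames power-averaged in coarse bins (default
  5 s × 5 Hz; the FFT length is chosen so the spectral line spacing
  never exceeds the frequency bin, otherwise cells would stay empty).
  Averaging is linear-power with dB conversion last, which is what makes
  the time-average identity (LTSA column means = whole-file average
  spectrum) hold to numerical precision.

# Noise budget

Events are clipped to their day and split at midnight; hourly presence
is the union (overlaps merged) of event intervals within each clock
hour, summed per day and averaged over recording days; daily totals use
the same union semantics, flagged quiet below 12 h. Splitting at
boundaries before aggregation is what makes the conservation identity
(`sum(hourly) × n_days = sum(daily)`) exact, and the hourly vector
agrees with a brute-force 1 s occupancy grid exactly for integer-second
events. Recorder-local clock time is used throughout; no timezone
conversion.

# Numerical choices

* Brick-wall FFT filters (envelope smoothing, band-limiting, shrimp/flow
  shaping) zero-pad to a fast composite length first — R's FFT is
  O(n²) at lengths with large prime factors, which arbitrary call
  durations hit regularly.
* Resampling is band-limited (FFT domain), used for the 22,050 →
  11,025 Hz day-file preparation.
* WAV I/O uses a symmetric PCM scale (`2^(bits−1) − 1` both directions)
  so a write/read round trip stays within half an LSB.
* Degenerate inputs error loudly: silent segments (no duration), white
  noise (undefined f0, via an in-band peak-to-median SNR gate, default
  8×), fewer than two pulses, empty bands, inverted bands, Nyquist
  violations (naming the offending harmonic).

# Known limitations

* Estimator quality is demonstrated on the synthetic world only; field
  recordings add reverberation, masking and overlapping callers that
  the generator deliberately does not model.
* The PSD/LTSA implementations hold the per-window density matrix in
  memory; day-scale files at full rate should be processed in chunks or
  at the subsampled rate.
* The forest breaks out-of-bag vote ties toward the earlier class label
  (deterministic, seed-reproducible) rather than at random.
* Hour-scale call-count aggregation assumes label timestamps are
  recorder-local seconds within a day.
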