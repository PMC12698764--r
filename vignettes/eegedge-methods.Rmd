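---
title: "Models and methods behind eegedge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eegedge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `eegedge` computes and why its defaults are
set where they are: the detection model and its assumptions, the
acquisition-characterization formulas, the agreement analysis, what the
synthetic generators do and do not emulate, and the numerical choices
that were genuinely open.

# The detection model

## Signal path

Low-channel wearable EEG (two frontotemporal bipolar derivations, F7T7
and F8T8) carries far less spatial information than a full cap, so the
pipeline leans on dense temporal features and careful post-processing:

1. **Band-pass** [1, 20] Hz, Butterworth of design order 4 applied
   forward and backward (zero phase). Seizure-band rhythms live well
   below 20 Hz; the 1 Hz edge removes electrode drift. The
   forward-backward pass squares the magnitude response (an effective
   8th-order roll-off) and cancels phase distortion, which matters
   because event onsets are read off window times.
2. **Windowing**: 4 s windows, 0.5 s step (87.5 % overlap). Four seconds
   is long enough for stable entropy and band-power estimates at these
   rates and short enough to resolve onset within the smoothing horizon.
3. **Features**: 56 per window per channel (registry below).
4. **Random forest** (probability forest, 100 trees, seeded): per-window
   ictal probability. Forests tolerate the heterogeneous feature scales
   here without normalization and are the model family such wearable
   systems deploy. The tree count for the seizure configuration is the
   package's own choice (the workload configuration uses the published
   200 trees; its full-cap variant 400); 100 trees saturate accuracy on
   the synthetic study while keeping TSCV retraining fast.
5. **Bayesian-style smoothing**: causal log-odds accumulation,
   `odds(t) = prior_odds * prod p_i/(1-p_i)` over the trailing
   `horizon = 8` windows (4 s of new evidence at the 0.5 s step),
   clipped to [1e-6, 1-1e-6]. One high-probability window cannot fire an
   alarm; a sustained run saturates quickly. `horizon = 1` with a flat
   prior is the identity, which the tests pin down.
6. **Event building**: supra-threshold runs (threshold 0.8) shorter than
   2 s are dropped, runs closer than 30 s merge. All three values are
   exposed in `detect_config()`; none is printed in the literature this
   pipeline models, so they are documented operating-point choices, not
   constants of nature.

## Evaluation protocol

Detection quality is scored at the **event level** with any-overlap
matching: one true positive per reference seizure overlapped by at least
one alarm, one false positive per alarm touching no seizure. Sensitivity,
precision, F1 and false alarms per 24 h follow. Pre/post-onset tolerances
exist as options and default to 0 s (the strictest reading).

Chronology is enforced by time-slice cross-validation: the warm-up
boundary is the earliest instant with at least 5 h of data *and* one
completed seizure before it; each later slice (a record, or a fixed
`slice_h`) is tested by a model trained on everything before it. The test
slices tile the post-warm-up timeline exactly once, and a causality
assertion (no test window starting before its training boundary) runs
over every fold in the acceptance tests.

Two scoring conventions deserve a note:

* **Gmean** is the geometric mean of sensitivity and *specificity*.
  A formula dialect with precision in place of specificity circulates in
  print, but published score tables (e.g. 82.9/66.1 → 74.0) are only
  consistent with the specificity reading, which is what `gmean_score()`
  implements; the discrepancy is noted in its documentation.
* Undefined metrics (no reference events in a fold) propagate as `NA`
  and are excluded from macro-averages rather than coerced to zero,
  which would silently deflate them.

## The 56-feature registry

The registry covers the classical low-compute EEG feature families:

| family | entries | contents |
|---|---|---|
| time domain | 8 | line length, mean amplitude, mean, variance, SD, Hjorth activity/mobility/complexity |
| band power | 8 | absolute + relative power in delta [1,4), theta [4,8), alpha [8,12), beta [12,20) Hz |
| entropies | 10 | Shannon (10/20 bins), Tsallis (q=2,3), Rényi (α=2,3), sample (m=2,3), permutation (order 3,5) |
| wavelet | 30 | mean, SD, RMS, mean amplitude, line length, peak over d1–d4, a4 of a 4-level db4 DWT |

The exact 56-entry composition of the deployed systems this models is not
recoverable from their public descriptions; this registry realizes every
named family at the published count, and the manifest (names +
parameters) is written alongside every feature matrix so the composition
is auditable. Conventions: population (1/n) variance throughout, matching
the signal-power semantics of Hjorth activity; histogram entropies over
10 (or 20) bins spanning mean ± 3 SD; sample-entropy tolerance
`0.2 * SD`; permutation entropy normalized by `log(order!)`. In matrix
extraction a sample-entropy value with zero surviving template matches is
capped at `log(B+1)` to stay finite for the forest; the scalar
`sample_entropy()` keeps the `Inf` sentinel with a flag.

Each feature's scaling behaviour (covariant like line length, invariant
like mobility and permutation entropy) is asserted by a scaling test.
The inner sample/permutation-entropy loops run in compiled code; the R
reference implementations remain exported and the test suite checks the
two routes against each other (and against an independent third-party
sample-entropy implementation).

# Acquisition characterization

From a shorted-input stream the package computes IRN (RMS), its
peak-to-peak estimate via the Gaussian crest-factor rule `6.6 × RMS`,
dynamic range, effective number of bits, and noise-free bits. Two
formula dialects exist for NFB; the form
`log2(2*VREF/(Gain*IRN_pp))` — full differential span over peak-to-peak
noise — is the one that reproduces published front-end tables (18.54
bits from 0.98 uVpp, 18.41 from 1.07 uVpp) and is the default, with the
`sqrt2` dialect exposed for comparison. CMRR is reported as positive
rejection `20*log10(Vin/Vout_input-referred)`; the residual amplitude at
the test frequency is read from a flat-top-windowed DFT with a 3-bin
energy sum, which keeps amplitude (not power-density) accuracy even when
the tone straddles bins. `VREF` defaults to 4.5 V, the reference of the
24-bit front end this models (consistent with its printed
0.023 uV/bit at gain 24), and is always overridable.

Eq.-level conventions: the RMS estimator removes DC by default — a
shorted input can carry offset, and offset is not noise — with a flag for
the literal raw-sample form; at least 10,000 samples are recommended and
shorter streams warn.

# Dual-device agreement

To compare two devices observing the same physiology at different rates,
the second stream is first resampled to the reference rate (polyphase
band-limited resampling for rational ratios), then residual timing error
is corrected by dynamic time warping restricted to a Sakoe–Chiba band of
0.25 s on z-scored segments. Unconstrained DTW would inflate the
correlation by re-ordering structure; the narrow band only absorbs
timing drift. Warped duplicates are averaged per reference index so
exactly one aligned sample exists per time point (the collapse rule is
this package's documented choice), and Pearson's r is computed on the
aligned pair over 60 s. Because DTW matches values, aligning an inverted
copy against the reference would destroy the anticorrelation it should
report; alignment therefore runs on the sign-corrected copy (sign taken
from the raw correlation) and the sign is restored in the reported r.

Welch periodograms use 4 s epochs, 50 % overlap, Hann taper (epoch
length is the published choice; overlap and taper are standard Welch
settings, stated in config). Bland–Altman analysis summarizes per-bin PSD
differences by MD, SD, limits MD ± 1.96 SD and the fraction of bins
inside; it operates on raw PSD by default with log-power as an option.

# The synthetic generators

The generators exist so that every module is exercisable and testable
without any external recording. They emulate, per channel:

* background EEG as 1/f^slope coloured noise (default slope 1,
  20 uV RMS) plus optional band oscillations;
* eye-closure alpha: a 10 Hz sinusoid gated by annotated closure
  intervals;
* seizures: amplitude-modulated sinusoids with a linear downward chirp
  (4 → 3 Hz), a 0.6-weight first harmonic, and a 10 % attack ramp —
  chosen to produce the line-length and band-power contrast the feature
  set targets, **not** as physiological seizure morphology;
* blinks: biphasic sub-4 Hz pulses on the frontal channel at Poisson
  times;
* the bench noise floor: Gaussian noise quantized at the acquisition
  spec's resolution;
* a second device: resampling, delay, gain and added noise on the same
  underlying signal.

Every generator is a pure function of its spec (seed included);
per-record seeds derive as `master + record index`.

**What passing tests do and do not show.** The default synthetic study —
ten 1 h two-channel records at 64 Hz with twelve annotated seizures —
is *separable by construction*: ictal RMS is ~4× background and the
discharge is narrow-band. End-to-end sensitivity 1.0 with zero false
alarms on this study demonstrates that the pipeline's plumbing,
causality, scoring and thresholds are correct; it says nothing about
performance on clinical recordings, where ictal patterns are diverse,
artifacts are adversarial, and reported sensitivities for two-channel
montages are far below 1. The 64 Hz default is an analysis-bandwidth
choice: every feature the pipeline computes lives below the 20 Hz band
edge, so a 32 Hz Nyquist loses nothing while keeping the study compact;
the I/O layer reads and writes 256 Hz clinical-dialect files unchanged.

# Numerical choices

* **Zero-phase filtering** pads by reflection over three time constants
  of the low band edge (`3*fs/low` samples) and removes the mean before
  zero-state filtering. A pad proportional to the filter order alone
  (the textbook shortcut) leaves visible low-edge startup transients at
  a 1 Hz edge; the time-constant rule makes the DC-rejection and
  stop-band tests pass with margin and is the package's documented
  choice.
* **Windowing** uses sample counts `round(win_s*fs)`/`round(step_s*fs)`;
  window times in seconds are authoritative, avoiding drift at
  non-integer sample steps.
* **DWT** uses periodized orthonormal Daubechies filters (db4 default,
  4 levels), so Parseval holds exactly and the inverse is the transpose;
  window lengths are powers of two times `2^levels` by construction of
  the window plan at the supported rates.
* **Interval conventions**: seconds, 0-based, half-open
  `[onset, offset)`; overlapping same-label events merge on
  construction, so interval arithmetic downstream assumes canonical
  form.
* **Units**: volts internally everywhere; microvolts only at
  presentation. The characterization (sub-microvolt) and EEG
  (tens-of-microvolts) code paths share containers, and a single
  internal unit prevents silent 1e6 errors between them.
* **Determinism**: every stochastic step (generators, forest training,
  negative down-sampling, fold assignment) takes an explicit seed;
  generators save and restore the caller's RNG state.
* **Degenerate inputs**: constant segments report zero
  mobility/complexity with a flag; zero-power spectra mark relative
  band powers undefined; empty reference event lists make sensitivity
  not-applicable rather than zero.

# Known limitations

* The artifact-rejection policy is a two-threshold amplitude/RMS rule
  with a running-median baseline — deliberately microcontroller-simple,
  pluggable, and not a substitute for ICA-class ocular correction.
* Event matching has no scoring-framework subtleties beyond any-overlap
  plus optional tolerances; split/merge penalties of full clinical
  scoring frameworks are out of scope.
* The workload-monitoring study is synthetic (alternating alpha/theta
  block signatures) and small; its role is to exercise the 56 s/60 %
  window plan, RFECV-to-18-features path and Gmean scoring, not to make
  claims about real cognitive-load data.
* EDF support is classic 16-bit EDF with integer rates and whole-second
  records; annotations travel in plain-text summaries, not EDF+ streams.
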