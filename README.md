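# eegedge

Processing toolkit for low-channel, glasses-form-factor EEG: seizure
detection from two frontotemporal bipolar channels, acquisition front-end
characterization, and dual-device agreement analysis — with seeded
synthetic-EEG generators so the whole pipeline runs and tests itself with
no external recordings.

## Who this is for

Engineers and researchers building or evaluating wearable EEG devices with
very few channels (F7-T7 / F8-T8 style montages), who need:

* a **seizure-detection pipeline** of the kind deployed on
  microcontroller-class wearables, reproduced on the desktop so its
  behaviour can be studied and scored properly;
* the **acquisition-quality math** used to qualify an EEG front end
  against clinical digital-EEG guidelines;
* **method-agreement analysis** for validating a new device against a
  reference amplifier recording the same physiology.

## What it computes

**Detection pipeline.** Records are band-pass filtered with a zero-phase
4th-order Butterworth over [1, 20] Hz, sliced into 4 s windows with a
0.5 s step (87.5 % overlap), and summarized by 56 features per window per
channel: line length, mean amplitude, mean, variance, standard deviation,
and the Hjorth parameters (activity, mobility, complexity); absolute and
relative band powers over delta/theta/alpha/beta; Shannon, Tsallis, Rényi,
sample and permutation entropy (two parameterizations each); and six
statistics over the five subbands of a 4-level Daubechies-4 wavelet
decomposition. A seeded random forest emits per-window ictal
probabilities p, smoothed causally by log-odds accumulation over a sliding
horizon *h*:

    odds(t) = prior/(1-prior) * prod_{i=t-h+1..t} p_i/(1-p_i)

Supra-threshold runs become alarm events, scored at the **event level**:

    Sens = Tp/(Tp+Fn)   Prec = Tp/(Tp+Fp)
    F1 = 2*Prec*Sens/(Prec+Sens)   FAR = Fp*24/total_time_h

under time-slice cross-validation (TSCV): every model trains only on data
strictly before its test slice, with a warm-up of at least 5 h containing
at least one seizure.

**Characterization.** From a shorted-input stream: input-referred noise
`IRN = sqrt(mean(v^2))`, peak-to-peak `6.6 * IRN`, and

    DR   = 20*log10( VREF / (sqrt(2)*Gain*IRN_rms) )     [dB]
    ENOB = log2( VREF / (sqrt(2)*Gain*V_rms) )           [bits]
    NFB  = log2( 2*VREF / (Gain*IRN_pp) )                [bits]
    CMRR = 20*log10( V_in_peak / V_out_inref_peak )      [dB]

plus an IFCN clinical digital-EEG compliance check (Fs >= 200 Hz,
resolution <= 0.5 uV/bit, impedance >= 100 MOhm, CMRR >= 110 dB,
IRN <= 1.5 uVpp).

**Agreement.** DTW-aligned Pearson correlation over 60 s windows (banded
dynamic time warping after band-limited resampling), Welch periodograms on
4 s epochs, and Bland-Altman analysis of per-bin PSD differences
(limits MD ± 1.96 SD).

## Worked example

```r
library(eegedge)

## characterize a simulated shorted-input bench stream (0.16 uV RMS)
nf  <- gen_noise_floor(synth_spec(fs = 250, duration_s = 60,
                                  noise_rms_uV = 0.16, seed = 8))
noise_report(nf)
#> <noise_report> IRN 0.161 uVrms / 1.07 uVpp | DR 118.29 dB | NFB 18.42 | ENOB 19.65 (n=15000)

## run the full TSCV seizure-detection pipeline on the default synthetic
## study: 10 x 1 h records, 12 annotated seizures (~40 s on one CPU)
recs <- default_seizure_dataset(seed = 42)
res  <- run_seizure_detection(recs, detect_config(seed = 1))
res$pooled
#> <event_score> Tp=6 Fp=0 Fn=0 | Sens=1.000 Prec=1.000 F1=1.000 FAR=0.00/day (5.00 h)

## dual-device agreement: same physiology at 250 vs 256 Hz with noise
rec  <- gen_background(synth_spec(fs = 250, duration_s = 65, seed = 11))
dev2 <- gen_dual_device(rec, fs2 = 256, jitter_s = 0.02, gain2 = 1.1,
                        noise2_uV = 2, seed = 3)
align_and_correlate(rec, dev2, window_s = 60)
#> [1] 0.970
```

Reading: the noise report says the simulated front end resolves ~18.4
noise-free bits and a 118 dB dynamic range at gain 24; the detector found
all 6 seizures in the 5 h of causally held-out test data with zero false
alarms; and the two simulated devices agree at r = 0.97 after warping away
their sampling-rate difference.

A command-line wrapper with `synth` / `detect` / `cwm` / `characterize` /
`agree` / `score` subcommands lives at `inst/cli/eegedge.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/eegedge.R", package="eegedge"))') synth --out data/`).

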