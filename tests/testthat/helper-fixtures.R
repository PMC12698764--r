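# Shared fixture builders; everything is generated in code at test time.

tiny_background <- function(fs = 64, duration_s = 30, seed = 11, ...) {
  gen_background(synth_spec(fs = fs, duration_s = duration_s, seed = seed, ...))
}

# A short two-record seizure set for fast pipeline checks.
tiny_seizure_records <- function(fs = 64, duration_s = 600, seed = 21,
                                 n_records = 2) {
  spec <- synth_spec(fs = fs, duration_s = duration_s,
                     background = list(slope = 1, rms_uV = 20,
                                       oscillations = list()),
                     noise_rms_uV = 0.5, seed = seed)
  tables <- lapply(seq_len(n_records), function(r) {
    data.frame(onset_s = 200 + 50 * r, duration_s = 40, freq_hz = 4,
               amp_uV = 100)
  })
  gen_seizure_dataset(spec, n_records = n_records, seizure_table = tables)
}

sine_recording <- function(freq, fs = 256, duration_s = 8, amp = 1) {
  tm <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  eeg_recording(cbind(amp * sin(2 * pi * freq * tm)), fs, "F7T7",
                montage = "bipolar")
}
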