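# Shared fixtures: tiny montages and quick synthetic datasets so tests
# stay fast while exercising the real code paths.

tiny_montage <- function() eegmatMontage()[c(1, 2, 8, 12, 21)]  # Fp1 Fp2 T3 C3 ECG

tone <- function(freqHz, fs, dur) {
  t <- seq_len(round(fs * dur)) / fs
  cos(2 * pi * freqHz * t)
}

make_recording <- function(subject = "s1", trial = "task", fs = 64,
                           dur = 2, channels = c("EEG Fp1", "EEG Fp2"),
                           seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(length(channels) * round(fs * dur)),
              length(channels), round(fs * dur),
              dimnames = list(channels, NULL))
  Recording(subject, trial, x, fs)
}

# Small two-class dataset already decomposed, for feature/classify tests.
small_dataset <- function(nGood = 3, nBad = 3, fs = 64, durTask = 2,
                          durBase = 2, effectSize = 2, seed = 7,
                          channels = c("EEG Fp1", "EEG T3"), K = 8) {
  out <- synthesizeRecordings(nGood = nGood, nBad = nBad, fs = fs,
                              durationTask = durTask,
                              durationBaseline = durBase,
                              channels = channels, effectSize = effectSize,
                              seed = seed)
  decomps <- lapply(out$recordings, decomposeRecording, K = K,
                    maxIter = 100, tol = 1e-6)
  list(decomps = decomps, labels = out$labels, recordings = out$recordings)
}
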