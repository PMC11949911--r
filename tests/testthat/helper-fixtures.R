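# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# Full-design simulation at the default (noisy) response model.
paperScaleSim <- function() {
  if (is.null(.fixtures$paperSim))
    .fixtures$paperSim <- simulateExperiment(experimentDesign(),
                                             responseModel(), seed = 101)
  .fixtures$paperSim
}

# Band-limited RMS of a buffer via the FFT (independent spectral oracle).
fftBandRms <- function(audio, lo, hi) {
  x <- rowMeans(samples(audio))
  n <- length(x)
  p <- Mod(fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * sampleRate(audio) / n
  keep <- f >= lo & f <= hi & f <= sampleRate(audio) / 2
  sqrt(2 * sum(p[keep]))
}

# Steady-state RMS (skips the first quarter to drop filter transients).
steadyRms <- function(audio) {
  x <- rowMeans(samples(audio))
  x <- x[-seq_len(length(x) %/% 4)]
  sqrt(mean(x^2))
}
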