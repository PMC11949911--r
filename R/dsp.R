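# Low-level signal operators used by the two filter chains. All operate
# per channel on plain numeric vectors; AudioBuffer plumbing lives in chain.R.

# Apply a function channel-wise to an AudioBuffer's sample matrix.
.perChannel <- function(audio, fun, ...) {
  s <- audio@samples
  out <- vapply(seq_len(ncol(s)), function(ch) fun(s[, ch], ...),
                numeric(nrow(s)))
  audioBuffer(matrix(out, ncol = ncol(s)), audio@sampleRate)
}

# Second-order peaking (peak/notch) equalizer biquad. `gain` is a linear
# amplitude multiplier at the center frequency: gain = 1 is an exact identity
# (b == a), gain > 1 boosts, gain < 1 cuts. Bandwidth parameterized via
# Q = center / bandwidth (audio-cookbook constant-Q peaking form with
# A = sqrt(gain)).
.peakEqCoef <- function(center, bandwidth, gain, fs) {
  A <- sqrt(gain)
  w0 <- 2 * pi * center / fs
  Q <- center / bandwidth
  alpha <- sin(w0) / (2 * Q)
  b <- c(1 + alpha * A, -2 * cos(w0), 1 - alpha * A)
  a <- c(1 + alpha / A, -2 * cos(w0), 1 - alpha / A)
  list(b = b / a[1], a = a / a[1])
}

.peakEq <- function(x, center, bandwidth, gain, fs) {
  if (gain == 1) return(x)
  co <- .peakEqCoef(center, bandwidth, gain, fs)
  .iirFilter(co$b, co$a, x)
}

# Second-order Butterworth sections: order 2 for low/high-pass, order 1 per
# edge (2 poles total) for band designs. Edges are clamped inside
# (0, Nyquist).
.butterCoef <- function(type, lo, hi, fs) {
  nyq <- fs / 2
  eps <- 1e-4
  W <- switch(type,
    low  = max(min(hi / nyq, 1 - eps), eps),
    high = max(min(lo / nyq, 1 - eps), eps),
    c(max(lo / nyq, eps), min(hi / nyq, 1 - eps)))
  n <- if (type %in% c("low", "high")) 2 else 1
  flt <- signal::butter(n, W, type = switch(type, low = "low", high = "high",
                                            pass = "pass", stop = "stop"))
  list(b = flt$b, a = flt$a)
}

.butterFilter <- function(x, type, lo, hi, fs) {
  co <- .butterCoef(type, lo, hi, fs)
  .iirFilter(co$b, co$a, x)
}

# Band edges are placed symmetrically around the center in prewarped (tan)
# space so the rejection zero of the bilinear design lands exactly on the
# commanded center frequency.
.bandReject <- function(x, center, width, fs) {
  if (width <= 0) return(x)
  hiMax <- fs / 2 - 1e-3
  width <- min(width, 2 * (hiMax - center), 2 * center - 2e-3)
  if (width <= 0) return(x)
  T0 <- tan(pi * center / fs)^2
  lo <- tryCatch(
    stats::uniroot(function(f1)
      tan(pi * f1 / fs) * tan(pi * (f1 + width) / fs) - T0,
      c(max(center - width, 1e-3), center - 1e-9))$root,
    error = function(e) max(center - width / 2, 1e-3))
  hi <- min(lo + width, hiMax)
  if (lo >= hi) return(x)
  .butterFilter(x, "stop", lo, hi, fs)
}

# Water effect: fixed two-band equalization (boost around 260 Hz, cut around
# 4.4 kHz) whose strength is one 0-1 control; the boost reaches +6 dB and the
# cut -6 dB at control 1.
.waterEffect <- function(x, control, fs) {
  if (control <= 0) return(x)
  x <- .peakEq(x, 260, 240, 10^(6 * control / 20), fs)
  .peakEq(x, 4400, 3600, 10^(-6 * control / 20), fs)
}

# Easing band-volume stage: low (<200 Hz), medium (band 1100/900 Hz
# center/bandwidth) and high (>2000 Hz) Butterworth splits, each scaled by
# its own gain and recombined additively against the dry signal so that unit
# gains are an exact identity:
#   y = x + (gLow-1) LP(x) + (gMed-1) BP(x) + (gHigh-1) HP(x)
# Band isolation is zero-phase (forward-backward filtering), so a band gain
# rescales its own band without phase-misalignment leakage into the others.
.butterZeroPhase <- function(x, type, lo, hi, fs) {
  co <- .butterCoef(type, lo, hi, fs)
  signal::filtfilt(co$b, co$a, x)
}

.bandVolumes <- function(x, gLow, gMed, gHigh, fs) {
  y <- x
  if (gLow != 1)
    y <- y + (gLow - 1) * .butterZeroPhase(x, "low", NA, 200, fs)
  if (gMed != 1)
    y <- y + (gMed - 1) * .butterZeroPhase(x, "pass", 650, 1550, fs)
  if (gHigh != 1)
    y <- y + (gHigh - 1) * .butterZeroPhase(x, "high", 2000, NA, fs)
  y
}

# FFT-based resampling to an arbitrary output length (band-limited sinc
# interpolation, as used for the 44.1 kHz -> 16 kHz frontend conversion).
.fftResample <- function(x, nOut) {
  n <- length(x)
  if (nOut == n) return(x)
  X <- fft(x)
  Y <- complex(nOut)
  m <- min(n, nOut)
  half <- floor((m - 1) / 2)
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(nOut - half + 1):nOut] <- X[(n - half + 1):n]
  }
  if (m %% 2 == 0) {
    # shared Nyquist bin: split evenly to keep the signal real
    ny <- X[m / 2 + 1]
    if (nOut < n) Y[nOut / 2 + 1] <- Re(ny) else {
      Y[m / 2 + 1] <- ny / 2
      Y[nOut - m / 2 + 1] <- Conj(ny) / 2
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}

# Phase-vocoder time stretch by `ratio` (output ratio times longer), hann
# analysis/synthesis windows of `nfft` with hop `hop`.
.pvStretch <- function(x, ratio, nfft = 2048, hop = 512) {
  n <- length(x)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)
  nOutFrames <- max(2L, floor((n - nfft) / (hop / ratio)) + 1L)
  anaPos <- pmin(pmax(round(seq(0, by = hop / ratio,
                                length.out = nOutFrames)), 0), n - nfft)
  frames <- vapply(anaPos, function(p) x[(p + 1):(p + nfft)] * win,
                   numeric(nfft))
  spec <- mvfft(frames)
  mag <- Mod(spec)
  ph <- Arg(spec)
  omega <- 2 * pi * (seq_len(nfft) - 1) / nfft  # bin frequency, rad/sample
  outPh <- matrix(0, nfft, nOutFrames)
  outPh[, 1] <- ph[, 1]
  for (k in 2:nOutFrames) {
    dAna <- anaPos[k] - anaPos[k - 1]
    dphi <- ph[, k] - ph[, k - 1] - omega * dAna
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))  # principal value
    trueFreq <- omega + dphi / dAna
    outPh[, k] <- outPh[, k - 1] + trueFreq * hop
  }
  outSpec <- mag * exp(1i * outPh)
  outFrames <- Re(mvfft(outSpec, inverse = TRUE)) / nfft
  nOut <- (nOutFrames - 1L) * hop + nfft
  y <- numeric(nOut)
  wsum <- numeric(nOut)
  for (k in seq_len(nOutFrames)) {
    idx <- ((k - 1L) * hop + 1L):((k - 1L) * hop + nfft)
    y[idx] <- y[idx] + outFrames[, k] * win
    wsum[idx] <- wsum[idx] + win^2
  }
  y / pmax(wsum, 1e-8)
}

# Duration-preserving pitch shift: phase-vocoder stretch by 2^(semitones/12)
# followed by FFT resampling back to the original length.
.pitchShift <- function(x, semitones) {
  if (semitones == 0) return(x)
  r <- 2^(semitones / 12)
  n <- length(x)
  stretched <- .pvStretch(x, r)
  out <- .fftResample(stretched, round(length(stretched) / r))
  if (length(out) >= n) out[seq_len(n)] else c(out, numeric(n - length(out)))
}
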