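# Identity and spectral contracts of the static filters and the two chains.

shortTone <- function(freq, amp = 0.3, dur = 0.5, channels = 1)
  sineBuffer(freq, dur, amp, channels = channels)

test_that("every filter at its default parameters is an identity transform", {
  x <- noiseBuffer(0.4, 0.3, seed = 3)
  for (task in c("Recollection", "Easing")) {
    spec <- filterSpecs(task)
    for (f in unique(spec$filter)) {
      if (f == "change_suppression") next  # needs >= 17 frames, tested below
      if (f == "tinnitus") next            # non-silent default, tested below
      y <- applyStaticFilter(x, f, task = task)
      # band_reject's default is a hairline 0.1 Hz notch: near-identity
      # (~ -66 dB residual over a short buffer), not bitwise identity
      tol <- if (f == "band_reject") 2e-3 else 1e-12
      expect_equal(samples(y), samples(x), tolerance = tol,
                   label = paste(task, f))
    }
  }
  # tinnitus: the documented default amplitude is non-silent; identity holds
  # at amplitude 0
  expect_equal(settingValues(defaultSettings("Recollection"))[[
    "tinnitus.amplitude"]], 0.05)
  y <- applyStaticFilter(x, "tinnitus", list(amplitude = 0))
  expect_identical(samples(y), samples(x))
  y <- applyStaticFilter(x, "noise", list(amplitude = 0))
  expect_identical(samples(y), samples(x))
})

test_that("unknown names and out-of-range parameters are rejected", {
  x <- shortTone(440)
  expect_error(applyStaticFilter(x, "reverse"), "unknown filter")
  expect_error(applyStaticFilter(x, "amplify_all", list(gain = 6)),
               "out-of-range")
  expect_error(applyStaticFilter(x, "amplify_all", list(volume = 2)),
               "unknown parameter")
})

test_that("band equalizers boost monotonically in band and spare far bands", {
  bands <- list(amplify_low = c(50, 150, probe = 100, far = 8000),
                amplify_medium = c(650, 1550, probe = 1100, far = 12000),
                amplify_high = c(6000, 16000, probe = 11100, far = 100))
  for (f in names(bands)) {
    b <- bands[[f]]
    inTone <- shortTone(b[["probe"]], dur = 1)
    prev <- -Inf
    for (g in c(2, 3.5, 5)) {
      y <- applyStaticFilter(inTone, f, list(gain = g))
      gainDb <- 20 * log10(steadyRms(y) / steadyRms(inTone))
      expect_gt(gainDb, prev)
      expect_gt(gainDb, 1)  # a real boost at the center
      prev <- gainDb
    }
    far <- shortTone(b[["far"]], dur = 1)
    yFar <- applyStaticFilter(far, f, list(gain = 5))
    expect_lt(abs(20 * log10(steadyRms(yFar) / steadyRms(far))), 1)
  }
})

test_that("band reject notches the center and deepens with width", {
  tone <- shortTone(1000, dur = 1)
  ref <- shortTone(100, dur = 1)
  y <- applyStaticFilter(tone, "band_reject",
                         list(center = 1000, width = 500))
  yRef <- applyStaticFilter(ref, "band_reject",
                            list(center = 1000, width = 500))
  attCenter <- 20 * log10(steadyRms(y) / steadyRms(tone))
  attPass <- 20 * log10(steadyRms(yRef) / steadyRms(ref))
  expect_lt(attCenter, -20)
  expect_gt(attPass, -1)
  # attenuation of a fixed off-center tone grows with width
  probe <- shortTone(1300, dur = 1)
  atts <- vapply(c(200, 800, 2000), function(w) {
    yy <- applyStaticFilter(probe, "band_reject",
                            list(center = 1000, width = w))
    20 * log10(steadyRms(yy) / steadyRms(probe))
  }, numeric(1))
  expect_true(all(diff(atts) < 0))
})

test_that("additive filters put energy where they say", {
  x <- silenceBuffer(0.5)
  y <- applyStaticFilter(x, "tinnitus",
                         list(amplitude = 0.05, frequency = 2000))
  expect_gt(fftBandRms(y, 1950, 2050), 0.03)
  expect_lt(fftBandRms(y, 100, 1800), 1e-6)
  n1 <- applyStaticFilter(x, "noise", list(amplitude = 0.02), noiseSeed = 4)
  n2 <- applyStaticFilter(x, "noise", list(amplitude = 0.02), noiseSeed = 4)
  n3 <- applyStaticFilter(x, "noise", list(amplitude = 0.02), noiseSeed = 5)
  expect_identical(samples(n1), samples(n2))
  expect_false(identical(samples(n1), samples(n3)))
  expect_lte(max(abs(samples(n1))), 0.02)
})

test_that("echo and flanger are identities at zero mix and act when active", {
  x <- shortTone(500)
  expect_equal(samples(applyStaticFilter(x, "echo", list(mix = 0))),
               samples(x))
  expect_equal(samples(applyStaticFilter(x, "flanger", list(power = 0))),
               samples(x))
  e <- applyStaticFilter(x, "echo", list(mix = 0.8))
  expect_gt(max(abs(samples(e) - samples(x))), 0.01)
  fl <- applyStaticFilter(x, "flanger", list(power = 1, frequency = 1))
  expect_gt(max(abs(samples(fl) - samples(x))), 0.01)
})

test_that("water effect boosts its low band and cuts its high band", {
  lo <- shortTone(260, dur = 1)
  hi <- shortTone(4400, dur = 1)
  yLo <- applyStaticFilter(lo, "water_effect", list(gain = 1))
  yHi <- applyStaticFilter(hi, "water_effect", list(gain = 1))
  expect_gt(20 * log10(steadyRms(yLo) / steadyRms(lo)), 3)
  expect_lt(20 * log10(steadyRms(yHi) / steadyRms(hi)), -3)
})

test_that("easing band volumes scale their own band and can silence all", {
  lo <- shortTone(100, dur = 1)
  hi <- shortTone(8000, dur = 1)
  y <- applyStaticFilter(lo, "volume_low", list(gain = 0))
  expect_lt(steadyRms(y) / steadyRms(lo), 0.1)
  yHi <- applyStaticFilter(hi, "volume_low", list(gain = 0))
  expect_gt(steadyRms(yHi) / steadyRms(hi), 0.9)  # other bands untouched
  s <- filterSettings("Easing", "volume_all.gain" = 0)
  out <- applyChain(shortTone(440), s)
  expect_equal(max(abs(samples(out))), 0)
})

test_that("pitch shift is duration-preserving and moves the spectral peak", {
  x <- sineBuffer(440, 1, 0.4)
  up <- applyStaticFilter(x, "pitch_shift", list(semitones = 12))
  down <- applyStaticFilter(x, "pitch_shift", list(semitones = -12))
  expect_equal(nSamples(up), nSamples(x))
  expect_equal(nSamples(down), nSamples(x))
  peakHz <- function(a) {
    sp <- Mod(fft(samples(a)[, 1]))
    half <- seq_len(nSamples(a) %/% 2)
    (which.max(sp[half]) - 1) * sampleRate(a) / nSamples(a)
  }
  expect_equal(peakHz(up), 880, tolerance = 0.03)
  expect_equal(peakHz(down), 220, tolerance = 0.03)
})

test_that("base volume adjustment follows the correction curve", {
  x <- shortTone(440, amp = 0.05)
  expect_equal(samples(baseVolumeAdjust(x, 0.5)), samples(x))
  y <- baseVolumeAdjust(x, 0)  # +16 dB
  expect_equal(max(abs(samples(y))) / max(abs(samples(x))), 10^(16 / 20),
               tolerance = 1e-9)
  z <- baseVolumeAdjust(x, 1)  # -16 dB
  expect_equal(max(abs(samples(z))) / max(abs(samples(x))), 10^(-16 / 20),
               tolerance = 1e-9)
  expect_error(baseVolumeAdjust(x, 1.5), "0, 1")
})

test_that("full chains preserve length, clip output, and are deterministic", {
  x <- noiseBuffer(0.6, 0.4, seed = 9, channels = 2)
  for (task in c("Recollection", "Easing")) {
    out <- applyChain(x, defaultSettings(task), o = 0.5)
    expect_equal(samples(out), samples(x), tolerance = 1e-12,
                 label = paste(task, "default chain"))
  }
  s <- filterSettings("Recollection", "amplify_all.gain" = 2)
  out2 <- applyChain(x, s)
  expect_equal(samples(out2), pmin(pmax(samples(x) * 2, -1), 1))
  busy <- filterSettings("Easing", "volume_high.gain" = 0.3,
                         "noise.amplitude" = 0.02,
                         "pitch_shift.semitones" = 3,
                         "echo.mix" = 0.4)
  a <- applyChain(x, busy, noiseSeed = 11)
  b <- applyChain(x, busy, noiseSeed = 11)
  expect_identical(samples(a), samples(b))
  expect_equal(nSamples(a), nSamples(x))
  expect_lte(max(abs(samples(a))), 1)
  expect_error(applyChain(x, filterSettings("Recollection"), o = 2), "0, 1")
})

test_that("stereo processing equals channel-wise mono processing", {
  left <- sin(2 * pi * 300 * seq_len(22050) / 44100) * 0.3
  right <- sin(2 * pi * 700 * seq_len(22050) / 44100) * 0.2
  st <- audioBuffer(cbind(left, right))
  y <- applyStaticFilter(st, "amplify_medium", list(gain = 3))
  yl <- applyStaticFilter(audioBuffer(left), "amplify_medium",
                          list(gain = 3))
  yr <- applyStaticFilter(audioBuffer(right), "amplify_medium",
                          list(gain = 3))
  expect_equal(samples(y)[, 1], samples(yl)[, 1])
  expect_equal(samples(y)[, 2], samples(yr)[, 1])
})
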