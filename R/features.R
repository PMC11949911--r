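# Model-input construction: audio embeddings and normalized covariates.

# --- log-mel frontend ------------------------------------------------------

# HTK mel scale
.hzToMel <- function(f) 2595 * log10(1 + f / 700)
.melToHz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank, nMels x (nfft/2 + 1)
.melFilterbank <- function(nMels, nfft, fs, fmin, fmax) {
  mels <- seq(.hzToMel(fmin), .hzToMel(fmax), length.out = nMels + 2)
  hz <- .melToHz(mels)
  bins <- hz / (fs / nfft)
  nBins <- nfft / 2 + 1
  fb <- matrix(0, nMels, nBins)
  k <- seq_len(nBins) - 1
  for (m in seq_len(nMels)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    up <- (k - lo) / (ce - lo)
    down <- (hi - k) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Short-time log-mel spectrogram with the frontend framing: 25 ms windows,
# 10 ms hop, 64 mel bands over 125-7500 Hz at 16 kHz.
.logMelFrames <- function(x, fs = 16000, winLen = 400, hop = 160,
                          nfft = 512, nMels = 64, fmin = 125, fmax = 7500) {
  n <- length(x)
  nFrames <- 1L + floor((n - winLen) / hop)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(winLen) - 1) / winLen)
  idx <- outer(seq_len(winLen), (seq_len(nFrames) - 1L) * hop, `+`)
  frames <- matrix(x[idx], winLen, nFrames) * win
  frames <- rbind(frames, matrix(0, nfft - winLen, nFrames))
  spec <- mvfft(frames)[seq_len(nfft / 2 + 1), , drop = FALSE]
  power <- Mod(spec)^2
  fb <- .melFilterbank(nMels, nfft, fs, fmin, fmax)
  mel <- fb %*% power
  t(log(mel + 1e-3))  # nFrames x nMels
}

# Fixed Gaussian projection used by the fallback frontend (seeded, so the
# embedding is a deterministic function of the audio).
.fallbackProjection <- function(dIn, dOut, seed = 20240401) {
  .withSeed(seed, matrix(rnorm(dIn * dOut), dIn, dOut)) / sqrt(dIn)
}

#' Embed a stimulus into 41 x 1024 feature frames
#'
#' Converts the audio to 16 kHz and computes the per-patch embedding used as
#' the recurrent model's sequence input: for a 20-second clip, 41 feature
#' frames of 1024 features each. Inputs shorter than 20 s are loop-padded and
#' longer ones trimmed, mirroring the stimulus preparation.
#'
#' The `"fallback"` frontend (default, self-contained) computes log-mel
#' spectrogram patches with the standard framing of the pretrained audio
#' frontend — 0.96 s patch windows hopped by 0.48 s over 10 ms mel frames,
#' with the waveform right-padded by one patch hop so a 20-s clip yields
#' exactly 41 patches — and projects each flattened 96 x 64 patch to 1024
#' dimensions through a fixed seeded Gaussian matrix. The `"pretrained"`
#' frontend requires the pretrained YAMNet weights, which must be downloaded
#' separately; when unavailable an error points to the fallback. Both yield
#' the same shape, so downstream code is frontend-agnostic.
#'
#' @param audio an [AudioBuffer-class].
#' @param frontend `"fallback"` or `"pretrained"`.
#' @param projectionSeed seed of the fallback projection matrix.
#' @return numeric matrix, 41 x 1024 for a 20-s input, with attribute
#'   `"frontend"`.
#' @examples
#' emb <- embedAudio(sineBuffer(440, duration = 20, amplitude = 0.1))
#' dim(emb)  # 41 1024
#' @export
embedAudio <- function(audio, frontend = c("fallback", "pretrained"),
                       projectionSeed = 20240401) {
  stopifnot(is(audio, "AudioBuffer"))
  frontend <- match.arg(frontend)
  if (frontend == "pretrained")
    stop("the pretrained frontend needs the downloadable YAMNet weights, ",
         "which are not bundled; use frontend = \"fallback\" for the ",
         "self-contained log-mel embedding of identical shape")
  x <- rowMeans(audio@samples)  # mono mix
  fs <- audio@sampleRate
  target <- round(20 * fs)
  if (length(x) < target) x <- rep_len(x, target)  # loop-pad
  if (length(x) > target) x <- x[seq_len(target)]
  x16 <- if (fs == 16000) x else .fftResample(x, round(length(x) * 16000 / fs))
  x16 <- c(x16, numeric(7680))  # right-pad one patch hop (0.48 s)
  lm <- .logMelFrames(x16)
  patchLen <- 96L; patchHop <- 48L
  nPatches <- 1L + floor((nrow(lm) - patchLen) / patchHop)
  P <- .fallbackProjection(patchLen * ncol(lm), 1024L, projectionSeed)
  out <- matrix(0, nPatches, 1024L)
  for (k in seq_len(nPatches)) {
    rows <- ((k - 1L) * patchHop + 1L):((k - 1L) * patchHop + patchLen)
    out[k, ] <- as.numeric(t(lm[rows, , drop = FALSE])) %*% P
  }
  attr(out, "frontend") <- "fallback"
  out
}

# --- covariates ------------------------------------------------------------

.covariateBounds <- list(
  sleep_minutes = c(0, 1440), fatigue_physical = c(1, 7),
  fatigue_mental = c(1, 7), age = c(20, 64), aq = c(0, 50),
  aasp_low_registration = c(15, 75), aasp_sensation_seeking = c(15, 75),
  aasp_sensory_sensitivity = c(15, 75), aasp_sensation_avoiding = c(15, 75),
  aasp_auditory_total = c(11, 55), volume_correction = c(-16, 16))

#' Covariate component order
#'
#' Fixed, documented order of the unit-scaled covariate vector: session state
#' (sleep, physical and mental fatigue), participant characteristics (age,
#' one-hot sex, AQ, the four AASP quadrant scores, the AASP auditory total),
#' then environment (volume correction in dB scaled over \[-16, 16\], one-hot
#' Bluetooth profile).
#'
#' @return character vector of component names (length 15).
#' @export
covariateSchema <- function() {
  c("sleep_minutes", "fatigue_physical", "fatigue_mental", "age",
    "sex_female", "sex_male", "aq", "aasp_low_registration",
    "aasp_sensation_seeking", "aasp_sensory_sensitivity",
    "aasp_sensation_avoiding", "aasp_auditory_total",
    "volume_correction", "bt_a2dp", "bt_hfp")
}

#' @describeIn covariateSchema the Easing model's extended schema: the base
#'   covariates followed by the 13 normalized Recollection filter parameters
#'   and the 5 normalized Recollection ratings.
#' @export
easingInputSchema <- function() {
  c(covariateSchema(),
    paste0("recollection.", filterSpecs("Recollection")$key),
    paste0("recollection.rating_", ratingItems()))
}

#' Build the unit-scaled covariate vector
#'
#' Min-max scales every numeric field by its instrument-defined bounds (sleep
#' 0-1440 min, fatigue 1-7, age 20-64, AQ 0-50, AASP quadrants 15-75, AASP
#' auditory total 11-55, volume correction -16 to 16 dB) and one-hot encodes
#' sex and Bluetooth profile. Component order is [covariateSchema()].
#'
#' @param profile named list: `group` ("DD"/"TD"), `age`, `sex`
#'   ("female"/"male"), `aq`, `aasp_low_registration`,
#'   `aasp_sensation_seeking`, `aasp_sensory_sensitivity`,
#'   `aasp_sensation_avoiding`, `aasp_auditory_total`.
#' @param state named list: `sleep_minutes`, `fatigue_physical`,
#'   `fatigue_mental`, `bluetooth` ("A2DP"/"HFP").
#' @param volumeCorrection correction A in dB (see [volumeCorrectionDb()]).
#' @return named numeric vector in \[0, 1\], ordered by [covariateSchema()].
#' @export
buildCovariates <- function(profile, state, volumeCorrection) {
  sc <- function(field, value) {
    b <- .covariateBounds[[field]]
    if (!is.finite(value) || value < b[1] - 1e-9 || value > b[2] + 1e-9)
      stop("covariate '", field, "' = ", value, " outside [",
           b[1], ", ", b[2], "]")
    (value - b[1]) / (b[2] - b[1])
  }
  if (!profile$sex %in% c("female", "male"))
    stop("covariate 'sex' must be 'female' or 'male'")
  if (!state$bluetooth %in% c("A2DP", "HFP"))
    stop("covariate 'bluetooth' must be 'A2DP' or 'HFP'")
  v <- c(
    sleep_minutes = sc("sleep_minutes", state$sleep_minutes),
    fatigue_physical = sc("fatigue_physical", state$fatigue_physical),
    fatigue_mental = sc("fatigue_mental", state$fatigue_mental),
    age = sc("age", profile$age),
    sex_female = as.numeric(profile$sex == "female"),
    sex_male = as.numeric(profile$sex == "male"),
    aq = sc("aq", profile$aq),
    aasp_low_registration = sc("aasp_low_registration",
                               profile$aasp_low_registration),
    aasp_sensation_seeking = sc("aasp_sensation_seeking",
                                profile$aasp_sensation_seeking),
    aasp_sensory_sensitivity = sc("aasp_sensory_sensitivity",
                                  profile$aasp_sensory_sensitivity),
    aasp_sensation_avoiding = sc("aasp_sensation_avoiding",
                                 profile$aasp_sensation_avoiding),
    aasp_auditory_total = sc("aasp_auditory_total",
                             profile$aasp_auditory_total),
    volume_correction = sc("volume_correction", volumeCorrection),
    bt_a2dp = as.numeric(state$bluetooth == "A2DP"),
    bt_hfp = as.numeric(state$bluetooth == "HFP"))
  v[covariateSchema()]
}

#' Extend covariates with Recollection outputs for the Easing model
#'
#' Appends the 13 min-max normalized Recollection filter parameters and the
#' five Recollection stress ratings scaled from the 1-7 scale onto \[0, 1\].
#'
#' @param covariates base covariate vector from [buildCovariates()].
#' @param recollectionSettings a [FilterSettings-class] with task
#'   `"Recollection"`.
#' @param recollectionRatings numeric vector of the five 1-7 ratings, ordered
#'   as [ratingItems()].
#' @return named numeric vector ordered by [easingInputSchema()].
#' @export
buildEasingInputs <- function(covariates, recollectionSettings,
                              recollectionRatings) {
  stopifnot(is(recollectionSettings, "FilterSettings"))
  if (settingTask(recollectionSettings) != "Recollection")
    stop("recollectionSettings must be for the Recollection task")
  if (length(recollectionRatings) != 5)
    stop("recollectionRatings must have the five rating items")
  out <- c(covariates,
           setNames(normalizeSettings(recollectionSettings),
                    paste0("recollection.", filterSpecs("Recollection")$key)),
           setNames(normalizeRatings(recollectionRatings),
                    paste0("recollection.rating_", ratingItems())))
  out[easingInputSchema()]
}
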