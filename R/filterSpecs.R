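# Registry of every auditory filter parameter in the two task chains.
# Ranges and defaults follow the protocol's filter tables; the tinnitus
# amplitude default is clamped into its printed range (see vignette).

.recollectionSpec <- data.frame(
  filter  = c("amplify_all", "amplify_low", "amplify_medium", "amplify_high",
              "noise", "tinnitus", "tinnitus", "band_reject", "band_reject",
              "echo", "flanger", "flanger", "water_effect"),
  param   = c("gain", "gain", "gain", "gain",
              "amplitude", "amplitude", "frequency", "width", "center",
              "mix", "power", "frequency", "gain"),
  default = c(1, 1, 1, 1, 0, 0.05, 1000, 0.1, 1000, 0, 0, 0.1, 0),
  min     = c(1, 1, 1, 1, 0, 0, 20, 0, 20, 0, 0, 0.1, 0),
  max     = c(5, 5, 5, 5, 0.05, 0.05, 5000, 5000, 5000, 1, 1, 10, 1),
  stringsAsFactors = FALSE)

.easingSpec <- data.frame(
  filter  = c("volume_low", "volume_medium", "volume_high", "pitch_shift",
              "change_suppression", "change_suppression", "change_suppression",
              "volume_all", "noise", "tinnitus", "tinnitus",
              "band_reject", "band_reject", "echo", "flanger", "flanger",
              "water_effect"),
  param   = c("gain", "gain", "gain", "semitones",
              "threshold", "suppression", "back_time",
              "gain", "amplitude", "amplitude", "frequency",
              "width", "center", "mix", "power", "frequency", "gain"),
  default = c(1, 1, 1, 0, 0.0015, 1, 0.05, 1, 0, 0.05, 1000,
              0.1, 1000, 0, 0, 0.1, 0),
  min     = c(0, 0, 0, -12, 0, 0.2, 0.05, 0, 0, 0, 20, 0, 20, 0, 0, 0.1, 0),
  max     = c(5, 5, 5, 12, 0.015, 1, 10, 5, 0.05, 0.05, 5000,
              5000, 5000, 1, 1, 10, 1),
  stringsAsFactors = FALSE)

.withKeys <- function(spec) {
  spec$key <- paste(spec$filter, spec$param, sep = ".")
  spec
}
.recollectionSpec <- .withKeys(.recollectionSpec)
.easingSpec <- .withKeys(.easingSpec)

#' Filter parameter registry
#'
#' Returns the registry of tunable filter parameters for one task: one row per
#' scalar parameter with its owning filter, default value and valid range.
#' The Recollection chain exposes 13 parameters, the Easing chain 17.
#'
#' @param task `"Recollection"` or `"Easing"`.
#' @return data.frame with columns `filter`, `param`, `key`
#'   (`"<filter>.<param>"`), `default`, `min`, `max`.
#' @examples
#' nrow(filterSpecs("Recollection"))  # 13
#' nrow(filterSpecs("Easing"))        # 17
#' @export
filterSpecs <- function(task = c("Recollection", "Easing")) {
  task <- match.arg(task)
  if (task == "Recollection") .recollectionSpec else .easingSpec
}

#' @describeIn filterSpecs all-default settings for a task.
#' @export
defaultSettings <- function(task = c("Recollection", "Easing")) {
  filterSettings(match.arg(task))
}

#' @describeIn filterSpecs names of the five subjective stress rating items.
#' @export
ratingItems <- function() {
  c("overall", "painful", "distracting", "anxious", "impeditive")
}

#' Min-max normalization of filter settings and ratings
#'
#' Filter parameters are scaled onto \[0, 1\] with each parameter's declared
#' range, `x_norm = (x - min) / (max - min)`; ratings are scaled with minimum
#' 1 and maximum 7. `denormalizeSettings()` and `denormalizeRatings()` invert
#' the maps exactly, so round-trips are identities to numerical precision.
#'
#' @param settings a [FilterSettings-class] object.
#' @return `normalizeSettings`: named numeric vector in \[0, 1\].
#' @examples
#' normalizeSettings(filterSettings("Recollection", "amplify_all.gain" = 3))
#' @export
normalizeSettings <- function(settings) {
  stopifnot(is(settings, "FilterSettings"))
  validObject(settings)
  spec <- filterSpecs(settings@task)
  setNames((settings@values - spec$min) / (spec$max - spec$min), spec$key)
}

#' @describeIn normalizeSettings map a unit-scale vector back to native
#'   parameter values.
#' @param x numeric vector with components in \[0, 1\] (settings: ordered by
#'   the task's parameter keys; ratings: 5 items).
#' @param task `"Recollection"` or `"Easing"`.
#' @export
denormalizeSettings <- function(x, task = c("Recollection", "Easing")) {
  task <- match.arg(task)
  spec <- filterSpecs(task)
  x <- as.numeric(x)
  if (length(x) != nrow(spec))
    stop(sprintf("expected %d components for the %s task", nrow(spec), task))
  if (any(x < -1e-9 | x > 1 + 1e-9))
    stop("unit-scale components must lie in [0, 1]")
  v <- spec$min + pmin(pmax(x, 0), 1) * (spec$max - spec$min)
  new("FilterSettings", task = task, values = setNames(v, spec$key))
}

#' @describeIn normalizeSettings scale 1-7 ratings onto \[0, 1\].
#' @param ratings numeric vector of ratings on the 1-7 scale.
#' @export
normalizeRatings <- function(ratings) {
  ratings <- as.numeric(ratings)
  if (any(!is.finite(ratings)) || any(ratings < 1 | ratings > 7))
    stop("ratings must lie in [1, 7]")
  (ratings - 1) / 6
}

#' @describeIn normalizeSettings map unit-scale ratings back to the 1-7 scale
#'   (continuous; not rounded).
#' @export
denormalizeRatings <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x < -1e-9 | x > 1 + 1e-9))
    stop("unit-scale components must lie in [0, 1]")
  1 + pmin(pmax(x, 0), 1) * 6
}

#' Volume correction in decibels
#'
#' Correction applied before the filter chain when the device volume setting
#' `o` differs from its 0.5 midpoint: `A = 2.0 * (0.5 - o) / 0.0625`
#' = `32 * (0.5 - o)` dB, spanning +16 dB at `o = 0` to -16 dB at `o = 1`.
#'
#' @param o device volume setting in \[0, 1\].
#' @return Correction A in dB.
#' @examples
#' volumeCorrectionDb(0.5)  # 0
#' volumeCorrectionDb(0)    # +16
#' @export
volumeCorrectionDb <- function(o) {
  if (any(!is.finite(o)) || any(o < 0 | o > 1))
    stop("volume setting o must lie in [0, 1]")
  2.0 * (0.5 - o) / 0.0625
}

#' @describeIn volumeCorrectionDb the averaging window of the
#'   change-suppression detector in milliseconds: 16 analysis frames of
#'   `frameLength` samples.
#' @param frameLength analysis frame length in samples (default 1024).
#' @param sampleRate sampling rate in Hz (default 44100).
#' @export
changeSuppressionWindowMs <- function(frameLength = 1024, sampleRate = 44100) {
  16 * frameLength / sampleRate * 1000
}
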