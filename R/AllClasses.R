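#' @import methods
#' @importFrom stats fft rnorm runif setNames sd cor mvfft approx
#' @importFrom utils head tail
#' @useDynLib hearease, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' In-memory audio buffer
#'
#' `AudioBuffer` holds a sampled waveform as a numeric matrix with one column
#' per channel (1 = mono, 2 = stereo), together with its sampling rate in Hz.
#' Amplitudes are dimensionless and nominally lie in \[-1, 1\]; intermediate
#' processing stages may exceed that range, and the filter chain hard-clips
#' only at its output.
#'
#' @slot samples numeric matrix, `nSamples x nChannels`.
#' @slot sampleRate numeric scalar, Hz.
#' @export
setClass("AudioBuffer",
  representation(samples = "matrix", sampleRate = "numeric"))

setValidity("AudioBuffer", function(object) {
  msg <- character()
  if (!is.numeric(object@samples)) msg <- c(msg, "samples must be numeric")
  if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
      object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "all sample values must be finite")
  nc <- ncol(object@samples)
  if (!nc %in% c(1L, 2L)) msg <- c(msg, "channels must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct an AudioBuffer
#'
#' @param samples numeric vector (mono) or matrix with one column per channel.
#' @param sampleRate sampling rate in Hz (default 44100).
#' @return An [AudioBuffer-class] object.
#' @examples
#' tone <- sineBuffer(440, duration = 0.5)
#' duration(tone)
#' @export
audioBuffer <- function(samples, sampleRate = 44100) {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1L)
  new("AudioBuffer", samples = samples, sampleRate = as.numeric(sampleRate))
}

#' @describeIn audioBuffer number of sample frames.
#' @param x an `AudioBuffer`.
#' @export
nSamples <- function(x) nrow(x@samples)

#' @describeIn audioBuffer number of channels (1 or 2).
#' @export
nChannels <- function(x) ncol(x@samples)

#' @describeIn audioBuffer duration in seconds.
#' @export
duration <- function(x) nrow(x@samples) / x@sampleRate

#' @describeIn audioBuffer the sample matrix (`nSamples x nChannels`).
#' @export
samples <- function(x) x@samples

#' @describeIn audioBuffer sampling rate in Hz.
#' @export
sampleRate <- function(x) x@sampleRate

setMethod("show", "AudioBuffer", function(object) {
  cat(sprintf("AudioBuffer: %d samples x %d channel(s), %g Hz (%.3f s)\n",
              nSamples(object), nChannels(object), sampleRate(object),
              duration(object)))
})

#' Task-specific filter settings
#'
#' A named, validated parameter vector for one task's filter chain: 13 scalar
#' parameters for the Recollection task, 17 for the Easing task. Values are on
#' their native (denormalized) scales and must lie within the declared ranges
#' (see [filterSpecs()]).
#'
#' @slot task `"Recollection"` or `"Easing"`.
#' @slot values named numeric vector keyed `<filter>.<param>`.
#' @export
setClass("FilterSettings",
  representation(task = "character", values = "numeric"))

setValidity("FilterSettings", function(object) {
  if (!object@task %in% c("Recollection", "Easing"))
    return("task must be 'Recollection' or 'Easing'")
  spec <- filterSpecs(object@task)
  v <- object@values
  if (!identical(names(v), spec$key))
    return(sprintf("values must be named exactly by the %d %s parameter keys",
                   nrow(spec), object@task))
  if (!all(is.finite(v))) return("all values must be finite")
  bad <- which(v < spec$min - 1e-12 | v > spec$max + 1e-12)
  if (length(bad))
    return(sprintf("out-of-range parameter(s): %s",
                   paste(spec$key[bad], collapse = ", ")))
  TRUE
})

#' Construct FilterSettings
#'
#' Starts from the task defaults and overrides the named parameters supplied
#' in `...` (or as a named vector/list via `values`).
#'
#' @param task `"Recollection"` or `"Easing"`.
#' @param ... named parameter overrides, e.g. `"amplify_all.gain" = 2`.
#' @param values alternatively, a named numeric vector/list of overrides.
#' @return A [FilterSettings-class] object.
#' @examples
#' s <- filterSettings("Recollection", "amplify_all.gain" = 2)
#' settingValues(s)[["amplify_all.gain"]]
#' @export
filterSettings <- function(task = c("Recollection", "Easing"), ...,
                           values = NULL) {
  task <- match.arg(task)
  spec <- filterSpecs(task)
  v <- setNames(spec$default, spec$key)
  ov <- c(list(...), as.list(values))
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov))))
      stop("all overrides must be named")
    unknown <- setdiff(names(ov), spec$key)
    if (length(unknown))
      stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
    v[names(ov)] <- as.numeric(unlist(ov))
  }
  new("FilterSettings", task = task, values = v)
}

#' @describeIn filterSettings the named value vector.
#' @param x a `FilterSettings` object.
#' @export
settingValues <- function(x) x@values

#' @describeIn filterSettings the task the settings belong to.
#' @export
settingTask <- function(x) x@task

setMethod("show", "FilterSettings", function(object) {
  spec <- filterSpecs(object@task)
  changed <- object@values != setNames(spec$default, spec$key)
  cat(sprintf("FilterSettings (%s task): %d parameters, %d non-default\n",
              object@task, length(object@values), sum(changed)))
  if (any(changed)) {
    for (k in names(object@values)[changed])
      cat(sprintf("  %s = %g\n", k, object@values[[k]]))
  }
})

#' Trained (or untrained) predictor bundle
#'
#' Bundles the network weights with the configuration, the ordered output
#' schema (filter parameter keys followed by the five stress-rating items),
#' and normalization metadata, so that predictions can always be mapped back
#' to native units.
#'
#' @slot task `"Recollection"` or `"Easing"`.
#' @slot config list, see [modelConfig()].
#' @slot weights list of numeric arrays (empty until trained/initialized).
#' @slot outputSchema character vector of output names (length 18 or 22).
#' @slot covariateSchema character vector of covariate component names.
#' @slot trained logical scalar.
#' @slot lossTrace numeric vector of per-epoch mean training losses.
#' @export
setClass("ModelBundle",
  representation(task = "character", config = "list", weights = "list",
                 outputSchema = "character", covariateSchema = "character",
                 trained = "logical", lossTrace = "numeric"))

setValidity("ModelBundle", function(object) {
  if (!object@task %in% c("Recollection", "Easing"))
    return("task must be 'Recollection' or 'Easing'")
  expect <- nrow(filterSpecs(object@task)) + length(ratingItems())
  if (length(object@outputSchema) != expect)
    return(sprintf("outputSchema must have %d entries", expect))
  TRUE
})

setMethod("show", "ModelBundle", function(object) {
  cat(sprintf("ModelBundle (%s task): %s, %d outputs, lstm %d/direction, dense [%s]\n",
              object@task,
              if (object@trained) "trained" else "untrained",
              length(object@outputSchema),
              object@config$lstmHidden,
              paste(object@config$denseWidths, collapse = ", ")))
  if (object@trained && length(object@lossTrace))
    cat(sprintf("  %d epochs, final MSE %.5g\n",
                length(object@lossTrace), tail(object@lossTrace, 1)))
})
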