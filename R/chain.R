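# The two task filter chains and their stages.

#' Test-signal constructors
#'
#' Convenience constructors for pure tones, uniform white noise and silence,
#' used throughout the examples and tests.
#'
#' @param freq tone frequency in Hz.
#' @param duration length in seconds.
#' @param amplitude peak amplitude.
#' @param sampleRate sampling rate in Hz.
#' @param channels 1 (mono) or 2 (stereo).
#' @param seed RNG seed for the noise draw.
#' @return An [AudioBuffer-class].
#' @export
sineBuffer <- function(freq, duration = 1, amplitude = 0.5,
                       sampleRate = 44100, channels = 1) {
  t <- seq_len(round(duration * sampleRate)) / sampleRate
  x <- amplitude * sin(2 * pi * freq * t)
  audioBuffer(matrix(rep(x, channels), ncol = channels), sampleRate)
}

#' @describeIn sineBuffer uniform white noise in `[-amplitude, amplitude]`.
#' @export
noiseBuffer <- function(duration = 1, amplitude = 0.5, sampleRate = 44100,
                        channels = 1, seed = 1) {
  n <- round(duration * sampleRate)
  x <- .withSeed(seed, matrix(runif(n * channels, -amplitude, amplitude),
                              ncol = channels))
  audioBuffer(x, sampleRate)
}

#' @describeIn sineBuffer all-zero buffer.
#' @export
silenceBuffer <- function(duration = 1, sampleRate = 44100, channels = 1) {
  audioBuffer(matrix(0, round(duration * sampleRate), channels), sampleRate)
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Base volume correction
#'
#' Scales the audio by the linear factor `10^(A/20)` where
#' `A = volumeCorrectionDb(o)`; at the midpoint `o = 0.5` the audio is
#' unchanged. Applied as the first stage of both chains. The output is
#' clipped to \[-1, 1\].
#'
#' @param audio an [AudioBuffer-class].
#' @param o device volume setting in \[0, 1\].
#' @return An [AudioBuffer-class].
#' @export
baseVolumeAdjust <- function(audio, o) {
  stopifnot(is(audio, "AudioBuffer"))
  A <- volumeCorrectionDb(o)
  clipAudio(audioBuffer(audio@samples * 10^(A / 20), audio@sampleRate))
}

#' @describeIn baseVolumeAdjust hard-clip all samples to \[-1, 1\].
#' @export
clipAudio <- function(audio) {
  audioBuffer(pmin(pmax(audio@samples, -1), 1), audio@sampleRate)
}

#' Apply one named static filter
#'
#' Dispatches to the named filter operator with parameters given as a named
#' list/vector (using the parameter names of [filterSpecs()]). All operators
#' preserve length and sampling rate and act identically on each channel.
#' Unlike [applyChain()], no output clipping is applied here.
#'
#' @param audio an [AudioBuffer-class]; must be non-empty.
#' @param filter filter identifier, e.g. `"amplify_all"`, `"band_reject"`.
#' @param params named parameter values for that filter; missing parameters
#'   take their defaults. Values must lie within the declared ranges.
#' @param task which task's registry to validate against (the shared filters
#'   accept either).
#' @param noiseSeed RNG seed for the white-noise generator.
#' @return An [AudioBuffer-class].
#' @examples
#' tone <- sineBuffer(1000, duration = 0.25)
#' louder <- applyStaticFilter(tone, "amplify_all", list(gain = 2))
#' max(abs(samples(louder))) / max(abs(samples(tone)))  # ~2
#' @export
applyStaticFilter <- function(audio, filter, params = list(),
                              task = NULL, noiseSeed = 0) {
  stopifnot(is(audio, "AudioBuffer"))
  if (nSamples(audio) == 0) stop("audio must be non-empty")
  if (is.null(task))
    task <- if (filter %in% unique(.recollectionSpec$filter))
      "Recollection" else "Easing"
  spec <- filterSpecs(task)
  spec <- spec[spec$filter == filter, , drop = FALSE]
  if (!nrow(spec)) stop("unknown filter name: ", filter)
  p <- setNames(spec$default, spec$param)
  if (length(params)) {
    params <- unlist(params)
    unknown <- setdiff(names(params), spec$param)
    if (length(unknown))
      stop("unknown parameter(s) for ", filter, ": ",
           paste(unknown, collapse = ", "))
    p[names(params)] <- as.numeric(params)
  }
  bad <- p < setNames(spec$min, spec$param) - 1e-12 |
         p > setNames(spec$max, spec$param) + 1e-12
  if (any(bad))
    stop("out-of-range parameter(s) for ", filter, ": ",
         paste(names(p)[bad], collapse = ", "))
  fs <- audio@sampleRate
  n <- nSamples(audio)
  nc <- nChannels(audio)
  out <- switch(filter,
    amplify_all = audioBuffer(audio@samples * p[["gain"]], fs),
    volume_all  = audioBuffer(audio@samples * p[["gain"]], fs),
    amplify_low    = .perChannel(audio, .peakEq, 100, 100, p[["gain"]], fs),
    amplify_medium = .perChannel(audio, .peakEq, 1100, 900, p[["gain"]], fs),
    amplify_high   = .perChannel(audio, .peakEq, 11100, 9000, p[["gain"]], fs),
    noise = {
      if (p[["amplitude"]] == 0) audio else {
        nz <- .withSeed(noiseSeed,
                        matrix(runif(n * nc, -1, 1), ncol = nc)) *
          p[["amplitude"]]
        audioBuffer(audio@samples + nz, fs)
      }
    },
    tinnitus = {
      if (p[["amplitude"]] == 0) audio else {
        s <- p[["amplitude"]] *
          sin(2 * pi * p[["frequency"]] * seq_len(n) / fs)
        audioBuffer(audio@samples + s, fs)
      }
    },
    band_reject = .perChannel(audio, .bandReject, p[["center"]],
                              p[["width"]], fs),
    echo = {
      if (p[["mix"]] == 0) audio else {
        wet <- .perChannel(audio, function(x, fs) .schroederWet(x, fs), fs)
        audioBuffer((1 - p[["mix"]]) * audio@samples +
                      p[["mix"]] * wet@samples, fs)
      }
    },
    flanger = .perChannel(audio, function(x)
      .flangerChannel(x, fs, p[["power"]], p[["frequency"]], 5, 2)),
    water_effect = .perChannel(audio, .waterEffect, p[["gain"]], fs),
    volume_low = .perChannel(audio, .bandVolumes, p[["gain"]], 1, 1, fs),
    volume_medium = .perChannel(audio, .bandVolumes, 1, p[["gain"]], 1, fs),
    volume_high = .perChannel(audio, .bandVolumes, 1, 1, p[["gain"]], fs),
    pitch_shift = .perChannel(audio, .pitchShift, p[["semitones"]]),
    change_suppression = changeSuppression(audio, p[["threshold"]],
                                           p[["suppression"]],
                                           p[["back_time"]]),
    stop("unknown filter name: ", filter))
  out
}

#' Change suppression (dynamic gain gate)
#'
#' Detects sudden loudness increases and temporarily ducks the signal. The
#' signal is framed into consecutive blocks of `frameLength` samples; each
#' frame's amplitude is its mean absolute value (or RMS when
#' `method = "rms"`). Once 17 frames have been observed, the mean of the last
#' 16 frame-to-frame amplitude differences is compared against `threshold`:
#' when exceeded, the gain drops immediately to `suppression` and then relaxes
#' linearly back to 1 over `backTime` seconds. Re-triggering restarts the
#' relaxation. At 44.1 kHz the 16-frame window spans approximately 372 ms
#' (see [changeSuppressionWindowMs()]).
#'
#' @param audio an [AudioBuffer-class].
#' @param threshold activation threshold on the averaged amplitude increase
#'   (0 to 0.015).
#' @param suppression gain applied on activation (0.2 to 1).
#' @param backTime relaxation time in seconds (0.05 to 10).
#' @param frameLength analysis frame length in samples (default 1024).
#' @param method frame amplitude statistic, `"mean_abs"` (default) or `"rms"`.
#' @return An [AudioBuffer-class] with attribute `"gain"`: the per-sample gain
#'   trajectory (never above 1, piecewise drop-then-recover).
#' @examples
#' step <- audioBuffer(c(numeric(22050), rep(0.9, 22050)))
#' out <- changeSuppression(step, threshold = 0.0015, suppression = 0.2,
#'                          backTime = 0.05)
#' min(attr(out, "gain"))  # 0.2
#' @export
changeSuppression <- function(audio, threshold = 0.0015, suppression = 1,
                              backTime = 0.05, frameLength = 1024,
                              method = c("mean_abs", "rms")) {
  stopifnot(is(audio, "AudioBuffer"))
  method <- match.arg(method)
  if (threshold < 0 || threshold > 0.015) stop("threshold outside [0, 0.015]")
  if (suppression < 0.2 || suppression > 1) stop("suppression outside [0.2, 1]")
  if (backTime < 0.05 || backTime > 10) stop("back_time outside [0.05, 10]")
  if (nSamples(audio) < 17 * frameLength) {
    warning("audio shorter than 17 analysis frames; returned unchanged")
    attr(audio, "gain") <- rep(1, nSamples(audio))
    return(audio)
  }
  res <- .changeSuppression(audio@samples, audio@sampleRate, threshold,
                            suppression, backTime, as.integer(frameLength),
                            method == "rms")
  out <- audioBuffer(res$samples, audio@sampleRate)
  attr(out, "gain") <- as.numeric(res$gain)
  out
}

# Stage order of each chain: base volume first, then the filter-table order
# (the Easing band-volume trio forms one parallel split stage; change
# suppression follows the volume-change stages).
.chainStages <- function(task) {
  if (task == "Recollection")
    c("amplify_all", "amplify_low", "amplify_medium", "amplify_high",
      "noise", "tinnitus", "band_reject", "echo", "flanger", "water_effect")
  else
    c("band_volumes", "pitch_shift", "change_suppression", "volume_all",
      "noise", "tinnitus", "band_reject", "echo", "flanger", "water_effect")
}

#' Apply a full task filter chain
#'
#' Runs the base-volume correction followed by every filter of the task's
#' chain in its fixed order (Recollection: the amplify/noise/tinnitus/
#' band-reject/echo/flanger/water sequence; Easing: band-volume split, pitch
#' shift, change suppression, overall volume, then the shared filters).
#' Filters whose parameters equal their defaults are identity stages and are
#' bypassed. The output is hard-clipped to \[-1, 1\]; intermediate stages are
#' not clipped. Deterministic given `noiseSeed`.
#'
#' @param audio an [AudioBuffer-class].
#' @param settings a [FilterSettings-class]; its task selects the chain.
#' @param o device volume setting in \[0, 1\] (default 0.5 = no correction).
#' @param noiseSeed seed for the white-noise stage (default 0).
#' @param stages optional character vector overriding the stage order.
#' @return An [AudioBuffer-class] of identical length and rate.
#' @examples
#' tone <- sineBuffer(440, duration = 0.5, amplitude = 0.2)
#' out <- applyChain(tone, filterSettings("Recollection",
#'                                        "amplify_all.gain" = 2))
#' max(abs(samples(out))) / max(abs(samples(tone)))  # ~2
#' @export
applyChain <- function(audio, settings, o = 0.5, noiseSeed = 0,
                       stages = NULL) {
  stopifnot(is(audio, "AudioBuffer"), is(settings, "FilterSettings"))
  validObject(settings)
  task <- settings@task
  spec <- filterSpecs(task)
  v <- settings@values
  defaults <- setNames(spec$default, spec$key)
  if (is.null(stages)) stages <- .chainStages(task)
  out <- baseVolumeAdjust(audio, o)
  paramsOf <- function(f) {
    rows <- spec$filter == f
    setNames(v[spec$key[rows]], spec$param[rows])
  }
  isDefault <- function(f) {
    rows <- spec$filter == f
    all(v[spec$key[rows]] == defaults[spec$key[rows]])
  }
  for (st in stages) {
    res <- tryCatch({
      if (st == "band_volumes") {
        g <- c(v[["volume_low.gain"]], v[["volume_medium.gain"]],
               v[["volume_high.gain"]])
        if (all(g == 1)) out
        else .perChannel(out, .bandVolumes, g[1], g[2], g[3],
                         out@sampleRate)
      } else if (isDefault(st)) out
      else applyStaticFilter(out, st, paramsOf(st), task = task,
                             noiseSeed = noiseSeed)
    }, error = function(e)
      stop("chain stage '", st, "': ", conditionMessage(e), call. = FALSE))
    out <- res
  }
  clipAudio(out)
}
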