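# Synthetic experiment generator: stimuli, participants and trial-by-trial
# responses from a known ground-truth response model, so the full pipeline is
# testable end to end without any recorded participant data.

#' Experiment design
#'
#' Counts and probabilities defining the simulated study: 28 DD and 29 TD
#' participants; 62 stimuli split into Training (30), Training-reserve (10),
#' Test (12) and Test-reserve (10); 42 scored trials per participant per task
#' plus 3 repeat presentations; a per-trial skip probability calibrated so
#' about 31 of the 2,394 scored trials are replaced by reserve stimuli; and a
#' missing-data event removing 2 trials of one participant.
#'
#' @param nDd,nTd group sizes (defaults 28, 29).
#' @param nTraining,nTrainingReserve,nTest,nTestReserve stimulus set sizes
#'   (defaults 30, 10, 12, 10).
#' @param nRepeats repeated Training stimuli per participant (default 3).
#' @param skipProb per-trial skip probability (default 31/2394).
#' @param missingEvent logical; inject the default missing-data event (one
#'   participant loses one Training-stimulus and one Test-stimulus trial).
#' @return A named list of class `"experimentDesign"`.
#' @export
experimentDesign <- function(nDd = 28, nTd = 29, nTraining = 30,
                             nTrainingReserve = 10, nTest = 12,
                             nTestReserve = 10, nRepeats = 3,
                             skipProb = 31 / 2394, missingEvent = TRUE) {
  stopifnot(nDd >= 1, nTd >= 1, nTraining >= 1, nTest >= 1,
            nTrainingReserve >= 0, nTestReserve >= 0,
            nRepeats >= 0, nRepeats <= nTraining,
            skipProb >= 0, skipProb <= 1)
  structure(list(nDd = nDd, nTd = nTd, nTraining = nTraining,
                 nTrainingReserve = nTrainingReserve, nTest = nTest,
                 nTestReserve = nTestReserve, nRepeats = nRepeats,
                 skipProb = skipProb, missingEvent = isTRUE(missingEvent)),
            class = "experimentDesign")
}

#' Ground-truth response model
#'
#' Linear-Gaussian response structure on two latents: a per-stimulus
#' aversiveness (driven by loudness, high-band energy and onset density) and
#' a per-participant sensitivity (driven by the normalized AQ, sensory
#' sensitivity, auditory and avoiding scores, exactly the quantities the
#' predictor receives as covariates). Their combination
#' `s = a + b + interaction` drives ratings (discretized to 1-7), filter
#' usage (latent-threshold with logistic noise: with `noiseSd = 1` usage is
#' Bernoulli with a logistic link; with `noiseSd = 0` it is a deterministic
#' threshold) and touched parameter values (logistic-squashed monotone
#' functions of `s`, min-max mapped into each parameter's range). Easing
#' ratings are reduced by `easingEffect` rating points before discretization.
#'
#' @param easingEffect mean rating-point reduction in the Easing task
#'   (default 1.5).
#' @param noiseSd scale of all response noise components (default 1; 0 gives
#'   fully deterministic responses, the regime used for recovery testing).
#' @param repeatNoise scale multiplier on the usage noise of the second
#'   presentation of a repeated stimulus (default 2, which places the
#'   test-retest reproducibility value in the 0.4 regime observed for this
#'   kind of task).
#' @param interaction weight of the aversiveness-by-sensitivity product term
#'   (default 0.25).
#' @return A named list of class `"responseModel"` carrying all coefficients
#'   (`usage` and `value` coefficient tables included).
#' @export
responseModel <- function(easingEffect = 1.5, noiseSd = 1,
                          repeatNoise = 2, interaction = 0.25) {
  stopifnot(easingEffect >= 0, noiseSd >= 0, repeatNoise >= 0)
  usage <- rbind(
    data.frame(task = "Recollection",
      filter = c("amplify_all", "amplify_low", "amplify_medium",
                 "amplify_high", "noise", "tinnitus", "band_reject", "echo",
                 "flanger", "water_effect"),
      u0 = c(0.0, -0.3, -0.35, -0.2, -1.2, -1.85, -0.75, -1.1, -2.1, -2.15),
      u1 = c(1.2, 0.6, 0.8, 0.9, 0.8, 0.6, 0.5, 0.5, 0.4, 0.3)),
    data.frame(task = "Easing",
      filter = c("volume_low", "volume_medium", "volume_high", "pitch_shift",
                 "change_suppression", "volume_all", "noise", "tinnitus",
                 "band_reject", "echo", "flanger", "water_effect"),
      u0 = c(0.15, -0.1, 0.45, -0.8, -0.75, 0.15, -2.55, -2.2, -0.8, -2.45,
             -3.6, -2.1),
      u1 = c(0.4, 0.5, 0.9, 0.5, 0.9, 1.0, 0.3, 0.3, 0.6, 0.3, 0.2, 0.4)))
  value <- rbind(
    data.frame(task = "Recollection",
      key = filterSpecs("Recollection")$key,
      v0 = c(0, 0, 0, 0, -0.8, -0.8, 0, 0, 0, -0.8, -1.0, -0.5, -1.0),
      v1 = c(1.4, 1.0, 1.2, 1.2, 0.8, 0.6, 0.5, 0.9, 0.3, 0.5, 0.4, 0.3,
             0.3)),
    data.frame(task = "Easing",
      key = filterSpecs("Easing")$key,
      v0 = c(-1.2, -1.2, -1.4, 0, -1.0, -0.5, -2.0, -1.2, -2.0, -2.0, 0, 0,
             -1.5, -2.0, -2.0, 0, -1.0),
      v1 = c(-0.8, -0.8, -0.9, -0.8, -0.6, -0.8, 0.4, -1.0, 0.2, 0.2, 0.3,
             0.8, 0.2, 0.3, 0.2, 0.3, 0.5)))
  structure(list(
    easingEffect = easingEffect, noiseSd = noiseSd,
    repeatNoise = repeatNoise, interaction = interaction,
    # stimulus aversiveness: affine in log10 RMS, high-band fraction and
    # onset density (fixed constants; roughly zero-mean unit-sd over the
    # default stimulus population)
    aversiveness = c(intercept = 1.45, logRms = 1.8, highFrac = 0.6,
                     onsets = 0.12),
    # participant sensitivity from unit-scaled traits
    sensitivity = c(aq = 1.2, sensory_sensitivity = 1.0,
                    auditory_total = 0.8, sensation_avoiding = 0.3,
                    scale = 2.2),
    ratingSlope = 1.5, ratingNoise = 0.8, valueNoise = 0.35,
    itemOffsets = c(overall = 0, painful = -0.5, distracting = 0.2,
                    anxious = -0.2, impeditive = 0),
    usage = usage, value = value), class = "responseModel")
}

# --- stimuli ---------------------------------------------------------------

#' Generate the synthetic stimulus set
#'
#' Draws 62 parameterized 20-second sound scenes at 44.1 kHz covering the
#' four stress-inducing characteristics (sudden sounds, steady interfering
#' noise, multi-source environments, strong sounds) plus low-stress fillers,
#' and assigns each to a stimulus set (Training 30 / Training-reserve 10 /
#' Test 12 / Test-reserve 10) at random so the sets are statistically
#' comparable. Waveforms are synthesized on demand by
#' [synthesizeStimulus()] from the recorded per-clip parameters; the table
#' carries per-clip ground-truth descriptors (mean frame RMS, band energy
#' fractions, onset count) and the latent aversiveness they induce.
#'
#' @param design an [experimentDesign()].
#' @param seed integer seed.
#' @param response a [responseModel()] supplying the aversiveness weights.
#' @return data.frame with one row per stimulus: `stimulus`, `stimulus_set`,
#'   `category`, synthesis parameters, descriptors and `aversiveness`.
#' @export
generateStimuli <- function(design = experimentDesign(), seed = 1,
                            response = responseModel()) {
  stopifnot(inherits(design, "experimentDesign"))
  nStim <- design$nTraining + design$nTrainingReserve + design$nTest +
    design$nTestReserve
  .withSeed(seed + 1000L, {
    cats <- c("sudden", "steady", "multiple", "strong", "calm")
    category <- rep_len(cats, nStim)[sample.int(nStim)]
    sets <- sample(rep(c("Training", "TrainingReserve", "Test",
                         "TestReserve"),
                       c(design$nTraining, design$nTrainingReserve,
                         design$nTest, design$nTestReserve)))
    levelRange <- list(sudden = c(0.06, 0.30), steady = c(0.10, 0.35),
                       multiple = c(0.08, 0.28), strong = c(0.28, 0.60),
                       calm = c(0.015, 0.06))
    level <- vapply(category, function(ca) {
      r <- levelRange[[ca]]
      10^runif(1, log10(r[1]), log10(r[2]))
    }, numeric(1))
    nOnsets <- ifelse(category == "sudden", sample(2:6, nStim, TRUE), 0L)
    nTones <- ifelse(category %in% c("multiple", "calm"),
                     sample(2:5, nStim, TRUE),
                     ifelse(category == "strong", 1L, 0L))
    noiseMix <- c(sudden = 0.9, steady = 1, multiple = 0.35, strong = 0.6,
                  calm = 0.1)[category]
    clipSeed <- sample.int(.Machine$integer.max %/% 2, nStim)
    stim <- data.frame(stimulus = seq_len(nStim), stimulus_set = sets,
                       category = category, level = level,
                       n_onsets = as.integer(nOnsets),
                       n_tones = as.integer(nTones), noise_mix = noiseMix,
                       clip_seed = clipSeed, row.names = NULL)
  })
  desc <- t(vapply(seq_len(nStim), function(i) {
    au <- synthesizeStimulus(stim, i)
    x <- rowMeans(au@samples)
    rms <- stimulusRms(au)
    p <- Mod(fft(x))^2
    n <- length(x)
    f <- (seq_len(n) - 1) * au@sampleRate / n
    half <- f <= au@sampleRate / 2
    tot <- sum(p[half])
    c(rms = rms,
      low_frac = sum(p[half & f < 200]) / tot,
      mid_frac = sum(p[half & f >= 200 & f < 2000]) / tot,
      high_frac = sum(p[half & f >= 2000]) / tot)
  }, numeric(4)))
  stim <- cbind(stim, as.data.frame(desc))
  av <- response$aversiveness
  stim$aversiveness <- av[["intercept"]] + av[["logRms"]] * log10(stim$rms) +
    av[["highFrac"]] * stim$high_frac + av[["onsets"]] * stim$n_onsets
  stim
}

#' Synthesize one stimulus waveform
#'
#' Deterministically regenerates the 20-s, 44.1 kHz waveform of one stimulus
#' from its recorded synthesis parameters (`clip_seed` etc.), so waveforms
#' never need to be stored.
#'
#' @param stimuli the table from [generateStimuli()].
#' @param id stimulus id (row of the table).
#' @param duration clip length in seconds (default 20).
#' @return An [AudioBuffer-class] (mono).
#' @export
synthesizeStimulus <- function(stimuli, id, duration = 20) {
  r <- stimuli[stimuli$stimulus == id, ]
  if (nrow(r) != 1) stop("unknown stimulus id: ", id)
  fs <- 44100
  n <- round(duration * fs)
  x <- .withSeed(r$clip_seed, {
    t <- seq_len(n) / fs
    sig <- numeric(n)
    if (r$n_tones > 0) {
      freqs <- 10^runif(r$n_tones, log10(150), log10(4000))
      amps <- runif(r$n_tones, 0.3, 1)
      for (k in seq_len(r$n_tones))
        sig <- sig + amps[k] * sin(2 * pi * freqs[k] * t)
      sig <- sig / max(abs(sig))
    }
    nz <- runif(n, -1, 1)
    base <- (1 - r$noise_mix) * sig + r$noise_mix * nz
    if (r$category == "sudden") {
      quiet <- 0.12 * base
      for (k in seq_len(r$n_onsets)) {
        at <- round(runif(1, 0.05, 0.9) * n)
        len <- round(runif(1, 0.15, 0.5) * fs)
        idx <- at:min(at + len - 1, n)
        env <- c(seq(0, 1, length.out = min(220, length(idx))),
                 rep(1, max(0, length(idx) - 220)))
        env <- env * rev(seq_len(length(env))) / length(env) # decay
        quiet[idx] <- quiet[idx] + env * runif(1, 0.7, 1) *
          runif(length(idx), -1, 1)
      }
      base <- quiet
    }
    base
  })
  x <- x / sqrt(mean(x^2)) * r$level  # calibrate to the target RMS
  clipAudio(audioBuffer(pmin(pmax(x, -1.5), 1.5), fs))
}

#' Frame-wise RMS of an audio buffer
#'
#' RMS per analysis frame (length 2048, hop 512 by default) on the mono mix;
#' [stimulusRms()] aggregates a clip to one value as the mean over frames.
#'
#' @param audio an [AudioBuffer-class].
#' @param frameLength,hop framing in samples.
#' @return numeric vector of per-frame RMS values.
#' @export
frameRms <- function(audio, frameLength = 2048, hop = 512) {
  x <- rowMeans(audio@samples)
  n <- length(x)
  if (n < frameLength) return(sqrt(mean(x^2)))
  starts <- seq(1, n - frameLength + 1, by = hop)
  vapply(starts, function(s)
    sqrt(mean(x[s:(s + frameLength - 1)]^2)), numeric(1))
}

#' @describeIn frameRms single RMS value per clip (mean over frames).
#' @export
stimulusRms <- function(audio, frameLength = 2048, hop = 512) {
  mean(frameRms(audio, frameLength, hop))
}

# --- participants ----------------------------------------------------------

# Truncated-normal draw by clipping (bounds are instrument bounds).
.rtrunc <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)

#' Generate synthetic participants
#'
#' Trait draws from truncated normals within instrument bounds. The DD group
#' mean is shifted upward on AQ, low registration, sensory sensitivity,
#' sensation avoiding and the AASP auditory total; sensation seeking has zero
#' shift (the null contrast). Ages are uniform over 20-64.
#'
#' @param design an [experimentDesign()].
#' @param seed integer seed.
#' @param shifts named numeric vector of DD-minus-TD mean shifts.
#' @return data.frame, one row per participant (`participant`, `group`,
#'   demographics, questionnaire scores, session state, `sensitivity`).
#' @export
generateParticipants <- function(design = experimentDesign(), seed = 1,
                                 shifts = c(aq = 12, aasp_low_registration = 9,
                                            aasp_sensation_seeking = 0,
                                            aasp_sensory_sensitivity = 9,
                                            aasp_sensation_avoiding = 9,
                                            aasp_auditory_total = 7)) {
  stopifnot(inherits(design, "experimentDesign"))
  n <- design$nDd + design$nTd
  grp <- rep(c("DD", "TD"), c(design$nDd, design$nTd))
  .withSeed(seed + 2000L, {
    sh <- function(f) ifelse(grp == "DD", shifts[[f]], 0)
    p <- data.frame(
      participant = seq_len(n), group = grp,
      age = round(runif(n, 20, 64)),
      sex = sample(c("female", "male"), n, TRUE),
      aq = round(.rtrunc(n, 18 + sh("aq"), 7, 0, 50)),
      aasp_low_registration =
        round(.rtrunc(n, 36 + sh("aasp_low_registration"), 8, 15, 75)),
      aasp_sensation_seeking =
        round(.rtrunc(n, 40 + sh("aasp_sensation_seeking"), 8, 15, 75)),
      aasp_sensory_sensitivity =
        round(.rtrunc(n, 38 + sh("aasp_sensory_sensitivity"), 8, 15, 75)),
      aasp_sensation_avoiding =
        round(.rtrunc(n, 38 + sh("aasp_sensation_avoiding"), 8, 15, 75)),
      aasp_auditory_total =
        round(.rtrunc(n, 30 + sh("aasp_auditory_total"), 6, 11, 55)),
      sleep_minutes = round(.rtrunc(n, 420, 60, 0, 1440)),
      fatigue_physical = sample(1:7, n, TRUE,
                                prob = c(1, 2, 3, 3, 2, 1, 0.5)),
      fatigue_mental = sample(1:7, n, TRUE,
                              prob = c(1, 2, 3, 3, 2, 1, 0.5)),
      volume_o = round(runif(n, 0.35, 0.65), 2),
      bluetooth = sample(c("A2DP", "HFP"), n, TRUE, prob = c(0.9, 0.1)),
      row.names = NULL)
  })
  p$sensitivity <- .participantSensitivity(p)
  p
}

# Latent sensitivity from the same unit-scaled traits the model receives.
.participantSensitivity <- function(p, response = responseModel()) {
  w <- response$sensitivity
  b <- .covariateBounds
  un <- function(x, f) (x - b[[f]][1]) / (b[[f]][2] - b[[f]][1])
  w[["scale"]] * (w[["aq"]] * (un(p$aq, "aq") - 0.5) +
    w[["sensory_sensitivity"]] *
      (un(p$aasp_sensory_sensitivity, "aasp_sensory_sensitivity") - 0.5) +
    w[["auditory_total"]] *
      (un(p$aasp_auditory_total, "aasp_auditory_total") - 0.5) +
    w[["sensation_avoiding"]] *
      (un(p$aasp_sensation_avoiding, "aasp_sensation_avoiding") - 0.5))
}

# --- trials ----------------------------------------------------------------

# Draw one task's settings vector for a trial with latent stress s.
.drawSettings <- function(task, s, response, spec, usageNoise = NULL) {
  usage <- response$usage[response$usage$task == task, ]
  value <- response$value[response$value$task == task, ]
  if (is.null(usageNoise))
    usageNoise <- stats::rlogis(nrow(usage)) * response$noiseSd
  u <- usage$u0 + usage$u1 * s + usageNoise
  used <- setNames(u > 0, usage$filter)
  out <- setNames(spec$default, spec$key)
  for (i in seq_len(nrow(spec))) {
    f <- spec$filter[i]
    if (!used[[f]]) next
    vc <- value[value$key == spec$key[i], ]
    lat <- vc$v0 + vc$v1 * s +
      rnorm(1, 0, response$valueNoise * response$noiseSd)
    out[[spec$key[i]]] <- spec$min[i] +
      (spec$max[i] - spec$min[i]) * stats::plogis(lat)
  }
  list(values = out, usageNoise = usageNoise)
}

.drawRatings <- function(s, response, easing = FALSE) {
  off <- response$itemOffsets
  lat <- 4 + response$ratingSlope * (s + off) +
    rnorm(length(off), 0, response$ratingNoise * response$noiseSd) -
    if (easing) response$easingEffect else 0
  setNames(pmin(pmax(round(lat), 1), 7), paste0("rating_", names(off)))
}

#' Generate the full trial table
#'
#' Simulates every participant x stimulus x task observation: each
#' participant responds to all Training and Test stimuli (42 scored trials
#' per task at the default design), with skipped stimuli replaced by unused
#' reserve stimuli of the matching pool, plus `nRepeats` repeated Training
#' stimuli for the test-retest check. Both tasks share the trial list; the
#' Easing rows reuse the Recollection latent with the easing reduction
#' applied to ratings and the Easing coefficient set for settings. The
#' default missing-data event flags one Training-stimulus and one
#' Test-stimulus trial of the first participant as missing in both tasks.
#'
#' @param stimuli from [generateStimuli()].
#' @param participants from [generateParticipants()].
#' @param response a [responseModel()].
#' @param seed integer seed.
#' @param design the [experimentDesign()] used for the stimuli.
#' @return data.frame with one row per trial per task: identifiers,
#'   participant covariates, `latent_stress`, `setting.<filter>.<param>`
#'   columns on native scales, `rating_*` columns (1-7),
#'   `presentation` (`"scored"`/`"repeat"`), `skip_replaced` and `missing`
#'   flags. The ground-truth latents are the `latent_stress` column plus the
#'   `aversiveness`/`sensitivity` columns of the input tables.
#' @export
generateTrials <- function(stimuli, participants, response = responseModel(),
                           seed = 1, design = experimentDesign()) {
  stopifnot(inherits(response, "responseModel"))
  specR <- filterSpecs("Recollection")
  specE <- filterSpecs("Easing")
  av <- setNames(stimuli$aversiveness, stimuli$stimulus)
  .withSeed(seed + 3000L, {
    rows <- vector("list", nrow(participants) * 2L)
    ri <- 0L
    for (pi in seq_len(nrow(participants))) {
      p <- participants[pi, ]
      pool <- function(set) stimuli$stimulus[stimuli$stimulus_set == set]
      plan <- data.frame(
        stimulus = c(pool("Training"), pool("Test")),
        presentation = "scored", skip_replaced = FALSE)
      # skips: replace with an unused reserve stimulus of the matching pool
      reserves <- list(Training = sample(pool("TrainingReserve")),
                       Test = sample(pool("TestReserve")))
      for (i in seq_len(nrow(plan))) {
        set0 <- stimuli$stimulus_set[stimuli$stimulus == plan$stimulus[i]]
        poolName <- if (set0 == "Training") "Training" else "Test"
        if (length(reserves[[poolName]]) > 0 &&
            runif(1) < design$skipProb) {
          plan$stimulus[i] <- reserves[[poolName]][1]
          reserves[[poolName]] <- reserves[[poolName]][-1]
          plan$skip_replaced[i] <- TRUE
        }
      }
      repeated <- head(plan$stimulus[plan$stimulus %in% pool("Training")],
                       design$nRepeats)
      plan <- rbind(plan, data.frame(stimulus = repeated,
                                     presentation = "repeat",
                                     skip_replaced = FALSE))
      nT <- nrow(plan)
      recRows <- easeRows <- vector("list", nT)
      for (i in seq_len(nT)) {
        sid <- plan$stimulus[i]
        s <- av[[as.character(sid)]] + p$sensitivity +
          response$interaction * av[[as.character(sid)]] * p$sensitivity
        # repeats share the deterministic latent; their usage noise is an
        # independent redraw at `repeatNoise` times the scale
        drawNoise <- function(task, nFilters) {
          fresh <- stats::rlogis(nFilters) * response$noiseSd
          if (plan$presentation[i] == "repeat")
            fresh <- fresh * response$repeatNoise
          fresh
        }
        nzR <- drawNoise("Recollection",
                         length(unique(specR$filter)))
        nzE <- drawNoise("Easing", length(unique(specE$filter)))
        setR <- .drawSettings("Recollection", s, response, specR, nzR)
        setE <- .drawSettings("Easing", s, response, specE, nzE)
        ratR <- .drawRatings(s, response, easing = FALSE)
        ratE <- .drawRatings(s, response, easing = TRUE)
        base <- data.frame(
          participant = p$participant, group = p$group, stimulus = sid,
          stimulus_set = stimuli$stimulus_set[stimuli$stimulus == sid],
          category = stimuli$category[stimuli$stimulus == sid],
          presentation = plan$presentation[i],
          skip_replaced = plan$skip_replaced[i], missing = FALSE,
          age = p$age, sex = p$sex, aq = p$aq,
          aasp_low_registration = p$aasp_low_registration,
          aasp_sensation_seeking = p$aasp_sensation_seeking,
          aasp_sensory_sensitivity = p$aasp_sensory_sensitivity,
          aasp_sensation_avoiding = p$aasp_sensation_avoiding,
          aasp_auditory_total = p$aasp_auditory_total,
          sleep_minutes = p$sleep_minutes,
          fatigue_physical = p$fatigue_physical,
          fatigue_mental = p$fatigue_mental, volume_o = p$volume_o,
          bluetooth = p$bluetooth, latent_stress = s, row.names = NULL)
        recRows[[i]] <- cbind(base, task = "Recollection",
          as.data.frame(as.list(setNames(setR$values,
            paste0("setting.", names(setR$values))))),
          as.data.frame(as.list(ratR)))
        easeRows[[i]] <- cbind(base, task = "Easing",
          as.data.frame(as.list(setNames(setE$values,
            paste0("setting.", names(setE$values))))),
          as.data.frame(as.list(ratE)))
      }
      ri <- ri + 1L; rows[[ri]] <- do.call(rbind, recRows)
      ri <- ri + 1L; rows[[ri]] <- do.call(rbind, easeRows)
    }
    # the two tasks carry different setting columns; pad to the union
    allCols <- unique(unlist(lapply(rows[seq_len(ri)], names)))
    rows <- lapply(rows[seq_len(ri)], function(d) {
      for (cn in setdiff(allCols, names(d))) d[[cn]] <- NA_real_
      d[, allCols]
    })
    trials <- do.call(rbind, rows)
    rownames(trials) <- NULL
    if (design$missingEvent) {
      p1 <- participants$participant[1]
      scored1 <- trials$participant == p1 & trials$presentation == "scored"
      trainStim <- trials$stimulus[scored1 & trials$stimulus_set %in%
                                     c("Training", "TrainingReserve")][1]
      testStim <- trials$stimulus[scored1 & trials$stimulus_set %in%
                                    c("Test", "TestReserve")][1]
      trials$missing[scored1 & trials$stimulus %in%
                       c(trainStim, testStim)] <- TRUE
    }
    trials
  })
}

#' Run the whole synthetic experiment
#'
#' Convenience wrapper: generates stimuli, participants and trials under one
#' seed and returns them together with the response model (the ground truth).
#'
#' @param design an [experimentDesign()].
#' @param response a [responseModel()].
#' @param seed integer seed for all draws.
#' @return list with `stimuli`, `participants`, `trials`, `response`,
#'   `design`.
#' @export
simulateExperiment <- function(design = experimentDesign(),
                               response = responseModel(), seed = 1) {
  stimuli <- generateStimuli(design, seed, response)
  participants <- generateParticipants(design, seed)
  participants$sensitivity <- .participantSensitivity(participants, response)
  trials <- generateTrials(stimuli, participants, response, seed, design)
  list(stimuli = stimuli, participants = participants, trials = trials,
       response = response, design = design)
}

#' Embed every stimulus of a set
#'
#' Synthesizes each stimulus waveform and embeds it (see [embedAudio()]),
#' returning the `41 x 1024 x S` array consumed by [buildTaskDataset()].
#'
#' @param stimuli table from [generateStimuli()].
#' @param frontend embedding frontend (see [embedAudio()]).
#' @return numeric array `41 x 1024 x nrow(stimuli)`.
#' @export
embedStimulusSet <- function(stimuli, frontend = "fallback") {
  out <- array(0, c(41, 1024, nrow(stimuli)))
  for (i in seq_len(nrow(stimuli))) {
    au <- synthesizeStimulus(stimuli, stimuli$stimulus[i])
    out[, , i] <- embedAudio(au, frontend)
  }
  out
}
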