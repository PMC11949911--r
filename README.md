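# hearease

Auditory hypersensitivity — intense distress caused by sounds most listeners
tolerate — is one of the most commonly reported sensory challenges for
people with autism spectrum disorder or ADHD. One promising support strategy
asks listeners to *show* how a sound feels to them (a **Recollection** task:
set audio filters until the playback matches how a similar sound sounded in
their own life) and how it would have to change to become bearable (an
**Easing** task: set the filters until the sound is tolerable for prolonged
listening), and then learns to predict those filter settings and the
accompanying stress ratings from the sound itself plus listener covariates.
A model that predicts Easing settings is the core of a personalised digital
earplug; one that predicts Recollection settings and stress ratings is an
assessment tool.

`hearease` implements that whole pipeline in R:

* **Filter engine** — the two task filter chains with validated parameter
  ranges: stereo faders, second-order peaking equalizers (low/medium/high
  bands), white-noise and tinnitus (sine) injection, a Butterworth
  second-order band-reject, a Schroeder reverb ("Echo"), a modulated-delay
  flanger, a two-band "Water effect", Butterworth band-volume splits, a
  phase-vocoder pitch shifter (duration-preserving), and a dynamic
  **change-suppression** gate that detects sudden loudness increases by
  averaging frame-to-frame amplitude differences over 16 × 1024-sample
  frames (≈ 372 ms at 44.1 kHz) and ducks the gain, recovering over a
  configurable back time. A device-volume correction
  `A = 32·(0.5 − o) dB ∈ [−16, 16]` precedes both chains.
* **Features** — a log-mel audio embedding frontend (41 frames × 1024
  features per 20-s stimulus at 16 kHz) and min-max-scaled covariates
  (sleep, fatigue, age, sex, AQ, AASP quadrant and auditory scores, volume
  correction, Bluetooth profile); the Easing model additionally receives the
  normalized Recollection settings and ratings.
* **Model** — a bidirectional LSTM over the embedding frames whose final
  hidden states are fused with the covariates and passed through a dense
  stack (batch normalization, SiLU, dropout) into a sigmoid head, so every
  prediction is range-respecting by construction; trained with minibatch
  Adam on MSE (300 epochs, batch 24 by default), with the train/test split
  **by stimulus** so evaluation measures generalization to novel sounds.
  The trainer is implemented in C++ (RcppArmadillo) with full
  backpropagation, verified against finite differences.
* **Evaluation** — per-parameter Pearson and per-rating Spearman
  correlations with significance, MAE in native units, per-parameter usage
  counts, a test-retest reproducibility value, the Recollection-vs-Easing
  paired contrast, Kolmogorov–Smirnov train/test loudness comparability,
  and DD-vs-TD Mann–Whitney trait comparisons.
* **Synthetic experiment generator** — 62 parameterized 20-s sound scenes
  (sudden onsets, steady noise, multi-source, strong, calm), 28 + 29
  synthetic participants with planted DD/TD trait shifts, and a fully
  documented ground-truth response model that maps stimulus aversiveness ×
  listener sensitivity to filter usage, settings and ratings — so the whole
  pipeline is testable end to end, including parameter-recovery tests
  against the known generative mapping.

## Worked example

```r
library(hearease)

# 1. a stimulus and a listener's Easing settings
sim  <- simulateExperiment(experimentDesign(nDd = 2, nTd = 2), seed = 1)
clip <- synthesizeStimulus(sim$stimuli, sim$stimuli$stimulus[1])
s    <- filterSettings("Easing", "volume_high.gain" = 0.4,
                       "change_suppression.threshold" = 0.001,
                       "change_suppression.suppression" = 0.3)
eased <- applyChain(clip, s, o = 0.5)
c(before = stimulusRms(clip), after = stimulusRms(eased))
#>    before     after
#> 0.2291442 0.1438068

# 2. embed, split by stimulus, train, evaluate
emb <- embedStimulusSet(sim$stimuli)          # 41 x 1024 x 62
tr  <- sim$trials[sim$trials$task == "Recollection", ]
sp  <- splitByStimulus(tr)                    # no stimulus on both sides
m   <- trainModel(buildModel(modelConfig("Recollection", lstmHidden = 8,
                                         denseWidths = 32, epochs = 60)),
                  buildTaskDataset(sp$train, sim$stimuli, emb))
rep <- evaluateModel(m, buildTaskDataset(sp$test, sim$stimuli, emb), "All")
head(rep[, c("output", "used", "correlation", "stars", "mae")], 3)
#>                output used correlation stars  mae
#> 1    amplify_all.gain   29       0.717   *** 1.09
#> 2    amplify_low.gain   23       0.537   *** 1.12
#> 3 amplify_medium.gain   24       0.436   *** 1.18
```

`correlation` is Pearson r between predicted and actual settings over all
held-out trials (novel stimuli); `used` counts trials in which the
parameter was moved off its default; `mae` is in the parameter's native
units (here, fader gain on its 1–5 scale).

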