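# The generator's contracts: set sizes, determinism, bounds, planted effects.

test_that("the stimulus set matches the design and clips are full length", {
  sim <- paperScaleSim()
  st <- sim$stimuli
  expect_equal(nrow(st), 62)
  expect_equal(as.integer(table(st$stimulus_set)[c("Training",
    "TrainingReserve", "Test", "TestReserve")]), c(30L, 10L, 12L, 10L))
  au <- synthesizeStimulus(st, st$stimulus[1])
  expect_equal(nSamples(au), 882000)  # 20 s x 44.1 kHz
  expect_equal(sampleRate(au), 44100)
  expect_lte(max(abs(samples(au))), 1)
  # regeneration is deterministic
  au2 <- synthesizeStimulus(st, st$stimulus[1])
  expect_identical(samples(au), samples(au2))
})

test_that("sudden-category clips carry onsets that trip the gate", {
  sim <- paperScaleSim()
  sudden <- sim$stimuli[sim$stimuli$category == "sudden", ][1, ]
  au <- synthesizeStimulus(sim$stimuli, sudden$stimulus)
  expect_gte(sudden$n_onsets, 1)
  out <- changeSuppression(au, threshold = 0.0015, suppression = 0.2,
                           backTime = 0.05)
  expect_lt(min(attr(out, "gain")), 1)  # at least one trigger
})

test_that("generated stimuli are reproducible and descriptors are sane", {
  d <- experimentDesign()
  s1 <- generateStimuli(d, seed = 5)
  s2 <- generateStimuli(d, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1$rms > 0))
  expect_true(all(abs(s1$low_frac + s1$mid_frac + s1$high_frac - 1) < 1e-6))
})

test_that("participant traits respect instrument bounds and planted shifts", {
  big <- experimentDesign(nDd = 400, nTd = 400)
  p <- generateParticipants(big, seed = 3)
  expect_true(all(p$aq >= 0 & p$aq <= 50))
  for (f in c("aasp_low_registration", "aasp_sensation_seeking",
              "aasp_sensory_sensitivity", "aasp_sensation_avoiding"))
    expect_true(all(p[[f]] >= 15 & p[[f]] <= 75))
  expect_true(all(p$aasp_auditory_total >= 11 & p$aasp_auditory_total <= 55))
  expect_true(all(p$age >= 20 & p$age <= 64))
  dd <- p[p$group == "DD", ]; td <- p[p$group == "TD", ]
  shift <- mean(dd$aq) - mean(td$aq)
  se <- sqrt(var(dd$aq) / nrow(dd) + var(td$aq) / nrow(td))
  expect_lt(abs(shift - 12), 3 * se)  # generator self-calibration
  nullShift <- mean(dd$aasp_sensation_seeking) -
    mean(td$aasp_sensation_seeking)
  seNull <- sqrt(var(dd$aasp_sensation_seeking) / nrow(dd) +
                   var(td$aasp_sensation_seeking) / nrow(td))
  expect_lt(abs(nullShift), 3 * seNull)  # null by construction
})

test_that("trial counts reproduce the design arithmetic", {
  sim <- paperScaleSim()
  tr <- sim$trials
  for (task in c("Recollection", "Easing")) {
    tt <- tr[tr$task == task, ]
    expect_equal(sum(tt$presentation == "scored"), 2394)  # 42 x 57
    expect_equal(sum(tt$presentation == "scored" & !tt$missing), 2392)
    expect_equal(sum(tt$presentation == "repeat"), 3 * 57)
  }
  small <- simulateExperiment(experimentDesign(nDd = 2, nTd = 2,
                                               missingEvent = FALSE),
                              seed = 4)
  expect_equal(sum(small$trials$task == "Recollection" &
                     small$trials$presentation == "scored"), 168)  # 42 x 4
})

test_that("all generated settings and ratings are in range", {
  sim <- paperScaleSim()
  tr <- sim$trials
  for (task in c("Recollection", "Easing")) {
    tt <- tr[tr$task == task, ]
    spec <- filterSpecs(task)
    for (i in seq_len(nrow(spec))) {
      v <- tt[[paste0("setting.", spec$key[i])]]
      expect_true(all(v >= spec$min[i] - 1e-9 & v <= spec$max[i] + 1e-9),
                  label = paste(task, spec$key[i]))
    }
    for (it in ratingItems()) {
      r <- tt[[paste0("rating_", it)]]
      expect_true(all(r %in% 1:7), label = paste(task, it))
    }
  }
})

test_that("a degenerate response model collapses the two tasks", {
  sim <- simulateExperiment(experimentDesign(nDd = 3, nTd = 3,
                                             missingEvent = FALSE),
                            responseModel(noiseSd = 0, easingEffect = 0),
                            seed = 9)
  rec <- sim$trials[sim$trials$task == "Recollection", ]
  eas <- sim$trials[sim$trials$task == "Easing", ]
  for (it in ratingItems())
    expect_identical(rec[[paste0("rating_", it)]],
                     eas[[paste0("rating_", it)]])
})

test_that("the easing reduction shows up in the planted direction", {
  sim <- paperScaleSim()  # easingEffect = 1.5 by default
  rec <- sim$trials[sim$trials$task == "Recollection", ]
  eas <- sim$trials[sim$trials$task == "Easing", ]
  for (it in ratingItems())
    expect_lt(mean(eas[[paste0("rating_", it)]]),
              mean(rec[[paste0("rating_", it)]]))
})
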