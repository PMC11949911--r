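# The metric layer against brute-force oracles on small hand tables.

# A minimal trial table with the columns the evaluation functions expect.
handTrials <- function(task, n, settingsList = NULL, ratings = NULL,
                       participant = 1, stimulus = seq_len(n),
                       presentation = "scored",
                       stimulus_set = "Training", group = "DD") {
  spec <- filterSpecs(task)
  d <- data.frame(participant = participant, group = group, task = task,
                  stimulus = stimulus, stimulus_set = stimulus_set,
                  presentation = presentation, missing = FALSE)
  for (i in seq_len(nrow(spec)))
    d[[paste0("setting.", spec$key[i])]] <- spec$default[i]
  if (!is.null(settingsList))
    for (j in seq_along(settingsList)) {
      v <- settingsList[[j]]
      d[j, paste0("setting.", names(v))] <- unname(v)
    }
  for (it in ratingItems())
    d[[paste0("rating_", it)]] <-
      if (is.null(ratings)) 4 else ratings
  d
}

test_that("Pearson, Spearman and MAE match brute-force sums on hand data", {
  # 6-point hand table with known ranks
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1, 2.8)
  y <- c(2.0, 3.0, 2.5, 4.8, 5.1, 2.4)
  spec <- filterSpecs("Recollection")
  K <- nrow(spec) + 5
  truth <- cbind(matrix(rep(spec$default, each = 6), 6, nrow(spec)),
                  matrix(4, 6, 5))
  pred <- truth
  truth[, spec$key == "amplify_all.gain"] <- x
  pred[, spec$key == "amplify_all.gain"] <- y
  truth[, nrow(spec) + 1] <- x  # rating_overall column
  pred[, nrow(spec) + 1] <- y
  truth[, (nrow(spec) + 2):K] <- 4
  pred[, (nrow(spec) + 2):K] <- 4
  rep <- scoreOutputs(pred, truth, "Recollection")
  # brute-force Pearson from raw sums
  n <- 6
  rBrute <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(rep$correlation[rep$output == "amplify_all.gain"], rBrute,
               tolerance = 1e-12)
  expect_equal(rep$mae[rep$output == "amplify_all.gain"],
               mean(abs(x - y)), tolerance = 1e-12)
  # brute-force Spearman: 1 - 6 sum d^2 / (n(n^2-1)), no ties
  d2 <- (rank(x) - rank(y))^2
  rhoBrute <- 1 - 6 * sum(d2) / (n * (n^2 - 1))
  expect_equal(rep$correlation[rep$output == "rating_overall"], rhoBrute,
               tolerance = 1e-12)
  # zero-variance outputs are NA, not numbers
  expect_true(is.na(rep$correlation[rep$output == "rating_painful"]))
  expect_true(is.na(rep$correlation[rep$output == "echo.mix"]))
})

test_that("a perfect predictor scores correlation 1 and MAE 0", {
  set.seed(12)
  spec <- filterSpecs("Easing")
  K <- nrow(spec) + 5
  truth <- matrix(runif(8 * K), 8, K)
  rep <- scoreOutputs(truth, truth, "Easing")
  expect_true(all(abs(rep$correlation - 1) < 1e-9))
  expect_true(all(rep$mae == 0))
})

test_that("usage counts count parameters away from their defaults", {
  base <- handTrials("Recollection", 42,
                     stimulus_set = rep(c("Training", "Test"), c(30, 12)))
  uc0 <- usageCounts(base, "Recollection")
  expect_true(all(uc0$train_all == 0) && all(uc0$test_all == 0))
  one <- base
  one[1, "setting.noise.amplitude"] <- 0.01
  uc1 <- usageCounts(one, "Recollection")
  expect_equal(uc1$train_all[uc1$key == "noise.amplitude"], 1)
  expect_equal(sum(uc1$train_all), 1)
})

test_that("usage probabilities planted in the generator come back out", {
  sim <- paperScaleSim()
  tr <- sim$trials[sim$trials$task == "Recollection", ]
  uc <- usageCounts(tr, "Recollection")
  # amplify_all usage is planted at plogis(u1 * s); with the latent spread
  # observed in the simulation the count must sit inside generous binomial
  # bounds around the empirical mean usage probability
  n <- sum(tr$presentation == "scored" & !tr$missing &
             tr$stimulus_set %in% c("Training", "TrainingReserve"))
  resp <- sim$response
  u <- resp$usage[resp$usage$task == "Recollection" &
                    resp$usage$filter == "amplify_all", ]
  keep <- tr$presentation == "scored" & !tr$missing &
    tr$stimulus_set %in% c("Training", "TrainingReserve")
  pTrial <- plogis(u$u0 + u$u1 * tr$latent_stress[keep])
  mu <- sum(pTrial); sdv <- sqrt(sum(pTrial * (1 - pTrial)))
  cnt <- uc$train_all[uc$key == "amplify_all.gain"]
  expect_gt(cnt, mu - 3 * sdv)
  expect_lt(cnt, mu + 3 * sdv)
})

test_that("the reproducibility ratio follows direct set enumeration", {
  # first presentation changes {amplify_all, amplify_low};
  # second changes {amplify_all, noise}: C_both = 1, C_one = 2 -> 0.5
  first <- handTrials("Recollection", 1, stimulus = 7,
    settingsList = list(c("amplify_all.gain" = 2, "amplify_low.gain" = 3)))
  second <- handTrials("Recollection", 1, stimulus = 7,
    presentation = "repeat",
    settingsList = list(c("amplify_all.gain" = 1.5,
                          "noise.amplitude" = 0.01)))
  rv <- reproducibilityValue(rbind(first, second), "Recollection")
  expect_equal(rv$perParticipant$cBoth, 1)
  expect_equal(rv$perParticipant$cOne, 2)
  expect_equal(rv$mean, 0.5)
  expect_equal(reproducibilityValue(rbind(first, second), "Recollection",
                                    method = "proportion")$mean, 1 / 3)
  # both change exactly the same single filter: zero denominator -> flagged
  both <- handTrials("Recollection", 1, stimulus = 7,
    settingsList = list(c("amplify_all.gain" = 2)))
  bothRep <- handTrials("Recollection", 1, stimulus = 7,
    presentation = "repeat",
    settingsList = list(c("amplify_all.gain" = 3)))
  expect_warning(rvU <- reproducibilityValue(rbind(both, bothRep),
                                             "Recollection"), "undefined")
  expect_false(rvU$perParticipant$defined)
  expect_equal(rvU$nDefined, 0)
  # nothing changed anywhere: flagged and excluded too
  none <- rbind(handTrials("Recollection", 1, stimulus = 7),
                handTrials("Recollection", 1, stimulus = 7,
                           presentation = "repeat"))
  expect_warning(rvN <- reproducibilityValue(none, "Recollection"),
                 "undefined")
  expect_equal(rvN$nDefined, 0)
})

test_that("the task contrast detects a constructed rating shift", {
  keep <- c("participant", "stimulus", "task", "presentation", "missing",
            paste0("rating_", ratingItems()))
  rec <- handTrials("Recollection", 40,
                    ratings = rep(c(3, 4, 5, 6), 10))[keep]
  eas <- handTrials("Easing", 40,
                    ratings = rep(c(3, 4, 5, 6), 10) +
                      rep(c(0, -1, -1, -2), 10))[keep]
  ct <- compareTaskRatings(rbind(rec, eas))
  expect_equal(ct$meanDiff, rep(-1, 5))
  expect_true(all(ct$p < 0.001))
  expect_true(all(ct$direction == "lower"))
  same <- compareTaskRatings(rbind(rec,
    handTrials("Easing", 40, ratings = rep(c(3, 4, 5, 6), 10))[keep]))
  expect_equal(same$meanDiff, rep(0, 5))
  expect_true(all(same$direction == "none"))
  expect_error(compareTaskRatings(rbind(rec[-1, ], eas)), "unpaired")
})

test_that("RMS comparability reports the expected KS extremes", {
  a <- seq(0.1, 0.5, length.out = 12)
  expect_equal(rmsComparability(a, a)$statistic, 0)
  expect_equal(rmsComparability(a, a)$p, 1)
  disjoint <- rmsComparability(seq(0.01, 0.05, length.out = 10),
                               seq(0.5, 0.9, length.out = 10))
  expect_equal(disjoint$statistic, 1)
  expect_lt(disjoint$p, 0.001)
  expect_error(rmsComparability(0.1, a), "at least 2")
})

test_that("KS p-values are well calibrated under the null", {
  set.seed(31)
  ps <- replicate(200, {
    rmsComparability(rlnorm(30, -2, 0.5), rlnorm(12, -2, 0.5))$p
  })
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.75)
})

test_that("group comparison flags planted shifts and spares the null", {
  p <- generateParticipants(experimentDesign(), seed = 6)
  gp <- groupProfileComparison(p)
  shifted <- c("aq", "aasp_low_registration", "aasp_sensory_sensitivity",
               "aasp_sensation_avoiding", "aasp_auditory_total")
  expect_true(all(gp$p[gp$measure %in% shifted] < 0.05))
  expect_true(all(gp$direction[gp$measure %in% shifted] == "DD higher"))
  expect_gt(gp$p[gp$measure == "aasp_sensation_seeking"], 0.05)
  tiny <- p[c(1, 2, 29, 30), ]
  expect_error(groupProfileComparison(tiny), "at least 3")
})
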