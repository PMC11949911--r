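# Network construction, gradient correctness, training behavior, prediction.

tinyDataset <- function(n = 30, S = 4, T = 41, D = 1024, p = 15, K = 18,
                        seed = 1) {
  set.seed(seed)
  E <- array(rnorm(T * D * S, sd = 0.3), c(T, D, S))
  list(embeddings = E,
       stimIndex = sample(S, n, TRUE),
       covariates = matrix(runif(n * p), n, p),
       targets = matrix(runif(n * K), n, K))
}

test_that("output dimensionality follows the task", {
  mR <- buildModel(modelConfig("Recollection", lstmHidden = 3,
                               denseWidths = 4))
  mE <- buildModel(modelConfig("Easing", lstmHidden = 3, denseWidths = 4))
  expect_length(outputSchema(mR), 18)  # 13 parameters + 5 ratings
  expect_length(outputSchema(mE), 22)  # 17 parameters + 5 ratings
})

test_that("builds are reproducible under a seed", {
  cfg <- modelConfig("Recollection", lstmHidden = 4, denseWidths = c(6, 5),
                     seed = 42)
  m1 <- buildModel(cfg)
  m2 <- buildModel(cfg)
  expect_identical(m1@weights, m2@weights)
  m3 <- buildModel(modelConfig("Recollection", lstmHidden = 4,
                               denseWidths = c(6, 5), seed = 43))
  expect_false(identical(m1@weights, m3@weights))
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  T <- 5; D <- 7; S <- 3; H <- 4; P <- 3; K <- 2; n <- 6
  E <- array(rnorm(T * D * S), c(T, D, S))
  stim <- sample(0:(S - 1), n, TRUE)
  C <- matrix(rnorm(n * P), n, P)
  Y <- matrix(runif(n * K), n, K)
  w0 <- hearease:::.lstmInit(D, H, P, 5L, K, 7L)
  lossAt <- function(w)
    hearease:::.lstmTrain(w, E, stim, C, Y, 1L, 6L, 1e-3, 0, 99L,
                          gradCheck = TRUE)$loss
  g <- hearease:::.lstmTrain(w0, E, stim, C, Y, 1L, 6L, 1e-3, 0, 99L,
                             gradCheck = TRUE)$grads
  eps <- 1e-6
  for (nm in c("Wx_f", "Wh_b", "b_f", "W1", "gamma1", "beta1", "W_out",
               "b_out")) {
    idx <- sample(length(w0[[nm]]), min(4, length(w0[[nm]])))
    for (i in idx) {
      wp <- w0; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w0; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("training runs for the configured epochs and reduces the loss", {
  d <- tinyDataset(n = 30)
  cfg <- modelConfig("Recollection", lstmHidden = 4, denseWidths = 6,
                     epochs = 2, seed = 2)
  m <- trainModel(buildModel(cfg), d)
  expect_length(lossTrace(m), 2)
  # a learnable constant target: loss must drop over a longer run
  dConst <- tinyDataset(n = 40)
  dConst$targets[] <- 0.25
  cfg2 <- modelConfig("Recollection", lstmHidden = 4, denseWidths = 6,
                      epochs = 25, seed = 2)
  m2 <- trainModel(buildModel(cfg2), dConst)
  expect_lt(tail(lossTrace(m2), 1), head(lossTrace(m2), 1))
})

test_that("training is bit-for-bit reproducible under a fixed seed", {
  d <- tinyDataset(n = 24)
  cfg <- modelConfig("Recollection", lstmHidden = 3, denseWidths = 5,
                     epochs = 3, seed = 11)
  m1 <- trainModel(buildModel(cfg), d)
  m2 <- trainModel(buildModel(cfg), d)
  expect_identical(m1@weights, m2@weights)
  expect_identical(lossTrace(m1), lossTrace(m2))
})

test_that("predictions respect every declared range and batching is inert", {
  d <- tinyDataset(n = 25)
  cfg <- modelConfig("Recollection", lstmHidden = 3, denseWidths = 5,
                     epochs = 2, seed = 4)
  m <- trainModel(buildModel(cfg), d)
  pred <- predictModel(m, d)
  spec <- filterSpecs("Recollection")
  expect_true(all(pred$unit >= 0 & pred$unit <= 1))
  for (j in seq_len(nrow(spec))) {
    expect_true(all(pred$settings[, j] >= spec$min[j] - 1e-9))
    expect_true(all(pred$settings[, j] <= spec$max[j] + 1e-9))
  }
  expect_true(all(pred$ratings >= 1 & pred$ratings <= 7))
  # chunked vs whole-batch prediction agree (evaluation mode)
  pred2 <- predictModel(m, d, chunkSize = 7L)
  expect_equal(pred$unit, pred2$unit, tolerance = 1e-12)
  one <- lapply(d[c("stimIndex", "covariates", "targets")],
                function(z) if (is.matrix(z)) z[3, , drop = FALSE] else z[3])
  one$embeddings <- d$embeddings
  predOne <- predictModel(m, one)
  expect_equal(predOne$unit[1, ], pred$unit[3, ], tolerance = 1e-6)
  # unit output 0.5 inverts to the range midpoint
  expect_equal(unname((spec$min + 0.5 * (spec$max - spec$min))[1]), 3)
})

test_that("untrained models and mismatched inputs are refused", {
  d <- tinyDataset(n = 10)
  m <- buildModel(modelConfig("Recollection", lstmHidden = 3,
                              denseWidths = 4))
  expect_error(predictModel(m, d), "not been trained")
  dBad <- tinyDataset(n = 10, p = 33)  # Easing-shaped covariates
  expect_error(trainModel(m, dBad), "covariates")
  dEmpty <- tinyDataset(n = 30)
  dEmpty$stimIndex <- integer(0)
  dEmpty$covariates <- dEmpty$covariates[0, , drop = FALSE]
  dEmpty$targets <- dEmpty$targets[0, , drop = FALSE]
  expect_error(trainModel(m, dEmpty), "empty")
})

test_that("the stimulus split partitions scored trials with no leakage", {
  sim <- paperScaleSim()
  for (task in c("Recollection", "Easing")) {
    tr <- sim$trials[sim$trials$task == task, ]
    sp <- splitByStimulus(tr)
    expect_length(intersect(unique(sp$train$stimulus),
                            unique(sp$test$stimulus)), 0)
    scored <- sum(tr$presentation == "scored" & !tr$missing)
    expect_equal(nrow(sp$train) + nrow(sp$test), scored)
  }
  # single-participant table still splits by stimulus with both sides filled
  one <- sim$trials[sim$trials$task == "Recollection" &
                      sim$trials$participant == 5, ]
  spOne <- splitByStimulus(one)
  expect_gt(nrow(spOne$train), 0)
  expect_gt(nrow(spOne$test), 0)
  bad <- one
  bad$stimulus_set[1] <- "Unknown"
  expect_error(splitByStimulus(bad), "[Uu]nlabel")
})
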