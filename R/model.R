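# Predictor construction, training and prediction.

#' Model configuration
#'
#' Hyperparameters of the task predictor: a bidirectional LSTM over the 41
#' embedding frames whose final forward and backward hidden states are
#' concatenated with the covariate vector and passed through a dense stack
#' (linear, batch normalization, SiLU activation, dropout per layer) into a
#' sigmoid output head, so every prediction lies on the unit scale by
#' construction. Trained with minibatch Adam on mean squared error.
#'
#' @param task `"Recollection"` or `"Easing"`.
#' @param lstmHidden LSTM units per direction (default 128).
#' @param denseWidths integer vector of dense-layer widths (default
#'   `c(256, 128)`).
#' @param dropout dropout fraction in `[0, 1)` (default 0.2).
#' @param epochs training epochs (default 300).
#' @param batchSize minibatch size (default 24).
#' @param learningRate Adam step size (default 1e-3).
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @return A named list of class `"modelConfig"`.
#' @export
modelConfig <- function(task = c("Recollection", "Easing"), lstmHidden = 128,
                        denseWidths = c(256, 128), dropout = 0.2,
                        epochs = 300, batchSize = 24, learningRate = 1e-3,
                        seed = 1) {
  task <- match.arg(task)
  stopifnot(lstmHidden >= 1, all(denseWidths >= 1), length(denseWidths) >= 1,
            dropout >= 0, dropout < 1, epochs >= 1, batchSize >= 2,
            learningRate > 0)
  structure(list(task = task, lstmHidden = as.integer(lstmHidden),
                 denseWidths = as.integer(denseWidths),
                 dropout = dropout, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, seed = as.integer(seed)),
            class = "modelConfig")
}

#' @export
print.modelConfig <- function(x, ...) {
  cat(sprintf(
    "modelConfig (%s): lstm %d/dir, dense [%s], dropout %g, %d epochs, batch %d, lr %g, seed %d\n",
    x$task, x$lstmHidden, paste(x$denseWidths, collapse = ", "),
    x$dropout, x$epochs, x$batchSize, x$learningRate, x$seed))
  invisible(x)
}

# Output schema: the task's filter parameter keys, then the five ratings.
.outputSchema <- function(task) {
  c(filterSpecs(task)$key, paste0("rating_", ratingItems()))
}

#' Build an untrained predictor
#'
#' Initializes all weights (Glorot-uniform, forget-gate bias 1) under
#' `config$seed`; two builds with the same seed are identical.
#'
#' @param config a [modelConfig()].
#' @param covariateLength length of the covariate vector (default: the
#'   task's standard schema length, 15 for Recollection and 33 for Easing).
#' @return An untrained [ModelBundle-class].
#' @examples
#' m <- buildModel(modelConfig("Recollection", lstmHidden = 4,
#'                             denseWidths = 8))
#' length(outputSchema(m))  # 18
#' @export
buildModel <- function(config, covariateLength = NULL) {
  stopifnot(inherits(config, "modelConfig"))
  covSchema <- if (config$task == "Recollection") covariateSchema()
               else easingInputSchema()
  if (is.null(covariateLength)) covariateLength <- length(covSchema)
  if (covariateLength != length(covSchema))
    covSchema <- paste0("cov", seq_len(covariateLength))
  schema <- .outputSchema(config$task)
  w <- .lstmInit(1024L, config$lstmHidden, as.integer(covariateLength),
                 config$denseWidths, length(schema), config$seed)
  new("ModelBundle", task = config$task, config = unclass(config),
      weights = w, outputSchema = schema, covariateSchema = covSchema,
      trained = FALSE, lossTrace = numeric())
}

#' @describeIn buildModel ordered names of the model outputs.
#' @param model a [ModelBundle-class].
#' @export
outputSchema <- function(model) model@outputSchema

#' @describeIn buildModel per-epoch mean training loss of a trained model.
#' @export
lossTrace <- function(model) model@lossTrace

# Validate a dataset list as produced by buildTaskDataset().
.checkDataset <- function(data, model = NULL) {
  need <- c("embeddings", "stimIndex", "covariates", "targets")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dataset is missing component(s): ", paste(miss, collapse = ", "))
  n <- length(data$stimIndex)
  stopifnot(nrow(data$covariates) == n, nrow(data$targets) == n)
  if (!is.null(model)) {
    if (ncol(data$covariates) != length(model@covariateSchema))
      stop(sprintf("dataset has %d covariates but the model expects %d",
                   ncol(data$covariates), length(model@covariateSchema)))
    if (ncol(data$targets) != length(model@outputSchema))
      stop(sprintf("dataset has %d targets but the model expects %d",
                   ncol(data$targets), length(model@outputSchema)))
  }
  if (any(data$targets < -1e-9 | data$targets > 1 + 1e-9))
    stop("all targets must be unit-scaled")
  invisible(TRUE)
}

#' Train a predictor
#'
#' Runs minibatch backpropagation for exactly `config$epochs` epochs with the
#' Adam optimizer on mean squared error. All targets must be unit-scaled.
#' Deterministic under a fixed seed on a single thread. Minibatches with
#' fewer than two samples are dropped (batch normalization needs a batch).
#'
#' @param model an untrained (or previously trained) [ModelBundle-class].
#' @param data a dataset list with components `embeddings` (41 x 1024 x S
#'   array of stimulus embeddings), `stimIndex` (1-based stimulus index per
#'   trial), `covariates` (n x p matrix) and `targets` (n x K unit-scale
#'   matrix); see [buildTaskDataset()].
#' @return The trained [ModelBundle-class]; the per-epoch loss trace is
#'   available via [lossTrace()].
#' @export
trainModel <- function(model, data) {
  stopifnot(is(model, "ModelBundle"))
  .checkDataset(data, model)
  if (length(data$stimIndex) < 2) stop("training set is empty or too small")
  cfg <- model@config
  res <- .lstmTrain(model@weights, data$embeddings,
                    as.integer(data$stimIndex - 1L),
                    as.matrix(data$covariates), as.matrix(data$targets),
                    cfg$epochs, cfg$batchSize, cfg$learningRate,
                    cfg$dropout, cfg$seed)
  initialize(model, weights = res$weights, trained = TRUE,
             lossTrace = as.numeric(res$lossTrace))
}

#' Predict filter settings and stress ratings
#'
#' Runs the network in evaluation mode (batch normalization uses running
#' statistics; dropout disabled), then maps the unit-scale outputs back to
#' native units: filter parameters through the inverse min-max map of their
#' declared ranges, ratings onto the continuous 1-7 scale. Predictions are
#' therefore range-respecting for any input.
#'
#' @param model a trained [ModelBundle-class].
#' @param data a dataset list (see [trainModel()]); `targets` not required.
#' @param chunkSize rows propagated per forward pass (memory control).
#' @return list with `unit` (n x K matrix on the unit scale), `settings`
#'   (n x nParams matrix in native units), `ratings` (n x 5 matrix on the
#'   1-7 scale).
#' @export
predictModel <- function(model, data, chunkSize = 64L) {
  stopifnot(is(model, "ModelBundle"))
  if (!model@trained) stop("model has not been trained")
  n <- length(data$stimIndex)
  if (ncol(data$covariates) != length(model@covariateSchema))
    stop("covariates do not match the model's input schema (wrong task?)")
  K <- length(model@outputSchema)
  unit <- matrix(NA_real_, n, K, dimnames = list(NULL, model@outputSchema))
  for (start in seq(1, n, by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, n)
    unit[idx, ] <- .lstmPredict(model@weights, data$embeddings,
                                as.integer(data$stimIndex[idx] - 1L),
                                as.matrix(data$covariates[idx, ,
                                                          drop = FALSE]))
  }
  spec <- filterSpecs(model@task)
  nP <- nrow(spec)
  settings <- sweep(sweep(unit[, seq_len(nP), drop = FALSE], 2,
                          spec$max - spec$min, `*`), 2, spec$min, `+`)
  ratings <- 1 + unit[, nP + seq_len(5), drop = FALSE] * 6
  list(unit = unit, settings = settings, ratings = ratings)
}

#' Split trials by stimulus
#'
#' Partitions scored trials into a training set (trials on Training and
#' Training-reserve stimuli) and a test set (Test and Test-reserve stimuli).
#' No stimulus appears on both sides, so evaluation measures generalization
#' to novel sounds. Repeat presentations and trials flagged missing are
#' excluded from both sides.
#'
#' @param trials a trial table as produced by [generateTrials()]; must carry
#'   `stimulus_set`, `presentation` and `missing` columns.
#' @return list with `train` and `test` data.frames.
#' @examples
#' \donttest{
#' sim <- simulateExperiment(experimentDesign(nDd = 2, nTd = 2), seed = 1)
#' sp <- splitByStimulus(sim$trials[sim$trials$task == "Recollection", ])
#' intersect(unique(sp$train$stimulus), unique(sp$test$stimulus))  # empty
#' }
#' @export
splitByStimulus <- function(trials) {
  need <- c("stimulus_set", "presentation", "missing")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(trials$stimulus_set)))
    stop("every trial must carry a labeled stimulus set")
  bad <- setdiff(unique(trials$stimulus_set),
                 c("Training", "TrainingReserve", "Test", "TestReserve"))
  if (length(bad))
    stop("unlabeled stimulus set(s): ", paste(bad, collapse = ", "))
  keep <- trials$presentation == "scored" & !trials$missing
  scored <- trials[keep, , drop = FALSE]
  train <- scored[scored$stimulus_set %in%
                    c("Training", "TrainingReserve"), , drop = FALSE]
  test <- scored[scored$stimulus_set %in%
                   c("Test", "TestReserve"), , drop = FALSE]
  list(train = train, test = test)
}

#' Assemble model inputs and targets from a trial table
#'
#' Builds the dataset consumed by [trainModel()]/[predictModel()] for one
#' task: the stimulus-embedding index per trial, the unit-scaled covariates
#' (for the Easing task, extended with the trial's Recollection settings and
#' ratings), and the unit-scaled targets (normalized filter parameters
#' followed by normalized ratings).
#'
#' @param trials trial table rows for one task (see [generateTrials()]).
#' @param stimuli the stimulus table the trials refer to (see
#'   [generateStimuli()]).
#' @param embeddings 41 x 1024 x S array, slice `s` embedding stimulus id
#'   `s` (see [embedStimulusSet()]).
#' @param recollectionTrials for the Easing task: the Recollection rows to
#'   pull carried-over settings/ratings from (matched by participant and
#'   stimulus).
#' @return dataset list (`embeddings`, `stimIndex`, `covariates`, `targets`,
#'   `meta`).
#' @export
buildTaskDataset <- function(trials, stimuli, embeddings,
                             recollectionTrials = NULL) {
  task <- unique(trials$task)
  if (length(task) != 1)
    stop("trial rows must belong to a single task")
  spec <- filterSpecs(task)
  n <- nrow(trials)
  settingCols <- paste0("setting.", spec$key)
  ratingCols <- paste0("rating_", ratingItems())
  targets <- cbind(
    as.matrix(sweep(sweep(trials[, settingCols, drop = FALSE], 2, spec$min),
                    2, spec$max - spec$min, `/`)),
    (as.matrix(trials[, ratingCols, drop = FALSE]) - 1) / 6)
  colnames(targets) <- .outputSchema(task)
  cov <- t(vapply(seq_len(n), function(i) {
    r <- trials[i, ]
    buildCovariates(
      profile = list(group = r$group, age = r$age, sex = r$sex, aq = r$aq,
                     aasp_low_registration = r$aasp_low_registration,
                     aasp_sensation_seeking = r$aasp_sensation_seeking,
                     aasp_sensory_sensitivity = r$aasp_sensory_sensitivity,
                     aasp_sensation_avoiding = r$aasp_sensation_avoiding,
                     aasp_auditory_total = r$aasp_auditory_total),
      state = list(sleep_minutes = r$sleep_minutes,
                   fatigue_physical = r$fatigue_physical,
                   fatigue_mental = r$fatigue_mental,
                   bluetooth = r$bluetooth),
      volumeCorrection = volumeCorrectionDb(r$volume_o))
  }, numeric(length(covariateSchema()))))
  if (task == "Easing") {
    if (is.null(recollectionTrials))
      stop("the Easing dataset needs recollectionTrials for inputs (e)")
    key <- paste(trials$participant, trials$stimulus, trials$presentation)
    rkey <- paste(recollectionTrials$participant,
                  recollectionTrials$stimulus,
                  recollectionTrials$presentation)
    m <- match(key, rkey)
    if (any(is.na(m)))
      stop("unmatched Recollection rows for ", sum(is.na(m)), " trial(s)")
    rspec <- filterSpecs("Recollection")
    rs <- as.matrix(recollectionTrials[m, paste0("setting.", rspec$key),
                                       drop = FALSE])
    rsNorm <- sweep(sweep(rs, 2, rspec$min), 2, rspec$max - rspec$min, `/`)
    rr <- (as.matrix(recollectionTrials[m, ratingCols, drop = FALSE]) - 1) / 6
    cov <- cbind(cov, rsNorm, rr)
    colnames(cov) <- easingInputSchema()
  } else {
    colnames(cov) <- covariateSchema()
  }
  list(embeddings = embeddings,
       stimIndex = match(trials$stimulus, stimuli$stimulus),
       covariates = cov, targets = targets,
       meta = trials[, c("participant", "group", "stimulus", "stimulus_set",
                         "task", "presentation")])
}
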