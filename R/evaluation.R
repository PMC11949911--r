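# Evaluation statistics: per-output correlations and MAE, usage counts,
# test-retest reproducibility, task contrast, stimulus comparability and
# group profile comparison.

#' @importFrom stats cor.test ks.test shapiro.test t.test wilcox.test
#'   complete.cases p.adjust plogis rlogis
NULL

.sigStars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.005, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", ""))))
}

#' Evaluate a trained predictor on a test set
#'
#' Computes, for each filter parameter, the Pearson correlation (with
#' p-value) between predicted and true values over all test trials of the
#' selected regime, and for each rating item the Spearman correlation;
#' the mean absolute error is reported in native units (filter parameters on
#' their declared scales, ratings on the 1-7 scale). Outputs without
#' variance on either side yield `NA` correlations. Usage counts (trials in
#' which the parameter differs from its default) are attached per output.
#'
#' @param model a trained [ModelBundle-class].
#' @param data a test dataset from [buildTaskDataset()] (with `meta`).
#' @param regime `"All"`, `"DD"` or `"TD"`: which participants' trials to
#'   evaluate on.
#' @return data.frame of class `"evaluationReport"`: one row per output with
#'   `output`, `type`, `regime`, `n`, `used`, `correlation`, `p`, `stars`,
#'   `mae`.
#' @export
evaluateModel <- function(model, data, regime = c("All", "DD", "TD")) {
  regime <- match.arg(regime)
  stopifnot(is(model, "ModelBundle"))
  keep <- if (regime == "All") rep(TRUE, length(data$stimIndex))
          else data$meta$group == regime
  if (!any(keep)) stop("no trials in regime ", regime)
  sub <- list(embeddings = data$embeddings,
              stimIndex = data$stimIndex[keep],
              covariates = data$covariates[keep, , drop = FALSE],
              targets = data$targets[keep, , drop = FALSE],
              meta = data$meta[keep, , drop = FALSE])
  pred <- predictModel(model, sub)
  spec <- filterSpecs(model@task)
  nP <- nrow(spec)
  trueUnit <- sub$targets
  trueNative <- cbind(
    sweep(sweep(trueUnit[, seq_len(nP), drop = FALSE], 2,
                spec$max - spec$min, `*`), 2, spec$min, `+`),
    1 + trueUnit[, nP + 1:5, drop = FALSE] * 6)
  predNative <- cbind(pred$settings, pred$ratings)
  out <- scoreOutputs(predNative, trueNative, model@task)
  out$regime <- regime
  class(out) <- c("evaluationReport", "data.frame")
  out
}

#' Score predictions against true values, output by output
#'
#' The metric core of [evaluateModel()], usable on any pair of prediction
#' and truth matrices in native units (columns ordered as the task's
#' parameter keys followed by the five rating items): Pearson correlation
#' for filter parameters, Spearman for ratings (ordinal), mean absolute
#' error in native units, and usage counts (true value different from the
#' parameter default). Zero-variance outputs yield `NA` correlations.
#'
#' @param predNative,trueNative numeric matrices, n x (nParams + 5).
#' @param task `"Recollection"` or `"Easing"`.
#' @return data.frame: `output`, `type`, `n`, `used`, `correlation`, `p`,
#'   `stars`, `mae`.
#' @export
scoreOutputs <- function(predNative, trueNative,
                         task = c("Recollection", "Easing")) {
  task <- match.arg(task)
  spec <- filterSpecs(task)
  nP <- nrow(spec)
  schema <- .outputSchema(task)
  if (ncol(predNative) != length(schema) ||
      ncol(trueNative) != length(schema))
    stop(sprintf("matrices must have %d columns for the %s task",
                 length(schema), task))
  res <- lapply(seq_along(schema), function(j) {
    truth <- trueNative[, j]
    est <- predNative[, j]
    isRating <- j > nP
    if (sd(truth) < 1e-12 || sd(est) < 1e-12) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(
        cor.test(est, truth,
                 method = if (isRating) "spearman" else "pearson"))
      r <- unname(ct$estimate); p <- ct$p.value
    }
    used <- if (isRating) NA_integer_
            else sum(abs(truth - spec$default[j]) > 1e-9)
    data.frame(output = schema[j],
               type = if (isRating) "rating" else "setting",
               n = length(truth), used = used,
               correlation = r, p = p, stars = .sigStars(p),
               mae = mean(abs(est - truth)), row.names = NULL)
  })
  do.call(rbind, res)
}

#' Per-parameter usage counts
#'
#' A parameter counts as "used" in a trial when its value differs from the
#' table default. Counts are reported per parameter for the training and
#' test splits, overall and per group.
#'
#' @param trials one task's trial rows (scored, non-missing rows are
#'   counted).
#' @param task `"Recollection"` or `"Easing"`.
#' @return data.frame: `key`, then `train_all`, `test_all`, `train_dd`,
#'   `test_dd`, `train_td`, `test_td`.
#' @export
usageCounts <- function(trials, task = c("Recollection", "Easing")) {
  task <- match.arg(task)
  trials <- trials[trials$task == task, , drop = FALSE]
  spec <- filterSpecs(task)
  sp <- splitByStimulus(trials)
  cnt <- function(d, key, dflt)
    if (!nrow(d)) 0L else
      sum(abs(d[[paste0("setting.", key)]] - dflt) > 1e-9)
  out <- lapply(seq_len(nrow(spec)), function(i) {
    k <- spec$key[i]; d0 <- spec$default[i]
    data.frame(
      key = k,
      train_all = cnt(sp$train, k, d0),
      test_all = cnt(sp$test, k, d0),
      train_dd = cnt(sp$train[sp$train$group == "DD", ], k, d0),
      test_dd = cnt(sp$test[sp$test$group == "DD", ], k, d0),
      train_td = cnt(sp$train[sp$train$group == "TD", ], k, d0),
      test_td = cnt(sp$test[sp$test$group == "TD", ], k, d0),
      row.names = NULL)
  })
  do.call(rbind, out)
}

#' Test-retest reproducibility value
#'
#' For each participant, over the repeated stimuli: a filter counts as
#' "changed" in a presentation when any of its parameters differs from the
#' default. With `C_both` the number of (stimulus, filter) pairs changed in
#' both presentations and `C_one` the number changed in exactly one, the
#' reproducibility value is `C_both / C_one` (the literal ratio reading;
#' `method = "proportion"` gives `C_both / (C_both + C_one)`). Participants
#' with `C_one = 0` (or nothing changed at all) are flagged undefined and
#' excluded from the group mean with a warning.
#'
#' @param trials one task's trial rows including `presentation = "repeat"`
#'   rows.
#' @param task `"Recollection"` or `"Easing"`.
#' @param method `"ratio"` (default) or `"proportion"`.
#' @return list with `perParticipant` (data.frame: participant, cBoth, cOne,
#'   value, defined), `mean`, `se`, `nDefined`.
#' @export
reproducibilityValue <- function(trials,
                                 task = c("Recollection", "Easing"),
                                 method = c("ratio", "proportion")) {
  task <- match.arg(task)
  method <- match.arg(method)
  trials <- trials[trials$task == task, , drop = FALSE]
  spec <- filterSpecs(task)
  filters <- unique(spec$filter)
  changedSet <- function(row) {
    vapply(filters, function(f) {
      keys <- spec$key[spec$filter == f]
      any(abs(as.numeric(row[paste0("setting.", keys)]) -
                spec$default[spec$filter == f]) > 1e-9)
    }, logical(1))
  }
  reps <- trials[trials$presentation == "repeat", , drop = FALSE]
  if (!nrow(reps)) stop("no repeat presentations in the trial table")
  per <- lapply(unique(reps$participant), function(pid) {
    rp <- reps[reps$participant == pid, , drop = FALSE]
    cBoth <- 0L; cOne <- 0L
    for (i in seq_len(nrow(rp))) {
      first <- trials[trials$participant == pid &
                        trials$stimulus == rp$stimulus[i] &
                        trials$presentation == "scored", , drop = FALSE]
      if (!nrow(first)) next
      ch1 <- changedSet(first[1, ])
      ch2 <- changedSet(rp[i, ])
      cBoth <- cBoth + sum(ch1 & ch2)
      cOne <- cOne + sum(xor(ch1, ch2))
    }
    value <- if (method == "ratio") {
      if (cOne == 0) NA_real_ else cBoth / cOne
    } else {
      if (cBoth + cOne == 0) NA_real_ else cBoth / (cBoth + cOne)
    }
    data.frame(participant = pid, cBoth = cBoth, cOne = cOne,
               value = value, defined = !is.na(value), row.names = NULL)
  })
  per <- do.call(rbind, per)
  if (any(!per$defined))
    warning(sum(!per$defined),
            " participant(s) with an undefined reproducibility value ",
            "excluded from the mean")
  vals <- per$value[per$defined]
  list(perParticipant = per,
       mean = mean(vals), se = sd(vals) / sqrt(length(vals)),
       nDefined = length(vals))
}

#' Compare Recollection and Easing stress ratings
#'
#' Pairs trials by (participant, stimulus), checks each item's paired
#' differences with a Shapiro-Wilk test, and runs a paired t-test per rating
#' item (a Wilcoxon signed-rank test is reported alongside for the
#' non-normal case).
#'
#' @param trials the full trial table (both tasks; scored, non-missing rows
#'   are used).
#' @return data.frame: one row per item with `item`, `n`, `meanDiff`
#'   (Easing minus Recollection), `t`, `p`, `pWilcoxon`, `shapiroP`,
#'   `direction` (`"lower"`, `"higher"`, `"none"`).
#' @export
compareTaskRatings <- function(trials) {
  keep <- trials$presentation == "scored" & !trials$missing
  rec <- trials[keep & trials$task == "Recollection", , drop = FALSE]
  eas <- trials[keep & trials$task == "Easing", , drop = FALSE]
  key <- function(d) paste(d$participant, d$stimulus)
  if (nrow(rec) != nrow(eas))
    stop("unpaired rows: ", nrow(rec), " Recollection vs ", nrow(eas),
         " Easing trials")
  m <- match(key(rec), key(eas))
  if (any(is.na(m)))
    stop("unpaired rows: ", sum(is.na(m)),
         " Recollection trial(s) lack an Easing counterpart")
  eas <- eas[m, , drop = FALSE]
  items <- ratingItems()
  out <- lapply(items, function(it) {
    col <- paste0("rating_", it)
    d <- eas[[col]] - rec[[col]]
    sw <- tryCatch(
      shapiro.test(if (length(d) > 5000) sample(d, 5000) else d)$p.value,
      error = function(e) NA_real_)
    tt <- tryCatch(t.test(eas[[col]], rec[[col]], paired = TRUE),
                   error = function(e) list(statistic = NA_real_,
                                            p.value = NA_real_))
    wt <- tryCatch(suppressWarnings(
      wilcox.test(eas[[col]], rec[[col]], paired = TRUE, exact = FALSE)),
      error = function(e) list(p.value = NA_real_))
    dir <- if (is.na(tt$p.value) || tt$p.value >= 0.05 || mean(d) == 0)
      "none" else if (mean(d) < 0) "lower" else "higher"
    data.frame(item = it, n = length(d), meanDiff = mean(d),
               t = unname(tt$statistic), p = tt$p.value,
               pWilcoxon = wt$p.value, shapiroP = sw, direction = dir,
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Train/test stimulus loudness comparability
#'
#' Two-sample Kolmogorov-Smirnov test on the per-stimulus RMS values
#' (frame-wise RMS, frame 2048 / hop 512, averaged per clip) of the training
#' and test stimuli.
#'
#' @param trainRms,testRms numeric vectors of per-stimulus RMS values
#'   (at least 2 each).
#' @return list with `statistic`, `p`.
#' @export
rmsComparability <- function(trainRms, testRms) {
  if (length(trainRms) < 2 || length(testRms) < 2)
    stop("need at least 2 stimuli per side")
  ks <- suppressWarnings(ks.test(trainRms, testRms))
  list(statistic = unname(ks$statistic), p = ks$p.value)
}

#' DD vs TD trait comparison
#'
#' Per measure (AQ, the four AASP quadrants, the AASP auditory total):
#' Shapiro-Wilk normality check per group, then a Mann-Whitney U test with
#' the direction of the group difference.
#'
#' @param participants table from [generateParticipants()].
#' @return data.frame: `measure`, `U`, `p`, `medianDd`, `medianTd`,
#'   `direction` (`"DD higher"`, `"TD higher"`, `"none"`), `shapiroP`.
#' @export
groupProfileComparison <- function(participants) {
  dd <- participants[participants$group == "DD", , drop = FALSE]
  td <- participants[participants$group == "TD", , drop = FALSE]
  if (nrow(dd) < 3 || nrow(td) < 3)
    stop("each group needs at least 3 members")
  measures <- c("aq", "aasp_low_registration", "aasp_sensation_seeking",
                "aasp_sensory_sensitivity", "aasp_sensation_avoiding",
                "aasp_auditory_total")
  out <- lapply(measures, function(msr) {
    x <- dd[[msr]]; y <- td[[msr]]
    sw <- tryCatch(min(shapiro.test(x)$p.value, shapiro.test(y)$p.value),
                   error = function(e) NA_real_)
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    dir <- if (wt$p.value >= 0.05) "none"
           else if (median(x) > median(y)) "DD higher" else "TD higher"
    data.frame(measure = msr, U = unname(wt$statistic), p = wt$p.value,
               medianDd = median(x), medianTd = median(y), direction = dir,
               shapiroP = sw, row.names = NULL)
  })
  do.call(rbind, out)
}

#' @importFrom stats median
NULL
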