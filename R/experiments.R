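#' Run one of the four canonical experiments on a synthetic cohort
#'
#' Reproduces the experimental designs at configurable scale:
#' \describe{
#'   \item{1}{train on the (imbalanced) rolling-kernel dataset, evaluate on
#'     its pooled test split;}
#'   \item{2}{same, but on the key-frame dataset;}
#'   \item{3}{re-evaluate the experiment-1 models class by class (no new
#'     training), reporting average and weighted-average accuracies;}
#'   \item{4}{oversample-balance the rolling-kernel dataset, split, train
#'     and evaluate (typically only the best models).}
#' }
#' Experiment 3 must reuse experiment-1 checkpoints: pass them via
#' `trainedModels`; training anew for experiment 3 is refused.
#'
#' @param id experiment id in 1..4.
#' @param dataset an [SEIDataset-class] (the rolling-kernel dataset for
#'   experiments 1/3/4, the key-frame dataset for 2).
#' @param models character vector of model names (e.g. `"cnn-5"`).
#' @param trainCfg a [TrainConfig-class].
#' @param inputSize classifier input edge length in pixels.
#' @param seed seed for splitting and weight initialization.
#' @param balanceMode `"paper"` balances before splitting (the published
#'   order, which lets duplicates cross the train/test boundary) or
#'   `"train-only"` (default for new work: balance the training split
#'   only).
#' @param trainedModels named list of trained `GaitModel`s (required for
#'   experiment 3).
#' @param channels optional CNN block widths forwarded to [modelSpec()]
#'   (ignored for resnet/vit).
#' @return Named list per model with elements `model` (trained) and
#'   `report` (an [EvalReport-class]).
#' @export
runExperiment <- function(id, dataset, models = "cnn-5",
                          trainCfg = trainConfig(), inputSize = 64L,
                          seed = 1L, balanceMode = c("train-only", "paper"),
                          trainedModels = NULL, channels = NULL) {
  stopifnot(id %in% 1:4, is(dataset, "SEIDataset"))
  balanceMode <- match.arg(balanceMode)
  if (id == 3) {
    if (is.null(trainedModels))
      stop("experiment 3 reuses the experiment-1 checkpoints; ",
           "pass them as 'trainedModels'")
    split <- splitDataset(dataset, seed = childSeed(seed, "split"))
    parts <- perClassPartitions(split@test)
    return(lapply(trainedModels, function(m) {
      perAcc <- vapply(parts$partitions, function(p) {
        evaluateModel(m, dataset, p)@accuracy
      }, numeric(1))
      pooled <- evaluateModel(m, dataset, split@test)
      list(model = m, report = pooled, perClassAccuracy = perAcc,
           averageAccuracy = mean(perAcc),
           weightedAccuracy = sum(parts$weights * perAcc))
    }))
  }
  if (id == 4 && balanceMode == "paper") {
    dataset <- oversampleBalance(dataset, seed = childSeed(seed, "balance"))
    split <- splitDataset(dataset, seed = childSeed(seed, "split"))
  } else if (id == 4) {
    split <- splitDataset(dataset, seed = childSeed(seed, "split"))
    balTrain <- oversampleBalance(split@train,
                                  seed = childSeed(seed, "balance"))
    extra <- balTrain[!balTrain$id %in% split@train$id, , drop = FALSE]
    if (nrow(extra)) {
      idmap <- stats::setNames(seq_along(dataset@images),
                               dataset@records$id)
      dataset <- new("SEIDataset",
                     images = c(dataset@images,
                                dataset@images[idmap[extra$duplicate_of]]),
                     records = rbind(dataset@records, extra))
    }
    split <- new("DatasetSplit", train = balTrain,
                 validation = split@validation, test = split@test,
                 ratios = split@ratios, seed = split@seed)
  } else {
    split <- splitDataset(dataset, seed = childSeed(seed, "split"))
  }
  out <- list()
  for (nm in models) {
    spec <- modelSpec(nm, inputSize = inputSize, channels = channels)
    model <- buildModel(spec, seed = childSeed(seed, paste0("init_", nm)))
    cfg <- trainCfg
    cfg@seed <- childSeed(seed, paste0("train_", nm))
    model <- trainModel(model, dataset, split, cfg)
    report <- evaluateModel(model, dataset, split@test)
    out[[nm]] <- list(model = model, report = report, split = split)
  }
  out
}

#' End-to-end synthetic pipeline run
#'
#' Convenience wrapper chaining the whole pipeline on generated data:
#' cohort generation, skeleton rendering, rolling-kernel (or key-frame)
#' energy-image synthesis, 8:1:1 split, training and evaluation of one
#' model. This is the package's one-call smoke test and the basis of the
#' worked example in the README.
#'
#' @param sequencesPerClass,framesPerSequence cohort size controls
#'   (defaults 10 and 60: 40 sequences, 44 energy images each).
#' @param model model name (default `"cnn-5"`).
#' @param variant `"normal"` or `"keyframe"`.
#' @param trainCfg a [TrainConfig-class]; the default here is a reduced
#'   budget (a fixed 6 epochs at learning rate 1e-3, narrow channels)
#'   suited to the small synthetic problem.
#' @param inputSize classifier input size (default 64).
#' @param seed master seed.
#' @param hardMode narrow class separation (see [severityProfiles()]).
#' @param channels CNN block widths of the reduced-budget configuration
#'   (default 8, 16, 32, 64, 128).
#' @return List with the trained `model`, the `report`
#'   ([EvalReport-class]), the `dataset` and the `split`.
#' @export
runSyntheticPipeline <- function(sequencesPerClass = 10L,
                                 framesPerSequence = 60L,
                                 model = "cnn-5",
                                 variant = "normal",
                                 trainCfg = trainConfig(
                                   learningRate = 1e-3, minEpochs = 6L,
                                   patience = 5L, maxEpochs = 6L),
                                 inputSize = 64L, seed = 1L,
                                 hardMode = FALSE,
                                 channels = c(8, 16, 32, 64, 128)) {
  coh <- generateCohort(sequencesPerClass, framesPerSequence,
                        seed = childSeed(seed, "cohort"),
                        hardMode = hardMode)
  dataset <- buildSEIDataset(coh$sequences, variant = variant,
                             outputSize = inputSize)
  res <- runExperiment(if (variant == "keyframe") 2 else 1, dataset,
                       models = model, trainCfg = trainCfg,
                       inputSize = inputSize, seed = seed,
                       channels = if (model %in% c("cnn-5", "cnn-6"))
                         channels else NULL)
  list(model = res[[model]]$model, report = res[[model]]$report,
       dataset = dataset, split = res[[model]]$split)
}
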