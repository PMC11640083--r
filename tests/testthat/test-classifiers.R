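test_that("exactly the seven model variants are constructible", {
  tab <- SEIgait:::modelTable()
  expect_equal(nrow(tab), 7)
  for (i in seq_len(nrow(tab)))
    expect_s4_class(modelSpec(tab$family[i], tab$variant[i]), "ModelSpec")
  expect_error(modelSpec("resnet", "50"), "valid options")
  expect_error(modelSpec("cnn", "7"), "valid options")
})

test_that("forward pass yields 4 logits per sample for each family", {
  x1 <- array(stats::runif(32 * 32), c(32, 32, 1, 2))
  m <- buildModel(modelSpec("cnn-5", inputSize = 32), seed = 1)
  expect_equal(dim(predictLogits(m, x1)), c(4, 2))
  x3 <- array(stats::runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  m <- buildModel(modelSpec("resnet-18", inputSize = 32), seed = 1)
  expect_equal(dim(predictLogits(m, x3)), c(4, 2))
  m <- buildModel(modelSpec("vit-tiny", inputSize = 32), seed = 1)
  expect_equal(dim(predictLogits(m, x3)), c(4, 2))
})

test_that("parameter counts are ordered within families", {
  n <- vapply(c("cnn-5", "cnn-6", "resnet-18", "resnet-34"), function(nm)
    countParameters(buildModel(modelSpec(nm, inputSize = 64), seed = 1)),
    numeric(1))
  expect_lt(n[["cnn-5"]], n[["cnn-6"]])
  expect_lt(n[["cnn-6"]], n[["resnet-18"]])
  expect_lt(n[["resnet-18"]], n[["resnet-34"]])
  # resnet-34 has almost twice the parameters of resnet-18
  expect_gt(n[["resnet-34"]] / n[["resnet-18"]], 1.7)
  v <- vapply(c("vit-tiny", "vit-small", "vit-base"), function(nm)
    countParameters(buildModel(modelSpec(nm, inputSize = 32), seed = 1)),
    numeric(1))
  expect_lt(v[["vit-tiny"]], v[["vit-small"]])
  expect_lt(v[["vit-small"]], v[["vit-base"]])
})

test_that("model construction is deterministic given a seed", {
  a <- buildModel(modelSpec("cnn-5", inputSize = 32), seed = 5)
  b <- buildModel(modelSpec("cnn-5", inputSize = 32), seed = 5)
  x <- array(stats::runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(predictLogits(a, x), predictLogits(b, x))
})

test_that("early stopping follows the min-epoch and patience rules", {
  runTrace <- function(losses, minEpochs = 25, patience = 20) {
    mon <- earlyStopMonitor(minEpochs, patience)
    e <- 0
    while (e < length(losses) && mon$update(losses[e + 1])) e <- e + 1
    if (e < length(losses)) e <- e + 1       # epoch at which stop fired
    list(stop = mon$epoch(), best = mon$bestEpoch())
  }
  # improving through epoch 5 then flat: min-epoch rule binds, stop at 25
  tr <- runTrace(c(seq(1, 0.5, length.out = 5), rep(0.5, 100)))
  expect_equal(tr$stop, 25)
  expect_equal(tr$best, 5)
  # improving through epoch 30 then flat: stop at 30 + 20 = 50
  tr <- runTrace(c(seq(1, 0.3, length.out = 30), rep(0.3, 100)))
  expect_equal(tr$stop, 50)
  expect_equal(tr$best, 30)
  # retained checkpoint is the global argmin, not the last improvement
  losses <- c(1, 0.4, 0.8, 0.41, rep(0.6, 60))
  tr <- runTrace(losses)
  expect_equal(tr$best, which.min(losses))
  # a late improvement resets the patience window
  losses <- c(seq(1, 0.5, length.out = 10), rep(0.55, 19), 0.45,
              rep(0.5, 40))
  tr <- runTrace(losses)
  expect_equal(tr$stop, 50)
  expect_equal(tr$best, 30)
})

test_that("evaluation reports are internally consistent", {
  truth <- rep(severityClasses(), times = c(10, 5, 3, 2))
  rep1 <- SEIgait:::evalReportFromPredictions(truth, truth)
  expect_equal(rep1@accuracy, 100)
  expect_true(all(rep1@confusion[row(rep1@confusion) !=
                                   col(rep1@confusion)] == 0))
  # constant single-class predictor on a balanced set: 25%
  bal <- rep(severityClasses(), each = 5)
  rep2 <- SEIgait:::evalReportFromPredictions(bal, rep("normal", 20))
  expect_equal(rep2@accuracy, 25)
  # row sums = per-class test counts; accuracy = trace / total
  pred <- withr::with_seed(3, sample(severityClasses(), 20, replace = TRUE))
  rep3 <- SEIgait:::evalReportFromPredictions(truth, pred)
  expect_equal(unname(rowSums(rep3@confusion)), c(10, 5, 3, 2))
  expect_equal(rep3@accuracy,
               100 * sum(diag(rep3@confusion)) / sum(rep3@confusion))
})

test_that("a cnn learns a linearly separable two-blob toy quickly", {
  mk <- function(cls, n) lapply(seq_len(n), function(i) {
    m <- matrix(1, 32, 32)
    r <- if (cls == "normal") 4 else 20
    m[r:(r + 5), 10:22] <- 0
    m
  })
  labels <- rep(c("normal", "severe"), each = 30)
  seis <- c(mk("normal", 30), mk("severe", 30))
  ds <- seiDataset(lapply(seq_along(seis), function(i)
    new("SkeletonEnergyImage", pixels = seis[[i]], segmentId = "s",
        startIndex = 0L, kernel = 17L, variant = "normal",
        label = labels[i])))
  sp <- splitDataset(ds, seed = 2)
  m <- buildModel(modelSpec("cnn-5", inputSize = 32,
                            channels = c(4, 8, 8, 16, 16)), seed = 3)
  m <- suppressWarnings(
    trainModel(m, ds, sp, trainConfig(learningRate = 2e-3,
                                      batchSize = 16, minEpochs = 5,
                                      patience = 4, maxEpochs = 5,
                                      seed = 4)))
  expect_gte(utils::tail(m$curves$valAcc, 1), 100)
})

test_that("training is deterministic given seed and data", {
  ds <- fixtureDataset(c(normal = 8, mild = 8, moderate = 8, severe = 8),
                       h = 16)
  sp <- splitDataset(ds, seed = 1)
  cfg <- trainConfig(learningRate = 1e-3, batchSize = 8, minEpochs = 2,
                     patience = 2, maxEpochs = 2, seed = 6)
  run <- function() {
    m <- buildModel(modelSpec("cnn-5", inputSize = 32,
                              channels = c(2, 2, 4, 4, 4)), seed = 7)
    suppressWarnings(trainModel(m, ds, sp, cfg))$curves
  }
  expect_identical(run(), run())
})
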