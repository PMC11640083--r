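#' TrainConfig: training hyperparameters
#'
#' Defaults follow the study protocol: AdamW, cross-entropy loss, learning
#' rate 5e-5, batch size 64, random weight initialization, a minimum of 25
#' epochs, and early stopping after 20 consecutive epochs without
#' validation-loss improvement. There is no upper epoch limit in the
#' protocol itself; `maxEpochs` is an engineering safety cap that logs
#' loudly when hit.
#'
#' @slot learningRate numeric (default 5e-5).
#' @slot batchSize integer (default 64).
#' @slot minEpochs integer minimum epochs before stopping (default 25).
#' @slot patience integer epochs without validation-loss improvement that
#'   trigger the stop (default 20).
#' @slot maxEpochs integer safety cap (default 500).
#' @slot weightDecay numeric AdamW decoupled weight decay (default 0.01).
#' @slot seed integer.
#' @seealso [trainConfig()], [trainModel()]
#' @export
setClass("TrainConfig", representation(
  learningRate = "numeric",
  batchSize = "integer",
  minEpochs = "integer",
  patience = "integer",
  maxEpochs = "integer",
  weightDecay = "numeric",
  seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@minEpochs < 1L) msg <- c(msg, "minEpochs must be positive")
  if (object@patience < 1L) msg <- c(msg, "patience must be positive")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
  if (length(msg)) msg else TRUE
})

#' @param learningRate,batchSize,minEpochs,patience,maxEpochs,weightDecay,seed
#'   see the class slots.
#' @return `trainConfig()` returns a [TrainConfig-class].
#' @rdname TrainConfig-class
#' @examples
#' trainConfig()
#' @export
trainConfig <- function(learningRate = 5e-5, batchSize = 64L,
                        minEpochs = 25L, patience = 20L, maxEpochs = 500L,
                        weightDecay = 1e-2, seed = 1L) {
  new("TrainConfig", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), minEpochs = as.integer(minEpochs),
      patience = as.integer(patience), maxEpochs = as.integer(maxEpochs),
      weightDecay = as.numeric(weightDecay), seed = as.integer(seed))
}

#' Early-stopping monitor on validation loss
#'
#' Implements the stop rule: training never stops before `minEpochs`;
#' afterwards it stops as soon as the last `patience` consecutive epochs
#' brought no improvement (strict decrease) of the validation loss. The
#' retained checkpoint is the global best epoch. The monitor is a small
#' stateful object so the rule can be exercised with scripted loss traces
#' independently of any actual training.
#'
#' @param minEpochs,patience integers (defaults 25 and 20).
#' @return A list with `update(valLoss)` (returns `TRUE` while training
#'   should continue), `bestEpoch()`, `bestLoss()` and `epoch()`.
#' @examples
#' # improves through epoch 5, flat afterwards: stops at epoch 25
#' mon <- earlyStopMonitor(25, 20)
#' losses <- c(seq(1, 0.6, length.out = 5), rep(0.6, 40))
#' e <- 0
#' while (e < length(losses) && mon$update(losses[e + 1])) e <- e + 1
#' mon$epoch()      # 25
#' mon$bestEpoch()  # 5
#' @export
earlyStopMonitor <- function(minEpochs = 25L, patience = 20L) {
  st <- new.env(parent = emptyenv())
  st$epoch <- 0L
  st$best <- Inf
  st$bestEpoch <- 0L
  st$sinceBest <- 0L
  list(
    update = function(valLoss) {
      st$epoch <- st$epoch + 1L
      if (valLoss < st$best) {
        st$best <- valLoss
        st$bestEpoch <- st$epoch
        st$sinceBest <- 0L
      } else {
        st$sinceBest <- st$sinceBest + 1L
      }
      !(st$epoch >= minEpochs && st$sinceBest >= patience)
    },
    epoch = function() st$epoch,
    bestEpoch = function() st$bestEpoch,
    bestLoss = function() st$best)
}

labelIndex <- function(labels) {
  match(labels, severityClasses())
}

# Mean loss and accuracy of a model on an image list, in inference mode.
evalLoss <- function(model, imgs, labels, batchSize = 64L) {
  n <- length(imgs)
  y <- labelIndex(labels)
  tot <- 0
  hits <- 0L
  for (start in seq(1L, n, by = batchSize)) {
    sel <- start:min(start + batchSize - 1L, n)
    logits <- predictLogits(model, batchInput(model, imgs[sel]))
    sc <- softmaxCrossEntropy(logits, y[sel])
    tot <- tot + sc$loss * length(sel)
    hits <- hits + sum(apply(logits, 2, which.max) == y[sel])
  }
  list(loss = tot / n, acc = 100 * hits / n)
}

#' Train a classifier with AdamW, cross-entropy and early stopping
#'
#' Runs seeded mini-batch training on the train split, evaluates loss and
#' accuracy on the validation split after every epoch, applies the
#' [earlyStopMonitor()] rule, and restores the parameters of the epoch with
#' the best validation loss before returning. Fully deterministic given
#' `config@seed`.
#'
#' @param model a `GaitModel` from [buildModel()].
#' @param data an [SEIDataset-class] holding the images.
#' @param split a [DatasetSplit-class] over the dataset's records.
#' @param config a [TrainConfig-class].
#' @param verbose print a line per epoch (default `FALSE`).
#' @return The model, with trained weights and a `curves` data.frame
#'   (epoch, trainLoss, trainAcc, valLoss, valAcc) attached.
#' @export
trainModel <- function(model, data, split, config = trainConfig(),
                       verbose = FALSE) {
  stopifnot(inherits(model, "GaitModel"), is(data, "SEIDataset"),
            is(split, "DatasetSplit"))
  idmap <- stats::setNames(seq_along(data@images), data@records$id)
  trIds <- split@train$id
  if (!length(trIds)) stop("training split is empty")
  # duplicates created by oversampling reference the original image
  srcIds <- ifelse(is.na(split@train$duplicate_of), split@train$id,
                   split@train$duplicate_of)
  trImgs <- data@images[idmap[srcIds]]
  trY <- labelIndex(split@train$label)
  vaSrc <- ifelse(is.na(split@validation$duplicate_of), split@validation$id,
                  split@validation$duplicate_of)
  vaImgs <- data@images[idmap[vaSrc]]
  vaLab <- split@validation$label
  layers <- collectParams(model$net)
  opt <- newAdamW(layers, lr = config@learningRate,
                  weightDecay = config@weightDecay)
  mon <- earlyStopMonitor(config@minEpochs, config@patience)
  curves <- NULL
  bestSnap <- snapshotParams(layers)
  withSeed(config@seed, {
    n <- length(trImgs)
    repeat {
      ep <- mon$epoch() + 1L
      if (ep > config@maxEpochs) {
        warning("maxEpochs safety cap (", config@maxEpochs,
                ") reached before the early-stopping rule fired")
        break
      }
      perm <- sample.int(n)
      epLoss <- 0
      epHits <- 0L
      for (start in seq(1L, n, by = config@batchSize)) {
        sel <- perm[start:min(start + config@batchSize - 1L, n)]
        x <- batchInput(model, trImgs[sel])
        logits <- model$net$forward(x, training = TRUE)
        sc <- softmaxCrossEntropy(logits, trY[sel])
        model$net$backward(sc$dlogits)
        opt$step()
        epLoss <- epLoss + sc$loss * length(sel)
        epHits <- epHits + sum(apply(logits, 2, which.max) == trY[sel])
      }
      # pin batch-norm inference statistics to the current weights before
      # measuring validation performance
      nCal <- min(n, 512L)
      calSel <- perm[seq_len(nCal)]
      calBatches <- lapply(seq(1L, nCal, by = config@batchSize),
                           function(start) {
                             sel <- calSel[start:min(start +
                                                       config@batchSize - 1L,
                                                     nCal)]
                             batchInput(model, trImgs[sel])
                           })
      calibrateBatchNorm(model$net, calBatches)
      va <- evalLoss(model, vaImgs, vaLab, config@batchSize)
      curves <- rbind(curves, data.frame(
        epoch = ep, trainLoss = epLoss / n, trainAcc = 100 * epHits / n,
        valLoss = va$loss, valAcc = va$acc))
      if (verbose)
        message(sprintf("epoch %3d: train loss %.4f acc %5.1f%% | val loss %.4f acc %5.1f%%",
                        ep, epLoss / n, 100 * epHits / n, va$loss, va$acc))
      cont <- mon$update(va$loss)
      if (mon$bestEpoch() == ep) bestSnap <- snapshotParams(layers)
      if (!cont) break
    }
  })
  restoreParams(layers, bestSnap)
  model$curves <- curves
  model$bestEpoch <- mon$bestEpoch()
  model
}

#' Evaluate a classifier on labeled records
#'
#' Computes the full evaluation report: overall accuracy, the 4 x 4
#' confusion matrix (rows = true class), per-class precision / recall / F1
#' / support, and the per-class accuracies with their unweighted and
#' support-weighted averages (the weighted average equals pooled accuracy).
#'
#' @param model a `GaitModel`.
#' @param data an [SEIDataset-class].
#' @param recs records data.frame (e.g. the `test` slot of a
#'   [DatasetSplit-class]).
#' @param batchSize evaluation batch size.
#' @return An [EvalReport-class].
#' @export
evaluateModel <- function(model, data, recs, batchSize = 64L) {
  idmap <- stats::setNames(seq_along(data@images), data@records$id)
  src <- ifelse(is.na(recs$duplicate_of), recs$id, recs$duplicate_of)
  imgs <- data@images[idmap[src]]
  pred <- predictClasses(model, imgs, batchSize)
  evalReportFromPredictions(recs$label, pred,
                            curves = model$curves %||% data.frame())
}

# Build an EvalReport from true/predicted label vectors.
evalReportFromPredictions <- function(truth, pred, curves = data.frame()) {
  cls <- severityClasses()
  conf <- table(factor(truth, levels = cls), factor(pred, levels = cls))
  conf <- matrix(as.integer(conf), 4, 4, dimnames = dimnames(conf))
  support <- rowSums(conf)
  tp <- diag(conf)
  precision <- ifelse(colSums(conf) > 0, tp / colSums(conf), NA_real_)
  recall <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  perAcc <- 100 * recall
  present <- support > 0
  weights <- support[present] / sum(support)
  new("EvalReport",
      accuracy = 100 * sum(tp) / sum(conf),
      confusion = conf,
      perClass = data.frame(class = cls, precision = precision,
                            recall = recall, f1 = f1, support = support,
                            accuracy = perAcc, row.names = NULL),
      averageAccuracy = mean(perAcc[present]),
      weightedAccuracy = sum(weights * perAcc[present]),
      curves = curves)
}
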