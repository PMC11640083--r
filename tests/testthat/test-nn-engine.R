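# Gradient checks of the backprop engine against central finite
# differences, per architectural family.

gradCheckNet <- function(net, xdim, seed = 42, nPerParam = 4, eps = 1e-5) {
  withr::local_seed(seed)
  layers <- SEIgait:::collectParams(net)
  x <- array(stats::rnorm(prod(xdim)), xdim)
  y <- sample(1:4, xdim[length(xdim)], replace = TRUE)
  lossAt <- function()
    SEIgait:::softmaxCrossEntropy(net$forward(x, training = TRUE), y)$loss
  sc <- SEIgait:::softmaxCrossEntropy(net$forward(x, training = TRUE), y)
  dx <- net$backward(sc$dlogits)
  worst <- 0
  for (l in layers) for (nm in names(l$params)) {
    idx <- sample(length(l$params[[nm]]),
                  min(nPerParam, length(l$params[[nm]])))
    for (i in idx) {
      orig <- l$params[[nm]][i]
      l$params[[nm]][i] <- orig + eps; lp <- lossAt()
      l$params[[nm]][i] <- orig - eps; lm <- lossAt()
      l$params[[nm]][i] <- orig
      num <- (lp - lm) / (2 * eps)
      ana <- l$grads[[nm]][i]
      worst <- max(worst, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
    }
  }
  for (i in sample(length(x), 6)) {
    orig <- x[i]
    x[i] <- orig + eps; lp <- lossAt()
    x[i] <- orig - eps; lm <- lossAt()
    x[i] <- orig
    num <- (lp - lm) / (2 * eps)
    worst <- max(worst, abs(num - dx[i]) / max(1e-6, abs(num) + abs(dx[i])))
  }
  worst
}

test_that("convolutional stack gradients match finite differences", {
  net <- withr::with_seed(1, SEIgait:::newSequential(
    SEIgait:::newConv2d(1L, 3L, 3L), SEIgait:::newBatchNorm2d(3L),
    SEIgait:::newGELU(), SEIgait:::newMaxPool2(),
    SEIgait:::newConv2d(3L, 4L, 3L, 2L), SEIgait:::newGlobalAvgPool(),
    SEIgait:::newDense(4L, 4L)))
  expect_lt(gradCheckNet(net, c(9, 9, 1, 3)), 1e-4)
})

test_that("residual block gradients match finite differences", {
  net <- withr::with_seed(2, SEIgait:::newSequential(
    SEIgait:::newResBlock(2L, 3L, 2L), SEIgait:::newResBlock(3L, 3L, 1L),
    SEIgait:::newGlobalAvgPool(), SEIgait:::newDense(3L, 4L)))
  expect_lt(gradCheckNet(net, c(8, 8, 2, 2)), 1e-4)
})

test_that("transformer gradients match finite differences", {
  net <- withr::with_seed(3, SEIgait:::newSequential(
    SEIgait:::newPatchEmbed(8L, 4L, 1L, 8L),
    SEIgait:::newTransformerBlock(8L, 2L),
    SEIgait:::newLayerNorm(8L), SEIgait:::newClsPool(),
    SEIgait:::newDense(8L, 4L)))
  expect_lt(gradCheckNet(net, c(8, 8, 1, 2)), 1e-4)
})

test_that("batch-norm calibration reproduces exact population statistics", {
  bn <- withr::with_seed(4, SEIgait:::newBatchNorm2d(3L))
  batches <- withr::with_seed(5, lapply(1:4, function(i)
    array(stats::rnorm(6 * 6 * 3 * 5, mean = i), c(6, 6, 3, 5))))
  SEIgait:::calibrateBatchNorm(bn, batches)
  allv <- lapply(1:3, function(c_)
    unlist(lapply(batches, function(b) b[, , c_, ])))
  expect_equal(bn$runMean, vapply(allv, mean, numeric(1)),
               tolerance = 1e-12)
  popVar <- vapply(allv, function(v) mean((v - mean(v))^2), numeric(1))
  expect_equal(bn$runVar, popVar, tolerance = 1e-10)
})

test_that("softmax cross-entropy matches a direct computation", {
  withr::local_seed(6)
  logits <- matrix(stats::rnorm(12), 4, 3)
  y <- c(2L, 4L, 1L)
  sc <- SEIgait:::softmaxCrossEntropy(logits, y)
  direct <- -mean(vapply(1:3, function(n)
    logits[y[n], n] - log(sum(exp(logits[, n]))), numeric(1)))
  expect_equal(sc$loss, direct, tolerance = 1e-12)
  expect_equal(colSums(sc$probs), rep(1, 3), tolerance = 1e-12)
})
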