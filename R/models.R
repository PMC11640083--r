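#' ModelSpec: one of the seven classifier variants
#'
#' Exactly seven `(family, variant)` pairs are constructible: `cnn` with 5
#' or 6 convolution blocks, `resnet` at depth 18 or 34, and `vit` at tiny,
#' small or base size.
#'
#' @slot family `"cnn"`, `"resnet"` or `"vit"`.
#' @slot variant `"5"`/`"6"`, `"18"`/`"34"`, or `"tiny"`/`"small"`/`"base"`.
#' @slot numClasses integer, fixed at 4.
#' @slot inputSize integer edge length in pixels images are resized to
#'   (default 224).
#' @slot channels numeric CNN block widths (unused for resnet/vit).
#' @slot dropout numeric length-2: conv-block and head dropout rates.
#' @seealso [modelSpec()], [buildModel()]
#' @export
setClass("ModelSpec", representation(
  family = "character",
  variant = "character",
  numClasses = "integer",
  inputSize = "integer",
  channels = "numeric",
  dropout = "numeric"))

modelTable <- function() {
  data.frame(family = c("cnn", "cnn", "resnet", "resnet",
                        "vit", "vit", "vit"),
             variant = c("5", "6", "18", "34", "tiny", "small", "base"),
             stringsAsFactors = FALSE)
}

setValidity("ModelSpec", function(object) {
  tab <- modelTable()
  ok <- any(tab$family == object@family & tab$variant == object@variant)
  if (!ok)
    return(paste0("unknown model; valid options: ",
                  paste(tab$family, tab$variant, sep = "-", collapse = ", ")))
  if (object@numClasses != 4L) return("numClasses is fixed at 4")
  if (object@inputSize < 16L) return("inputSize must be >= 16")
  TRUE
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec %s-%s (%d classes, input %dx%d)\n", object@family,
              object@variant, object@numClasses, object@inputSize,
              object@inputSize))
})

#' Construct a model specification
#'
#' @param family,variant one of the seven pairs: cnn-5, cnn-6, resnet-18,
#'   resnet-34, vit-tiny, vit-small, vit-base. A single string like
#'   `"cnn-5"` may be given as `family`.
#' @param inputSize input edge length in pixels (default 224; smaller
#'   values give proportionally cheaper models for reduced-budget runs).
#' @param channels CNN block widths; default 16, 32, 64, 128, 256 and, for
#'   cnn-6, 512.
#' @param dropout conv-block and head dropout rates (default 0.25, 0.5).
#' @return A [ModelSpec-class].
#' @examples
#' modelSpec("cnn-5")
#' modelSpec("vit", "tiny", inputSize = 64)
#' @export
modelSpec <- function(family, variant = NULL, inputSize = 224L,
                      channels = NULL, dropout = c(0.25, 0.5)) {
  if (is.null(variant) && grepl("-", family)) {
    parts <- strsplit(family, "-", fixed = TRUE)[[1]]
    family <- parts[1]; variant <- parts[2]
  }
  if (is.null(channels))
    channels <- if (identical(variant, "6")) c(16, 32, 64, 128, 256, 512)
                else c(16, 32, 64, 128, 256)
  new("ModelSpec", family = family, variant = as.character(variant),
      numClasses = 4L, inputSize = as.integer(inputSize),
      channels = as.numeric(channels), dropout = as.numeric(dropout))
}

# Standard published dimension sets, patch 16.
vitDims <- function(variant) {
  switch(variant,
         tiny  = list(D = 192L, heads = 3L, depth = 12L),
         small = list(D = 384L, heads = 6L, depth = 12L),
         base  = list(D = 768L, heads = 12L, depth = 12L),
         stop("unknown vit variant: ", variant))
}

buildCnn <- function(spec) {
  ch <- as.integer(spec@channels)
  nblocks <- as.integer(spec@variant)
  if (length(ch) != nblocks)
    stop("cnn-", spec@variant, " needs ", nblocks, " channel widths")
  if (spec@inputSize %/% 2^nblocks < 1L)
    stop("inputSize ", spec@inputSize, " collapses to nothing after ",
         nblocks, " pooling stages; use at least ", 2^nblocks, " pixels")
  layers <- list()
  inC <- 1L
  for (i in seq_len(nblocks)) {
    layers <- c(layers, list(newConv2d(inC, ch[i], 3L),
                             newBatchNorm2d(ch[i]), newReLU(),
                             newMaxPool2(), newDropout(spec@dropout[1])))
    inC <- ch[i]
  }
  layers <- c(layers, list(newGlobalAvgPool(),
                           newDense(inC, 256L), newReLU(),
                           newDropout(spec@dropout[2]),
                           newDense(256L, spec@numClasses)))
  do.call(newSequential, layers)
}

buildResnet <- function(spec) {
  blocks <- switch(spec@variant, "18" = c(2L, 2L, 2L, 2L),
                   "34" = c(3L, 4L, 6L, 3L))
  widths <- c(64L, 128L, 256L, 512L)
  layers <- list(newConv2d(3L, 64L, 7L, 2L, pad = 3L),
                 newBatchNorm2d(64L), newReLU(), newMaxPool2())
  inC <- 64L
  for (s in seq_along(widths)) {
    for (b in seq_len(blocks[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      layers <- c(layers, list(newResBlock(inC, widths[s], stride)))
      inC <- widths[s]
    }
  }
  layers <- c(layers, list(newGlobalAvgPool(),
                           newDense(512L, spec@numClasses)))
  do.call(newSequential, layers)
}

buildVit <- function(spec) {
  dm <- vitDims(spec@variant)
  if (spec@inputSize %% 16L != 0L)
    stop("vit input size must be a multiple of the 16-pixel patch")
  layers <- list(newPatchEmbed(spec@inputSize, 16L, 3L, dm$D))
  for (i in seq_len(dm$depth))
    layers <- c(layers, list(newTransformerBlock(dm$D, dm$heads)))
  layers <- c(layers, list(newLayerNorm(dm$D), newClsPool(),
                           newDense(dm$D, spec@numClasses)))
  do.call(newSequential, layers)
}

#' Build an untrained classifier
#'
#' Instantiates the network for a [ModelSpec-class] with randomly
#' initialized weights (no pretraining). CNNs take a single grayscale
#' channel; ResNets and ViTs use their standard 3-channel stems, so
#' grayscale energy images are replicated across channels at input time.
#' The CNN head applies global average pooling before the 256-unit hidden
#' layer, which keeps the head size independent of input resolution and
#' preserves the parameter-count ordering cnn-5 < cnn-6.
#'
#' @param spec a [ModelSpec-class].
#' @param seed integer seed for weight initialization.
#' @return A `GaitModel` object (list with the network, spec, and a
#'   `forward(x, training)` function producing 4 logits per sample).
#' @examples
#' m <- buildModel(modelSpec("cnn-5", inputSize = 32), seed = 1)
#' dim(predictLogits(m, array(runif(32 * 32), c(32, 32, 1, 1))))
#' @export
buildModel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  net <- withSeed(seed, switch(spec@family,
                               cnn = buildCnn(spec),
                               resnet = buildResnet(spec),
                               vit = buildVit(spec)))
  structure(list(spec = spec, net = net, seed = as.integer(seed)),
            class = "GaitModel")
}

#' @export
print.GaitModel <- function(x, ...) {
  cat(sprintf("GaitModel %s-%s: %s learnable parameters\n",
              x$spec@family, x$spec@variant,
              format(countParameters(x), big.mark = ",")))
  invisible(x)
}

#' Count learnable parameters of a model
#'
#' @param model a `GaitModel` from [buildModel()].
#' @return Number of learnable scalars (weights, biases, norm parameters,
#'   class/position tokens).
#' @examples
#' countParameters(buildModel(modelSpec("cnn-5", inputSize = 32)))
#' @export
countParameters <- function(model) {
  countLayerParams(model$net)
}

# Assemble a batch array from a list of grayscale matrices, resizing to the
# spec input size and replicating channels for 3-channel stems. Images are
# fed as stroke intensity (1 - gray level): energy images are white-
# background rasters, and presenting the strokes as signal on a zero
# background is the natural input coding for nets trained from scratch.
batchInput <- function(model, imgs) {
  s <- model$spec@inputSize
  C <- if (model$spec@family == "cnn") 1L else 3L
  n <- length(imgs)
  x <- array(0, c(s, s, C, n))
  for (i in seq_len(n)) {
    im <- 1 - resizeImage(imgs[[i]], s)
    for (c_ in seq_len(C)) x[, , c_, i] <- im
  }
  x
}

#' Forward pass: logits and class probabilities
#'
#' `predictLogits()` runs the network in inference mode on a batch array
#' `(H, W, C, N)`; `predictClasses()` maps a list of grayscale images to
#' severity labels.
#'
#' @param model a `GaitModel`.
#' @param x batch array `(H, W, C, N)`.
#' @param imgs list of grayscale matrices.
#' @param batchSize evaluation batch size.
#' @return `predictLogits()`: a `numClasses x N` matrix.
#'   `predictClasses()`: a character vector of predicted labels.
#' @export
predictLogits <- function(model, x) {
  model$net$forward(x, training = FALSE)
}

#' @rdname predictLogits
#' @export
predictClasses <- function(model, imgs, batchSize = 64L) {
  n <- length(imgs)
  out <- character(n)
  for (start in seq(1L, n, by = batchSize)) {
    sel <- start:min(start + batchSize - 1L, n)
    logits <- predictLogits(model, batchInput(model, imgs[sel]))
    out[sel] <- severityClasses()[apply(logits, 2, which.max)]
  }
  out
}
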