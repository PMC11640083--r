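#' Energy-image synthesis settings
#'
#' @param kernel number of consecutive skeleton images averaged into one
#'   energy image (default 17; about 1.5 gait cycles at 10 fps).
#' @param keyframeWindow history length of the key-frame rule (default 10).
#' @param keyframeFactor key-frame threshold multiplier (default 1.5).
#' @param keyframeFollowers frames required after a key frame; must be
#'   `kernel - 1` (default 16).
#' @return An [SEIConfig-class] object.
#' @examples
#' seiConfig()
#' @export
seiConfig <- function(kernel = 17L, keyframeWindow = 10L,
                      keyframeFactor = 1.5,
                      keyframeFollowers = kernel - 1L) {
  new("SEIConfig", kernel = as.integer(kernel),
      keyframeWindow = as.integer(keyframeWindow),
      keyframeFactor = as.numeric(keyframeFactor),
      keyframeFollowers = as.integer(keyframeFollowers))
}

# Pull a list of pixel matrices out of SkeletonImage lists (or pass through
# plain matrices), checking shapes agree.
asPixelStack <- function(imgs) {
  mats <- lapply(imgs, function(im)
    if (is.matrix(im)) im else pixels(im))
  d <- dim(mats[[1]])
  same <- vapply(mats, function(m) identical(dim(m), d), logical(1))
  if (!all(same)) stop("all images must have the same shape")
  mats
}

#' Compute one skeleton energy image from a full kernel of skeleton images
#'
#' The energy image is the pixel-wise arithmetic mean of exactly `kernel`
#' skeleton images: `E(i,j) = (1/K) * sum_n S_n(i,j)`.
#'
#' @param imgs list of exactly `config@kernel` [SkeletonImage-class]
#'   objects (or plain matrices), all of the same shape.
#' @param config an [SEIConfig-class].
#' @param variant `"normal"` or `"keyframe"`, recorded as provenance.
#' @param label severity label recorded on the output.
#' @param segmentId,startIndex provenance; by default taken from the first
#'   image.
#' @return A [SkeletonEnergyImage-class].
#' @examples
#' imgs <- replicate(17, matrix(1, 4, 4), simplify = FALSE)
#' imgs[[1]][2, 2] <- 0
#' pixels(computeSEI(imgs))[2, 2] * 17  # 16
#' @export
computeSEI <- function(imgs, config = seiConfig(), variant = "normal",
                       label = NA_character_, segmentId = NULL,
                       startIndex = NULL) {
  if (length(imgs) != config@kernel)
    stop("computeSEI needs exactly ", config@kernel, " images, got ",
         length(imgs))
  mats <- asPixelStack(imgs)
  acc <- Reduce(`+`, mats) / length(mats)
  first <- imgs[[1]]
  if (is.null(segmentId))
    segmentId <- if (is.matrix(first)) "unknown" else first@segmentId
  if (is.null(startIndex))
    startIndex <- if (is.matrix(first)) 0L else first@frameIndex
  new("SkeletonEnergyImage", pixels = acc,
      segmentId = as.character(segmentId),
      startIndex = as.integer(startIndex),
      kernel = config@kernel, variant = variant,
      label = as.character(label))
}

#' Slide a stride-1 rolling kernel over a skeleton sequence
#'
#' Produces `N - kernel + 1` energy images from `N` skeleton images: the
#' m-th uses frames `m ... m + kernel - 1`. A 17-image sequence yields
#' exactly one energy image; shorter sequences are an error because they
#' are discarded upstream (see [dropShortSegments()] and
#' [validateSequence()]).
#'
#' @inheritParams computeSEI
#' @return List of [SkeletonEnergyImage-class], in window order.
#' @examples
#' imgs <- replicate(20, matrix(1, 4, 4), simplify = FALSE)
#' length(rollingSEI(imgs))  # 4
#' @export
rollingSEI <- function(imgs, config = seiConfig(), label = NA_character_) {
  k <- config@kernel
  n <- length(imgs)
  if (n < k)
    stop("sequence has ", n, " skeleton images but the kernel needs ", k,
         "; sequences shorter than the kernel are discarded upstream")
  mats <- asPixelStack(imgs)
  lapply(seq_len(n - k + 1L), function(m)
    computeSEI(imgs[m:(m + k - 1L)], config, variant = "normal",
               label = label))
}

#' Per-frame difference series of a frame sequence
#'
#' The difference value of frame `t` (t >= 2) is the mean absolute
#' grayscale pixel difference between frame `t` and frame `t - 1`; the
#' first frame has no difference value (`NA`).
#'
#' @param frames a [FrameSequence-class], [VideoFrames-class], or list of
#'   numeric matrices.
#' @return Numeric vector of length `length(frames)`; first element `NA`.
#' @examples
#' frameDifferenceSeries(list(matrix(0, 2, 2), matrix(1, 2, 2)))
#' @export
frameDifferenceSeries <- function(frames) {
  if (is(frames, "FrameSequence") || is(frames, "VideoFrames"))
    frames <- frames@frames
  if (length(frames) < 2)
    stop("need at least 2 frames to form a difference series")
  mats <- asPixelStack(frames)
  c(NA_real_,
    vapply(seq_along(mats)[-1], function(t)
      mean(abs(mats[[t]] - mats[[t - 1]])), numeric(1)))
}

#' Detect key frames from a difference series
#'
#' The first frame is always a key frame. Frame `t` is a key frame when its
#' difference value strictly exceeds `keyframeFactor` times the mean of the
#' differences of the preceding `keyframeWindow` frames (window truncated to
#' the available history; at least one prior difference is required).
#'
#' @param diffs numeric difference series from [frameDifferenceSeries()]
#'   (first element `NA`).
#' @param config an [SEIConfig-class].
#' @return Integer vector of key-frame indices (1-based), always containing
#'   1.
#' @examples
#' detectKeyFrames(c(NA, rep(1, 10), 2))  # frames 1 and 12
#' @export
detectKeyFrames <- function(diffs, config = seiConfig()) {
  n <- length(diffs)
  keys <- 1L
  if (n < 3) return(keys)
  for (t in 3:n) {
    lo <- max(2L, t - config@keyframeWindow)
    hist <- diffs[lo:(t - 1L)]
    hist <- hist[!is.na(hist)]
    if (length(hist) && !is.na(diffs[t]) &&
        diffs[t] > config@keyframeFactor * mean(hist))
      keys <- c(keys, t)
  }
  keys
}

#' Form key-frame energy images
#'
#' For each key frame with at least `kernel - 1` following frames in the
#' segment, averages the 17-frame window starting at the key frame into one
#' energy image. A window is only formed when every frame in it has a valid
#' skeleton image: if any frame in the window was rejected during pose
#' filtering, that key frame generates no energy image.
#'
#' @param keyFrames integer key-frame indices (1-based, aligned to the
#'   sampled frame sequence).
#' @param sis list of [SkeletonImage-class] (or `NULL` for frames rejected
#'   by pose filtering), aligned to the same frame indices.
#' @param config an [SEIConfig-class].
#' @param label severity label recorded on the outputs.
#' @return List of [SkeletonEnergyImage-class] with `variant = "keyframe"`;
#'   possibly empty.
#' @export
keyframeSEIs <- function(keyFrames, sis, config = seiConfig(),
                         label = NA_character_) {
  k <- config@kernel
  out <- list()
  for (kf in keyFrames) {
    if (kf + config@keyframeFollowers > length(sis)) next
    window <- sis[kf:(kf + k - 1L)]
    if (any(vapply(window, is.null, logical(1)))) next
    sei <- computeSEI(window, config, variant = "keyframe", label = label)
    sei@variant <- "keyframe"
    out <- c(out, sei)
  }
  out
}
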