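#' @import methods
NULL

#' PoseFrame: the keypoints of one video frame
#'
#' Holds the `(x, y, p)` records of the body joints detected in a single
#' frame: pixel coordinates (origin top-left, y increasing downward, 0-based)
#' and a detection confidence in `[0, 1]` per joint. A frame that has passed
#' [filterFrame()] carries exactly the 12 body joints.
#'
#' @slot frameIndex integer ordinal of the frame within its segment (>= 0).
#' @slot joint character vector of joint names (subset of [jointNames()],
#'   no duplicates).
#' @slot x,y numeric pixel coordinates, finite.
#' @slot confidence numeric detection confidences in `[0, 1]`.
#' @seealso [PoseFrame()], [filterFrame()]
#' @export
setClass("PoseFrame", representation(
  frameIndex = "integer",
  joint = "character",
  x = "numeric",
  y = "numeric",
  confidence = "numeric"))

setValidity("PoseFrame", function(object) {
  msg <- character()
  n <- length(object@joint)
  if (length(object@x) != n || length(object@y) != n ||
      length(object@confidence) != n)
    msg <- c(msg, "joint, x, y and confidence must have equal length")
  if (anyDuplicated(object@joint))
    msg <- c(msg, "duplicate joint names")
  bad <- setdiff(object@joint, jointNames())
  if (length(bad))
    msg <- c(msg, paste0("unknown joint name(s): ", paste(bad, collapse = ", ")))
  if (n > 0 && (!all(is.finite(object@x)) || !all(is.finite(object@y))))
    msg <- c(msg, "coordinates must be finite")
  if (n > 0 && (any(object@confidence < 0) || any(object@confidence > 1)))
    msg <- c(msg, "confidence must lie in [0, 1]")
  if (length(object@frameIndex) != 1 || is.na(object@frameIndex) ||
      object@frameIndex < 0)
    msg <- c(msg, "frameIndex must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' PoseSequence: an ordered run of pose frames from one video segment
#'
#' Groups the retained [PoseFrame-class] objects of a single manually
#' segmented video clip, together with its provenance: segment and subject
#' identifiers, the severity class label, and the walking orientation.
#'
#' @slot segmentId,subjectId character identifiers.
#' @slot label one of [severityClasses()], or `NA` when unlabeled.
#' @slot orientation one of [segmentOrientations()].
#' @slot frames list of [PoseFrame-class] with strictly increasing
#'   `frameIndex`.
#' @seealso [PoseSequence()], [validateSequence()]
#' @export
setClass("PoseSequence", representation(
  segmentId = "character",
  subjectId = "character",
  label = "character",
  orientation = "character",
  frames = "list"))

setValidity("PoseSequence", function(object) {
  msg <- character()
  if (!all(vapply(object@frames, is, logical(1), "PoseFrame")))
    msg <- c(msg, "frames must all be PoseFrame objects")
  else if (length(object@frames) > 1) {
    idx <- vapply(object@frames, function(f) f@frameIndex, integer(1))
    if (any(diff(idx) <= 0))
      msg <- c(msg, "frameIndex must be strictly increasing")
  }
  if (!is.na(object@label) && !object@label %in% severityClasses())
    msg <- c(msg, paste0("label must be one of: ",
                         paste(severityClasses(), collapse = ", ")))
  if (!object@orientation %in% segmentOrientations())
    msg <- c(msg, paste0("orientation must be one of: ",
                         paste(segmentOrientations(), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SkeletonImage: one rasterized, height-normalized headless skeleton
#'
#' A single stick-figure raster: dark strokes (0) on a white background (1),
#' drawn from the 12 normalized keypoints of one frame.
#'
#' @slot pixels numeric matrix with values in `[0, 1]`; rows are image rows
#'   (y), columns are image columns (x).
#' @slot segmentId character provenance.
#' @slot frameIndex integer provenance.
#' @seealso [renderSkeleton()]
#' @export
setClass("SkeletonImage", representation(
  pixels = "matrix",
  segmentId = "character",
  frameIndex = "integer"))

setValidity("SkeletonImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (any(p < 0) || any(p > 1)) return("pixel values must lie in [0, 1]")
  TRUE
})

#' SkeletonEnergyImage: the pixel-wise mean of a kernel of skeleton images
#'
#' The energy image `E(i,j)` obtained by averaging the corresponding pixels
#' of `kernel` consecutive skeleton images; gray levels encode how long each
#' pixel was covered by a bone over the window.
#'
#' @slot pixels numeric matrix in `[0, 1]`.
#' @slot segmentId character provenance.
#' @slot startIndex integer: frame index of the first skeleton image in the
#'   kernel window.
#' @slot kernel integer window length (default pipeline value 17).
#' @slot variant `"normal"` (rolling kernel) or `"keyframe"`.
#' @slot label severity class inherited from the source sequence (`NA` if
#'   unlabeled).
#' @seealso [computeSEI()], [rollingSEI()]
#' @export
setClass("SkeletonEnergyImage", representation(
  pixels = "matrix",
  segmentId = "character",
  startIndex = "integer",
  kernel = "integer",
  variant = "character",
  label = "character"))

setValidity("SkeletonEnergyImage", function(object) {
  msg <- character()
  if (any(object@pixels < 0) || any(object@pixels > 1))
    msg <- c(msg, "pixel values must lie in [0, 1]")
  if (!object@variant %in% c("normal", "keyframe"))
    msg <- c(msg, "variant must be 'normal' or 'keyframe'")
  if (object@kernel < 1L)
    msg <- c(msg, "kernel must be >= 1")
  if (length(msg)) msg else TRUE
})

#' RenderConfig: skeleton rasterization settings
#'
#' @slot targetHeight numeric: vertical extent, in pixels, that every pose is
#'   scaled to before rasterization (default 360).
#' @slot canvas integer length-2 `(height, width)` of the output raster
#'   (default 400 x 400; the ~11% margin keeps swinging limbs on-canvas).
#' @slot lineWidth numeric stroke width in pixels (default 3).
#' @seealso [renderConfig()], [renderSkeleton()]
#' @export
setClass("RenderConfig", representation(
  targetHeight = "numeric",
  canvas = "integer",
  lineWidth = "numeric"))

setValidity("RenderConfig", function(object) {
  msg <- character()
  if (length(object@canvas) != 2 || any(object@canvas < 1))
    msg <- c(msg, "canvas must be two positive integers (height, width)")
  if (object@targetHeight > object@canvas[1])
    msg <- c(msg, "targetHeight must not exceed canvas height")
  if (object@lineWidth < 1)
    msg <- c(msg, "lineWidth must be >= 1")
  if (length(msg)) msg else TRUE
})

#' SEIConfig: energy-image synthesis settings
#'
#' @slot kernel integer number of consecutive skeleton images averaged into
#'   one energy image (default 17, about 1.5 gait cycles at 10 fps).
#' @slot keyframeWindow integer history length for the key-frame rule
#'   (default 10 preceding frame differences).
#' @slot keyframeFactor numeric threshold multiplier (default 1.5): a frame
#'   is a key frame when its difference strictly exceeds `keyframeFactor`
#'   times the mean of the preceding window.
#' @slot keyframeFollowers integer frames required after a key frame to form
#'   a sequence; must equal `kernel - 1` (default 16).
#' @seealso [seiConfig()], [detectKeyFrames()]
#' @export
setClass("SEIConfig", representation(
  kernel = "integer",
  keyframeWindow = "integer",
  keyframeFactor = "numeric",
  keyframeFollowers = "integer"))

setValidity("SEIConfig", function(object) {
  msg <- character()
  if (object@kernel < 1L) msg <- c(msg, "kernel must be >= 1")
  if (object@keyframeFollowers != object@kernel - 1L)
    msg <- c(msg, "keyframeFollowers must equal kernel - 1")
  if (object@keyframeWindow < 1L) msg <- c(msg, "keyframeWindow must be >= 1")
  if (object@keyframeFactor <= 0) msg <- c(msg, "keyframeFactor must be > 0")
  if (length(msg)) msg else TRUE
})

#' VideoFrames: an in-memory stack of video frames
#'
#' Container standing in for a decoded video: an ordered list of grayscale
#' rasters (matrices in `[0, 1]`) at a fixed native frame rate. Frame `k`
#' (1-based) has timestamp `(k - 1) / fps` seconds. Produced by the synthetic
#' stick-figure rasterizer or loaded from a directory of PNG frames.
#'
#' @slot videoId character identifier.
#' @slot fps numeric native frame rate (frames per second).
#' @slot frames list of numeric matrices, all of identical shape.
#' @seealso [videoFrames()], [sampleFrames()]
#' @export
setClass("VideoFrames", representation(
  videoId = "character",
  fps = "numeric",
  frames = "list"))

setValidity("VideoFrames", function(object) {
  if (object@fps <= 0) return("fps must be positive")
  if (length(object@frames)) {
    dims <- vapply(object@frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      return("all frames must have the same shape")
  }
  TRUE
})

#' FrameSequence: frames sampled from one manifest segment
#'
#' The result of sampling a manifest segment from a video at a fixed rate:
#' the sampled rasters, their timestamps, and the segment's provenance.
#'
#' @slot segmentId,subjectId character identifiers.
#' @slot label severity class or `NA`.
#' @slot orientation one of [segmentOrientations()].
#' @slot frames list of numeric matrices.
#' @slot timestamps numeric seconds, uniformly spaced at `1/fps`.
#' @slot fps numeric sampling rate.
#' @seealso [sampleFrames()], [dropShortSegments()]
#' @export
setClass("FrameSequence", representation(
  segmentId = "character",
  subjectId = "character",
  label = "character",
  orientation = "character",
  frames = "list",
  timestamps = "numeric",
  fps = "numeric"))

setValidity("FrameSequence", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@timestamps))
    msg <- c(msg, "frames and timestamps must have equal length")
  if (length(object@timestamps) > 1) {
    sp <- diff(object@timestamps)
    if (any(abs(sp - 1 / object@fps) > 1 / object@fps))
      msg <- c(msg, "inter-frame spacing must be 1/fps within one frame period")
  }
  if (length(msg)) msg else TRUE
})

#' SEIDataset: labeled energy images with provenance
#'
#' Column-oriented container for a set of energy images destined for
#' classifier training: a list of pixel matrices plus a records table with
#' one row per image (id, label, provenance, oversampling marker).
#'
#' @slot images list of numeric matrices, parallel to `records$id`.
#' @slot records data.frame with columns `id`, `label`, `video_id`,
#'   `segment_id`, `subject_id`, `start_index`, `variant`, `duplicate_of`
#'   (`NA` for originals; set by [oversampleBalance()]).
#' @seealso [seiDataset()], [splitDataset()], [oversampleBalance()]
#' @export
setClass("SEIDataset", representation(
  images = "list",
  records = "data.frame"))

setValidity("SEIDataset", function(object) {
  msg <- character()
  need <- c("id", "label", "video_id", "segment_id", "subject_id",
            "start_index", "variant", "duplicate_of")
  miss <- setdiff(need, names(object@records))
  if (length(miss))
    msg <- c(msg, paste0("records is missing column(s): ",
                         paste(miss, collapse = ", ")))
  else {
    if (nrow(object@records) != length(object@images))
      msg <- c(msg, "images and records must have equal length")
    bad <- !object@records$label %in% severityClasses()
    if (any(bad)) msg <- c(msg, "labels must be severity classes")
  }
  if (length(msg)) msg else TRUE
})

#' DatasetSplit: a train/validation/test partition of dataset records
#'
#' @slot train,validation,test data.frames of records (same columns as
#'   `records(SEIDataset)`), forming a partition of the input records.
#' @slot ratios numeric length-3 target ratios (default `c(8, 1, 1)`).
#' @slot seed integer seed that produced the assignment.
#' @seealso [splitDataset()]
#' @export
setClass("DatasetSplit", representation(
  train = "data.frame",
  validation = "data.frame",
  test = "data.frame",
  ratios = "numeric",
  seed = "integer"))

#' EvalReport: classifier evaluation outputs
#'
#' @slot accuracy overall accuracy in percent.
#' @slot confusion 4 x 4 integer matrix, rows = true class, columns =
#'   predicted class, in [severityClasses()] order.
#' @slot perClass data.frame with per-class `precision`, `recall`, `f1`,
#'   `support` and `accuracy` (the class-wise accuracy when the test set is
#'   supplied class by class, which equals recall).
#' @slot averageAccuracy unweighted mean of per-class accuracies (percent).
#' @slot weightedAccuracy support-weighted mean of per-class accuracies
#'   (percent); equals pooled accuracy.
#' @slot curves data.frame of per-epoch training/validation loss and
#'   accuracy (empty when the model was not trained by [trainModel()]).
#' @seealso [evaluateModel()]
#' @export
setClass("EvalReport", representation(
  accuracy = "numeric",
  confusion = "matrix",
  perClass = "data.frame",
  averageAccuracy = "numeric",
  weightedAccuracy = "numeric",
  curves = "data.frame"))

#' GaitParams: synthetic gait generator controls
#'
#' Parameters of the sagittal-plane stick-figure walker used to generate
#' labeled 12-joint pose sequences.
#'
#' @slot severity one of [severityClasses()].
#' @slot trunkLean numeric forward trunk inclination, degrees from vertical.
#' @slot armSwing numeric shoulder-angle amplitude, degrees.
#' @slot cadence numeric gait cycles per second.
#' @slot stepLength numeric hip-angle amplitude as a fraction of leg length.
#' @slot footLift numeric swing-phase knee flexion as a fraction of leg
#'   length.
#' @slot tremorJitter numeric sd of Gaussian coordinate noise, pixels.
#' @slot fps numeric sampling rate of the emitted sequence.
#' @slot seed integer RNG seed.
#' @seealso [gaitParams()], [generateGaitSequence()]
#' @export
setClass("GaitParams", representation(
  severity = "character",
  trunkLean = "numeric",
  armSwing = "numeric",
  cadence = "numeric",
  stepLength = "numeric",
  footLift = "numeric",
  tremorJitter = "numeric",
  fps = "numeric",
  seed = "integer"))

setValidity("GaitParams", function(object) {
  msg <- character()
  if (!object@severity %in% severityClasses())
    msg <- c(msg, "severity must be one of the severity classes")
  if (object@cadence <= 0) msg <- c(msg, "cadence must be > 0")
  amps <- c(object@armSwing, object@stepLength, object@footLift,
            object@tremorJitter)
  if (any(amps < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (length(msg)) msg else TRUE
})
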