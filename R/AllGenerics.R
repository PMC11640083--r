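#' Accessors for pipeline objects
#'
#' Small accessor family used across the pipeline classes: `pixels()` for
#' raster content, `seqLabel()` for severity labels, `segmentId()` for
#' provenance, `poseFrames()` for the frame list of a [PoseSequence-class],
#' `nFrames()` for frame counts, and `records()`/`images()` for the record
#' table and image list of an [SEIDataset-class].
#'
#' @param x a pipeline object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("seqLabel", function(x) standardGeneric("seqLabel"))

#' @rdname accessors
#' @export
setGeneric("segmentId", function(x) standardGeneric("segmentId"))

#' @rdname accessors
#' @export
setGeneric("poseFrames", function(x) standardGeneric("poseFrames"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname accessors
#' @export
setMethod("pixels", "SkeletonImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("pixels", "SkeletonEnergyImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("seqLabel", "PoseSequence", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("seqLabel", "SkeletonEnergyImage", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("segmentId", "PoseSequence", function(x) x@segmentId)

#' @rdname accessors
#' @export
setMethod("segmentId", "SkeletonImage", function(x) x@segmentId)

#' @rdname accessors
#' @export
setMethod("segmentId", "SkeletonEnergyImage", function(x) x@segmentId)

#' @rdname accessors
#' @export
setMethod("segmentId", "FrameSequence", function(x) x@segmentId)

#' @rdname accessors
#' @export
setMethod("poseFrames", "PoseSequence", function(x) x@frames)

#' @rdname accessors
#' @export
setMethod("nFrames", "PoseSequence", function(x) length(x@frames))

#' @rdname accessors
#' @export
setMethod("nFrames", "FrameSequence", function(x) length(x@frames))

#' @rdname accessors
#' @export
setMethod("nFrames", "VideoFrames", function(x) length(x@frames))

#' @rdname accessors
#' @export
setMethod("records", "SEIDataset", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("records", "DatasetSplit", function(x)
  rbind(x@train, x@validation, x@test))

#' @rdname accessors
#' @export
setMethod("images", "SEIDataset", function(x) x@images)

setMethod("show", "PoseFrame", function(object) {
  cat(sprintf("PoseFrame #%d with %d keypoint(s)\n",
              object@frameIndex, length(object@joint)))
})

setMethod("show", "PoseSequence", function(object) {
  cat(sprintf("PoseSequence '%s' (subject %s, label %s, %s): %d frame(s)\n",
              object@segmentId, object@subjectId, object@label,
              object@orientation, length(object@frames)))
})

setMethod("show", "SkeletonImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SkeletonImage %dx%d (segment %s, frame %d)\n",
              d[1], d[2], object@segmentId, object@frameIndex))
})

setMethod("show", "SkeletonEnergyImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SkeletonEnergyImage %dx%d (%s, segment %s, start %d, kernel %d, label %s)\n",
              d[1], d[2], object@variant, object@segmentId,
              object@startIndex, object@kernel, object@label))
})

setMethod("show", "SEIDataset", function(object) {
  tab <- table(factor(object@records$label, levels = severityClasses()))
  cat(sprintf("SEIDataset: %d image(s)\n", nrow(object@records)))
  cat("  per class:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit (%s, seed %d): train %d / validation %d / test %d\n",
              paste(object@ratios, collapse = ":"), object@seed,
              nrow(object@train), nrow(object@validation), nrow(object@test)))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.2f%%\n", object@accuracy))
  cat("Confusion matrix (rows = true):\n")
  print(object@confusion)
  print(object@perClass, digits = 4)
  cat(sprintf("Average accuracy %.2f%%, weighted average %.2f%%\n",
              object@averageAccuracy, object@weightedAccuracy))
})

setMethod("show", "VideoFrames", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1]]) else c(0L, 0L)
  cat(sprintf("VideoFrames '%s': %d frame(s) %dx%d at %g fps\n",
              object@videoId, length(object@frames), d[1], d[2], object@fps))
})

setMethod("show", "FrameSequence", function(object) {
  cat(sprintf("FrameSequence '%s' (label %s, %s): %d frame(s) at %g fps\n",
              object@segmentId, object@label, object@orientation,
              length(object@frames), object@fps))
})

setMethod("show", "GaitParams", function(object) {
  cat(sprintf(
    "GaitParams [%s]: lean %.1f deg, swing %.1f deg, cadence %.2f Hz, step %.2f, lift %.2f, jitter %.1f px\n",
    object@severity, object@trunkLean, object@armSwing, object@cadence,
    object@stepLength, object@footLift, object@tremorJitter))
})
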