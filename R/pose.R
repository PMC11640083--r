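#' Construct a PoseFrame
#'
#' @param frameIndex integer ordinal of the frame within its segment (>= 0).
#' @param joint character vector of joint names (see [jointNames()]).
#' @param x,y numeric pixel coordinates (origin top-left, y downward,
#'   0-based).
#' @param confidence numeric detection confidences in `[0, 1]`.
#' @return A [PoseFrame-class] object.
#' @examples
#' PoseFrame(0L, jointNames(), x = 1:12, y = 1:12, confidence = rep(1, 12))
#' @export
PoseFrame <- function(frameIndex, joint, x, y, confidence) {
  new("PoseFrame", frameIndex = as.integer(frameIndex),
      joint = as.character(joint), x = as.numeric(x), y = as.numeric(y),
      confidence = as.numeric(confidence))
}

#' Construct a PoseSequence
#'
#' @param segmentId,subjectId character identifiers.
#' @param label one of [severityClasses()] or `NA`.
#' @param orientation one of [segmentOrientations()].
#' @param frames list of [PoseFrame-class] objects with strictly increasing
#'   `frameIndex`.
#' @return A [PoseSequence-class] object.
#' @export
PoseSequence <- function(segmentId, subjectId, label = NA_character_,
                         orientation = "sideways", frames = list()) {
  new("PoseSequence", segmentId = as.character(segmentId),
      subjectId = as.character(subjectId), label = as.character(label),
      orientation = as.character(orientation), frames = frames)
}

#' Filter one frame's raw keypoints down to the 12 confident body joints
#'
#' Applies the per-frame retention rule: a keypoint is valid only when its
#' confidence is strictly greater than `threshold` (default 0.5), and a
#' frame is retained only when all 12 body joints are valid. Head and face
#' points (e.g. the 5 COCO head keypoints) are dropped before the count.
#' COCO names (`"nose"`, `"left_ankle"`, ...) are translated via
#' [cocoJointMap()]; unknown joint names are an input error, distinct from
#' rejection.
#'
#' @param raw data.frame with columns `joint`, `x`, `y`, `confidence` (one
#'   row per detected keypoint), or a [PoseFrame-class].
#' @param threshold numeric retention threshold; a keypoint with confidence
#'   exactly equal to the threshold is rejected (the rule is strict).
#' @param frameIndex integer index used when `raw` is a data.frame.
#' @return A [PoseFrame-class] with exactly 12 keypoints, or `NULL` when the
#'   frame is rejected (any body joint missing or at or below threshold).
#' @examples
#' raw <- data.frame(joint = jointNames(), x = 1:12, y = 1:12,
#'                   confidence = 0.9)
#' filterFrame(raw)                      # retained
#' raw$confidence[5] <- 0.4
#' is.null(filterFrame(raw))             # rejected: only 11 valid joints
#' @export
filterFrame <- function(raw, threshold = 0.5, frameIndex = 0L) {
  if (is(raw, "PoseFrame")) {
    frameIndex <- raw@frameIndex
    raw <- data.frame(joint = raw@joint, x = raw@x, y = raw@y,
                      confidence = raw@confidence, stringsAsFactors = FALSE)
  }
  need <- c("joint", "x", "y", "confidence")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("raw keypoints are missing column(s): ", paste(miss, collapse = ", "))
  joint <- as.character(raw$joint)
  map <- cocoJointMap()
  head_names <- map$coco_name[is.na(map$joint)]
  coco_body <- map$coco_name[!is.na(map$joint)]
  # translate COCO body names; drop head points silently
  is_head <- joint %in% head_names
  joint[joint %in% coco_body] <-
    map$joint[match(joint[joint %in% coco_body], map$coco_name)]
  unknown <- !is_head & !joint %in% jointNames()
  if (any(unknown))
    stop("unknown joint name(s): ",
         paste(unique(joint[unknown]), collapse = ", "))
  keep <- !is_head
  joint <- joint[keep]
  x <- as.numeric(raw$x)[keep]
  y <- as.numeric(raw$y)[keep]
  p <- as.numeric(raw$confidence)[keep]
  valid <- p > threshold
  if (anyDuplicated(joint[valid]))
    stop("duplicate joint name(s) in frame")
  if (sum(valid) < 12L || !setequal(joint[valid], jointNames()))
    return(NULL)
  ord <- match(jointNames(), joint[valid])
  PoseFrame(frameIndex, jointNames(), x[valid][ord], y[valid][ord],
            p[valid][ord])
}

#' Accept or reject a pose sequence by retained-frame count
#'
#' A sequence whose retained frames cannot fill one energy-image kernel is
#' discarded: fewer than `minFrames` (default 17) skeleton images means no
#' energy image can be formed from it.
#'
#' @param seq a [PoseSequence-class].
#' @param minFrames integer minimum number of retained frames (default 17).
#' @return `TRUE` (accepted) or `FALSE` (rejected).
#' @examples
#' fr <- lapply(0:16, function(i)
#'   PoseFrame(i, jointNames(), 1:12, 1:12, rep(1, 12)))
#' validateSequence(PoseSequence("s", "p", "normal", frames = fr))
#' @export
validateSequence <- function(seq, minFrames = 17L) {
  stopifnot(is(seq, "PoseSequence"))
  length(seq@frames) >= minFrames
}

# Convert a PoseFrame to a 12 x 2 coordinate matrix in jointNames() order.
poseCoords <- function(frame) {
  ord <- match(jointNames(), frame@joint)
  if (anyNA(ord))
    stop("frame does not contain all 12 body joints")
  co <- cbind(x = frame@x[ord], y = frame@y[ord])
  rownames(co) <- jointNames()
  co
}
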