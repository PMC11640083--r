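#' The 12-joint body vocabulary
#'
#' The pipeline works on a fixed set of 12 body joints: shoulders, elbows,
#' wrists, hips, knees and feet (left and right). Head and face joints are
#' never used, because the source videos are face-blurred and the rendered
#' skeletons are headless. Joints carry stable integer codes 0-11 in the
#' order returned by `jointNames()`.
#'
#' @return `jointNames()` returns the 12 joint names in code order;
#'   `jointCodes()` returns the named integer codes 0-11.
#' @examples
#' jointNames()
#' jointCodes()["left_knee"]
#' @export
jointNames <- function() {
  c("right_shoulder", "left_shoulder",
    "right_elbow",    "left_elbow",
    "right_wrist",    "left_wrist",
    "right_hip",      "left_hip",
    "right_knee",     "left_knee",
    "right_foot",     "left_foot")
}

#' @rdname jointNames
#' @export
jointCodes <- function() {
  stats::setNames(0:11, jointNames())
}

#' Map 17-point COCO keypoints onto the 12-joint body vocabulary
#'
#' The COCO convention indexes 17 keypoints 0-16: nose (0), eyes (1-2), ears
#' (3-4), shoulders (5-6), elbows (7-8), wrists (9-10), hips (11-12), knees
#' (13-14) and ankles (15-16). The five head points map to nothing; COCO
#' ankles serve as "feet". The mapping is fixed by index: COCO 5 is the left
#' shoulder and COCO 6 the right (COCO's left/right are the subject's own).
#'
#' @return A data.frame with columns `coco_index` (0-16), `coco_name`, and
#'   `joint` (one of [jointNames()] or `NA` for head points).
#' @examples
#' cocoJointMap()
#' @export
cocoJointMap <- function() {
  coco <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
            "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
            "left_wrist", "right_wrist", "left_hip", "right_hip",
            "left_knee", "right_knee", "left_ankle", "right_ankle")
  joint <- c(rep(NA_character_, 5),
             "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
             "left_wrist", "right_wrist", "left_hip", "right_hip",
             "left_knee", "right_knee", "left_foot", "right_foot")
  data.frame(coco_index = 0:16, coco_name = coco, joint = joint,
             stringsAsFactors = FALSE)
}

#' Severity class labels
#'
#' The four severity classes, corresponding to UPDRS gait scores 0-3, in
#' increasing order of severity.
#'
#' @return Character vector `c("normal", "mild", "moderate", "severe")`.
#' @export
severityClasses <- function() {
  c("normal", "mild", "moderate", "severe")
}

#' Segment orientations
#'
#' The four walking orientations a video segment can capture.
#'
#' @return Character vector of the orientation labels.
#' @export
segmentOrientations <- function() {
  c("forwards", "backwards", "sideways", "transition")
}

#' Skeleton bone connectivity
#'
#' The 12 straight bones traced between the 12 joints when rasterizing a
#' headless skeleton: upper/lower arms and legs on both sides, the shoulder
#' and hip cross-bars, and the two ipsilateral trunk edges (shoulder to hip).
#'
#' @return A 12 x 2 character matrix; each row is one bone, columns are the
#'   two joint names it connects.
#' @examples
#' boneList()
#' @export
boneList <- function() {
  bones <- rbind(
    c("right_shoulder", "right_elbow"),
    c("right_elbow",    "right_wrist"),
    c("left_shoulder",  "left_elbow"),
    c("left_elbow",     "left_wrist"),
    c("right_hip",      "right_knee"),
    c("right_knee",     "right_foot"),
    c("left_hip",       "left_knee"),
    c("left_knee",      "left_foot"),
    c("right_shoulder", "left_shoulder"),
    c("right_hip",      "left_hip"))
  bones <- rbind(bones,
    c("right_shoulder", "right_hip"),
    c("left_shoulder",  "left_hip"))
  colnames(bones) <- c("from", "to")
  bones
}
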