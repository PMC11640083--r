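# Shared fixture builders for the test suite.

# A full 12-joint raw keypoint table at a given confidence.
rawBodyFrame <- function(confidence = 0.9, x = NULL, y = NULL) {
  data.frame(joint = jointNames(),
             x = x %||% seq(40, 160, length.out = 12),
             y = y %||% seq(100, 280, length.out = 12),
             confidence = confidence,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A 17-point COCO frame (5 head + 12 body joints).
rawCocoFrame <- function(confidence = 0.8) {
  map <- cocoJointMap()
  data.frame(joint = map$coco_name,
             x = seq_len(17) * 10, y = seq_len(17) * 15,
             confidence = confidence, stringsAsFactors = FALSE)
}

# An accepted PoseFrame with all 12 joints.
bodyPoseFrame <- function(frameIndex = 0L, xoff = 0, yoff = 0, scale = 1) {
  co <- seq(100, 280, length.out = 12)
  PoseFrame(frameIndex, jointNames(),
            x = (seq(40, 160, length.out = 12)) * scale + xoff,
            y = co * scale + yoff,
            confidence = rep(1, 12))
}

# A PoseSequence of n accepted frames.
fixtureSequence <- function(n = 17, segmentId = "seg1", label = "normal") {
  PoseSequence(segmentId, "subj1", label, "sideways",
               lapply(seq_len(n) - 1L, bodyPoseFrame))
}

# A stack of random-valued images in [0, 1].
randomStack <- function(n, h = 8, w = 8, seed = 1) {
  withr::with_seed(seed,
    replicate(n, matrix(runif(h * w), h, w), simplify = FALSE))
}

# A small labeled SEIDataset with the given per-class counts.
fixtureDataset <- function(counts = c(normal = 6, mild = 3, moderate = 4,
                                      severe = 5), h = 8, seed = 1) {
  labels <- rep(names(counts), counts)
  seis <- withr::with_seed(seed, lapply(seq_along(labels), function(i)
    new("SkeletonEnergyImage", pixels = matrix(runif(h * h), h, h),
        segmentId = paste0("seg", i), startIndex = 0L, kernel = 17L,
        variant = "normal", label = labels[i])))
  seiDataset(seis)
}
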