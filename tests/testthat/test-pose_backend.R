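frameSeqOf <- function(n, segmentId = "seg1") {
  new("FrameSequence", segmentId = segmentId, subjectId = "p1",
      label = "normal", orientation = "sideways",
      frames = replicate(n, matrix(0.5, 4, 4), simplify = FALSE),
      timestamps = (seq_len(n) - 1) / 10, fps = 10)
}

test_that("registry resolves built-ins and rejects duplicates and unknowns", {
  expect_true(all(c("replay", "synthetic", "yolov8m") %in% listBackends()))
  expect_error(registerBackend("replay", function() NULL),
               "already registered")
  expect_error(resolveBackend("openpose"), "available: .*replay")
  expect_error(resolveBackend("yolov8m"), "optional")
  nm <- paste0("custom", as.integer(stats::runif(1, 1, 1e6)))
  registerBackend(nm, function() poseBackend(nm, function(f, m) NULL))
  expect_s3_class(resolveBackend(nm), "PoseBackend")
})

test_that("replay backend reproduces stored sequences exactly", {
  sq <- fixtureSequence(17)
  be <- resolveBackend("replay", sequences = list(sq))
  est <- suppressMessages(estimateSequence(be, frameSeqOf(17)))
  expect_equal(nFrames(est), 17)
  expect_equal(est@frames[[5]]@x, sq@frames[[5]]@x)
  expect_equal(est@label, "normal")
})

test_that("frames where the backend returns 11 joints are omitted, others kept", {
  sq <- fixtureSequence(17)
  # drop one joint from stored frame index 7
  sq@frames[[8]]@joint <- sq@frames[[8]]@joint[-1]
  sq@frames[[8]]@x <- sq@frames[[8]]@x[-1]
  sq@frames[[8]]@y <- sq@frames[[8]]@y[-1]
  sq@frames[[8]]@confidence <- sq@frames[[8]]@confidence[-1]
  be <- resolveBackend("replay", sequences = list(sq))
  est <- suppressMessages(estimateSequence(be, frameSeqOf(17)))
  expect_equal(nFrames(est), 16)
  expect_false(7L %in% vapply(est@frames, function(f) f@frameIndex,
                              integer(1)))
})

test_that("the largest-bounding-box person is selected in multi-person frames", {
  small <- data.frame(joint = jointNames(), x = seq(0, 11), y = seq(0, 22, 2),
                      confidence = 1, stringsAsFactors = FALSE)
  big <- data.frame(joint = jointNames(), x = seq(0, 110, 10),
                    y = seq(0, 220, 20), confidence = 1,
                    stringsAsFactors = FALSE)
  be <- poseBackend("twoPeople", function(frame, meta) list(small, big))
  est <- suppressMessages(estimateSequence(be, frameSeqOf(3)))
  expect_equal(nFrames(est), 3)
  expect_equal(max(est@frames[[1]]@x), 110)
})

test_that("downstream results are identical between live and saved-replayed poses", {
  params <- gaitParams("mild", seed = 21L)
  be <- resolveBackend("synthetic", params = params)
  live <- suppressMessages(estimateSequence(be, frameSeqOf(20)))
  path <- withr::local_tempfile(fileext = ".csv")
  writePoseFile(list(live), path)
  rb <- resolveBackend("replay", sequences = readPoseFile(path))
  replayed <- suppressMessages(estimateSequence(rb, frameSeqOf(20)))
  s1 <- lapply(poseFrames(live), function(f)
    pixels(renderSkeleton(normalizePose(f))))
  s2 <- lapply(poseFrames(replayed), function(f)
    pixels(renderSkeleton(normalizePose(f))))
  expect_identical(s1, s2)
})
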