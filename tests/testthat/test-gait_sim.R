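test_that("generated sequences honor frame counts, joints and determinism", {
  p <- gaitParams("normal", seed = 3L)
  sq <- generateGaitSequence(p, 17)
  expect_equal(nFrames(sq), 17)
  for (fr in poseFrames(sq)) {
    expect_length(fr@joint, 12)
    expect_true(all(fr@confidence == 1))
  }
  sq2 <- generateGaitSequence(p, 17)
  expect_identical(lapply(poseFrames(sq), function(f) f@x),
                   lapply(poseFrames(sq2), function(f) f@x))
  expect_error(generateGaitSequence(p, 0), "nFrames")
})

test_that("foot trajectory period matches fps / cadence", {
  p <- gaitParams("normal", cadence = 1.25, tremorJitter = 0,
                  fps = 20, seed = 1L)
  sq <- generateGaitSequence(p, 200)
  fy <- vapply(poseFrames(sq), function(f)
    SEIgait:::poseCoords(f)["right_foot", "y"], numeric(1))
  fy <- fy - mean(fy)
  ac <- stats::acf(fy, lag.max = 60, plot = FALSE)$acf[-1]
  # first pronounced autocorrelation peak at the gait period
  period <- p@fps / p@cadence                 # 16 frames
  peak <- which.max(ac[5:60]) + 4
  expect_lt(abs(peak - period), 2)
})

test_that("severity ordering is encoded monotonically in the kinematics", {
  coh <- generateCohort(10, framesPerSequence = 40, seed = 17)
  labs <- vapply(coh$sequences, seqLabel, character(1))
  lean <- tapply(vapply(coh$sequences, measureTrunkLean, numeric(1)),
                 factor(labs, levels = severityClasses()), mean)
  disp <- tapply(vapply(coh$sequences, meanFootDisplacement, numeric(1)),
                 factor(labs, levels = severityClasses()), mean)
  expect_true(all(diff(lean) > 0))
  expect_true(all(diff(disp) < 0))
})

test_that("severity profiles order strictly, also in hard mode", {
  for (hard in c(FALSE, TRUE)) {
    prof <- severityProfiles(hard)
    lean <- vapply(prof, `[[`, numeric(1), "trunkLean")
    expect_true(all(diff(lean) > 0))
    for (k in c("armSwing", "cadence", "stepLength"))
      expect_true(all(diff(vapply(prof, `[[`, numeric(1), k)) < 0))
  }
  # hard mode narrows the gaps
  easy <- severityProfiles(FALSE)
  hard <- severityProfiles(TRUE)
  expect_lt(hard$severe$trunkLean - hard$normal$trunkLean,
            easy$severe$trunkLean - easy$normal$trunkLean)
})

test_that("normal-cohort energy images sit higher than severe ones", {
  darkHeight <- function(seq) {
    sis <- lapply(poseFrames(seq), function(f)
      renderSkeleton(normalizePose(f)))
    sei <- pixels(computeSEI(sis[1:17]))
    dark <- 1 - sei                           # weight by stroke darkness
    rows <- rowSums(dark)
    # mean height above the image bottom, in pixels
    nrow(sei) - sum(seq_len(nrow(sei)) * rows) / sum(rows)
  }
  hN <- mean(vapply(1:6, function(i) darkHeight(generateGaitSequence(
    gaitParams("normal", seed = i), 17)), numeric(1)))
  hS <- mean(vapply(1:6, function(i) darkHeight(generateGaitSequence(
    gaitParams("severe", seed = i), 17)), numeric(1)))
  expect_gt(hN, hS)
})

test_that("cohorts honor imbalanced counts and interoperate with balancing", {
  coh <- generateCohort(c(normal = 8, mild = 2, moderate = 4, severe = 4),
                        framesPerSequence = 17, seed = 5)
  expect_length(coh$sequences, 18)
  labs <- vapply(coh$sequences, seqLabel, character(1))
  expect_equal(unname(table(factor(labs, severityClasses()))[["mild"]]), 2)
  expect_equal(nrow(coh$manifest), 18)
  expect_true(all(coh$manifest$segment_id ==
                    vapply(coh$sequences, segmentId, character(1))))
  # manifest is valid for the ingest reader
  path <- withr::local_tempfile(fileext = ".csv")
  writeManifest(coh$manifest, path)
  expect_equal(nrow(readManifest(path)), 18)
})

test_that("cohort pose files are byte-identical under a fixed seed", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writePoseFile(generateCohort(2, 17, seed = 9)$sequences, p1)
  writePoseFile(generateCohort(2, 17, seed = 9)$sequences, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("rasterized gait videos drive key-frame detection end to end", {
  p <- gaitParams("normal", tremorJitter = 0, seed = 2L)
  sq <- generateGaitSequence(p, 30)
  vid <- rasterizeGaitVideo(sq)
  expect_equal(nFrames(vid), 30)
  diffs <- frameDifferenceSeries(vid)
  expect_true(is.na(diffs[1]))
  expect_true(all(diffs[-1] >= 0))
  keys <- detectKeyFrames(diffs)
  expect_true(1L %in% keys)
})
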