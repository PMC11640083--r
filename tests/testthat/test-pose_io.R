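test_that("filterFrame retains a complete confident frame", {
  fr <- filterFrame(rawBodyFrame(0.9))
  expect_s4_class(fr, "PoseFrame")
  expect_length(fr@joint, 12)
  expect_setequal(fr@joint, jointNames())
})

test_that("filterFrame rejects a frame with one low-confidence joint", {
  raw <- rawBodyFrame(0.9)
  raw$confidence[raw$joint == "left_wrist"] <- 0.4
  expect_null(filterFrame(raw))
})

test_that("confidence exactly at the threshold is rejected (strict rule)", {
  raw <- rawBodyFrame(0.9)
  raw$confidence[3] <- 0.5
  expect_null(filterFrame(raw, threshold = 0.5))
  raw$confidence[3] <- 0.5 + 1e-9
  expect_s4_class(filterFrame(raw, threshold = 0.5), "PoseFrame")
})

test_that("17 COCO keypoints reduce to exactly the 12 body joints", {
  fr <- filterFrame(rawCocoFrame(0.8))
  expect_s4_class(fr, "PoseFrame")
  expect_length(fr@joint, 12)
  expect_setequal(fr@joint, jointNames())
  # head points are gone, and COCO ankles became feet
  expect_false(any(grepl("nose|eye|ear|ankle", fr@joint)))
})

test_that("malformed joint names are an input error, not a rejection", {
  raw <- rawBodyFrame(0.9)
  raw$joint[1] <- "left_flipper"
  expect_error(filterFrame(raw), "unknown joint")
  expect_error(filterFrame(raw[, c("joint", "x", "y")]), "missing column")
})

test_that("filtering is idempotent and order-invariant", {
  raw <- rawCocoFrame(0.8)
  once <- filterFrame(raw)
  twice <- filterFrame(once)
  expect_equal(once@x, twice@x)
  expect_equal(once@joint, twice@joint)
  for (i in 1:5) {
    perm <- withr::with_seed(i, sample.int(nrow(raw)))
    fr <- filterFrame(raw[perm, ])
    expect_equal(fr@joint, once@joint)
    expect_equal(fr@x, once@x)
  }
})

test_that("acceptance frequency of random frames matches (1-threshold)^12", {
  n <- 10000
  accepted <- withr::with_seed(99, {
    sum(vapply(seq_len(n), function(i) {
      raw <- rawBodyFrame(stats::runif(12))
      !is.null(filterFrame(raw, threshold = 0.5))
    }, logical(1)))
  })
  p <- 0.5^12
  # binomial 99.9% band around the theoretical acceptance probability
  band <- stats::qbinom(c(5e-4, 1 - 5e-4), n, p)
  expect_gte(accepted, band[1])
  expect_lte(accepted, band[2])
})

test_that("validateSequence applies the 17-frame boundary", {
  expect_true(validateSequence(fixtureSequence(17)))
  expect_false(validateSequence(fixtureSequence(16)))
  expect_false(validateSequence(fixtureSequence(0)))
})

test_that("pose CSV and JSON round-trip exactly, including empty files", {
  sq <- fixtureSequence(17)
  # perturb coordinates to non-representable values
  sq@frames <- lapply(sq@frames, function(f) {
    f@x <- f@x + pi * 1e-3
    f
  })
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    writePoseFile(list(sq), path)
    back <- readPoseFile(path)
    expect_length(back, 1)
    expect_identical(back[[1]]@frames[[3]]@x, sq@frames[[3]]@x)
    expect_identical(back[[1]]@frames[[17]]@confidence,
                     sq@frames[[17]]@confidence)
    expect_equal(back[[1]]@label, sq@label)
  }
  # 17 frames x 12 joints = 204 keypoint rows in the CSV
  path <- withr::local_tempfile(fileext = ".csv")
  writePoseFile(list(sq), path)
  expect_equal(nrow(utils::read.csv(path)), 204)
  # empty sequence list: header-only file reads back empty
  writePoseFile(list(), path)
  expect_length(readPoseFile(path), 0)
})

test_that("pose files with unknown joints raise a parse error", {
  sq <- fixtureSequence(2)
  path <- withr::local_tempfile(fileext = ".csv")
  writePoseFile(list(sq), path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$joint[5] <- "antenna"
  utils::write.csv(tab, path, row.names = FALSE)
  expect_error(readPoseFile(path), "unknown joint")
})
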