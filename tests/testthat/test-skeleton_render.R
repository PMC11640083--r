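test_that("normalizePose scales the vertical extent to exactly 360 and centers", {
  fr <- bodyPoseFrame()                      # y extent 180
  nf <- normalizePose(fr)
  co <- SEIgait:::poseCoords(nf)
  expect_equal(max(co[, "y"]) - min(co[, "y"]), 360)
  # scale factor 360/180 = 2 preserved isotropically in x
  expect_equal(max(co[, "x"]) - min(co[, "x"]), (160 - 40) * 2)
  expect_equal((min(co[, "y"]) + max(co[, "y"])) / 2, (400 - 1) / 2)
  expect_equal((min(co[, "x"]) + max(co[, "x"])) / 2, (400 - 1) / 2)
})

test_that("normalizePose is idempotent and handles degenerate poses", {
  nf <- normalizePose(bodyPoseFrame())
  nf2 <- normalizePose(nf)
  expect_equal(nf2@x, nf@x, tolerance = 1e-12)
  expect_equal(nf2@y, nf@y, tolerance = 1e-12)
  flat <- PoseFrame(0L, jointNames(), x = 1:12, y = rep(5, 12),
                    confidence = rep(1, 12))
  expect_error(normalizePose(flat), "zero vertical extent")
})

test_that("rendering is invariant to input translation and uniform rescaling", {
  base <- renderSkeleton(normalizePose(bodyPoseFrame()))
  moved <- renderSkeleton(normalizePose(bodyPoseFrame(xoff = 37, yoff = -12)))
  scaled <- renderSkeleton(normalizePose(bodyPoseFrame(scale = 2.5)))
  both <- renderSkeleton(normalizePose(bodyPoseFrame(xoff = -90, yoff = 55,
                                                     scale = 0.5)))
  expect_identical(pixels(base), pixels(moved))
  expect_identical(pixels(base), pixels(scaled))
  expect_identical(pixels(base), pixels(both))
  expect_gt(sum(pixels(base) == 0), 0)
})

test_that("rendering is deterministic and strokes are binary", {
  a <- renderSkeleton(normalizePose(bodyPoseFrame()))
  b <- renderSkeleton(normalizePose(bodyPoseFrame()))
  expect_identical(pixels(a), pixels(b))
  expect_setequal(unique(as.vector(pixels(a))), c(0, 1))
})

test_that("mirror-image poses render as horizontal flips", {
  # exactly representable coordinates so reflection is bit-exact
  x <- c(170, 230, 150, 250, 140, 260, 180, 220, 175, 225, 170, 230)
  y <- c(40, 40, 110, 110, 180, 180, 200, 200, 290, 290, 380, 380)
  fr <- PoseFrame(0L, jointNames(), x, y, rep(1, 12))
  mir <- PoseFrame(0L, jointNames(), 399 - x, y, rep(1, 12))
  cfg <- renderConfig()
  a <- pixels(renderSkeleton(fr, cfg))
  b <- pixels(renderSkeleton(mir, cfg))
  expect_identical(a, b[, ncol(b):1])
})

test_that("a single displaced wrist yields a visible stroke", {
  x <- rep(200, 12); y <- rep(200, 12)
  y[match(c("right_hip", "left_hip"), jointNames())] <- 300  # give extent
  x[match("right_wrist", jointNames())] <- 240
  fr <- PoseFrame(0L, jointNames(), x, y, rep(1, 12))
  img <- renderSkeleton(normalizePose(fr))
  expect_gt(sum(pixels(img) == 0), 0)
})

test_that("off-canvas keypoints are clipped with a warning", {
  fr <- bodyPoseFrame()
  fr@x[1] <- 1e4
  expect_warning(img <- renderSkeleton(fr), "clipped")
  expect_true(all(pixels(img) >= 0 & pixels(img) <= 1))
})

test_that("PNG export round-trips an 8-bit quantized raster", {
  img <- renderSkeleton(normalizePose(bodyPoseFrame()))
  path <- withr::local_tempfile(fileext = ".png")
  writeGrayPNG(img, path)
  back <- readGrayPNG(path)
  expect_equal(dim(back), dim(pixels(img)))
  expect_equal(back, pixels(img), tolerance = 1 / 255)
})
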