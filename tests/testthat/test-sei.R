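# Independent per-pixel mean oracle: plain double loop over pixels.
bruteForceMean <- function(mats) {
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  out <- matrix(0, h, w)
  for (i in seq_len(h))
    for (j in seq_len(w)) {
      s <- 0
      for (m in mats) s <- s + m[i, j]
      out[i, j] <- s / length(mats)
    }
  out
}

test_that("computeSEI of 17 identical images returns the input exactly", {
  img <- randomStack(1, seed = 5)[[1]]
  sei <- computeSEI(replicate(17, img, simplify = FALSE))
  expect_identical(pixels(sei), img)
})

test_that("a pixel dark in 1 of 17 white images averages to 16/17", {
  imgs <- replicate(17, matrix(1, 4, 4), simplify = FALSE)
  imgs[[9]][2, 3] <- 0
  sei <- computeSEI(imgs)
  expect_equal(pixels(sei)[2, 3], 16 / 17)
  expect_equal(pixels(sei)[1, 1], 1)
})

test_that("computeSEI matches the brute-force oracle on random stacks", {
  for (s in 1:20) {
    stack <- randomStack(17, seed = s)
    expect_lt(max(abs(pixels(computeSEI(stack)) - bruteForceMean(stack))),
              1e-12)
  }
  # other kernel sizes obey the same mean law
  cfg5 <- seiConfig(kernel = 5L)
  stack <- randomStack(5, seed = 77)
  expect_lt(max(abs(pixels(computeSEI(stack, cfg5)) -
                      bruteForceMean(stack))), 1e-12)
})

test_that("computeSEI validates count and shape", {
  expect_error(computeSEI(randomStack(16)), "exactly 17")
  bad <- randomStack(17)
  bad[[4]] <- matrix(0.5, 3, 3)
  expect_error(computeSEI(bad), "same shape")
})

test_that("computeSEI is permutation-invariant and range-conserving", {
  stack <- randomStack(17, seed = 31)
  sei <- pixels(computeSEI(stack))
  for (s in 1:3) {
    perm <- withr::with_seed(s, sample(17))
    expect_equal(pixels(computeSEI(stack[perm])), sei, tolerance = 1e-15)
  }
  lo <- do.call(pmin, stack); hi <- do.call(pmax, stack)
  expect_true(all(sei >= lo - 1e-15 & sei <= hi + 1e-15))
})

test_that("rollingSEI yields N - 16 windows with stride 1", {
  expect_length(rollingSEI(randomStack(17)), 1)
  out <- rollingSEI(randomStack(20, seed = 3))
  expect_length(out, 4)
  expect_error(rollingSEI(randomStack(16)), "discarded upstream")
  # count law over a range of N
  for (n in c(17L, 18L, 25L, 40L, 63L, 100L))
    expect_length(rollingSEI(randomStack(n, h = 3, w = 3, seed = n)),
                  n - 16L)
  # m-th window spans frames m..m+16
  stack <- randomStack(20, seed = 3)
  expect_equal(pixels(out[[3]]), bruteForceMean(stack[3:19]),
               tolerance = 1e-12)
})

test_that("frame differences are mean absolute pixel differences", {
  a <- matrix(0, 4, 4); b <- matrix(1, 4, 4)
  expect_equal(frameDifferenceSeries(list(a, a, b)), c(NA, 0, 1))
  chk <- matrix(rep(c(0, 1), 8), 4, 4)
  expect_equal(frameDifferenceSeries(list(chk, 1 - chk))[2], 1)
  expect_error(frameDifferenceSeries(list(a)), "at least 2")
  expect_error(frameDifferenceSeries(list(a, matrix(0, 2, 2))),
               "same shape")
})

test_that("key-frame detection applies the strict 1.5x-of-history rule", {
  # constant nonzero differences: only frame 1
  expect_equal(detectKeyFrames(c(NA, rep(1, 30))), 1L)
  # ten 1.0 diffs then a 2.0: flagged (2.0 > 1.5 * 1.0)
  expect_equal(detectKeyFrames(c(NA, rep(1, 10), 2)), c(1L, 12L))
  # exactly 1.5x is NOT flagged (strict inequality)
  expect_equal(detectKeyFrames(c(NA, rep(1, 10), 1.5)), 1L)
  # all-zero differences: only frame 1 (0 > 0 is false)
  expect_equal(detectKeyFrames(c(NA, rep(0, 10))), 1L)
  # history truncates to the available prefix
  expect_equal(detectKeyFrames(c(NA, 1, 4)), c(1L, 3L))
})

test_that("key-frame windows need 16 followers and all-valid skeletons", {
  cfg <- seiConfig()
  sis <- randomStack(20, seed = 8)
  # key frame at index 5 of 20 frames: only 15 followers, no window
  expect_length(keyframeSEIs(5L, sis, cfg), 0)
  # key frame 1 in a 17-frame segment: exactly one window
  expect_length(keyframeSEIs(1L, sis[1:17], cfg), 1)
  # a pose-rejected frame inside the window kills it
  broken <- sis
  broken[9] <- list(NULL)
  expect_length(keyframeSEIs(1L, broken, cfg), 0)
  expect_length(keyframeSEIs(c(1L, 2L), sis, cfg), 2)
})

test_that("key-frame energy images equal rolling ones at the same start", {
  sis <- randomStack(25, seed = 13)
  roll <- rollingSEI(sis)
  kf <- keyframeSEIs(c(1L, 4L), sis)
  expect_identical(pixels(kf[[1]]), pixels(roll[[1]]))
  expect_identical(pixels(kf[[2]]), pixels(roll[[4]]))
})
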