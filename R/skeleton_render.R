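#' Rasterization settings for skeleton images
#'
#' @param targetHeight vertical extent in pixels every pose is scaled to
#'   (default 360).
#' @param canvas `(height, width)` of the raster (default `c(400, 400)`);
#'   the margin around the 360-px figure keeps swinging limbs on-canvas.
#' @param lineWidth stroke width in pixels (default 3).
#' @return A [RenderConfig-class] object.
#' @examples
#' renderConfig()
#' @export
renderConfig <- function(targetHeight = 360, canvas = c(400L, 400L),
                         lineWidth = 3) {
  new("RenderConfig", targetHeight = as.numeric(targetHeight),
      canvas = as.integer(canvas), lineWidth = as.numeric(lineWidth))
}

#' Center and scale a pose to a fixed height
#'
#' Applies a single isotropic scale factor so the vertical extent
#' (`max(y) - min(y)`) of the 12 keypoints becomes exactly `targetHeight`,
#' then translates the bounding-box center to the canvas center. This makes
#' every downstream raster invariant to where the subject stood in the
#' original video and how large they appeared, which is the point of the
#' step: distortions from varying subject position and camera distance are
#' removed before any image is formed.
#'
#' @param frame a [PoseFrame-class] with all 12 body joints.
#' @param config a [RenderConfig-class].
#' @return A new [PoseFrame-class] with normalized coordinates.
#' @examples
#' fr <- PoseFrame(0L, jointNames(), x = rep(50, 12),
#'                 y = seq(100, 280, length.out = 12), rep(1, 12))
#' rng <- range(normalizePose(fr)@y)
#' diff(rng)  # 360
#' @export
normalizePose <- function(frame, config = renderConfig()) {
  stopifnot(is(frame, "PoseFrame"))
  co <- poseCoords(frame)
  extent <- max(co[, "y"]) - min(co[, "y"])
  if (extent <= 0)
    stop("degenerate pose: zero vertical extent, cannot normalize")
  s <- config@targetHeight / extent
  cx <- (min(co[, "x"]) + max(co[, "x"])) / 2
  cy <- (min(co[, "y"]) + max(co[, "y"])) / 2
  ctr <- (config@canvas - 1) / 2        # canvas center, 0-based pixel coords
  ord <- match(jointNames(), frame@joint)
  PoseFrame(frame@frameIndex, jointNames(),
            (co[, "x"] - cx) * s + ctr[2],
            (co[, "y"] - cy) * s + ctr[1],
            frame@confidence[ord])
}

# Stamp one thick line segment (dark = 0) onto a white canvas matrix.
# Coordinates are 0-based pixel centers; endpoints are (x0,y0)-(x1,y1).
drawSegment <- function(canvas, x0, y0, x1, y1, halfWidth) {
  h <- nrow(canvas); w <- ncol(canvas)
  rmin <- max(1L, floor(min(y0, y1) - halfWidth) + 1L)
  rmax <- min(h, ceiling(max(y0, y1) + halfWidth) + 1L)
  cmin <- max(1L, floor(min(x0, x1) - halfWidth) + 1L)
  cmax <- min(w, ceiling(max(x0, x1) + halfWidth) + 1L)
  if (rmin > rmax || cmin > cmax) return(canvas)
  ys <- (rmin:rmax) - 1; xs <- (cmin:cmax) - 1
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    d2 <- (px - x0)^2 + (py - y0)^2
  } else {
    t <- pmin(pmax(((px - x0) * dx + (py - y0) * dy) / len2, 0), 1)
    d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
  }
  hit <- d2 <= halfWidth^2
  if (any(hit)) {
    block <- canvas[rmin:rmax, cmin:cmax]
    block[hit] <- 0
    canvas[rmin:rmax, cmin:cmax] <- block
  }
  canvas
}

#' Rasterize a normalized pose into a headless skeleton image
#'
#' Draws the 12 bones of [boneList()] as straight, binary (no
#' anti-aliasing) dark strokes on a white canvas, so that gray levels in the
#' downstream energy images arise only from temporal averaging. Keypoints
#' falling outside the canvas are clipped with a warning.
#'
#' @param frame a normalized [PoseFrame-class] (see [normalizePose()]).
#' @param config a [RenderConfig-class].
#' @param segmentId,frameIndex provenance recorded on the output (frameIndex
#'   defaults to the frame's own index).
#' @return A [SkeletonImage-class].
#' @export
renderSkeleton <- function(frame, config = renderConfig(),
                           segmentId = "unknown",
                           frameIndex = frame@frameIndex) {
  stopifnot(is(frame, "PoseFrame"))
  co <- poseCoords(frame)
  h <- config@canvas[1]; w <- config@canvas[2]
  if (any(co[, "x"] < 0 | co[, "x"] > w - 1 |
          co[, "y"] < 0 | co[, "y"] > h - 1)) {
    warning("keypoints outside canvas were clipped")
    co[, "x"] <- pmin(pmax(co[, "x"], 0), w - 1)
    co[, "y"] <- pmin(pmax(co[, "y"], 0), h - 1)
  }
  canvas <- matrix(1, h, w)
  bones <- boneList()
  for (b in seq_len(nrow(bones))) {
    a <- match(bones[b, "from"], jointNames())
    z <- match(bones[b, "to"], jointNames())
    canvas <- drawSegment(canvas, co[a, "x"], co[a, "y"],
                          co[z, "x"], co[z, "y"], config@lineWidth / 2)
  }
  new("SkeletonImage", pixels = canvas, segmentId = as.character(segmentId),
      frameIndex = as.integer(frameIndex))
}

# Round-half-up quantization to 8-bit gray levels.
quantize8 <- function(p) {
  floor(pmin(pmax(p, 0), 1) * 255 + 0.5) / 255
}

#' Export or import a grayscale raster as 8-bit PNG
#'
#' Values are quantized to 255 gray levels with round-half-up before
#' writing.
#'
#' @param img a [SkeletonImage-class], [SkeletonEnergyImage-class], or
#'   numeric matrix in `[0, 1]`.
#' @param path file path ending in `.png`.
#' @return `writeGrayPNG()` returns `path` invisibly; `readGrayPNG()`
#'   returns a numeric matrix in `[0, 1]`.
#' @export
writeGrayPNG <- function(img, path) {
  p <- if (is.matrix(img)) img else pixels(img)
  png::writePNG(quantize8(p), path)
  invisible(path)
}

#' @rdname writeGrayPNG
#' @export
readGrayPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3)
    img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}
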