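#' Construct an in-memory video frame stack
#'
#' @param videoId character identifier.
#' @param frames list of grayscale matrices in `[0, 1]`, all the same shape.
#' @param fps native frame rate.
#' @return A [VideoFrames-class] object.
#' @export
videoFrames <- function(videoId, frames, fps) {
  new("VideoFrames", videoId = as.character(videoId), fps = as.numeric(fps),
      frames = frames)
}

#' Load a video from a directory of PNG frames
#'
#' Reads `*.png` files in lexicographic order as grayscale frames. This is
#' the on-disk video representation the pipeline consumes (video container
#' decoding is out of scope; the segmentation step already externalizes
#' clips, and frames can be exported with any standard tool).
#'
#' @param dir directory containing PNG frames.
#' @param videoId identifier; defaults to the directory name.
#' @param fps native frame rate of the exported frames.
#' @return A [VideoFrames-class] object.
#' @export
readVideoFrames <- function(dir, videoId = basename(dir), fps) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
    img
  })
  videoFrames(videoId, frames, fps)
}

manifestColumns <- function() {
  c("video_id", "segment_id", "start_s", "end_s", "orientation",
    "subject_id", "label")
}

#' Read or write a segment manifest
#'
#' The manifest externalizes the manual segmentation step: one row per clip
#' with columns `video_id, segment_id, start_s, end_s, orientation,
#' subject_id, label`. Within a video, intervals must satisfy `end > start`
#' and must not overlap.
#'
#' @param path CSV file path.
#' @param manifest data.frame with the manifest columns.
#' @return `readManifest()` returns the validated manifest data.frame;
#'   `writeManifest()` returns `path` invisibly.
#' @export
readManifest <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(video_id = "character",
                                        segment_id = "character",
                                        subject_id = "character"))
  miss <- setdiff(manifestColumns(), names(tab))
  if (length(miss))
    stop("manifest is missing required column(s): ",
         paste(miss, collapse = ", "))
  validateManifest(tab)
  tab
}

#' @rdname readManifest
#' @export
writeManifest <- function(manifest, path) {
  validateManifest(manifest)
  utils::write.csv(manifest[manifestColumns()], path, row.names = FALSE)
  invisible(path)
}

validateManifest <- function(manifest) {
  miss <- setdiff(manifestColumns(), names(manifest))
  if (length(miss))
    stop("manifest is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (any(manifest$end_s <= manifest$start_s))
    stop("manifest entries must have end_s > start_s")
  for (vid in unique(manifest$video_id)) {
    m <- manifest[manifest$video_id == vid, ]
    m <- m[order(m$start_s), ]
    if (nrow(m) > 1 && any(m$start_s[-1] < m$end_s[-nrow(m)]))
      stop("manifest segments overlap within video ", vid)
  }
  invisible(TRUE)
}

#' Sample frames from a manifest segment at a fixed rate
#'
#' Samples the half-open interval `[start_s, end_s)` on the grid
#' `start_s + k/fps`, `k = 0, 1, ...`, stopping before `end_s` and taking
#' the nearest native frame at each grid time. The start frame is always
#' included, so a segment of duration `d` yields `floor(d * fps)` frames
#' when `d * fps` is an integer and `floor(d * fps) + 1` otherwise.
#'
#' @param video a [VideoFrames-class].
#' @param segment one manifest row (data.frame or list with `segment_id`,
#'   `start_s`, `end_s`, `orientation`, `subject_id`, `label`).
#' @param fps sampling rate (default 10 frames per second).
#' @return A [FrameSequence-class]; empty when the interval is empty.
#' @export
sampleFrames <- function(video, segment, fps = 10) {
  stopifnot(is(video, "VideoFrames"))
  start <- as.numeric(segment$start_s)
  end <- as.numeric(segment$end_s)
  dur <- nFrames(video) / video@fps
  if (start < 0 || end > dur + 1e-9)
    stop("segment interval [", start, ", ", end,
         ") lies outside video duration ", signif(dur, 6), " s")
  eps <- 1e-9
  times <- if (end - start <= eps) numeric(0)
           else seq(start, end - eps, by = 1 / fps)
  idx <- pmin(pmax(round(times * video@fps) + 1L, 1L), nFrames(video))
  new("FrameSequence",
      segmentId = as.character(segment$segment_id),
      subjectId = as.character(segment$subject_id),
      label = as.character(segment$label),
      orientation = as.character(segment$orientation),
      frames = video@frames[idx],
      timestamps = times, fps = as.numeric(fps))
}

#' Drop segments too short to fill one energy-image kernel
#'
#' Retains exactly the sequences with at least `minFrames` frames (default
#' 17), preserving order, labels and provenance. Warns when everything is
#' discarded.
#'
#' @param sequences list of [FrameSequence-class] or [PoseSequence-class]
#'   objects.
#' @param minFrames integer threshold (default 17).
#' @return The retained subset of `sequences` (possibly empty).
#' @export
dropShortSegments <- function(sequences, minFrames = 17L) {
  n <- vapply(sequences, nFrames, integer(1))
  keep <- n >= minFrames
  if (length(sequences) && !any(keep))
    warning("all ", length(sequences), " segment(s) have fewer than ",
            minFrames, " frames; nothing retained")
  sequences[keep]
}
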