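#' Read and write pose files (CSV and JSON dialects)
#'
#' Two on-disk dialects carry pose sequences. The CSV dialect has one row per
#' keypoint with columns `segment_id, subject_id, label, orientation,
#' frame_index, joint, x, y, confidence`. The JSON dialect is an array of
#' sequence objects, each with `segment_id`, `subject_id`, `label`,
#' `orientation` and a `frames` array of `{frame_index, keypoints:
#' [{joint, x, y, confidence}, ...]}`. Coordinates survive a write/read
#' round trip at full double precision in both dialects. `readPoseFile()` and
#' `writePoseFile()` dispatch on the file extension (`.csv` vs `.json`).
#'
#' @param path file path.
#' @param sequences list of [PoseSequence-class] objects.
#' @return `readPoseFile()` (and the dialect readers) return a list of
#'   [PoseSequence-class]; the writers return `path` invisibly.
#' @examples
#' fr <- lapply(0:16, function(i)
#'   PoseFrame(i, jointNames(), 1:12, 1:12, rep(1, 12)))
#' sq <- PoseSequence("seg1", "subj1", "normal", "sideways", fr)
#' f <- tempfile(fileext = ".csv")
#' writePoseFile(list(sq), f)
#' length(readPoseFile(f))
#' @export
readPoseFile <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = readPoseCsv(path),
         json = readPoseJson(path),
         stop("unsupported pose file extension: ", tools::file_ext(path)))
}

#' @rdname readPoseFile
#' @export
writePoseFile <- function(sequences, path) {
  switch(tolower(tools::file_ext(path)),
         csv = writePoseCsv(sequences, path),
         json = writePoseJson(sequences, path),
         stop("unsupported pose file extension: ", tools::file_ext(path)))
}

poseCsvColumns <- function() {
  c("segment_id", "subject_id", "label", "orientation", "frame_index",
    "joint", "x", "y", "confidence")
}

emptyPoseTable <- function() {
  as.data.frame(stats::setNames(
    list(character(0), character(0), character(0), character(0),
         integer(0), character(0), numeric(0), numeric(0), numeric(0)),
    poseCsvColumns()))
}

# Flatten sequences into the one-row-per-keypoint table.
poseTable <- function(sequences) {
  if (!length(sequences)) return(emptyPoseTable())
  rows <- lapply(sequences, function(sq) {
    if (!length(sq@frames))
      return(data.frame(segment_id = character(), subject_id = character(),
                        label = character(), orientation = character(),
                        frame_index = integer(), joint = character(),
                        x = numeric(), y = numeric(), confidence = numeric(),
                        stringsAsFactors = FALSE))
    do.call(rbind, lapply(sq@frames, function(fr)
      data.frame(segment_id = sq@segmentId, subject_id = sq@subjectId,
                 label = sq@label, orientation = sq@orientation,
                 frame_index = fr@frameIndex, joint = fr@joint,
                 x = fr@x, y = fr@y, confidence = fr@confidence,
                 stringsAsFactors = FALSE)))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Rebuild sequences from the flat table, preserving first-appearance order.
poseTableToSequences <- function(tab) {
  if (!nrow(tab)) return(list())
  bad <- setdiff(unique(tab$joint), jointNames())
  if (length(bad))
    stop("pose file contains unknown joint name(s): ",
         paste(bad, collapse = ", "))
  lapply(split(tab, factor(tab$segment_id, levels = unique(tab$segment_id))),
         function(sg) {
           frames <- lapply(split(sg, sg$frame_index), function(fr)
             PoseFrame(fr$frame_index[1], fr$joint, fr$x, fr$y,
                       fr$confidence))
           frames <- frames[order(vapply(frames, function(f) f@frameIndex,
                                         integer(1)))]
           PoseSequence(sg$segment_id[1], sg$subject_id[1], sg$label[1],
                        sg$orientation[1], unname(frames))
         }) |> unname()
}

#' @rdname readPoseFile
#' @export
readPoseCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(segment_id = "character",
                                        subject_id = "character"))
  miss <- setdiff(poseCsvColumns(), names(tab))
  if (length(miss))
    stop("pose CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  poseTableToSequences(tab)
}

#' @rdname readPoseFile
#' @export
writePoseCsv <- function(sequences, path) {
  tab <- poseTable(sequences)
  if (nrow(tab)) {
    # full double precision so the round trip is exact
    tab$x <- sprintf("%.17g", tab$x)
    tab$y <- sprintf("%.17g", tab$y)
    tab$confidence <- sprintf("%.17g", tab$confidence)
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname readPoseFile
#' @export
readPoseJson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(doc, function(sq) {
    for (k in c("segment_id", "subject_id", "label", "orientation", "frames"))
      if (is.null(sq[[k]]))
        stop("pose JSON sequence is missing required key: ", k)
    frames <- lapply(sq$frames, function(fr) {
      if (is.null(fr$frame_index) || is.null(fr$keypoints))
        stop("pose JSON frame is missing required key: frame_index/keypoints")
      kp <- fr$keypoints
      joint <- vapply(kp, function(k) as.character(k$joint), character(1))
      bad <- setdiff(joint, jointNames())
      if (length(bad))
        stop("pose file contains unknown joint name(s): ",
             paste(bad, collapse = ", "))
      PoseFrame(fr$frame_index, joint,
                vapply(kp, function(k) as.numeric(k$x), numeric(1)),
                vapply(kp, function(k) as.numeric(k$y), numeric(1)),
                vapply(kp, function(k) as.numeric(k$confidence), numeric(1)))
    })
    PoseSequence(sq$segment_id, sq$subject_id,
                 if (is.null(sq$label) || is.na(sq$label)) NA_character_
                 else sq$label,
                 sq$orientation, frames)
  })
}

#' @rdname readPoseFile
#' @export
writePoseJson <- function(sequences, path) {
  doc <- lapply(sequences, function(sq) {
    list(segment_id = sq@segmentId, subject_id = sq@subjectId,
         label = sq@label, orientation = sq@orientation,
         frames = lapply(sq@frames, function(fr)
           list(frame_index = fr@frameIndex,
                keypoints = lapply(seq_along(fr@joint), function(i)
                  list(joint = fr@joint[i], x = fr@x[i], y = fr@y[i],
                       confidence = fr@confidence[i])))))
  })
  # I(17): 17 significant digits, enough to round-trip doubles exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}
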