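#' Assemble energy images into a labeled dataset
#'
#' @param seis list of [SkeletonEnergyImage-class] objects (each carrying
#'   its label and provenance), or a list of plain matrices together with a
#'   `records` data.frame.
#' @param videoIds,subjectIds optional character vectors (recycled) filling
#'   the provenance columns when the energy images do not carry them.
#' @return An [SEIDataset-class].
#' @export
seiDataset <- function(seis, videoIds = NA_character_,
                       subjectIds = NA_character_) {
  n <- length(seis)
  if (!n) stop("no energy images supplied")
  videoIds <- rep(as.character(videoIds), length.out = n)
  subjectIds <- rep(as.character(subjectIds), length.out = n)
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- seis[[i]]
    data.frame(id = sprintf("sei_%05d", i), label = s@label,
               video_id = videoIds[i], segment_id = s@segmentId,
               subject_id = subjectIds[i], start_index = s@startIndex,
               variant = s@variant, duplicate_of = NA_character_,
               stringsAsFactors = FALSE)
  }))
  new("SEIDataset", images = lapply(seis, pixels), records = recs)
}

# The deterministic 8:1:1 size rule: validation and test each get
# floor(N/10); of the remainder r = N - 10*floor(N/10), validation absorbs
# one unit first, then test, and the rest goes to train.
splitSizes <- function(n, ratios = c(8, 1, 1)) {
  if (!identical(as.numeric(ratios), c(8, 1, 1)))
    stop("only the 8:1:1 ratio rule is implemented")
  base <- n %/% 10L
  r <- n - 10L * base
  val <- base + (r >= 1L)
  test <- base + (r >= 2L)
  c(train = n - val - test, validation = val, test = test)
}

#' Split dataset records 8:1:1 into train/validation/test
#'
#' Sizes follow a deterministic rounding rule: validation and test each
#' receive `floor(N/10)`, the division remainder is absorbed one unit at a
#' time (validation first, then test, the rest to train), and assignment is
#' a seeded uniform shuffle. The same seed always reproduces the same
#' partition. A 23,580-record dataset therefore splits into
#' 18,864 / 2,358 / 2,358.
#'
#' @param x an [SEIDataset-class] or a records data.frame.
#' @param ratios numeric length-3; only `c(8, 1, 1)` is supported.
#' @param seed integer seed for the shuffle.
#' @param bySubject logical; when `TRUE`, whole subjects (by `subject_id`)
#'   are assigned to one side of the partition, preventing a subject's
#'   energy images from leaking across splits. Sizes then follow the rule
#'   as closely as whole-subject granularity allows.
#' @return A [DatasetSplit-class].
#' @export
splitDataset <- function(x, ratios = c(8, 1, 1), seed = 1L,
                         bySubject = FALSE) {
  recs <- if (is(x, "SEIDataset")) records(x) else x
  n <- nrow(recs)
  if (n < 10) stop("need at least 10 records to split 8:1:1, got ", n)
  sz <- splitSizes(n, ratios)
  if (!bySubject) {
    perm <- withSeed(seed, sample.int(n))
    grp <- rep(c("train", "validation", "test"), times = sz)
    assign_ <- character(n)
    assign_[perm] <- grp
  } else {
    subj <- unique(recs$subject_id)
    perm <- withSeed(seed, sample(subj))
    csize <- cumsum(vapply(perm, function(s) sum(recs$subject_id == s),
                           numeric(1)))
    cutVal <- which.min(abs(csize - sz["train"]))
    cutTest <- which.min(abs(csize - (sz["train"] + sz["validation"])))
    cutTest <- max(cutTest, cutVal + 1L)
    side <- rep("test", length(perm))
    side[seq_len(cutVal)] <- "train"
    if (cutTest > cutVal) side[(cutVal + 1L):cutTest] <- "validation"
    assign_ <- side[match(recs$subject_id, perm)]
  }
  new("DatasetSplit",
      train = recs[assign_ == "train", , drop = FALSE],
      validation = recs[assign_ == "validation", , drop = FALSE],
      test = recs[assign_ == "test", , drop = FALSE],
      ratios = as.numeric(ratios), seed = as.integer(seed))
}

#' Balance classes by random oversampling
#'
#' Duplicates randomly chosen records of every under-represented class
#' (uniformly, with replacement, seeded) until all four class counts equal
#' the pre-balancing maximum. Originals are all retained; added records get
#' fresh ids and `duplicate_of` set to the id of the record they copy.
#'
#' @param x an [SEIDataset-class] or a records data.frame.
#' @param seed integer seed.
#' @return Same type as `x`, balanced. For an [SEIDataset-class] the image
#'   list is extended in parallel with the records.
#' @export
oversampleBalance <- function(x, seed = 1L) {
  recs <- if (is(x, "SEIDataset")) records(x) else x
  counts <- table(factor(recs$label, levels = severityClasses()))
  if (any(counts == 0))
    stop("every class must have at least one record; empty: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  target <- max(counts)
  picks <- withSeed(seed, {
    unlist(lapply(severityClasses(), function(cl) {
      need <- target - counts[[cl]]
      if (need == 0) return(integer(0))
      pool <- which(recs$label == cl)
      pool[sample.int(length(pool), need, replace = TRUE)]
    }))
  })
  if (!length(picks)) return(x)
  dup <- recs[picks, , drop = FALSE]
  dup$duplicate_of <- dup$id
  dup$id <- sprintf("dup_%05d", seq_along(picks))
  out <- rbind(recs, dup)
  rownames(out) <- NULL
  if (is(x, "SEIDataset"))
    new("SEIDataset", images = c(x@images, x@images[picks]), records = out)
  else out
}

#' Partition test records by class, with class weights
#'
#' Supports class-by-class evaluation: one record list per class plus the
#' class proportions, so that the support-weighted average of per-class
#' accuracies reproduces the pooled accuracy exactly.
#'
#' @param recs a records data.frame (e.g. the `test` slot of a
#'   [DatasetSplit-class]).
#' @return List with `partitions` (named list of data.frames, one per class
#'   present) and `weights` (named numeric, class sizes / total).
#' @export
perClassPartitions <- function(recs) {
  if (!nrow(recs)) stop("test record set is empty")
  present <- severityClasses()[severityClasses() %in% recs$label]
  parts <- lapply(present, function(cl)
    recs[recs$label == cl, , drop = FALSE])
  names(parts) <- present
  sizes <- vapply(parts, nrow, integer(1))
  list(partitions = parts, weights = sizes / sum(sizes))
}

#' Build an SEI dataset from pose sequences
#'
#' Runs the downstream half of the pipeline: normalizes and rasterizes each
#' retained pose frame, discards sequences with fewer skeleton images than
#' the kernel, slides the rolling kernel (or applies the key-frame rule
#' against a difference series), and assembles the labeled dataset.
#'
#' @param sequences list of [PoseSequence-class].
#' @param renderCfg a [RenderConfig-class].
#' @param seiCfg an [SEIConfig-class].
#' @param variant `"normal"` (rolling kernel over every retained sequence)
#'   or `"keyframe"` (only windows anchored at key frames; requires
#'   `diffSeries`).
#' @param diffSeries optional named list of difference series per segment
#'   (from [frameDifferenceSeries()]); when `NULL` under
#'   `variant = "keyframe"`, differences are computed from rasterized
#'   skeleton frames.
#' @param minFrames upstream discard threshold (defaults to the kernel).
#' @param outputSize optional integer: store each energy image resized (by
#'   area averaging) to this edge length. Averaging and resizing commute up
#'   to quantization, so this only trades stored resolution for memory; the
#'   energy images themselves are always computed at full render
#'   resolution.
#' @return An [SEIDataset-class].
#' @export
buildSEIDataset <- function(sequences, renderCfg = renderConfig(),
                            seiCfg = seiConfig(),
                            variant = c("normal", "keyframe"),
                            diffSeries = NULL,
                            minFrames = seiCfg@kernel,
                            outputSize = NULL) {
  variant <- match.arg(variant)
  sequences <- dropShortSegments(sequences, minFrames)
  if (!length(sequences)) stop("no sequences left after the length filter")
  allSeis <- list()
  videoIds <- character()
  subjectIds <- character()
  for (sq in sequences) {
    sis <- lapply(sq@frames, function(fr)
      renderSkeleton(normalizePose(fr, renderCfg), renderCfg,
                     segmentId = sq@segmentId, frameIndex = fr@frameIndex))
    seis <- if (variant == "normal") {
      rollingSEI(sis, seiCfg, label = sq@label)
    } else {
      diffs <- if (!is.null(diffSeries)) diffSeries[[sq@segmentId]]
               else frameDifferenceSeries(lapply(sis, pixels))
      keys <- detectKeyFrames(diffs, seiCfg)
      keyframeSEIs(keys, sis, seiCfg, label = sq@label)
    }
    if (length(seis)) {
      if (!is.null(outputSize))
        seis <- lapply(seis, function(s) {
          s@pixels <- resizeImage(s@pixels, outputSize)
          s
        })
      allSeis <- c(allSeis, seis)
      videoIds <- c(videoIds, rep(sq@segmentId, length(seis)))
      subjectIds <- c(subjectIds, rep(sq@subjectId, length(seis)))
    }
  }
  if (!length(allSeis))
    stop("no energy images were produced (no key frames with enough followers?)")
  seiDataset(allSeis, videoIds = videoIds, subjectIds = subjectIds)
}
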