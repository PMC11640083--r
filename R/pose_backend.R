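# Plugin registry for human-pose-estimation backends. A backend estimates
# keypoints for one frame at a time; everything downstream of the estimate
# (filtering, rendering, energy images) is backend-independent.

.backendRegistry <- new.env(parent = emptyenv())

#' Construct a pose backend
#'
#' A backend is a named estimator with the contract: `estimate(frame, meta)`
#' receives one grayscale raster and a metadata list (`segment_id`,
#' `frame_index`, `timestamp`) and returns either a data.frame of keypoints
#' (columns `joint, x, y, confidence`; at most 17 named joints) for the
#' single detected person, a list of such data.frames when several people
#' are in frame, or `NULL` when detection fails. Estimation must be pure
#' per frame: no state may leak across frames.
#'
#' @param name backend name.
#' @param estimate the estimator function.
#' @param metadata list of descriptive fields (e.g. model parameter count).
#' @return A `PoseBackend` object (list with class attribute).
#' @seealso [registerBackend()], [estimateSequence()]
#' @export
poseBackend <- function(name, estimate, metadata = list()) {
  stopifnot(is.function(estimate))
  structure(list(name = name, estimate = estimate, metadata = metadata),
            class = "PoseBackend")
}

#' @export
print.PoseBackend <- function(x, ...) {
  cat(sprintf("PoseBackend '%s'\n", x$name))
  invisible(x)
}

#' Register, list and resolve pose backends
#'
#' The registry maps names to backend factories. `"replay"` (replays stored
#' pose files) and `"synthetic"` (closed-form synthetic walker) are always
#' present; `"yolov8m"` is a placeholder for an external pose model adapter
#' and resolving it raises a capability error with an installation hint
#' rather than failing silently.
#'
#' @param name backend name; must be unique at registration.
#' @param factory function called as `factory(...)` by [resolveBackend()],
#'   returning a [poseBackend()] object.
#' @param ... options forwarded to the backend factory (e.g. `sequences`
#'   for `"replay"`, `params` for `"synthetic"`).
#' @return `registerBackend()` returns the name invisibly;
#'   `listBackends()` the registered names; `resolveBackend()` a
#'   `PoseBackend`.
#' @examples
#' listBackends()
#' @export
registerBackend <- function(name, factory) {
  if (exists(name, envir = .backendRegistry, inherits = FALSE))
    stop("backend '", name, "' is already registered")
  stopifnot(is.function(factory))
  assign(name, factory, envir = .backendRegistry)
  invisible(name)
}

#' @rdname registerBackend
#' @export
listBackends <- function() {
  sort(ls(.backendRegistry))
}

#' @rdname registerBackend
#' @export
resolveBackend <- function(name, ...) {
  if (!exists(name, envir = .backendRegistry, inherits = FALSE))
    stop("unknown pose backend '", name, "'; available: ",
         paste(listBackends(), collapse = ", "))
  get(name, envir = .backendRegistry)(...)
}

#' Replay backend: serve previously stored poses
#'
#' Wraps a list of [PoseSequence-class] objects (e.g. read with
#' [readPoseFile()]) as a pose backend. `estimate` looks the keypoints up
#' by `(segment_id, frame_index)`; frames without a stored pose yield
#' `NULL` (treated as a failed detection).
#'
#' @param sequences list of [PoseSequence-class].
#' @return A `PoseBackend`.
#' @export
replayBackend <- function(sequences) {
  store <- new.env(parent = emptyenv())
  for (sq in sequences)
    for (fr in sq@frames)
      assign(paste0(sq@segmentId, "#", fr@frameIndex),
             data.frame(joint = fr@joint, x = fr@x, y = fr@y,
                        confidence = fr@confidence,
                        stringsAsFactors = FALSE),
             envir = store)
  poseBackend("replay", function(frame, meta) {
    key <- paste0(meta$segment_id, "#", meta$frame_index)
    if (exists(key, envir = store, inherits = FALSE))
      get(key, envir = store) else NULL
  }, metadata = list(n_sequences = length(sequences)))
}

#' Synthetic backend: closed-form walker poses
#'
#' Ignores the pixel content and emits the synthetic walker's joints for
#' the frame's timestamp, with deterministic per-frame jitter. Useful for
#' exercising the full frame-driven pipeline without a pose model.
#'
#' @param params a [GaitParams-class].
#' @return A `PoseBackend`.
#' @export
syntheticBackend <- function(params) {
  stopifnot(is(params, "GaitParams"))
  poseBackend("synthetic", function(frame, meta) {
    t <- if (!is.null(meta$timestamp)) meta$timestamp
         else meta$frame_index / params@fps
    co <- gaitPoseAt(params, t)
    if (params@tremorJitter > 0) {
      co <- co + withSeed(childSeed(params@seed, meta$frame_index),
                          matrix(stats::rnorm(24, 0, params@tremorJitter),
                                 12, 2))
    }
    data.frame(joint = jointNames(), x = co[, "x"], y = co[, "y"],
               confidence = 1, stringsAsFactors = FALSE)
  }, metadata = list(severity = params@severity))
}

# Among several detected persons, keep the one with the largest
# bounding-box area (the filmed subject stands closest to the camera).
selectPrimaryPerson <- function(persons) {
  if (is.data.frame(persons)) return(persons)
  if (!length(persons)) return(NULL)
  areas <- vapply(persons, function(p)
    (max(p$x) - min(p$x)) * (max(p$y) - min(p$y)), numeric(1))
  persons[[which.max(areas)]]
}

#' Run a pose backend over a frame sequence
#'
#' Estimates keypoints for every frame, keeps the largest-bounding-box
#' person when several are detected, and applies [filterFrame()]: frames
#' with any of the 12 body joints missing or at confidence `<= threshold`
#' are omitted from the output. Counts of accepted and rejected frames are
#' reported via `message()`.
#'
#' @param backend a `PoseBackend` (see [poseBackend()]).
#' @param frameSeq a [FrameSequence-class].
#' @param threshold keypoint confidence threshold (default 0.5, strict).
#' @return A [PoseSequence-class] containing the accepted frames, in order,
#'   carrying the frame sequence's provenance.
#' @export
estimateSequence <- function(backend, frameSeq, threshold = 0.5) {
  stopifnot(inherits(backend, "PoseBackend"), is(frameSeq, "FrameSequence"))
  if (!nFrames(frameSeq)) stop("frame sequence is empty")
  kept <- list()
  nrej <- 0L
  for (k in seq_len(nFrames(frameSeq))) {
    meta <- list(segment_id = frameSeq@segmentId, frame_index = k - 1L,
                 timestamp = frameSeq@timestamps[k])
    raw <- selectPrimaryPerson(backend$estimate(frameSeq@frames[[k]], meta))
    pf <- if (is.null(raw)) NULL
          else filterFrame(raw, threshold, frameIndex = k - 1L)
    if (is.null(pf)) nrej <- nrej + 1L else kept <- c(kept, pf)
  }
  message(sprintf("pose estimation for segment '%s': %d frame(s) accepted, %d rejected",
                  frameSeq@segmentId, length(kept), nrej))
  PoseSequence(frameSeq@segmentId, frameSeq@subjectId, frameSeq@label,
               frameSeq@orientation, kept)
}

# Built-in backends registered at package load.
registerBuiltinBackends <- function() {
  if (!exists("replay", envir = .backendRegistry, inherits = FALSE))
    registerBackend("replay", function(sequences) replayBackend(sequences))
  if (!exists("synthetic", envir = .backendRegistry, inherits = FALSE))
    registerBackend("synthetic", function(params) syntheticBackend(params))
  if (!exists("yolov8m", envir = .backendRegistry, inherits = FALSE))
    registerBackend("yolov8m", function(...)
      stop("the 'yolov8m' pose model adapter is an optional extra and is ",
           "not installed; use the 'replay' backend with precomputed pose ",
           "files, or install an external pose model and register an ",
           "adapter with registerBackend()"))
}

.onLoad <- function(libname, pkgname) {
  registerBuiltinBackends()
}
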