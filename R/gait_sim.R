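#' Synthetic gait parameters
#'
#' Controls of the sagittal-plane stick-figure walker. The generator is a
#' pipeline fixture, not a biomechanical model: hips and shoulders are
#' driven by phase-offset sinusoids at the given cadence, the trunk is a
#' rigid segment tilted forward by `trunkLean`, and Gaussian jitter emulates
#' tremor and pose-estimation noise.
#'
#' @param severity one of [severityClasses()].
#' @param trunkLean forward trunk inclination, degrees from vertical.
#' @param armSwing shoulder-angle amplitude, degrees.
#' @param cadence gait cycles per second.
#' @param stepLength hip-swing amplitude as a fraction of leg length.
#' @param footLift swing-phase knee flexion as a fraction of leg length.
#' @param tremorJitter sd of Gaussian coordinate noise, pixels.
#' @param fps sampling rate of the emitted pose sequence (default 10).
#' @param seed integer RNG seed.
#' @return A [GaitParams-class] object.
#' @examples
#' gaitParams("normal")
#' @export
gaitParams <- function(severity = "normal",
                       trunkLean = NULL, armSwing = NULL, cadence = NULL,
                       stepLength = NULL, footLift = NULL,
                       tremorJitter = NULL, fps = 10, seed = 1L) {
  def <- severityProfiles()[[severity]]
  if (is.null(def)) stop("unknown severity class: ", severity)
  pick <- function(v, d) if (is.null(v)) d else as.numeric(v)
  new("GaitParams", severity = severity,
      trunkLean = pick(trunkLean, def$trunkLean),
      armSwing = pick(armSwing, def$armSwing),
      cadence = pick(cadence, def$cadence),
      stepLength = pick(stepLength, def$stepLength),
      footLift = pick(footLift, def$footLift),
      tremorJitter = pick(tremorJitter, def$tremorJitter),
      fps = as.numeric(fps), seed = as.integer(seed))
}

#' Severity-dependent kinematic defaults
#'
#' Default gait parameters per severity class. Across
#' normal, mild, moderate, severe the trunk lean increases strictly while
#' arm swing, cadence, step length and foot lift decrease strictly --- the
#' stooped-posture, reduced-arm-swing, slow-feet progression that
#' distinguishes the classes in energy images. `hardMode` halves the gaps
#' between classes (pulling every parameter halfway toward the across-class
#' mean) for robustness testing.
#'
#' @param hardMode logical; narrow the class separation (default `FALSE`).
#' @return Named list (one element per class) of parameter lists.
#' @examples
#' sapply(severityProfiles(), `[[`, "trunkLean")
#' @export
severityProfiles <- function(hardMode = FALSE) {
  prof <- list(
    normal   = list(trunkLean = 3,  armSwing = 28, cadence = 0.95,
                    stepLength = 0.45, footLift = 0.35, tremorJitter = 0.5),
    mild     = list(trunkLean = 9,  armSwing = 18, cadence = 0.80,
                    stepLength = 0.35, footLift = 0.25, tremorJitter = 1.0),
    moderate = list(trunkLean = 16, armSwing = 10, cadence = 0.65,
                    stepLength = 0.25, footLift = 0.16, tremorJitter = 1.6),
    severe   = list(trunkLean = 24, armSwing = 4,  cadence = 0.50,
                    stepLength = 0.15, footLift = 0.08, tremorJitter = 2.2))
  if (hardMode) {
    keys <- names(prof[[1]])
    for (k in keys) {
      vals <- vapply(prof, `[[`, numeric(1), k)
      mid <- mean(vals)
      for (cl in names(prof)) prof[[cl]][[k]] <- (prof[[cl]][[k]] + mid) / 2
    }
  }
  prof
}

# Segment lengths of the stick figure, pixels.
gaitSkeletonDims <- function() {
  list(thigh = 42, shank = 42, trunk = 58, upperArm = 30, foreArm = 30,
       hipHalf = 9, shoulderHalf = 11, pelvis = c(x = 200, y = 190),
       bobAmp = 2)
}

# Closed-form joint positions at time t (seconds), no noise.
# Forward direction is +x; image y grows downward. The stooped posture is a
# coupled flexion pattern: the forward trunk lean comes with matching knee
# flexion (crouch), as in the flexed parkinsonian stance, while the arms
# hang close to gravity-vertical from the shoulders.
gaitPoseAt <- function(params, t) {
  d <- gaitSkeletonDims()
  lam <- params@trunkLean * pi / 180
  crouch <- lam
  aArm <- params@armSwing * pi / 180
  aHip <- asin(pmin(params@stepLength, 0.99))
  kAmp <- 2 * params@footLift
  phi <- 2 * pi * params@cadence * t
  pelvis <- c(d$pelvis["x"], d$pelvis["y"] + d$bobAmp * sin(2 * phi))
  neck <- pelvis + d$trunk * c(sin(lam), -cos(lam))
  out <- matrix(NA_real_, 12, 2,
                dimnames = list(jointNames(), c("x", "y")))
  for (side in c(1, -1)) {                      # +1 right, -1 left
    pre <- if (side > 0) "right_" else "left_"
    phis <- phi + if (side > 0) 0 else pi
    thigh <- crouch + aHip * sin(phis)
    knee <- 2 * crouch + kAmp * (1 - cos(phis)) / 2
    hip <- pelvis + c(0, 0)
    kneePt <- hip + d$thigh * c(sin(thigh), cos(thigh))
    footPt <- kneePt + d$shank * c(sin(thigh - knee), cos(thigh - knee))
    shoulder <- neck + c(0, 0)
    armAng <- aArm * sin(phis + pi)             # contralateral to the leg
    elbowPt <- shoulder + d$upperArm * c(sin(armAng), cos(armAng))
    wristPt <- elbowPt + d$foreArm * c(sin(armAng + 0.3), cos(armAng + 0.3))
    # small lateral offsets keep left/right bones distinct on the raster
    hip[1] <- hip[1] + side * d$hipHalf
    shoulder[1] <- shoulder[1] + side * d$shoulderHalf
    kneePt[1] <- kneePt[1] + side * d$hipHalf
    footPt[1] <- footPt[1] + side * d$hipHalf
    elbowPt[1] <- elbowPt[1] + side * d$shoulderHalf
    wristPt[1] <- wristPt[1] + side * d$shoulderHalf
    out[paste0(pre, "hip"), ] <- hip
    out[paste0(pre, "knee"), ] <- kneePt
    out[paste0(pre, "foot"), ] <- footPt
    out[paste0(pre, "shoulder"), ] <- shoulder
    out[paste0(pre, "elbow"), ] <- elbowPt
    out[paste0(pre, "wrist"), ] <- wristPt
  }
  out
}

#' Generate one synthetic 12-joint pose sequence
#'
#' Samples the parametric walker at `fps` for `nFrames` frames. All 12
#' joints are emitted with confidence 1.0; coordinates are deterministic
#' given `params@seed` (jitter uses a private RNG stream).
#'
#' @param params a [GaitParams-class].
#' @param nFrames number of frames (>= 1).
#' @param segmentId,subjectId identifiers recorded on the sequence.
#' @param orientation orientation label (default `"sideways"`, the view the
#'   sagittal-plane kinematics emulate).
#' @return A [PoseSequence-class] labeled with `params@severity`.
#' @examples
#' sq <- generateGaitSequence(gaitParams("normal"), 17)
#' nFrames(sq)
#' @export
generateGaitSequence <- function(params, nFrames,
                                 segmentId = "synthetic",
                                 subjectId = "synthetic",
                                 orientation = "sideways") {
  stopifnot(is(params, "GaitParams"))
  if (nFrames < 1) stop("nFrames must be >= 1")
  frames <- withSeed(params@seed, {
    lapply(seq_len(nFrames) - 1L, function(k) {
      co <- gaitPoseAt(params, k / params@fps)
      if (params@tremorJitter > 0)
        co <- co + matrix(stats::rnorm(24, 0, params@tremorJitter), 12, 2)
      PoseFrame(k, jointNames(), co[, "x"], co[, "y"], rep(1, 12))
    })
  })
  PoseSequence(segmentId, subjectId, params@severity, orientation, frames)
}

#' Generate a labeled multi-class cohort of pose sequences
#'
#' Emits `sequencesPerClass` sequences for each severity class, each from a
#' distinct synthetic subject whose parameters are a bounded random
#' perturbation (+-8%) of the class defaults, small enough that the
#' across-class ordering of every parameter is preserved. Also builds the
#' matching segment manifest.
#'
#' @param sequencesPerClass single integer, or named integer vector (names
#'   from [severityClasses()]) for imbalanced cohorts.
#' @param framesPerSequence frames per sequence (default 60).
#' @param seed integer master seed; every sequence derives its own stream.
#' @param hardMode logical, see [severityProfiles()].
#' @param fps sampling rate (default 10).
#' @return List with `sequences` (list of [PoseSequence-class]) and
#'   `manifest` (data.frame in the [readManifest()] layout).
#' @examples
#' coh <- generateCohort(2, framesPerSequence = 17, seed = 1)
#' length(coh$sequences)
#' @export
generateCohort <- function(sequencesPerClass = 10L, framesPerSequence = 60L,
                           seed = 1L, hardMode = FALSE, fps = 10) {
  classes <- severityClasses()
  counts <- if (length(sequencesPerClass) == 1)
    stats::setNames(rep(as.integer(sequencesPerClass), 4), classes)
  else {
    miss <- setdiff(classes, names(sequencesPerClass))
    if (length(miss)) stop("sequencesPerClass is missing class(es): ",
                           paste(miss, collapse = ", "))
    vapply(classes, function(cl) as.integer(sequencesPerClass[[cl]]),
           integer(1))
  }
  if (any(counts < 1)) stop("sequence counts must be >= 1")
  prof <- severityProfiles(hardMode)
  sequences <- list()
  rows <- list()
  for (cl in classes) {
    for (i in seq_len(counts[[cl]])) {
      sseed <- childSeed(seed, paste0(cl, "_", i))
      pert <- withSeed(sseed, stats::runif(5, 0.92, 1.08))
      p <- prof[[cl]]
      params <- gaitParams(cl,
                           trunkLean = p$trunkLean * pert[1],
                           armSwing = p$armSwing * pert[2],
                           cadence = p$cadence * pert[3],
                           stepLength = p$stepLength * pert[4],
                           footLift = p$footLift * pert[5],
                           tremorJitter = p$tremorJitter,
                           fps = fps, seed = childSeed(sseed, "jitter"))
      segId <- sprintf("seg_%s_%02d", cl, i)
      subjId <- sprintf("subj_%s_%02d", cl, i)
      sq <- generateGaitSequence(params, framesPerSequence, segId, subjId)
      sequences <- c(sequences, sq)
      rows[[length(rows) + 1L]] <- data.frame(
        video_id = sprintf("vid_%s_%02d", cl, i), segment_id = segId,
        start_s = 0, end_s = framesPerSequence / fps,
        orientation = "sideways", subject_id = subjId, label = cl,
        stringsAsFactors = FALSE)
    }
  }
  list(sequences = sequences,
       manifest = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Rasterize a pose sequence into stick-figure video frames
#'
#' Draws each frame's skeleton at its raw coordinates (no height
#' normalization) so that the resulting frame stack can exercise the ingest
#' and key-frame differencing steps like a decoded video would.
#'
#' @param seq a [PoseSequence-class].
#' @param canvas `(height, width)` of the frames (default `c(400, 400)`).
#' @param lineWidth stroke width in pixels (default 3).
#' @param fps native frame rate recorded on the stack (default 10).
#' @return A [VideoFrames-class] with one frame per pose frame.
#' @export
rasterizeGaitVideo <- function(seq, canvas = c(400L, 400L), lineWidth = 3,
                               fps = 10) {
  stopifnot(is(seq, "PoseSequence"))
  bones <- boneList()
  frames <- lapply(seq@frames, function(fr) {
    co <- poseCoords(fr)
    co[, "x"] <- pmin(pmax(co[, "x"], 0), canvas[2] - 1)
    co[, "y"] <- pmin(pmax(co[, "y"], 0), canvas[1] - 1)
    cv <- matrix(1, canvas[1], canvas[2])
    for (b in seq_len(nrow(bones))) {
      a <- match(bones[b, "from"], jointNames())
      z <- match(bones[b, "to"], jointNames())
      cv <- drawSegment(cv, co[a, "x"], co[a, "y"], co[z, "x"], co[z, "y"],
                        lineWidth / 2)
    }
    cv
  })
  videoFrames(seq@segmentId, frames, fps)
}

#' Kinematic summaries recovered from generated poses
#'
#' `measureTrunkLean()` returns the mean absolute inclination (degrees from
#' vertical) of the mid-shoulder to mid-hip segment across frames;
#' `meanFootDisplacement()` returns the mean per-frame displacement (pixels)
#' of the two foot keypoints. Used to verify that the generator encodes
#' severity monotonically.
#'
#' @param seq a [PoseSequence-class].
#' @return A single numeric value.
#' @export
measureTrunkLean <- function(seq) {
  angs <- vapply(seq@frames, function(fr) {
    co <- poseCoords(fr)
    sh <- colMeans(co[c("right_shoulder", "left_shoulder"), , drop = FALSE])
    hp <- colMeans(co[c("right_hip", "left_hip"), , drop = FALSE])
    v <- sh - hp                        # points upward (negative y)
    abs(atan2(v["x"], -v["y"])) * 180 / pi
  }, numeric(1))
  mean(angs)
}

#' @rdname measureTrunkLean
#' @export
meanFootDisplacement <- function(seq) {
  co <- lapply(seq@frames, poseCoords)
  if (length(co) < 2) return(0)
  disp <- vapply(seq_along(co)[-1], function(t) {
    d <- co[[t]][c("right_foot", "left_foot"), ] -
         co[[t - 1]][c("right_foot", "left_foot"), ]
    mean(sqrt(rowSums(d^2)))
  }, numeric(1))
  mean(disp)
}
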