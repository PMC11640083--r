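---
title: "Skeleton energy images for gait severity classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Skeleton energy images for gait severity classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SEIgait)
```

# The problem and the representation

Parkinson's disease alters gait in ways a clinician can read at a glance:
stooped posture, reduced arm swing, short slow steps. SEIgait implements a
video-based pipeline that turns a walking clip into a single grayscale
image — a *skeleton energy image* (SEI) — and classifies that image into
one of four severity classes (`normal`, `mild`, `moderate`, `severe`,
corresponding to UPDRS gait scores 0–3).

The pipeline is a chain of small, individually testable stages:

1. **Ingest** — a manifest externalizes the manual segmentation of each
   video into single-orientation clips; each clip is sampled at 10 frames
   per second and clips yielding fewer than 17 frames are discarded.
2. **Pose estimation and filtering** — a pluggable backend produces up to
   17 named COCO keypoints per frame. The five head points are dropped
   (source videos are face-blurred), and a frame is retained only when all
   12 body joints (shoulders, elbows, wrists, hips, knees, feet) have
   confidence strictly above 0.5. Sequences left with fewer than 17
   retained frames are discarded.
3. **Normalization and rasterization** — each frame's 12 keypoints are
   isotropically scaled so their vertical extent is exactly 360 pixels and
   centered on a 400×400 canvas, then 12 bones are drawn as binary dark
   strokes on white: a headless stick figure (skeleton image, SI).
4. **Energy images** — a stride-1 rolling kernel averages every 17
   consecutive SIs pixel by pixel: `E(i,j) = (1/17) Σ S_n(i,j)`. A
   17-frame window at 10 fps spans roughly 1.5 gait cycles, so each SEI
   integrates a little more than one full stride. An `N`-frame sequence
   yields `N − 16` SEIs.
5. **Datasets and classifiers** — labeled SEIs are split 8:1:1 into
   train/validation/test by seeded shuffle; optionally the classes are
   balanced by random oversampling. Seven shallow image classifiers (CNN
   with 5 or 6 blocks, ResNet-18/34, ViT tiny/small/base) are trained with
   AdamW and cross-entropy under patience-based early stopping.

Gray levels in an SEI arise *only* from temporal averaging (rasterization
is binary, anti-aliasing off), so pixel intensity is interpretable as the
fraction of the window during which a bone covered that pixel: dark, sharp
regions are slow or static body parts; light smears are fast-moving limbs.

# The key-frame variant

A reduced dataset keeps only windows anchored at *key frames*. The
difference value of frame *t* is the mean absolute grayscale difference to
frame *t − 1*; the first frame of a segment is always a key frame, and
frame *t* is a key frame when its difference strictly exceeds 1.5× the
mean of the previous 10 differences (history truncated to what exists, at
least one prior value). A key frame with fewer than 16 following frames
forms no window, and a window containing any pose-rejected frame produces
no SEI.

Two readings of the rule were possible and are settled here as package
choices: the "difference in value" is computed between consecutive
*sampled video frames* (before pose estimation), and the 10-frame history
averages *differences*, not frame values. Both choices are configurable
(`seiConfig()`), and the difference series can also be supplied
externally.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| sampling rate | 10 | fps | matches the 17-frame ≈ 1.5-cycle window |
| confidence threshold | 0.5 | probability | strict `p > 0.5`; equality rejects |
| kernel | 17 | frames | the averaging window; `keyframeFollowers = kernel − 1` |
| target height | 360 | px | normalized figure height |
| canvas | 400×400 | px | ~11% margin avoids limb clipping during swing |
| line width | 3 | px | stroke thickness of the rasterized bones |
| key-frame factor / window | 1.5 / 10 | — / frames | strict threshold on the difference history |
| learning rate / batch | 5e-5 / 64 | — | training protocol defaults |
| min epochs / patience | 25 / 20 | epochs | early-stopping rule |

The canvas size and line width are this package's documented defaults (the
rasterization geometry is not fully pinned down by the protocol the
pipeline follows); both are exposed in `renderConfig()`.

# Numerical and design choices

**Split rounding.** Validation and test each receive `floor(N/10)` records;
the division remainder is absorbed one unit at a time, validation first,
then test, and the rest goes to train. This reproduces the balanced-row
arithmetic 23,580 → 18,864/2,358/2,358 exactly. The published unbalanced
split 17,038 → 13,628/1705/1705 does not follow floor rounding (1703.8 →
1705 twice) and its exact rule is not recoverable; the rule here is the
documented behavior for all N.

**Oversampling order.** The replicated design balances the whole dataset
*before* splitting, which lets duplicates of one image land on both sides
of the train/test boundary and inflates test accuracy. `runExperiment(id =
4)` therefore defaults to balancing the training split only
(`balanceMode = "train-only"`) and restores the replicated order with
`balanceMode = "paper"`.

**Split granularity.** The published counts are SEI counts, so the default
split unit is the individual SEI. Because windows from one subject are
highly correlated, `splitDataset(bySubject = TRUE)` provides a
subject-level split that never separates a subject's images across
partitions; expect markedly lower (more honest) test accuracy with it.

**Bone list.** The protocol names the 12 joints but not the edges; the
stick figure drawn here uses 12 bones — both arms (2 edges each), both
legs (2 edges each), shoulder bar, hip bar, and the two ipsilateral
shoulder–hip edges.

**CNN head.** The convolutional blocks are conv(3×3) → batch norm → ReLU →
2×2 max-pool → dropout, with widths 16–256 (cnn-5) plus 512 (cnn-6), and
the head applies global average pooling before a 256-unit hidden layer.
With a flattening head at 224-px input, cnn-6's extra pooling stage
shrinks its feature map enough that it would have *fewer* parameters than
cnn-5; global average pooling keeps the head independent of input
resolution and preserves the intended ordering cnn-5 < cnn-6 <
resnet-18 < resnet-34.

**Input coding.** Classifiers receive `1 − gray`: energy images are
white-background, and presenting strokes as signal on a zero background is
the natural coding for networks trained from scratch. CNNs take one
channel; ResNet and ViT use their standard 3-channel stems with the
grayscale image replicated.

**Batch-norm statistics.** The networks here train for few epochs on small
datasets, where exponentially averaged batch-norm statistics lag the
weights they normalize. After each epoch (and in the retained checkpoint)
the inference statistics are recomputed exactly over a fixed-size
calibration subset of the training data. Checkpoints store these
statistics alongside the weights.

**Early stopping.** Training never stops before 25 epochs; it stops once
20 consecutive epochs bring no strict improvement of validation loss, and
the retained checkpoint is the global best epoch. The rule imposes no
upper epoch limit; a configurable safety cap (default 500) exists as an
engineering guard and warns loudly when it fires. The monitor is a
standalone object (`earlyStopMonitor()`) so the rule is testable against
scripted loss traces.

**Training engine.** No deep-learning framework is available to R in this
package's dependency footprint, so the layers (convolution via im2col and
BLAS matrix products, batch norm, max pooling, residual blocks, layer
norm, multi-head attention, patch embedding), backpropagation and AdamW
are implemented in the package and verified against central finite
differences in the test suite. This keeps the seven model variants
constructible and trainable anywhere R runs, at the cost of speed: the
practical training sizes are small images (32–96 px) and narrow widths.

# The synthetic cohort: what it is and is not

The real clinical videos are not redistributable, so the package ships a
parametric sagittal-plane walker (`gaitParams()`, `generateCohort()`) that
emits labeled 12-joint pose sequences. Hips and shoulders ride sinusoids
at the chosen cadence; the trunk is a rigid segment tilted forward by
`trunkLean` with a matching knee crouch (the flexed parkinsonian stance);
arms hang near gravity-vertical and swing contralaterally; Gaussian jitter
stands in for tremor and pose noise. Class defaults encode the clinical
signatures monotonically — trunk lean 3°/9°/16°/24° across
normal/mild/moderate/severe, arm swing 28°→4°, cadence 0.95→0.5 Hz, step
length 0.45→0.15, with per-subject ±8% perturbations bounded so the class
ordering is preserved. A `hardMode` flag halves the gaps for robustness
testing.

The generator is a *fixture*, not a biomechanical simulator: there is no
double-support dynamics, no ground contact, no freezing episodes, no
camera perspective, and pose confidences are always 1. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline's machinery —
filtering, rendering, averaging, splitting, training — behaves as
specified and that the classifiers can recover a severity signal that is
genuinely present in the keypoints; they say nothing about accuracy on
real clinical video, which depends on pose-model quality and real
kinematic variability.

Problem sizes in the shipped tests and acceptance script were chosen to
exercise the full pipeline at desk scale: cohorts of 10 sequences per
class × 60 frames (1,760 energy images), 64-px classifier inputs, narrow
CNN widths (8–128), and a fixed 6-epoch budget at learning rate 1e-3 —
the "reduced budget" configuration of `runSyntheticPipeline()`. Under
these conditions the 5-block CNN recovers held-out severity at ≥90%
accuracy averaged over seeds; the published protocol values (learning rate
5e-5, minimum 25 epochs, patience 20) remain the defaults of
`trainConfig()` for full-scale work.

# Degenerate inputs and edge behavior

* A pose with zero vertical extent cannot be normalized and errors.
* Keypoints that leave the canvas after normalization are clipped with a
  warning.
* `rollingSEI()` on fewer than 17 images errors, pointing at the upstream
  discard rule rather than silently returning nothing.
* An empty class makes `oversampleBalance()` error (the target count would
  be undefined).
* Confidence exactly equal to the threshold is rejected — the retention
  rule is strict, and the boundary is tested.
* Frame-difference series start with `NA` (the first frame has no
  predecessor); key-frame detection requires at least one prior
  difference, so frame 2 can never be a key frame.

# Known limitations

* The pipeline classifies single SEIs; it does not aggregate per-video
  predictions, which a deployment would want.
* SEI-level splitting leaks subjects across splits (see above); the
  subject-level mode is provided but not the default, to match the
  replicated protocol.
* The pure-R training engine is single-threaded beyond BLAS and is not
  suited to 224-px, full-width training runs; the architecture definitions
  support them, but wall-clock cost is the practical limit.
* The `yolov8m` backend is a named placeholder: resolving it explains how
  to plug in an external pose model; no pose model ships with the package.
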