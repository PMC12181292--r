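---
title: "Quantifying microbial surface coverage in co-culture fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microbial surface coverage in co-culture fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micov)
```

## The problem

Confocal z-stacks of implant surfaces exposed to the oral environment show
microorganisms — single bacteria, chains, and microcolonies — co-localized
with human cells, all stained by the same non-specific DNA dyes. Intensity
alone therefore cannot separate the two cell types, the titanium surface
produces smooth but irregular background staining, and signal strength
varies across the field of view. `micov` implements a semi-automated
workflow for this setting: deterministic preprocessing, a manual per-image
triage between three quantification methods, label-mask algebra for
combining segmentations from models operating at different object scales,
and an evaluation suite for scoring any segmenter against reference masks.

This vignette records the package's model choices, parameters, numerical
conventions, and known limitations. It states no result that the test suite
or `scripts/acceptance.R` does not itself compute.

## Preprocessing model

Each z-stack is reduced by **maximum-intensity projection** (per-pixel
maximum over z), converted to the 8-bit working scale (16-bit values are
scaled by 255/65535 and rounded half-up), then flatfield-corrected and
contrast-stretched. Everything downstream assumes this 8-bit scale; in
particular the fixed quantification threshold of 50 is meaningless on any
other scale, which is why the chain pins it.

**Flatfield correction** estimates the shading field as a Gaussian blur of
the image itself at scale `sigma` (default 50 px), floors it at a small
epsilon (1e-6, so an all-zero image passes through unchanged), and rescales:
`out = clip(img * mean(S) / S, 0, 255)`, computed in floating point and
rounded half-up. The blur uses a kernel truncated at 3σ and renormalised,
with edge-replicate padding. Replicate padding avoids the dark border halo
that circular padding would create, but it bends the shading estimate of a
strongly sloped background near the borders: on a 256×256 linear ramp from
50 to 200 the corrected image is constant at the ramp mean to within 2 grey
levels in the central half, while border pixels deviate by up to 24 grey
levels. Both bounds are frozen in the unit tests against an independent
dense-convolution oracle.

**Contrast stretching** follows the intensity-window convention: the window
`[low_in, high_in]` is mapped linearly onto `[0, 255]` with clipping.
`low_in` is the smallest *occupied* intensity whose cumulative pixel
fraction reaches `lowFrac`, `high_in` the smallest intensity whose
cumulative fraction reaches `1 − highFrac`; defaults are 0.01/0.01, the
conventional defaults of this adjustment. Requiring `low_in` to be occupied
makes the zero-saturation case the exact occupied-range stretch (an image
already spanning 0–255 is unchanged), which a literal cumulative-fraction
reading would not give for images whose minimum exceeds 0. In the
degenerate case `low_in == high_in` (e.g. constant images) pixels below the
window map to 0 and pixels at or above it to 255.

## The three quantification methods

Method selection is manual and per-image; the run configuration
(`readRunConfig()`) is its durable record, and no automatic triage
heuristic is provided on purpose.

1. **Threshold** (`quantifyThreshold`): foreground is every pixel with
   intensity strictly greater than the threshold (default 50). Strictness
   matters only at the boundary value and is covered by a test: on an image
   containing each intensity 0–255 once, exactly 205 pixels pass.
2. **Subtract, then threshold** (`quantifySubtracted`): interference
   regions (manually labelled areas and/or a human-cell segmenter's output,
   united by `buildInterferenceMask`) are set to intensity 0 before
   thresholding. The denominator remains the full pixel count by default:
   subtraction zeroes intensities rather than cropping the field of view,
   so subtracted pixels count as non-microbial surface. Because this
   convention is a genuine judgement call, `excludeInterference = TRUE`
   removes them from the denominator instead.
3. **Dual-model combination** (`quantifyDualModel`): the image is segmented
   by a single-cell-scale and a microcolony-scale backend and the masks are
   merged by `combineMasks`. The combined mask is persisted for external
   manual correction; `coverageFromMask()` recomputes coverage from the
   final mask file, so corrections flow through without special-casing.

**Overlap precedence.** When the two model masks overlap, the contested
pixels go to the microcolony-scale mask by default: microcolony objects
subsume their constituent single cells, and the combined mask is destined
for manual correction, which tolerates either convention. The rule is
configurable (`precedence = "secondary"`), and the combined *foreground* is
the exact pixel-set union either way — coverage is invariant to the choice,
which the tests assert. A secondary ROI split into several fragments by the
subtraction keeps a single label; restoring component integrity is the
manual-correction step's job.

**Microcolony bootstrapping.** `buildMicrocolonyTrainingSet` filters
existing masks to ROIs of 500–15,000 px (the operational definition of
"microcolony"; the interval is read as inclusive at both ends) and exports
congruent 256-px image/mask tiles, dropping tiles with empty masks.
Non-overlapping tiling with partial tiles discarded keeps exported tiles
identically sized and approximately independent.

## Segmenter backends

Neural-network segmentation is deliberately external. A backend adapter is
a function registered under a model name
(`registerSegmenterBackend`); `segmentImage` dispatches a `SegmenterSpec`
to it and normalises whatever it returns (`validateLabelMask`: negatives to
background, empty labels dropped, labels relabelled consecutively in
increasing original order). A missing backend is an explicit error, never a
silent fallback. Users who train their own models do so externally with a
human-in-the-loop procedure; typical training settings reported for such
models (stochastic gradient descent, learning rate 0.1, weight decay 1e-5,
batch size 8, a few hundred to a few thousand epochs) are backend
parameters that `micov` records opaquely in `extraParams` — inference-time
settings such as flow or cell-probability thresholds pass through the same
way. The builtin reference backend (threshold + connected components, with
optional ROI-area limits) exists so the whole workflow runs and is testable
offline; two builtin specs partitioned at an area cutoff emulate the
single-cell / microcolony model pair.

## Evaluation suite

* `pixelAccuracy`: TP/(TP+FP+FN) over binarized masks — the Jaccard index
  of the foregrounds; symmetric; 1 exactly when the foregrounds coincide;
  1 by convention when both masks are empty (the workflow never evaluates
  empty images, so the convention only matters for degenerate fixtures).
* `iouMatrix` + `matchObjects`: one-to-one matching maximising the number
  of pairs with IoU *strictly* above the threshold, ties broken by larger
  total IoU. The optimum is found by maximum-weight bipartite matching with
  cardinality-dominant weights (`1 + iou/K`, `K` greater than the number of
  admissible pairs), an equivalent formulation of the optimal-assignment
  approach used by reference implementations; an exhaustive assignment
  search arbitrates in the tests.
* `averagePrecision`: the same TP/(TP+FP+FN) formula at object level after
  matching, reported at IoU 0.5 and 0.75 by default; monotone
  non-increasing in the threshold.
* `stratifiedEval`: reference ROIs are split at 101 px (small < 101 ≤
  large). Predicted ROIs follow the stratum of the reference ROI they
  overlap most (ties to the lowest label); predictions overlapping nothing
  are classified by their own area. Assigning predictions by best-overlap
  rather than own size avoids double-penalising a correctly-placed but
  slightly-resized prediction in both strata; the cutoff and thresholds are
  arguments.
* `summarizeCoverage`: per-group mean and sample (n−1) standard deviation,
  the convention behind "mean (± sd)" reporting for biological replicates;
  single-record groups report sd 0 and are flagged by `n = 1`.

## Synthetic scenes

`generateScene` renders 1024×1024 single-channel scenes emulating the
content of the real datasets: individual bacteria as ellipses of 7.06 px
equivalent diameter (aspect ratio 1–2), chains of 2–3 touching cells
sharing one ROI label (mirroring the convention that a chain is one region
of interest), microcolonies as connected random blobs with exact areas
drawn uniformly from 500–15,000 px, and large dim human cells (80 px
diameter) labelled in a separate ground truth. Intensities default to
bacteria 180, human cells 90, background 20 on the 8-bit scale: human cells
are deliberately *above* the threshold of 50, so that thresholding alone
cannot remove them and the interference-subtraction / dual-model logic is
what separates the cell types — the workflow's core difficulty. A smooth
multiplicative sinusoidal shading field (default relative amplitude 0.15)
and additive Gaussian noise (default sd 2) model uneven illumination and
sensor noise; z-planes are attenuated copies (first plane unattenuated), so
the maximum projection recovers the brightest rendering exactly. Objects
are placed by rejection sampling with a 2-px separation margin and never
overlap; placement failure is an explicit error. Everything derives from
one seeded RNG stream per scene, and `generateBenchmarkSuite` derives scene
seeds as `seed + index` so suites are reproducible piecewise.

Default content (40 singles, 10 chains, 3 colonies, 3 human cells) yields
sparse scenes of roughly 2–4 % true coverage, emulating early-colonization
images. What the generator does **not** model: optical point-spread
blurring, dye chemistry and intensity texture within objects, touching
objects, debris, and 3-D structure. Passing tests therefore demonstrate the
correctness of the algebra and the pipeline's determinism, not segmentation
performance on real micrographs.

Problem sizes in the test suite were chosen for tight feedback: random-mask
properties run on 32×32 masks (200–500 cases), matching oracles on up to
6×6 IoU matrices, end-to-end checks on 20 full-size (1024×1024) scenes, and
determinism checks on 256×256 scenes.

## Known limitation: flatfield correction at colony scale

Self-estimated flatfield correction (shading = blur of the image itself)
assumes shading varies on scales much larger than any object. Microcolonies
violate this: at areas of 500–15,000 px their diameters (25–140 px) are
comparable to σ = 50, so the shading estimate rises inside and around them
and the correction compresses them toward the background — on default
synthetic scenes, objects rendered at intensity 180 come out of the
correction at 38–68 inside colonies. The percentile stretch then re-expands
whatever range remains, and with the default 1 % saturation the background
of a sparse scene can land above the fixed threshold of 50. Consequently,
thresholding *after* the full default preprocessing chain is only reliable
for images that are largely covered by biofilm (where the bright mass
dominates the histogram) or contain only objects much smaller than σ — precisely the images the triage assigns to methods 1 and 2. For sparse
colony-bearing images the triage's method 3 expects segmenters that are
robust to this compression (neural-network backends trained on preprocessed
images). The acceptance script quantifies the effect by running the builtin
threshold backends both on fully preprocessed scenes and on raw
projections: the quantification layer itself is exact (zero coverage error,
pixel accuracy 1 on the raw route), while the preprocessed route shows the
flatfield compression. The same mechanism is why the background
coefficient-of-variation reduction is asserted at the flatfield stage on
colony-free fixtures in the tests.

## Numerical conventions

* Pixel coordinates are 0-based `(row, column)`; connected-component labels
  are assigned in raster-scan (row-major) discovery order; 8-connectivity
  is the default (bright blobs on dark background), 4-connectivity is
  exposed for sensitivity checks.
* All intensity rounding is half-up (`floor(x + 0.5)`), applied after
  floating-point computation.
* Label masks are exchanged as 16-bit single-channel TIFF (lossless up to
  65,535 labels; PNG output is 8-bit and restricted to 255 labels, with an
  explicit error beyond).
* `filterByArea` bounds are inclusive; the threshold comparison is strict
  (`> 50`); IoU matching is strict (`iou > t`).
* Ties in best-overlap assignment and matching resolve to the lowest label
  index, making every pipeline output deterministic; identical run
  configurations reproduce coverage tables and masks bit-exactly.
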