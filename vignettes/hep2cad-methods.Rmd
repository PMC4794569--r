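---
title: "Methods: simulating and reading HEp-2 immunofluorescence wells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reading HEp-2 immunofluorescence wells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hep2cad)
```

## The problem

Antinuclear antibodies (ANA) are detected by indirect immunofluorescence
(IIF) on HEp-2 substrate cells. A reader assigns each well (one serum test
unit) a fluorescence **intensity** — negative, intermediate or positive —
and, for nonnegative wells, a **staining pattern** describing the spatial
distribution of nuclear fluorescence. Seven patterns are modeled here:
homogeneous, fine speckled, coarse speckled, nucleolar, centromere, nuclear
dots, and nuclear pore complex. A well is only diagnostically valid if at
least one **mitotic cell** is present (it confirms correct preparation), so
a reading pipeline must also detect mitoses and discard wells without any.
IIF reading is known to be subjective — double readings by experienced
immunologists agree only about 71% of the time on this taxonomy — which is
the motivation for computer-aided (CAD) second readers and for the
agreement statistics this package implements.

`hep2cad` provides the full loop in one package: a synthetic well simulator
with ground truth, classical cell segmentation, a 108-value cell
descriptor, the multi-classifier CAD pipeline, and the evaluation
statistics (CCR, accuracy, mean class accuracy, Cohen's kappa, chi-square,
McNemar) used to compare readers and CAD systems.

## The synthetic well simulator

No public image corpus ships with the package; instead the simulator
renders wells whose phenomenology matches the acquisition conventions of
routine IIF work: 24-bit RGB frames with fluorescence in the green channel
(5% bleed into red/blue, matching FITC imagery), one image per negative
well and three per nonnegative well, and roughly 10% negative wells — the
default `negative_fraction`.

Each interphase cell is an elliptical nucleus (axis ratio 0.8–1.0, random
orientation) whose interior texture keys on the one visual trait standard
ANA nomenclature attributes to its class:

| pattern | texture rule (relative levels `lo`/`hi`) |
|---|---|
| homogeneous | uniform fill at 1.0 |
| fine speckled | base 0.45 + dense 1–2 px granules at 1.0 (1 per 5 px²) |
| coarse speckled | base 0.40 + sparser 3–6 px granules (1 per 40 px²) |
| nucleolar | base 0.40 + 1–5 bright blobs of radius 4–6 px |
| centromere | base 0.30 + 30–60 discrete 2–3 px dots (scaled by area) |
| nuclear dots | base 0.32 + 2–10 dots of 3–5 px |
| nuclear pore complex | dim interior 0.35 + bright 2.5 px rim |

The nuclear-pore-complex rim rule follows the public ANA pattern
nomenclature rather than any single reference description, since the class
name itself is the only constraint available; the nucleolar base level
(0.40) is set high enough that the nucleoplasm, not just the nucleoli,
stays above a global Otsu threshold — consistent with how real nucleolar
wells look against a dark background, and necessary for whole-cell
segmentation. All texture parameters live in `hep2_sim_config()` and are
fixed package defaults, not tuning knobs.

Textures are scaled by a per-intensity amplitude (negative 40, intermediate
110, positive 185 gray levels), which makes mean cell brightness strictly
monotone across the three classes. Negative cells are rendered dim but
visible — their texture contrast is compressed toward a faint uniform
stain, mirroring real negative sera — and their interior mean stays below a
configured ceiling of 50 gray levels. Mitotic cells are rounded bodies with
a compact central chromosome mass: a *negative mitosis* has a bright body
(0.90) and dark mass (0.15); a *positive mitosis* the reverse, with the
"weakly fluorescent" body at 0.35 so the cell remains segmentable while the
mass/body contrast (≈2.9×) still defines the type.

Images add a constant background (8 gray levels) and additive Gaussian
camera noise (sd 4); JPEG artifacts are deliberately not simulated and all
output is lossless PNG. Cells are placed by rejection sampling with 200
attempts each and a 3-px border margin; failure raises a density error
rather than silently underfilling. Every generator is a pure function of
its arguments including the seed.

What the simulator does **not** emulate: photorealistic chromatin texture,
cytoplasmic staining, uneven illumination, focus drift, overlapping or
clumped cells, serum-dilution chemistry. Passing the end-to-end benchmark
therefore shows the pipeline is internally consistent and recovers the
generating classes under realistic noise — it does not certify performance
on clinical images.

## Segmentation

A single classical pipeline serves all classes: Gaussian smoothing (sd 2
px) of the green channel, Otsu thresholding, morphological opening (disc
radius 2), and watershed on the distance transform (tolerance 2) to split
touching cells. Regions under 200 px or touching the border are dropped.
Because Otsu always returns *some* threshold, featureless scenes would
otherwise dissolve into smoothed-noise blobs; a minimum
foreground/background contrast of 12 gray levels guards against that and
makes blank frames return an empty region list. Coordinates follow a
0-based, half-open, row-major convention end to end.

## The 108-value descriptor

The green patch of each cell is quantized at 256, 128, 64 and 32 gray
levels (`floor(v * levels / 256)`), and 27 features are computed at each
level: 9 intensity statistics (mean, sd, sd/mean, level-histogram entropy,
moment of inertia about the intensity-weighted centroid, skewness, excess
kurtosis, entropy of the gradient magnitudes on the mask boundary, median),
8 geometry features from the traced contour and second-moment ellipse
(radius mean/sd/max/sd-over-mean, circularity, anisotropy, box-counting
fractal index, eccentricity), 8 shape features (area, perimeter, convex
area, convex deficiency, solidity, compactness, roundness, Euler number),
and 2 gradient-descriptor entropies (9-bin HOG, 16-bin HAG).

Design choices worth recording:

* The ninth intensity feature is the **median level**: the intensity group
  is sized at nine but only eight canonical names are standard, and a
  robust central tendency is the natural complement to the mean.
* Geometry and shape are recomputed per quantization level on the
  **level-dependent mask** (region pixels quantized above level 0).
  Otherwise 16 of the 27 features would be copied four times; with the
  level mask, coarse quantization legitimately reshapes dark-interior
  patterns (centromere, nucleolar) and the 4 × 27 structure is
  non-degenerate. If a level mask falls under 8 px the full region mask is
  used instead.
* Entropies are base 2 with empty bins contributing zero; gradients are
  central differences with one-sided borders; the boundary-gradient
  entropy is computed on contour pixels only.
* HOG uses 9 unsigned-orientation bins over 0–180° and HAG 16 magnitude
  bins — conventional resolutions, both configurable.
* Perimeter is the 8-connected traced contour length with diagonal steps
  counting √2; the Euler number uses 8-connected foreground and
  4-connected background (quad-counting formula); the second-moment
  ellipse adds the half-pixel variance term so 1-px-thin shapes stay
  finite.

All quantities are mask-relative, so the descriptor is invariant to
translating the cell within the frame.

## The CAD pipeline

The classifier architecture mirrors the standard multi-stage reading flow:

1. **Intensity triage** — a cascade of two SVMs (negative vs nonnegative,
   then intermediate vs positive) on an image-level summary: global
   green-channel statistics plus the mean cell descriptor. Pattern
   analysis never runs for an image triaged negative.
2. **Seven one-vs-all pattern classifiers** — binary SVMs with
   per-classifier feature standardization, each emitting a membership
   score in [0, 1] (logistic squash of the decision value). The
   classifier family for this stage is a package choice: margin
   classifiers are deterministic and robust at the cell counts the
   simulator produces.
3. **Two mitosis classifiers** — small feed-forward networks (one hidden
   layer of 16 units, seeded initialisation): positive-mitosis vs rest and
   negative-mitosis vs rest.
4. **K-NN fusion** — a K-nearest-neighbour classifier over the nine scores
   (seven pattern + two mitosis), K odd, chosen from {3, 5, 7, 9} by
   cross-validated mean class accuracy; Euclidean metric; vote ties break
   by smallest summed neighbour distance, then pattern-list order. Fusion
   consumes exactly nine inputs — anything else is a schema error.

SVM cost and fusion K are tuned by stratified cross-validation with mean
class accuracy as the figure of merit (on a capped subsample for speed;
final fits always use all rows). Fusion operates **per cell**, with the
image pattern taken as the majority over the fused labels of non-mitotic
cells (ties → highest mean fused-class score); cells whose maximum mitosis
score exceeds 0.5 set the image's mitosis flag and are excluded from the
pattern vote. Well-level aggregation takes the majority intensity (ties
resolved toward the more positive class), the majority pattern over
nonnegative images (ties toward the earlier pattern-list label), and
discards any nonnegative well with no detected mitosis, reason
`"no mitosis detected"`. Fusion training reuses the training cells' own
scores rather than out-of-fold scores; with the well-separated synthetic
classes this optimism is harmless, but it is the first thing to revisit for
harder data.

An optional rejection rule (off by default) emits `"other"` when the
maximum fused-class confidence falls below a configurable floor; no
classifier is ever trained on an "other" class because no such training
definition exists.

## Evaluation statistics

For a confusion matrix with reference rows, `ccr()` is the per-class
correct classification rate `T_k / N_k`; `accuracy()` the class-weighted
mean of CCRs, identically `trace/N`; `mean_class_accuracy()` the unweighted
mean over classes with `N_k > 0` — empty classes are excluded and reported,
which is exactly how a reference table whose "other" class has no gold
examples averages six diagonal rates. Cohen's kappa uses the standard
`(p_o − p_e)/(1 − p_e)` form. McNemar comes in both flavours — exact
two-sided binomial, and continuity-corrected chi-square
`(|b−c|−1)²/(b+c)` — with the exact test chosen automatically below 25
discordant pairs, since which variant produced any given published p-value
is usually unstated. For agreement tables the CCR axis is ambiguous, so
both directions are reported. The second-reader combination policy is
pluggable (`never`, `always`, confidence-gated override) because no
canonical policy exists for how a human reader consults a CAD.

Two small fixtures ship in `inst/extdata/` for exercising these statistics
on published summary numbers: a 7-class, 589-well two-reader concordance
count matrix and a row-normalized reference CAD confusion (percent). Both
are retyped plain-text tables, documented in place.

## Operating points and numerical choices

The package's standing end-to-end check (`hep2_benchmark()`) trains on 30
wells per pattern (seed 7) and tests on 10 wells per pattern (seed 8) at
the default 10% negative fraction — 653 training and 218 test images of
256 × 256 px with 6 interphase and 1 mitotic cell each. These sizes were
chosen once as the smallest configuration that exercises every stage with
honest class variety; the acceptance thresholds (pattern MAC ≥ 0.70,
intensity accuracy ≥ 0.80) sit below the high-80s/high-70s figures expert
systems report on real data, to absorb synthetic-data variance. Wells whose
predicted pattern is missing (triaged negative or unanalyzable) count as
misclassified rather than being dropped.

Other numerical conventions: `sd/mean` ratios are 0 at zero mean; skewness
and kurtosis are 0 for constant regions; zero-gradient patches have zero
descriptor entropies; a zero discordant count gives a McNemar p of 1;
kappa is defined as 1 for a perfect matrix even when expected agreement is
1. Degenerate segmentation inputs (uniform frames) return empty lists, not
errors; degenerate geometry inputs (area < 4 px) are errors.

## Known limitations

* Synthetic textures are far easier to separate than clinical material;
  benchmark figures here are ceilings, not estimates, of real-world
  performance.
* A single shared segmentation serves all classes; systems built for
  clinical images differentiate preprocessing per class, which is
  represented here only as per-classifier feature standardization.
* Mitotic cells are segmented by the same procedure as interphase cells
  and distinguished downstream; very dim positive-mitosis bodies would be
  missed by a global threshold.
* The intensity cascade reads image-level summaries; per-cell intensity
  calls are not produced.
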