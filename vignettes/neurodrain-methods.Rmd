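---
title: "Quantifying drain position after minimally invasive ICH surgery"
author: "neurodrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drain position after minimally invasive ICH surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurodrain)
```

## The problem

Supratentorial intracerebral hemorrhage (ICH) above roughly 20–30 ml is
increasingly treated by minimally invasive surgery: a drain is placed
stereotactically into the hematoma and the clot is aspirated or lysed over
days. A post-operative CT confirms the drain position, but that reading is
subjective — experienced neuroradiologists disagree on borderline
placements — and no standardized imaging criterion for a "correct" drain
position exists. Voxelwise segmentation models can produce per-voxel
probability maps for both the hemorrhage and the drain; `neurodrain` turns
a pair of such co-registered probability volumes into objective,
reproducible quantities:

1. **Detection** — discrete drain objects, separated from high-density
   mimics (bone fragments, calcifications) by a probability threshold.
2. **Quantification** — a *coverage profile* per drain: how much of the
   drain's cross-section is in contact with the hemorrhage, as a function
   of distance from the drain tip.
3. **Classification** — a correct / not-correct position label from the
   profile over the distal 15 mm, the segment that carries the drain's
   openings.

The package is agnostic about where the probability maps come from; any
segmentation model that emits values in [0, 1] on a common grid will do.

## Detection: a fixed object universe

All inputs are first brought to 1 mm isotropic resolution (linear
interpolation for probabilities, nearest-neighbour for masks) — the
working resolution of the segmentation models this pipeline is designed
for. Thresholding the drain probability map at a *baseline* of 0.5 and
labelling 26-connected components defines the **object universe**: every
discrete object, drain or mimic, that the segmentation considers at all
plausible. 26-connectivity is the default because thin oblique drains
fragment under 6-connectivity at 1 mm; no minimum object size is imposed.

Each object is labelled `drain` or `noise` by ground truth (it is a drain
iff it shares at least one voxel with the GT drain mask), and judged
*retained* at a stricter threshold \(t\) iff its maximum probability is
\(\ge t\). This keeps the denominator fixed across the threshold sweep
(0.50–0.99 in steps of 0.01, inclusive comparison so saturated 0.99
probabilities survive the top of the sweep) and makes accuracy,
sensitivity and specificity comparable across thresholds; the sweep
reports every maximal run of thresholds with perfect accuracy. The
working detection threshold defaults to 0.9, which suppresses
high-density mimics while retaining drains. Touching drains merge into
one component; the outcome table flags objects that overlap two or more
distinct GT drains rather than pretending to separate them.

## Quantification: the volume of touch and the coverage profile

The contact construct is the **volume of touch** \(V\): a drain voxel
belongs to \(V\) iff its spatially nearest non-drain voxel (Euclidean
distance in world mm, so anisotropic grids are handled correctly) belongs
to the ICH rather than to the background. Intuitively, \(V\) is the part
of the drain whose surface "sees" hemorrhage rather than brain. It is
computed with two exact distance transforms (to all non-drain voxels and
to the ICH voxels); a drain voxel is in \(V\) iff the two distances agree
to within 1e-9 mm. This resolves the measure-zero ties (an ICH voxel and
a background voxel exactly equidistant) in favour of the ICH — a rule we
chose over scan-order tie-breaking because it is deterministic *and*
invariant under world translation and axis permutation, which the test
suite checks to 1e-6. Voxels claimed by both masks are assigned to the
drain ("drain-wins") before the transforms, since \(V\) is defined over
drain voxels.

Two thresholds feed this step. Detection happens at 0.9, but a drain
binarized at 0.9 is thinner than the physical drain; quantification uses
the 0.44-threshold connected component that *contains* the detected
object (0.44 optimizes profile agreement with ground truth in the data
this pipeline was developed on). Because thresholding is monotone this
component is always a superset of the detected object, and noise objects
absent at 0.9 can never re-enter. The ICH map is binarized at 0.5, the
usual mask convention for segmentation output.

The profile axis is the leading eigenvector of the second central moment
tensor of \(V\) (weighted world coordinates, mm²). Drain and touch masks
are regridded to 0.5 mm isotropic resolution and smoothed with a Gaussian
of FWHM 1.0 mm (sigma 0.4247 mm, integrated-Gaussian kernel, unit sum) —
we read "smoothing to 1-mm voxels" as 1 mm effective resolution on the
0.5-mm grid. Both smoothed weight fields are projected onto the axis and
accumulated in 0.5-mm slabs spanning the full drain extent; the profile
value in a slab is the touch mass over the drain mass (zero where the
drain mass is below 1e-6, clipped to [0, 1]). Using smoothed masses
rather than binary counts makes the "relative covered area" stable at
sub-voxel scale.

Orientation comes from a tip rule: the two extreme cross-sections along
the axis are candidates, and the tip is the one farther from the nearest
image face — drains enter through the skull near the volume surface, so
the deep end is the tip. A caller-supplied tip always wins, and an exact
tie (within 0.5 mm) falls back deterministically to the larger coordinate
along the axis, with a warning. Profile positions then run from 0 at the
tip in 0.5-mm steps.

Degenerate contact needs care. When \(V\) holds fewer than 10 voxels at
0.5 mm, its moment tensor is meaningless, so the frame falls back to the
drain's own tensor and the profile is computed anyway — a misplaced drain
with no contact must still yield (near-zero) features for the classifier.
When the contact is a thin disc at the tip (a drain barely touching the
hematoma), the touch-volume frame is legitimately degenerate
(near-equal leading eigenvalues); the package warns but proceeds, and the
resulting features remain near zero. Single-voxel weight sets raise an
error, as no axis is defined.

## Classification

The classifier features are the profile values at 0.5, 1.5, ..., 14.5 mm
from the tip — 15 numbers covering the distal 15 mm. Drains shorter than
15 mm are zero-padded and flagged. Features are centered and scaled with
training-set statistics (standard deviations below 1e-12 are replaced by
1 so constant features map to zero), and the model is a logistic
regression penalized by \(\lambda\lVert w\rVert^2\) (intercept
unpenalized), minimizing mean binomial deviance by Newton iterations with
step halving (convergence when the parameter change drops below 1e-8; the
penalized gradient norm at the solution is stored on the model and
checked below 1e-6 in the tests). The positive class is the malposition
("not correct"): detecting misplaced drains is the clinically actionable
event. The decision threshold is 0.5.

\(\lambda\) is tuned by leave-one-out cross-validation over a random grid
of 60 candidates drawn log-uniformly from [1e-6, 10] under a fixed seed;
the n held-out probabilities are pooled into a single AUC and the best
candidate wins. On well-separated data many candidates tie at AUC 1, and
the largest of them can be so strongly regularized that every predicted
probability falls below 0.5 — perfect ranking, useless labels. We
therefore break AUC ties by the pooled leave-one-out *accuracy* at the
decision threshold, and only then prefer the larger \(\lambda\) (the
simpler model). On realistic, non-separable cohorts the tie path is never
taken and the rule reduces to plain argmax-AUC. The value
\(\lambda = 6.619512 \times 10^{-4}\), selected on the clinical cohort
this pipeline mirrors, ships as the default penalty of `fitPLR()`.

## Agreement statistics

The package implements the statistics used to validate each stage:

* `icc21()` — ICC(2,1), the two-way random-effects, single-measure,
  absolute-agreement intraclass correlation (Shrout–Fleiss), from the
  ANOVA mean squares with the F-based 95% CI. It compares predicted and
  GT coverage profiles pointwise.
* `blandAltman()` — bias and 1.96·SD limits of agreement; pairs outside
  the limits are counted as outliers. We use the limits of agreement, not
  the much narrower CI of the mean difference: for well-behaved
  differences the expected outlier rate is then ~5%, which matches how
  such rates are conventionally reported.
* `fleissKappa()` — chance-corrected multi-rater agreement for the
  categorical position readings.
* `confusionMetrics()` — accuracy / sensitivity / specificity with exact
  Clopper–Pearson 95% intervals (`binom.test`).
* `rocAuc()` — Mann–Whitney AUC with ties counted 1/2 and a DeLong CI
  (via pROC).

SDs use n − 1 denominators throughout. Each statistic is validated in
the tests against an independent oracle: `aov()` mean squares for the
ICC, the direct formula for Fleiss' kappa, pair enumeration for the AUC,
`binom.test` for the intervals, and a seeded Monte-Carlo check of the
1.96 rule.

## The phantom generator

Patient data cannot ship with a package, so every stage is exercised on
synthetic phantoms with analytic truth. A phantom is a cylindrical drain
(radius 1.5 mm by default — a typical external drain is about 3 mm in
outer diameter — and length 60 mm) rasterized into a 81 × 29 × 29 grid at
1 mm (the pipeline's working resolution), with the entry end close to a
volume face and the tip deep, as a real drain lies. The hemorrhage is
either an ellipsoid or a half-space; the half-space form is parameterized
by the embedded fraction \(f\): the plane sits perpendicular to the drain
at \(f \cdot \mathrm{length}\) from the tip, so the analytic truth
profile is exactly 1 on the embedded fraction and 0 elsewhere
(\(f = 0\) generates no hemorrhage at all — a grazing half-space would
still touch the tip disc). Probability maps are the rasterizations,
optionally Gaussian-blurred (default 0.4 mm in the benchmark scenarios,
emulating the soft boundaries of segmentation output) with additive
clipped Gaussian noise (default SD 0.02); distractor blobs of
controllable peak probability emulate the bone fragments and
calcifications that cause false positive detections, and are added to
the drain map after the noise so their peak probability is exact.
Training labels for synthetic cohorts follow a transparent rule —
"correct" iff the mean truth coverage over the distal 15 mm is at least
0.5 — which makes no claim to match radiologists' judgment.

What the phantoms do *not* emulate: curved drains (the profile axis is
straight, as in the underlying method), realistic CT texture, skull and
ventricles, partial-volume effects of strongly anisotropic acquisitions,
or the inter-rater ambiguity of borderline positions. Passing the phantom
suite therefore shows that the geometry, the distance-transform contact
construct, the profile machinery and the classifier behave exactly as
specified on controlled input — not that the pipeline reaches any
particular accuracy on clinical data.

## Numerical choices, in one place

* Threshold comparisons are inclusive (\(\ge t\)).
* Working resolution 1 mm; profile resolution 0.5 mm; smoothing FWHM
  1.0 mm; profile step 0.5 mm; slab assignment by nearest slab center.
* Distance-transform ties resolved ICH-wins within 1e-9 mm.
* Drain-wins on drain/ICH mask overlap.
* Moment-tensor eigenvalues sorted descending; frames warn when
  \(\lambda_1 / \lambda_2 < 1.05\); axis sign fixed by the tip rule.
* Touch-volume frame fallback below 10 effective voxels at 0.5 mm.
* Newton convergence at 1e-8 parameter change, 100 iterations max;
  IRLS weights floored at 1e-10.
* LOOCV grid: 60 candidates, log-uniform on [1e-6, 10], seeded
  (default 20240101).
* Slab ratios are zeroed when the drain mass in the slab is below 1e-6.

## Problem sizes in the validation suite

The test suite and the acceptance script run entirely on generated data:
50 random grids up to 20³ voxels for the exhaustive distance-transform
oracle; 100 phantoms for the detection benchmark; 40 phantoms for the
profile-agreement statistics; 200 training and 100 test phantoms for the
classifier experiment. These sizes keep the full validation run in the
low minutes on a single CPU while leaving every statistic with a
comfortable margin to its acceptance bound.

## Known limitations

* Curved or kinked drains are projected onto a straight axis; coverage
  beyond a sharp bend is attributed to the wrong position bin.
* Touching drains form a single object and a single profile.
* The tip rule assumes the entry end is nearer to a volume face than the
  tip; heavily cropped volumes can defeat it (pass `tipHint` /
  `override` in that case).
* The synthetic position label is a coverage rule, not a clinical
  judgment; a classifier trained on phantoms is a demonstration of the
  machinery, not a clinically validated model.
* GT profiles computed from binary masks inherit the mask's resolution;
  at strongly anisotropic spacings the nearest-neighbour resampling to
  1 mm is the dominant error source.
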