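---
title: "aneumorph: models, phantoms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aneumorph: models, phantoms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aneumorph` is a desk-scale, fully synthetic pipeline for surgical planning of
coil embolization of unruptured intracranial aneurysms (UIAs): phantom
angiography volumes are segmented by a residual 3D U-Net, the segmented sac is
measured morphometrically, and a neural factorization machine (NFM) recommends
the diameter of the first (framing) coil from those measurements. This
vignette explains the models, why the phantoms look the way they do, which
knobs matter, and what results on phantoms do and do not say about clinical
data.

## The spherical-cap phantom

Real CTA cohorts for this task are not publicly available, so every stage is
validated against synthetic phantoms with analytic ground truth. The phantom
is a subtracted-angiography look-alike: a contrast-bright parent vessel
(straight tube) carrying a saccular aneurysm on a dark background, rendered as
a pre/post-contrast pair whose difference isolates the vasculature.

The aneurysm sac is a *spherical cap*: the part of a sphere of radius $R$ on
the dome side of the neck plane, with cap height $h$. This is deliberate — the
spherical cap is essentially the only sac shape for which all five standard
morphometric features have closed forms. With ostium (rim) radius
$a = \sqrt{h(2R-h)}$:

* **height** $= h$ (maximum perpendicular distance of the dome from the neck
  plane);
* **size** $= \max(h, a)$ (distance from the neck-plane gravity centre to the
  farthest dome point);
* **neck diameter** $= 2a$;
* **dome diameter** $= 2R$ when $h \ge R$ (the equator is the largest section
  parallel to the neck plane), and $2a$ otherwise (the largest parallel
  section is then the neck plane itself — the tie is broken toward the neck);
* **volume** $= \pi h^2 (3R - h)/3$.

Irregular, multilobular sacs are excluded by design, mirroring the usual
inclusion criteria of first-coil planning studies (regular saccular UIAs of
3–10 mm).

Sampling is parameterised clinically: aneurysm size uniform on 3–10 mm (the
inclusion window), a cap-fullness ratio $q = h/2R \sim U(0.55, 0.92)$ (berry
shapes whose dome is wider than the ostium; $q \to 1$ is a narrow-necked
berry), location classes with typical cohort frequencies (Acom/ACA 30.7%, ICA
47.7%, MCA 13.7%, posterior circulation 7.8%), and a parent-vessel radius
uniform on 1.5–2.5 mm (intracranial artery calibre). Because $q > 1/2$, the
apex is always the farthest dome point and size $= h$ exactly.

The tube axis is dropped below the neck plane just far enough that the tube
crests at the ostium, so the aneurysm and vessel labels share a genuine
interface (needed for neck-plane estimation); tube voxels that fall inside the
cap are labelled aneurysm, keeping the cap geometry exact and the two masks
disjoint.

Rendering defaults: a 64³ grid at 0.5 mm isotropic spacing (32 mm field of
view — desk scale, voxelization error of the cap volume ≤ 5%), contrast level
200 intensity units and additive Gaussian noise with sd 10 (a conservative
signal-to-noise for subtracted angiography; intensities are arbitrary units —
scanner window/level calibration is acquisition metadata with no phantom
analog, and the segmenter standardises each volume anyway). Voxel centres sit
at $(i + 0.5)\cdot s$ mm with 0-based indices; masks are written as unsigned
8-bit NIfTI.

**What the phantom does not emulate:** curved and branching vessels, skull
base structures, beam hardening, motion, inter-scanner variation, irregular
sac shapes, and the intensity statistics of real contrast. Passing phantoms
therefore demonstrates that the *pipeline machinery* — segmentation
optimisation, geometry, statistics — is correct at clinical geometry scales,
not that the trained weights transfer to patients.

## Segmentation: residual 3D U-Net

The segmenter is an encoder–decoder with skip connections. Each block applies
two 3×3×3 convolutions, each followed by group normalization and ReLU, with an
additive residual shortcut (an 1×1×1 projection where channel widths differ);
the encoder downsamples with 2×2×2 max pooling, the decoder upsamples with
kernel-2 stride-2 transposed convolutions, and a final 1×1×1 convolution plus
logistic function gives voxelwise foreground probabilities, thresholded at
0.5 (no threshold is standard; 0.5 is the natural choice for a calibrated
sigmoid).

Convolutions inside blocks carry no additive bias: group normalization
immediately follows each one, which makes a conv bias an *exactly* dead
parameter (its gradient is identically zero), so it is omitted. Group counts
are `min(8, channels)`.

The loss combines voxelwise cross-entropy and a soft-Dice term, both passed
through the exponential-logarithm transform
$L = w_{ce}\,\mathrm{mean}_i\, w_i(-\log p_{\mathrm{true},i})^{\gamma} +
w_{dice}\,(-\log S)^{\gamma}$ with soft Dice
$S = (2\sum p t + 1)/(\sum p + \sum t + 1)$. The defaults follow the
literature that introduced this loss family: $\gamma = 0.3$, a dominant Dice
term ($w_{dice} = 0.8$, $w_{ce} = 0.2$), and per-voxel inverse-root class
frequency weights $w_l = f_l^{-1/2}$ on the cross-entropy term. Both
weightings matter here because the sac occupies well under 1% of the volume:
without the class weights, the $\gamma < 1$ transform actually *weakens* the
gradient on confidently-wrong voxels (the $f^{\gamma-1}$ factor shrinks as
$-\log p$ grows) and the filling-in of under-segmented sacs is glacial;
without Dice dominance, the strongly weighted cross-entropy shifts the
decision boundary outward and systematically dilates predicted masks by
about a voxel, capping attainable Dice well below its ceiling. The final
1×1×1 convolution's bias is initialised to the prevalence logit
$\mathrm{qlogis}(0.01)$, so training starts at the foreground prior instead
of spending its first epochs learning "all background". Numerically,
probabilities are clipped to $[10^{-6}, 1-10^{-6}]$ and the $-\log$ terms
floored at $10^{-6}$ before the fractional power.

Optimisation is Adam at learning rate 0.001, stepped down to a tenth for the
final fifth of the schedule (the reference configuration "initialises" its
rate without stating the schedule; the step decay damps the end-of-training
oscillation of held-out Dice that single-precision small-batch training shows
on this task). The reference-scale
configuration (volumes magnified to 224×256×256 by trilinear interpolation —
the 3D reading of "bilinear" — batch 14, 300 epochs of 400 steps, a 16×16×16
bottom feature map) needs GPU hardware and remains available through
`seg_config()`; the desk default trains on 64³ volumes with 4 levels (4³
bottom map), 8 base filters, batch 4, and 8 epochs over a 96-case training
split (roughly 190 Adam steps, a quarter hour of one CPU core). The shipped
experiments bracket that default by their own runtime envelopes: the
acceptance script trains 7 epochs, the test-suite criterion experiment 9, at
which the held-out Dice of the reference run reaches 0.92. Convergence onset
varies a few epochs across seeds, and more epochs only help — the schedule
is a runtime choice, not a convergence one. One master seed fans out to the
split, initialisation and augmentation streams.

Training augmentation applies, each with probability ½ per sample: axis
flips, rotations up to ±15° about a random axis, zoom 0.9–1.1, brightness
shifts up to ±0.1 intensity-sd, contrast scaling 0.9–1.1, and elastic
deformation from a 4³ Gaussian control grid with 1.5 mm amplitude. Magnitudes
are deliberately mild: the phantom anatomy spans most of the field of view, so
aggressive spatial augmentation would push structure out of frame. Spatial
transforms are applied identically to image (trilinear) and mask
(nearest-neighbour, so masks stay binary).

The deep-learning stack is implemented in the package itself (single-precision
C++ kernels behind R orchestration): slab-blocked im2col+GEMM convolutions on
zero-haloed padded buffers, analytic backward passes for every layer, and the
fused sigmoid/loss gradient. Each kernel's backward pass is validated in the
test suite against finite differences and double-precision references.

## Morphometry from binary masks

The neck plane is not observable from a mask pair in any standard way, so it
is *estimated from the label interface*: the centroid is the mean of the
midpoints of voxel faces shared by the aneurysm and vessel labels, and the
normal is the smallest-variance principal direction of that interface point
cloud, oriented toward the aneurysm centroid. On phantoms this recovers the
analytic plane to well under a degree for typical geometry.

Given the oriented plane, in physical mm:

* **size** and **height** are maxima over dome-voxel centres of the distance
  to the neck centroid and of the signed perpendicular distance to the plane;
* **neck and dome diameters** average chord lengths through the section
  centroid over 180 equally spaced in-plane directions (1° resolution;
  doubling the count changes results by well under 0.1%). Cross-sections are
  measured on a plane-aligned 2D raster (pitch half a voxel) of trilinearly
  interpolated mask occupancy, thresholded at 0.40 — slightly below one half
  because the thin wedge at a cap rim has expected occupancy below ½ even
  inside the true section, and a strict majority vote erodes boundary
  sections. The raster approach replaces chords over slab voxel centres,
  whose staircase gaps bias chords low on tilted planes. Sections are probed
  half a voxel inside the dome (voxels exactly on the plane belong to the
  neck section; probing at their dome-side face height avoids interpolation
  mixing with sub-plane vessel voxels). These choices were fixed against a
  digitized-ball chord oracle of known radius.
* the **dome section** is the parallel section of maximal cross-sectional
  area, searched at half-voxel offsets up to the height, ties broken toward
  the neck;
* **volume** is voxel count × voxel volume.

A section with fewer than 3 voxels in its slab yields `NaN` for its diameter
(degenerate-section rule). Predicted masks are first reduced to their largest
26-connected component, because isolated false-positive specks would corrupt
the farthest-point size; an empty prediction raises a "no aneurysm detected"
condition.

Agreement between pipeline measurements and reference values is quantified
with the two-way random-effects, absolute-agreement, single-measure
intraclass correlation, ICC(2,1), computed from the mean-squares
decomposition; which ICC variant clinical reports use is often unstated, and
ICC(2,1) is the most conservative common choice (it penalises systematic
bias, not just decorrelation). Values above 0.8 are conventionally read as
good consistency.

## First-coil recommendation: neural factorization machine

The recommender predicts the continuous first-coil diameter from the five
morphometric features plus the location class, then rounds to the commercial
catalog (0.5 mm steps on 1–10 mm, ties up). Regression with a squared-error
objective was chosen over classification across catalog values: match ratios
compare millimetre diameters within a ±1 mm band, implying a metric target,
and at cohorts of ~10² cases most catalog classes would be near-empty.

Continuous features are discretised into 10 quantile bins each (breaks fitted
on training data only), locations one-hot encoded; each case activates one
index per feature field. The model is
$\hat y = w_0 + \sum_{i \in \mathcal{A}} w_i + f_{\mathrm{MLP}}
\big(\tfrac12[(\sum_{i} v_i)^2 - \sum_i v_i^2]\big)$:
a global bias, linear weights over active indices, and bi-interaction pooling
of the active-index embeddings fed through one ReLU hidden layer whose linear
read-out is summed with the factorization-machine part at the output node.
Desk hyperparameters: embedding dimension 8, hidden width 64, dropout 0.1 on
the bi-interaction vector, full-batch Adam at 0.01 for 200 epochs — seconds of
CPU time. An extra reserved embedding row absorbs location levels unseen at
fit time.

Evaluation mirrors the clinical protocol: the derivation cohort (113 of 153
cases; the split between derivation and validation is an explicit index split,
standing in for a temporal enrollment split) is divided 80/20 into training
(90) and testing (23) sets; fivefold cross-validation runs on the training
set, the per-fold held-out general-match percentages give a mean and a
t-based 95% confidence interval ($\bar x \pm t_{0.975,4}\, s/\sqrt 5$; which
interval construction clinical reports use is unstated, and the t interval is
the standard small-sample choice), the model is refit on the full training
set, and overfitting is flagged when the testing-set percentage falls outside
the interval (a zero-variance interval degenerates to its mean, compared
inclusively). Reading the "training percentages" of the learning curve as
per-fold *held-out* percentages, rather than in-sample fit percentages, makes
the curve compare two estimates of the same generalisation quantity — the
comparison the overfitting question actually needs.

The synthetic coil label is the catalog rounding of
$0.5(\text{dome} + \text{size}) + \varepsilon$,
$\varepsilon \sim N(0, 0.25\,\mathrm{mm})$ — the framing-coil heuristic that
the first coil approximates the dome calibre. The stated rule is the
recoverable signal the NFM is expected to learn; the noise sd keeps the ±1 mm
general-match band at 4 sd, so a model that recovers the rule scores near
(but not trivially at) 100%.

## Match ratios

A recommendation is an *absolute match* when it equals the actually used
diameter exactly (on the catalog grid, with a 10⁻⁶ mm numeric tolerance) and
a *general match* within ±1 mm. Both ratios are fractions of all cases.
Segmentation quality uses Dice = 2TP/(2TP+FP+FN) and precision = TP/(TP+FP);
for recall and F2 the standard forms TP/(TP+FN) and 5PR/(4P+R) are the
default, while the variant forms printed in some clinical reports
(2TP/(TP+FN), and 5PR/(4(P+R)) — note the former can exceed 1) are available
behind `as_printed = TRUE` for reproduction. When both masks are empty all
scores are defined as 1, so aneurysm-free negatives do not poison cohort
averages; such rows are flagged.

## Problem sizes and numerical choices

The shipped experiments use: 40 noise-free phantoms for morphometric
agreement; 120 phantoms (96 train / 24 held out) for segmentation with the
desk U-Net; 40 fresh phantoms (30 aneurysm-bearing, 10 vessel-only) for
case-level detection with a 10-voxel minimum component size; and a 153-case
tabular cohort (113 derivation / 40 validation) for the recommender. These
sizes mirror a single-centre clinical cohort and keep the full suite at
minutes of single-core CPU time.

Other numerics: group-norm variance epsilon 10⁻⁵; He initialisation scaled to
fan-in; Adam (0.9, 0.999, 10⁻⁸); soft-Dice smoothing 1; the elastic field is
resampled trilinearly from its control grid; out-of-volume samples during
warping take the background value (median for images, 0 for masks).

## Known limitations

* Phantom realism, as above: results bound pipeline correctness, not clinical
  performance.
* At desk training lengths the segmenter is a perfect *detector of
  aneurysms that exist* (no held-out case is missed in any shipped run) but
  an imperfect rejector of aneurysm-free anatomy: specificity on vessel-only
  phantoms is the last quality to emerge during training, so mixed-cohort
  detection accuracy ranges from about 0.75 (short schedules, slow seeds)
  to 0.90 (longer schedules) rather than the high-nineties a fully
  converged model reaches. Adding vessel-only negatives to the training
  cohort raises specificity but, within the same step budget, costs
  segmentation Dice; both improve together only with a longer schedule.
* The neck-plane estimator needs a vessel label adjacent to the sac; a
  free-floating aneurysm mask raises an "isolated mask" error rather than
  guessing.
* Chord-based diameters are measured on in-plane cross-sections; whether
  clinical "lines passing through the geometric centre" are 2D chords or 3D
  rays is ambiguous — in-plane chords are adopted and documented.
* Single-precision training: two runs agree to float accuracy, and seeded
  runs are reproducible on the same BLAS, but bit-identity across BLAS
  implementations is not guaranteed.
* The straight-tube vessel makes neck diameter the feature most sensitive to
  discretization (worst-case error just under one voxel diagonal at 0.5 mm
  spacing); all five features still reach ICC above 0.99 on ground-truth
  masks.
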