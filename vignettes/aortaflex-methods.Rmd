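---
title: "Quantifying ascending-aorta elasticity from cine imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ascending-aorta elasticity from cine imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An ascending aortic aneurysm progressively stiffens the vessel wall; wall
elasticity, not just diameter, carries information about rupture risk. Two
in-vivo quantities summarize it from a time-resolved (cine) axial acquisition
at the level of the pulmonary trunk, together with the blood pressures
recorded during the exam:

* **aortic compliance**
  $C = \dfrac{A_{\max} - A_{\min}}{P_{\mathrm{sys}} - P_{\mathrm{dia}}}$
  (mm^2^/mmHg), from the cross-sectional lumen area curve over the cardiac
  cycle, and
* **in-vivo wall strain**
  $\varepsilon = \dfrac{p_{\max} - p_{\min}}{p_{\min}}$ (dimensionless), from
  the outer wall perimeter curve.

Both are also evaluated **locally** on four 90° quadrants about the lumen's
center of gravity, rotated 60° so the sectors align with the medial,
anterior, lateral and posterior walls. The in-vivo values are compared with
ex-vivo stiffness from biaxial tensile tests of resected wall samples:
engineering strain $\varepsilon = \Delta l / l_0$, engineering stress
$\sigma = F/A_0$ with $A_0 = t \cdot l_0$, the tangent Young's modulus
$E(\varepsilon) = d\sigma/d\varepsilon$, its maximum $E_{\max}$, and a
physiological modulus $E_{\mathrm{phys}}$ averaged over the stress window
implied by the patient's blood pressures.

Computing the area and perimeter curves requires segmenting the ascending
aorta on every frame; the package trains a U-Net with instance
normalization and Dice loss for that purpose, entirely self-contained
(the network, its backpropagation and the Adam optimizer are implemented in
R/C++ on top of BLAS).

## The synthetic phantom: what it emulates

No patient data ship with the package. Every stage is instead exercised on
a synthetic **pulsating-vessel phantom** with exact analytic ground truth:

* a bright quasi-elliptical lumen (semi-axes $a, b$) inside darker tissue,
  with a thin rendered wall ring;
* a raised-cosine cardiac waveform (fast systolic rise peaking ~30% into
  the cycle, slower decay) scaling the semi-axes by a pulsation fraction;
  the waveform is sampled so the extreme frames attain the analytic
  extrema exactly;
* deterministic in-plane motion of the vessel center (default 1.5 mm,
  waveform-locked). Real aortas translate between frames — the center of
  gravity shifts from image to image — and this motion also varies the
  sub-pixel rasterization phase across frames. A perfectly static phantom
  would have *coherent* rasterization error across the cycle, an artifact
  real acquisitions do not show, which corrupts the max--min differences
  that compliance and strain are built from;
* Gaussian intensity noise, intra-lumen signal-dropout patches and
  ghosting streaks emulating turbulent-flow artifacts (scaled by
  `artifact_level`), and an optional abutting circular neighbor vessel
  reproducing the "wall not well defined next to another structure"
  failure mode. None of these ever touch the masks or the truth;
* ground-truth masks as the exact rasterization (pixel-center-inside rule)
  of the analytic ellipse, and a truth record carrying per-frame analytic
  areas ($\pi a b$), perimeters (Ramanujan's second approximation,
  error far below all tolerances), per-quadrant sector areas and arcs
  (dense quadrature), and the compliance/strain they imply.

Default conditions: 256×256 frames, 1.17 mm/px (mid-range of typical
1.09–1.25 mm/px acquisitions), 30 frames per cycle, diastolic semi-axes
25 × 22 mm — a vessel at the ~50 mm surgical-threshold diameter,
representative of a pre-operative aneurysm cohort — pulsation fraction
0.09 (matching reported in-vivo strains of ~0.07–0.10), pressures
120/80 mmHg. `phantom_cohort()` draws per-exam sizes (16–26 mm), pulsation
(0.05–0.12) and pressures (systolic 105–150, pulse 30–60 mmHg) from these
physiologic ranges.

What the phantom does **not** model: MR physics (k-space, coils,
acceleration), 3D geometry, through-plane motion, wall-thickness
heterogeneity, or genuinely non-elliptical lumen shapes. Passing tests on
phantoms therefore demonstrates correctness of the measurement chain on
known geometry, not clinical performance.

The tensile simulator (`generate_tensile()`) inverts the engineering
stress/strain definitions through a contiguous piecewise-linear tangent
modulus law, on a 15 × 15 mm sample geometry, with optional Gaussian
stress noise; the bilinear default (0.35 MPa toe, 1.1 MPa stiff branch)
mimics an elastin-to-collagen transition at 50% strain, placing physiological wall stresses near the transition.

## Segmentation network

`unet_config()` describes a standard symmetric encoder–decoder with skip
connections: per level, two 3×3 convolutions each followed by instance
normalization and ReLU; 2×2 max pooling between levels; channel counts
double per level; the decoder upsamples (nearest neighbor + 3×3
convolution), concatenates the skip feature map and applies the same double
convolution; a final 1×1 convolution and sigmoid produce the probability
map. `residual_blocks = TRUE` switches every double convolution to a
residual block (1×1 projection where channel counts differ), the residual
variant. Only instance normalization (and `"none"`) is provided: it is the
variant that the architecture search this design follows actually selected,
and with image-at-a-time optimization a batch variant would degenerate to
it anyway.

Two profiles are used throughout:

| profile | input | depth | base channels | purpose |
|---|---|---|---|---|
| paper  | 256×256 | 4 | 32 | full-scale configuration |
| desk   | 128×128 | 3 | 16 | minutes-scale CPU training in tests |

Training (`train_unet()`) minimizes the soft Dice loss
$1 - 2\sum pg / (\sum p + \sum g + \epsilon)$ with $\epsilon = 10^{-6}$
(focal and Tversky losses are available) using Adam, with the protocol:
initial learning rate $10^{-3}$, ×0.1 decay when the validation loss has
not improved for 5 epochs, early stopping after 16 stagnant epochs, at most
200 epochs, and K = 5 cross-validation folds formed **at the exam level**
(all slices of an exam stay in one fold). After cross-validation the model
is retrained on all exams for the median best-epoch count across folds —
the natural choice when the folds exist to estimate the stopping point.
`cross_validate = FALSE` replaces the folds by a single held-out exam split
(the fast path for large phantom corpora). Inference thresholds the sigmoid
map at 0.5 and keeps the largest 4-connected component, since there is one
target vessel per frame; an empty prediction is valid.

Scaled-down training runs in the tests use a higher initial learning rate
(3×10⁻³) and smaller batches than the full-scale defaults: with a few
dozen frames instead of ~1800 images, an epoch contains an order of
magnitude fewer optimizer steps, and the step size must compensate. The
package's test runs train ~40 two-frame desk-profile sequences for ~10
epochs (~10 minutes on one CPU) and reach held-out Dice ≳ 0.99 on
phantoms; the single-exam overfit check reaches Dice loss < 0.05 within 50
epochs at 64×64.

## Measurement chain

* **Areas** are pixel counts × pixel area (mm²), per frame; quadrant areas
  come from the angular partition about the per-frame centroid, so the
  four sectors always sum exactly to the total. The partition assigns each
  pixel by the angle of (pixel − centroid), counterclockwise from the
  +column axis in the displayed image, sectors `[start, start + 90°)` with
  `start = rotation + k·90°` — the half-open convention makes boundary
  pixels deterministic. Labels run (lateral, anterior, medial, posterior)
  counterclockwise from the rotation offset; the anatomical mapping is a
  convention and all results are label-permutation-equivalent. Whether the
  60° offset is applied clockwise or counterclockwise is likewise a
  convention; the sign can be flipped via `rotation_deg`.
* **Per-frame vs fixed centroid**: the center of gravity is recomputed per
  frame by default (it genuinely moves); `fixed_centroid = TRUE` freezes
  the first frame's centroid for sensitivity analyses.
* **Perimeters** use sub-pixel contours: the 0.5 iso-level of the mask
  indicator after a σ = 1.5 px Gaussian smoothing (raw marching squares
  overestimates curved perimeters by ~5–6% through staircase bias; the
  smoothed contour is within 0.3% on rasterized circles of radius ≥ 15 px).
  The contour is then regularized by truncated Fourier descriptors of its
  radius function about the centroid (6 harmonics, 3600 resampled points
  starting exactly at the first sector boundary): vessel cross-sections are
  star-shaped and near-elliptical, so a few harmonics capture the geometry
  while discarding high-frequency rasterization noise that would otherwise
  dominate per-quadrant arc lengths. Quadrant arcs are cut exactly at the
  sector angles and sum exactly to the total perimeter.
* **Local extrema** are taken independently per quadrant (each quadrant's
  own systolic/diastolic frames), the formula applied verbatim to each
  curve; consequently the sum of local compliances can exceed the global
  compliance.
* **Tangent modulus** uses central finite differences after a moving-average
  smoothing of stress (default window 11 samples) — derivatives amplify
  noise. The literal stress/strain ratio reading is available as
  `method = "secant"`. The physiological stress window maps pressures
  through thin-wall (Laplace) hoop stress $\sigma = P r / t$ with
  user-supplied radius and wall thickness (1 mmHg = 1.33322×10⁻⁴ MPa);
  the mapping is explicit and configurable because conventions differ
  between laboratories.
* **Agreement** statistics use Pearson correlation (`cor.test`; Spearman by
  flag), Bland–Altman mean ± SD of differences with the
  predicted − reference sign convention (a positive mean difference is an
  overestimation by the method), and n−1 sample SDs throughout, as cohort
  tables report sample statistics.

## Numerical and degenerate-input choices

* Constant frames normalize to all zeros (range contract without division
  by zero); coinciding stretch percentiles fall back to min–max scaling.
* Default stretch percentiles 1–99, robust to bright flow-artifact
  outliers.
* Augmentation defaults: rotation ±15°, flips p = 0.5 each, scale 0.9–1.1,
  translation ±5%; identical geometric transform to frame (bilinear) and
  mask (nearest neighbor, preserving binarity).
* Center crop/pad places the extra pixel of odd differences on the
  trailing side, preserving the image center.
* Both-empty mask pairs score Dice = IoU = 1; precision/recall use the
  matching empty-reference convention; the Hausdorff distance is an error
  on empty masks (undefined), and is the true 100th-percentile distance by
  default (`percentile = 95` gives HD95).
* Preprocessing order is stretch-then-normalize, exposed in
  `preprocess_sequence()`.
* The Dice smoothing constant, instance-norm ε (10⁻⁵), and He weight
  initialization are fixed, seed-controlled choices; identical seeds give
  bit-identical models, predictions, phantoms and reports.

## Known limitations

* Compliance differencing amplifies rasterization noise: from binary masks
  at ~1.1–1.2 mm/px on a ~20 px-radius vessel, per-frame pixel-count areas
  carry a few-px² quantization error, so max–min differences are accurate
  to roughly 1–2% under realistic (moving) conditions — and this is a
  floor imposed by binary masks, not by the implementation.
* The Fourier contour regularization assumes a star-shaped cross-section;
  strongly concave segmentation failures would be smoothed over rather
  than flagged.
* The network is CPU-only and double-precision; full-scale 256×256
  training is possible but slow (roughly half a minute per frame for a forward and backward pass).
* Batch/group normalization variants and the attention/recurrent/nested
  architecture family are out of scope.
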