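---
title: "Methods: the nodulescan detection pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nodulescan detection pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nodulescan)
```

# The problem

Pulmonary nodules — roughly spherical lung lesions 3–30 mm across — are
the main radiological target of early lung-cancer screening on thoracic
CT. A computer-aided detection (CAD) pipeline must first find *candidate*
dense structures inside the lung fields and then reject the many
non-nodule candidates (vessel cross-sections, scarring, focal opacities);
the quality of the second step is what separates a usable system from an
alarm generator. `nodulescan` implements a classical five-stage CAD
pipeline:

1. **Contrast enhancement** in the frequency domain,
2. **Lung-field segmentation** by optimal thresholding,
3. **Candidate extraction and pruning** by size and shape,
4. **Texture description** with the Weber Local Descriptor (WLD),
5. **Classification** of candidates with a support vector machine,

plus a **synthetic thorax phantom** that makes every stage testable
without any external imaging archive.

# Enhancement: CLAHE on the low-frequency DCT component

Each slice (8-bit gray levels; Hounsfield-unit slices are first windowed,
default window \[−1000, 400\] HU) is tiled into 8 × 8 blocks and
transformed with the orthonormal 2-D DCT

$$D_{u,v} = \rho(u)\,\rho(v) \sum_{x,y} d_{x,y}
  \cos\frac{(2x+1)u\pi}{2M}\cos\frac{(2y+1)v\pi}{2N},$$

with $\rho(0) = \sqrt{1/M}$ and $\rho(u>0) = \sqrt{2/M}$. The first
`lf_cutoff` coefficients in zig-zag order form the low-frequency (LF)
component — the coarse, blurred version of the image — and the remainder
the high-frequency (HF) component, which carries fine texture and most of
the noise. Contrast-limited adaptive histogram equalization
(CLAHE, $J = (j_{max}-j_{min})\,P(f) + j_{min}$ with clipped per-tile
cumulative histograms and bilinear blending) is applied to the *spatial
reconstruction of the LF component only*; the HF residual is added back
unchanged. Enhancing only LF raises local contrast without amplifying
high-frequency noise, and the HF content of the output is numerically
identical to the input's.

Choices the method's description leaves open, fixed here:

* **`lf_cutoff = 16` of 64** (DC + 15 AC): keeps the coarse structure in
  LF while leaving texture in HF. Exposed as a parameter.
* **CLAHE applied after inverse-transforming LF to image space** —
  histogram equalization of raw DCT coefficients is ill-defined; LF/HF
  are treated as images throughout.
* **CLAHE parameters** `clip_limit = 0.01` (fraction of tile pixels),
  8 × 8 tile grid, 256 bins; $j_{min}, j_{max}$ are the *global* display
  range, so a constant image is a fixed point and output never leaves the
  input range.
* **Edge blocks** use symmetric-reflection padding, cropped after
  reconstruction.

A note on measurement: on a thorax slice the global intensity variance is
dominated by the air background, so the contrast gain of enhancement is
visible in the *lung-interior* standard deviation (asserted in the test
suite), not necessarily the global one.

# Segmentation: DE optimal thresholding

Segmentation composes five operations (`segment_lungs()`):
border-connected background removal (scanline runs from the four corners
plus a middle-column traversal); an iterative intermeans threshold
started at −950 HU (the lung parenchyma band is roughly −950…−500 HU)
with convergence at |ΔT| < 0.5 HU or 100 iterations; a
differential-evolution refinement of the threshold; corner-seeded region
growing that removes air components connected to the image corners; and
hole filling, which restores dense structures (nodules, vessels) carved
out of the lung interior.

The threshold model treats the gray-level histogram as a K-component
Gaussian mixture fitted *to the partition the thresholds induce*
(interval mass, mean, and standard deviation per class; class $i$ holds
levels $T_{i-1} \le x < T_i$, standard deviations floored at $10^{-3}$).
The score of a threshold vector is the total misclassification mass

$$E(T) = \sum_{i=1}^{K-1} \Big[ P_i \Pr[X_i > T_i]
  + P_{i+1} \Pr[X_{i+1} < T_i] \Big],$$

each class's Gaussian tail on the *wrong* side of the threshold, so
well-separated classes drive $E \to 0$ and two identical adjacent classes
give $(P_i + P_{i+1})/2$. (The misclassification form is the standard
reading of the minimum-error criterion; the own-side form that sometimes
appears in print would be *maximized* at the optimum.)

The search is DE/rand/1/bin with population 20, $F = 0.5$, $CR = 0.9$,
100 generations, bounds at the histogram range, candidate vectors
repaired by sorting, and a fixed seed for reproducibility. On 8-bit
bimodal and trimodal histograms it matches exhaustive integer-threshold
search within ±3 gray levels (asserted over 20 seeds).

**A degeneracy worth knowing about.** The misclassification criterion has
spurious minima at the histogram extremes: a threshold pushed into a far
tail isolates a near-empty, near-zero-variance class whose wrong-side
mass is essentially zero. On a multimodal lung interior (parenchyma +
opacities + nodules) an unconstrained K = 2 search lands there and the
resulting threshold is useless for candidate extraction. The package
therefore (a) windows the DE search around an intermeans fixed point —
below soft tissue for segmentation, ±350 HU around the lung-interior
intermeans for candidate extraction — and (b) supports a minimum
class-mass floor (`min_mass`, 0.02 in the candidate stage, off by default
so the pure criterion is what the oracle-equivalence tests exercise).

# Candidates: median-slice threshold, size and shape pruning

Within a slice stack the dense-structure threshold is computed once, on
the median-index slice's lung-interior histogram, and reused everywhere —
keeping the candidate definition consistent across slices. Candidates are
8-connected components of lung-interior pixels at or above the threshold.
Geometry per region:

* **area-equivalent diameter** $2\sqrt{A/\pi}\cdot s$ mm (area $A$ px,
  in-plane spacing $s$ mm) — rotation-invariant and standard;
* **elongation**: the square root of the ratio of the eigenvalues of the
  pixel-coordinate covariance matrix (axis variances floored at 1/12, a
  single pixel's variance, so 1-px-wide bars stay finite). Discs score
  ≈ 1, tubular vessels score high.

Pruning labels every region non-destructively: diameter < 3 mm →
`pruned_small` (noise), > 30 mm → `pruned_large` (lesions/conglomerates),
elongation > 3 → `pruned_vessel`, otherwise `candidate`. The elongation
cut-off 3.0 is a package choice (not stated by the method's description);
at the phantom's geometry it cleanly separates tubes from blobs, and it
is exposed as a parameter.

# Features: Weber Local Descriptor

Each surviving candidate is cut out (bounding box + 4 px margin),
bilinearly resized to 32 × 32, and described by two per-pixel maps over
the 8-neighborhood $x_1..x_8$ (clockwise from North):

* differential excitation
  $\varepsilon_m = \arctan\!\big(\alpha \sum_i (x_i - x_c)/x_c\big)$,
  the arctan-compressed relative intensity difference (flat regions ≈ 0;
  $x_c$ floored at 1 to keep the ratio bounded; $\alpha = 3$, the typical
  WLD setting);
* gradient orientation
  $\theta = \mathrm{atan2}(x_1 - x_5,\; x_3 - x_7) \in [0, 2\pi)$,
  the quadrant-corrected angle of the (N − S, E − W) cross differences.

Each map is divided into a 2 × 2 block grid; per block, a normalized
`fs_bins`-bin histogram is computed (excitation over $(-\pi/2, \pi/2)$,
orientation over $[0, 2\pi)$), and the excitation histograms followed by
the orientation histograms are concatenated into the feature vector — the
"FS-k" family, `FS-14` by default giving $4\times(14+14) = 112$
dimensions. Fusion by concatenation (rather than weighting) is an
interpretation; it yields the monotone family of vector sizes the FS-10…
FS-18 naming implies. The descriptor is deliberately contrast-sensitive
in its excitation half (adding an offset to a patch changes excitation
but not orientation — asserted in the tests).

# Classifier and evaluation protocol

A soft-margin kernel SVM separates nodules from non-nodules. Features are
z-scored with training-set statistics only (no test leakage); the default
kernel is RBF with $\gamma = 1/(M \cdot \overline{\mathrm{var}})$ and
$C = 1$ — a robust default for ~100-dimensional histogram features. The
dual problem is solved by a sequential-minimal-optimization solver
written for this package (no SVM library is assumed present); it is
validated on separable toys and the analytic 1-D hyperplane in the test
suite.

The protocol mirrors the published evaluation: stratified splits at
70/30, 50/50, 30/70 (a balanced 1572-sample set at 70/30 gives the
1100/472 partition with 236 test samples per class); stratified k-fold
cross-validation for k = 5, 7, 10; accuracy, sensitivity (TP/(TP+FN)),
and specificity (TN/(TN+FP)) in percent; ROC curves swept over the
decision scores. Reported percentages are rounded half-up to 2 decimals —
published tables occasionally truncate instead (e.g. 456/550 = 82.909 →
"82.9", 542/550 = 98.5454 → "98.54"), so printed-precision comparisons
allow one unit in the last printed digit. One printed sensitivity formula
(TP/(TP+FP), i.e. precision) contradicts the reported numbers; the
standard form is the default and the printed variant is available as
`metrics(..., printed_eq12 = TRUE)`.

# The phantom: what it emulates and what it does not

`generate_slice()` draws a 256 × 256 slice at 0.7 mm spacing: scanner air
at −1000 HU, a soft-tissue body ellipse at 40 HU, two elliptical lung
fields of correlated parenchyma texture clipped to −945…−545 HU, vessels
as jittered random-walk tubes (width 1–4 px, ≈ −50 HU), focal opacity
clumps (irregular unions of small discs at −250…−120 HU — the realistic
false-positive source the classifier must reject), and nodules as
smooth-profile discs with diameters drawn from 5–20 mm and densities from
−100…100 HU, placed fully inside a lung and non-overlapping. Additive
Gaussian noise (σ = 20 HU) and an optional global contrast compression
emulate acquisition variation. Ground truth (lung mask, vessel mask,
nodule records) is returned with the image, and a fixed seed gives
bitwise-identical output.

`generate_dataset()` runs segmentation, candidate extraction and feature
extraction over a stack of such slices, labels surviving candidates by
whether their centroid falls inside a truth nodule disc, and balances the
classes by seeded subsampling. One sub-3 mm speck per dataset and the
vessels guarantee that both pruning rules are exercised.

What a green phantom test establishes: the pipeline's stages compose
correctly, the thresholds recover the designed intensity structure, the
WLD/SVM stack separates the designed texture classes, and the whole chain
is deterministic under a seed. What it does *not* establish: performance
on real CT — the phantom has no juxtapleural nodules, no 3-D coherence
between slices, no scanner artifacts, and its texture classes are far
cleaner than biology. Published sensitivities on an annotated clinical
archive are not reproducible at desk scale and are not claimed.

# Numerical choices and degenerate inputs

* DCT via the cached orthonormal basis-matrix product — exact inverse,
  Parseval holds to 1e−12 at block sizes used here.
* Histograms round real (HU) values to integer levels.
* Mixture fitting floors class standard deviations at 1e−3; empty classes
  raise a degenerate-partition error (treated as infeasible, +Inf, by the
  DE search).
* The intermeans iteration warns and returns its start when all pixels
  lie on one side of it; `segment_lungs` warns and returns an empty mask
  when no lung-like component survives.
* A constant candidate patch yields the all-spike excitation histogram
  and is flagged `degenerate`.
* All stochastic stages (DE, SVM sweeps, splits, folds, phantom) take
  explicit seeds; derived seeds stay inside 32-bit range.

# Limitations

Slice-wise 2-D processing only (the stack driver shares a threshold but
does not merge candidates across slices); no juxtapleural mask
correction beyond hole filling; no probability calibration; the CLI
reads PNG/ASCII-PGM/CSV rather than DICOM (HU rasters persist as ASCII
PGM with a +1024 offset).
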