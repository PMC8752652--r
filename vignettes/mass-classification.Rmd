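---
title: "Texture and geometry features for breast-mass classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture and geometry features for breast-mass classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`mammotex` implements a classical radiomics pipeline for discriminating
benign from malignant breast masses in mammographic regions of interest
(ROIs): a fixed battery of 125 texture and geometry features, four filter
feature-selection rankers, and distance-weighted k-nearest-neighbor
(k-NN) evaluation under repeated stratified 10-fold cross-validation.
Because clinical mammography datasets with pixel-level boundary
annotations are access-restricted, the package ships a synthetic
spiculated-lesion phantom generator that reproduces the geometric and
textural class contrasts the analysis relies on, so every stage is
testable end to end without any download.

This vignette records the model choices, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic benchmark can
and cannot tell you about real data.

## The lesion phantom

Each synthetic lesion is drawn on a square 8-bit patch (default 96 px).
The boundary is a radial curve about the patch center,

$$ r(\theta) = R\,\bigl(1 + a\, s(\theta)\bigr), $$

where $R$ is the base radius (default 22 px), $a \in [0,1)$ the
spiculation amplitude, and $s(\theta)$ a band-limited random harmonic
perturbation normalized to $\max|s| = 1$, with its energy concentrated at
the spiculation lobe count and truncated at the boundary-smoothness
cutoff harmonic. A radial (star-shaped) boundary is always a simple
closed polygon, and one knob — the amplitude — controls how spiculated
the outline is, which is exactly the benign/malignant geometric contrast
radiology describes: benign masses are round or oval with smooth,
well-circumscribed margins; malignant masses are irregular with rough,
spiculated margins.

The interior is filled with correlated noise from spectral synthesis of a
fractional-Brownian-motion-like (fBm) field: complex Gaussian white noise
shaped by an amplitude spectrum $\propto f^{-(H+1)}$, i.e. power
$\propto f^{-(2H+2)}$. For a two-dimensional field this is the exponent
for which mean absolute increments scale as $d^{H}$, so the Hurst
exponent the generator targets is the same quantity the fractal feature
estimator recovers — giving the estimator a recoverable ground truth.
The interior sits 60 gray levels above the background tissue and is
scaled to the per-class texture-contrast standard deviation; the
background carries mild fBm texture of its own.

Class presets (chosen once as plausible for the domain, since no
quantitative texture/geometry parameters are published for such masses):

| parameter | benign | malignant |
|---|---|---|
| spiculation amplitude | 0.06 | 0.35 |
| spiculation lobes | 5 | 11 |
| smoothness cutoff (harmonic) | 8 | 24 |
| interior Hurst exponent | 0.65 | 0.35 |
| interior contrast (gray SD) | 10 | 22 |

Per-sample morphology is jittered around the preset (radius ±25%, lobes
±2, amplitude scaled by U(0.2, 1.8) capped at 0.5, Hurst shifted by
±0.2, contrast scaled by U(0.6, 1.5)). The jitter ranges deliberately
overlap between classes: real benign and malignant masses are not
separable along any single morphological axis, and a phantom without
overlap saturates every classifier at 100% and makes comparisons between
feature sets vacuous. Per-sample seeds are a deterministic hash of the
master seed and the sample index, so regeneration is bit-identical and
independent of generation order.

What the phantom does *not* emulate: surrounding anatomy (pectoral
muscle, vasculature, overlapping fibroglandular tissue), calcifications,
acquisition physics (noise model, scatter, compression), multi-mass
images, and the label noise of BI-RADS-derived ground truth. Passing
tests on the phantom therefore validate the *implementation* of the
battery and the *internal* logic of selection and evaluation — not
clinical performance.

## ROI extraction

Annotations are closed polygons of (x, y) pixel coordinates. The
rasterizer marks a pixel as foreground when its center lies inside or on
the polygon (even-odd rule plus an explicit on-segment test), so an
axis-aligned square with integer corners has exactly the expected pixel
count. Conventions fixed once: (row, col) indexing, 0-based, pixel
centers at integer coordinates; annotation files store (x, y) =
(col, row). The ROI is the tight bounding box of the mask; pixels inside
the box but outside the mask are retained, and each feature model decides
what it consumes: texture models use the full rectangular ROI (matrix and
convolution operators need a regular grid), geometry models use only the
binary mask.

## The 125-feature battery

Texture (F1–F45), on the gray ROI:

* **SGLCM, F1–F14** — the 14 Haralick statistics of the gray-level
  co-occurrence matrix at displacement 1, accumulated symmetrically for
  0°, 90°, 45°, 135° and averaged over the four directions. Natural
  logarithms; levels indexed 1..G. Degenerate (zero-variance) marginals
  define correlation and the maximal correlation coefficient as 0.
* **GLDS, F15–F19** — homogeneity, contrast, mean, energy, entropy of
  the absolute gray-difference density, averaged over the displacement
  set {(0,1), (1,0), (1,1), (1,−1)}.
* **FOS, F20–F23** — population histogram moments; skewness and kurtosis
  fall back to 0 on constant patches.
* **SFM, F24–F27** — from the dissimilarity matrix
  $DSS(i,j) = E|I(x,y) - I(x+i,y+j)|$ on the lattice $0 \le i,j \le 4$:
  coarseness $= 100 / \overline{DSS}$, contrast $=$ RMS of the two
  unit-displacement mean squared differences, periodicity $=$ relative
  depth of the deepest $DSS$ valley, roughness $=$ mean of the
  directional fractal dimensions $3 - H$ fitted from the log–log $DSS$
  decay along rows and columns. The published description of this model
  names the four properties but not their formulas; these definitions are
  this package's own, documented reading.
* **LTEM, F28–F41** — mean absolute valid-convolution response to the
  fourteen 5×5 Laws masks (outer products of L5/E5/S5/W5/R5); the two
  orientations of each mixed mask are averaged into one feature.
* **Fractal, F42–F43** — Hurst exponents from the slope of
  $\log E|\Delta I|$ versus $\log d$ over rounded pair distances 1..8
  (full resolution) and 1..4 (after 2×2 block averaging), clipped to
  [0, 1].
* **FPS, F44–F45** — fractions of non-DC spectral power in a radial
  annulus (quarter to half Nyquist) and a ±22.5° wedge about the
  horizontal frequency axis.

Gray-level quantization for the GLCM/GLDS/SFM family: images whose
integer range already fits in G = 32 levels are only shifted to zero;
wider ranges are binned linearly. This keeps small worked examples exact
while binning 8-bit images as standard practice.

Geometry (F46–F125), on the binary mask:

* **Shape, F46–F58** — area, equivalent-ellipse axis lengths /
  eccentricity / orientation (with the 1/12 per-pixel moment correction;
  orientation in degrees in (−90, 90] from the row axis), convex area
  (pixel centers inside the hull), filled area, Euler number
  (8-connected components minus 4-connected holes), equivalent diameter,
  solidity, extent, perimeter (polygonal length of the Moore boundary
  trace), and the circularity ratio $P^2 / 4\pi A$ — the reading adopted
  for the truncated feature name "perimeter cirratio".
* **Zernike, F59–F73** — magnitudes $|Z_{nm}|$,
  $Z_{nm} = \frac{n+1}{\pi}\sum f(x,y) V^*_{nm}(x,y)$, over the 15
  signed pairs $n = 0..4$, $|m| \le n$, $n - |m|$ even, on the unit disk
  (centroid-centered, radius = max centroid distance). Computed on the
  mask, not gray levels: conjugate pairs are then exactly equal and the
  magnitudes rotation-invariant, consistent with the signed-repetition
  naming (ZM3−1, ZM31, ...).
* **GFD, F74–F125** — modified polar Fourier transform: each mask pixel
  contributes $\exp[-j(2\pi\rho r + \phi\theta)]$ with $r$ normalized by
  the maximum centroid distance, on the frequency grid $R = 4$,
  $T = 13$ (the unique small grid yielding 52 descriptors). Normalized
  as $|PF(0,0)|/\text{area}$ for the DC term (identically 1 for a binary
  mask) and $|PF(\rho,\phi)|/|PF(0,0)|$ otherwise; FD index
  $= \rho T + \phi + 1$. The pixel-sum form is exactly
  translation-invariant and rotation-invariant up to rasterization; a
  literal 4×13 spatial polar resampling could not be, which is why this
  form was chosen.

Several battery parameters are not published for the original analysis
(quantization level, GLCM aggregation, GLDS displacements, SFM spacings,
LTEM statistic, fractal distances, FPS band edges). Each default above is
an explicit substitution, surfaced in `analysis_config()` where it is
reasonable to vary.

## Feature selection

All four rankers consume z-scored features (scaling is configurable;
the original analysis does not state its normalization):

* **Relief-F** — two-class form, k = 10 nearest hits and misses by
  Euclidean distance, every instance a target once (m = n, the stable
  choice; estimate quality is known to improve as m approaches n).
  Per-feature differences are range-normalized, so weights lie in
  [−1, 1] and constant features score exactly 0.
* **Pearson** — absolute correlation with the class coding benign = 0,
  malignant = 1.
* **NCA** — diagonal neighborhood component analysis: gradient ascent on
  the expected leave-one-out same-class soft-neighbor probability with
  kernel $\exp(-d_w)$, $d_w(a,b) = \sum_f w_f^2 (a_f - b_f)^2$. The L2
  penalty (λ = 1/n) is applied as a proximal (implicit) step, which is
  stable for arbitrarily large λ; learning rate 0.1, 200 iterations,
  scores = final $w_f^2$ at the cap.
* **Term variance** — sample variance after min-max scaling, hence
  invariant to affine rescaling of raw inputs.

## Classification and evaluation

Three distance metrics (Euclidean, cosine, Minkowski order 3) and two
weighting schemes (uniform vote, squared inverse distance with
ε = 10⁻¹²) cover the conventional named k-NN variants: fine (k = 1),
medium / cosine / cubic / weighted (k = 10), and the best-performing
variant, cosine with k = 5 and squared-inverse weighting. The k values
behind the variant names are not printed in the original analysis; the
presets follow the conventional family those names imply. Neighbor
distance ties break by smallest training index; vote ties by the class
of the single nearest neighbor — both deterministic.

Evaluation is repeated stratified 10-fold CV (10 repeats). Fold
assignments derive from per-repeat seeds (master + repeat index),
features are standardized with training-fold statistics only, fold
predictions are pooled per repeat (more stable than per-fold averaging
at n ≈ 115; the original aggregation is unstated), and metrics —
accuracy, sensitivity, specificity with malignant positive — are
averaged over repeats.

The published analysis reduced its top-20 Relief-F list to nine features
by manual experimentation, which is not a reproducible procedure. The
package replaces it with deterministic greedy forward selection over the
top-20 candidates (max size 9): add the candidate maximizing mean CV
accuracy, ties by higher sensitivity then lower index, stop when nothing
improves; the full candidate set is also evaluated and the best subset
seen is returned, so the compact subset is never worse than the top-20
set on the same seeds.

## Degenerate inputs and numerical conventions

* Constant ROI: ASM = 1, entropies = 0, contrasts = 0, IDM = 1,
  correlation/MCC = 0, GLDS energy/homogeneity = 1, FOS
  skewness/kurtosis = 0, SFM contrast = 0, all Laws energies = 0,
  H1 = H2 = 0, Sr = Stheta = 0.
* Cosine distance to a zero-norm vector is 1.
* k > n_train clamps with a warning; folds exceeding the smallest class
  abort with instructions.
* Single-pixel masks: unit-disk radius falls back to 1; the boundary
  trace of an isolated pixel has zero length.
* 0·log 0 := 0 throughout; all entropies use natural logarithms.

## Problem sizes and reproducibility

The synthetic benchmark mirrors the published study population: 115
masses, 52 benign / 63 malignant. The test suite exercises the battery
oracles on small worked images, invariance properties on 48–72 px masks,
Hurst recovery on 128² fBm fields (20 seeds per target), Relief-F signal
recovery on 50 seeded 125-feature tables, and the full pipeline at the
115-sample scale. `scripts/acceptance.R` recomputes the headline
quantities from scratch from a single seed; all randomness in the
package flows from explicit seeds, and no function touches the global
RNG state.

## Known limitations

* The phantom's class contrast is encoded directly in generator
  parameters; feature models that read those parameters (solidity,
  Hurst, interior variance) are inevitably favored. Rankings on real
  mammograms will differ.
* Benchmark accuracies are far above what the same pipeline attains on
  clinical data — the phantom is a correctness vehicle, not a difficulty
  benchmark.
* The SFM scalar formulas and several battery tunables are this
  package's documented substitutions for unpublished choices; numerical
  agreement with other implementations of the same feature names is not
  guaranteed.
* Diagonal NCA leaves zero-gradient (constant) features at their
  regularization-shrunk initial weight rather than exactly 0.
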