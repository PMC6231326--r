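---
title: "Methods: quantifying fiber organization, transcription-factor localization, and screen hits"
author: "mechquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying fiber organization, transcription-factor localization, and screen hits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechquant)
```

mechquant implements the quantitative readouts of a mechanotransduction
imaging workflow: how organized a cell's actin cytoskeleton is, where a
transcriptional cofactor such as YAP sits between nucleus and cytosol,
and which gene knockdowns shift that localization in an arrayed siRNA
screen. This vignette explains each model, its assumptions and tunable
parameters, the synthetic data the package validates itself against,
and the numerical choices made where the design was genuinely open.

## Multiscale nematic anisotropy

### The model

Fibrous structures (actin stress fibers, collagen) have orientations
defined modulo 180 degrees, so directional statistics on the *doubled*
angle are the natural tool. At every interior pixel the local fiber
direction is the 90-degree rotation of the intensity gradient
(estimated by central differences), giving per-pixel values of
$\cos 2\theta$ and $\sin 2\theta$. A region's mean nematic tensor is

$$Q = \frac{1}{2}\begin{pmatrix} c & s \\ s & -c \end{pmatrix},
\qquad c = \overline{\cos 2\theta},\; s = \overline{\sin 2\theta},$$

with weighted means taken over the region. Its eigenvalue difference
$\sqrt{c^2 + s^2}$ is the anisotropy score: 0 for isotropic content, 1
for perfect alignment. For unit weights this is exactly the circular
resultant length $|\,\overline{e^{2i\theta}}\,|$ of the orientation
field — the standard nematic order parameter — and the test suite
asserts that identity to $10^{-12}$ against a direct brute-force
computation.

The multiscale aggregation captures organization at multiple scales and
locations: for each grid size $N$ in $\{2^i\} \cup \{3^i\}$
($i = 0, 1, 2, \dots$) the image is split into $N \times N$
non-overlapping patches (the last row/column absorbs any remainder so
the tiling is exact), each sufficiently textured patch is scored, each
pixel receives the mean score of all processed patches containing it,
and the global score is the mean over evaluated pixels. Grid sizes are
kept while `floor(side/N)` stays at or above the minimum patch side
(default 10 px). For a 241x261 cytoplasmic crop this yields
$N \in \{1, 2, 3, 4, 8, 9, 16\}$.

The powers reading of the scale collection is deliberate: the multiples
reading ($N = 2i$, $i \ge 0$) would start at an invalid $N = 0$ and
omit the whole-image scale, whereas $i = 0$ under the powers reading
gives $N = 1$, the natural coarsest scale. The alternative collection
remains selectable via `mq_config(anisotropy = list(scale_set =
"multiples"))`.

### Weighting

Each orientation sample is weighted by its squared gradient magnitude
(`weighting = "grad2"`, the default). The alternative, weight 1 per
nonzero-gradient pixel (`"unit"`), makes the score a pure order
parameter of the pixel orientation *distribution*, but it is badly
diluted in practice: pixels with vanishingly small gradients — ridge
crests, interference between overlapping fibers, faint background
texture — carry arbitrary orientations at full weight. On synthetic
fiber images this depresses the score of strongly aligned textures by
around 0.2 absolute at every scale, while gradient-squared weighting
tracks the planted order parameter to within a few hundredths across
the whole concentration range. Structure-tensor practice (averaging
outer products of raw gradients, which is exactly gradient-squared
weighting of normalized orientations) makes the same choice. Both
modes are exposed; scale-invariance of the score holds for either,
since weights enter numerator and denominator alike.

### Multiscale score versus global order parameter

The two summary quantities answer different questions.
`whole_image_anisotropy()` (equivalently a single-scale run with grid
$\{1\}$) estimates the global order parameter of the underlying fiber
angles and is the quantity that recovers a planted von Mises
concentration: across $\kappa \in \{0, 1, 2, 4, 8\}$ it lands within a
few hundredths of the empirical $|\,\overline{e^{2i\theta_k}}\,|$ of
the generated fibers. The multiscale `global_score` additionally
rewards *local* order: a sparse field of randomly oriented fibers is
locally parallel inside any patch containing a single fiber, so its
multiscale score sits well above the (near-zero) global order
parameter. That is by construction, not error — the multiscale score
measures organization at all scales. Validation against planted
ground truth therefore uses the whole-image score, and both values are
reported.

### Degenerate inputs and numerical choices

Image borders carry zero weight (no central difference exists). A
patch is processed only if it holds at least `min_valid_pixels`
(default 100, one full minimum-size patch) weighted samples;
insufficient patches are skipped rather than zero-scored, so flat
background neither dilutes nor inflates the result. An image or mask
offering no processable patch at any scale raises a "no quantifiable
texture" error instead of fabricating a zero. A constant-anisotropy
pixel map short-circuits the final mean so that the single-scale run is
bit-identical to the whole-image patch score.

## Nuclear/cytosolic quantification

### Segmentation

Nuclei are detected on the DNA (Hoechst) channel: Gaussian smoothing
(sigma 2 px), global Otsu threshold, hole filling, and a watershed
split of the distance transform for touching nuclei. Detection masks
are then *refined per object* on the raw image, keeping pixels above
half the object's median raw intensity within a slightly dilated search
zone. The refinement matters for two QC-relevant cases: a single
global threshold over-grows bright (mitotic) nuclei into their smoothed
halo, pulling their measured mean intensity down toward the threshold
criterion, and smoothing rounds the tips of elongated nuclei, inflating
their roundness past the aberrancy cutoff. Half-maximum refinement
restores both the true boundary and the true shape. Labels are
renumbered in raster order of centroids, and externally produced masks
can be supplied to bypass segmentation entirely.

### QC filtering

Each nucleus is flagged for exclusion when it is:

* `mitotic_intensity` — mean DNA stain above `mitotic_factor` (default
  2.0) times the population median; condensed mitotic chromatin is
  substantially brighter than interphase nuclei;
* `aberrant_roundness` — $4\pi A / P^2$ below `min_roundness` (default
  0.65), with the perimeter measured as the 8-connected border contour
  chain length (unit and $\sqrt 2$ steps). On rendered shapes this
  estimator gives discretized circles roughly 0.93-0.99 and 3:1
  ellipses roughly 0.62-0.65, so the default cutoff separates the two
  while tolerating discretization;
* `area_out_of_range` — outside `[min_area, max_area]` (defaults 100
  and 2000 px^2);
* `border` — any pixel on the outermost image row/column (truncated
  cells cannot be measured fairly).

### ROIs and readouts

The cytosolic reference is a 4-px perinuclear ring: background pixels
within `ring_width` of the nucleus (Euclidean distance), assigned to
the nearest nucleus where dilations of neighbors overlap, so rings are
disjoint and never include nuclear pixels. The whole-cell region grows
from the nucleus by seeded Voronoi propagation over an Otsu support of
the marker channel, capped at `max_grow_px` (default 40 px). Two
readouts are always computed: the ratio `nc_ratio = nuclear mean /
ring mean` (primary) and the fraction `nuclear_to_total = summed
nuclear marker / summed whole-cell marker`. Cells with zero ring
signal get an undefined ratio and are excluded from ratio summaries
rather than silently dropped to infinity.

Localization classes use a symmetric multiplicative band around ratio
1: nuclear (N) above $1 + \delta$, cytosolic (C) below $1/(1+\delta)$,
even (N/C) between, with $\delta = 0.2$ by default. The underlying
visual classification this mirrors has no published numeric cutoff, so
$\delta$ is an explicit, configurable parameter; the symmetric
multiplicative form guarantees that a uniform marker (ratio 1)
classifies N/C regardless of $\delta$.

## Screen statistics

Per-well ratios are normalized per plate, replicate, and genotype
against that plate's non-targeting control wells:
$Z = (x - \mu_{\mathrm{ctrl}})/\sigma_{\mathrm{ctrl}}$, where $x$ is
the mean of an siRNA's wells on the plate/replicate and
$\sigma_{\mathrm{ctrl}}$ is the sample SD ($n-1$; control panels are
small). The hit statistic is the mean Z across replicates with a
strict threshold, $|\bar Z| > 2.5$ — boundary values are not hits. A
pooled-controls mode exists for screens without plate structure.
Genotype specificity is operationalized as "hit in one genotype AND not
a hit in the other", with an optional stricter margin on the other
genotype's $|\bar Z|$; shared hits must agree in direction.

Enrichment of a gene set among selected genes uses the exact
hypergeometric tail computed from log-binomial coefficients, with the
one-sided "greater" alternative as the default (enrichment is the
question being asked); the sample odds ratio $(ad)/(bc)$ accompanies
the p-value. The implementation is validated against exhaustive
enumeration for every 2x2 table with grand total up to 60, to
$10^{-12}$.

Dual-luciferase normalization divides per-sample firefly activity by
the co-transfected secreted-luciferase activity and expresses results
as fold change over a reference condition's mean ratio. Gel
contraction is fractional area loss $(A_0 - A)/A_0$ relative to the
well area (the full frame unless a well mask is given), reported as
fold change over a control gel. Both are scale-invariant by
construction.

## Synthetic ground truth

The generators plant known parameters so every stage can be tested for
recovery, not just for running:

* **Fibers** (`generate_fibers()`): straight Gaussian-profile ridges
  (sigma 2 px, peak 100 a.u., lengths 25-75% of the short side) with
  angles drawn on the doubled circle, $2\theta \sim
  \mathrm{vM}(2\mu, \kappa)$, so the planted order parameter lives on
  the same scale as the anisotropy score. The default background is
  dark and noise-free, emulating a well-stained cytoskeletal channel;
  `noise_sd` adds camera-like Gaussian noise for robustness checks.
* **Cell fields** (`generate_cell_field()`): non-overlapping nuclear
  disks (radius 12 px) inside cytoplasmic disks (radius 24 px) on an
  800x800 field, placed by rejection sampling with a 10,000-attempt
  cap. The marker carries `marker_base` in cytoplasm and
  `nc_ratio_true` times that in the nucleus under mean-1 multiplicative
  lognormal noise (CV 0.1 by default), so planted ratios are unbiased.
  QC categories are planted by fraction: border cells centered half a
  nuclear radius from an edge, mitotic nuclei at 2.5x DNA intensity,
  aberrant nuclei as equal-area 3:1 ellipses.
* **Screen plates** (`simulate_screen()`): control wells
  $\sim N(\mu_c, \sigma_c)$ and effect wells shifted by planted
  multiples of $\sigma_c$, independent across three replicates, 89
  siRNAs at four wells each. The default control panel is 28 wells:
  89 x 4 = 356 siRNA wells fill a 384-well plate, and the 28 remaining
  wells carry the two non-targeting control pools. Panel size matters:
  with only a handful of control wells the sample SD occasionally
  inflates plate-wide and a true $4\sigma$ effect can slip under a
  strict 2.5 threshold, whereas the full-plate panel (27 df) makes
  recovery of $\pm 4\sigma$ effects essentially deterministic.

All generators are pure functions of their arguments including the
seed (bit-reproducible), and their truth tables enumerate exactly the
rendered objects.

What the synthetic data does *not* emulate: optical point-spread
functions, shot noise statistics, uneven illumination, out-of-focus
light, touching or overlapping cells, plate edge effects, and
biological covariance between channels. Passing recovery tests
therefore demonstrates correctness of the *computations* under
controlled conditions, not robustness to every real-microscope
artifact; the configurable QC and segmentation parameters are the
knobs a user would adjust on real data.

## Problem sizes used in validation

The shipped validation (test suite and `scripts/acceptance.R`) uses
512x512 fiber images (300 fibers, 5 concentrations x 5 seeds),
800x800 cell fields (50 cells, 4 planted ratios x 3 seeds, plus QC
fields at 10% border/mitotic/aberrant), 20 simulated screens, and the
exhaustive Fisher sweep to grand total 60 — sizes chosen so a complete
run finishes in minutes on a single core while leaving every recovery
margin wide.

## Known limitations

* The gradient stencil is fixed (central differences); sub-pixel or
  steerable orientation estimators are out of scope.
* Segmentation is a general-purpose recipe, not a re-implementation of
  any commercial system; heavily confluent fields will need external
  masks.
* No multiple-testing correction beyond the fixed screen threshold,
  and no plate-effect (B-score) correction.
* TIFF output is integer-valued (8/16-bit); unit-interval maps use a
  documented 16-bit fixed-point encoding with an NA sentinel, because
  no installed TIFF writer emits IEEE-float samples. Float TIFFs are
  read natively.
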