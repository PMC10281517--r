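---
title: "Methods: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidquant)
```

`organoidquant` implements the image-quantitation procedures used in
live-reporter and immunofluorescence studies of human lung tip-progenitor
organoids: kinase translocation reporter (KTR) ratio time series,
epithelial cell-shape morphometrics, nucleus circularity, per-cell marker
intensities, proliferation fractions and organoid-silhouette scoring.
Because the primary measurements in such studies are made on tissue images
that cannot be redistributed, every stage here is validated against a
seeded synthetic generator whose ground truth is known exactly. This
vignette documents the models, the defaults and why they were chosen, the
numerical decisions, and what the synthetic validation does and does not
establish.

## The KTR measurement model

A kinase translocation reporter shuttles between nucleus and cytoplasm as
it is phosphorylated, so the cytoplasm-to-nucleus (C/N) mean-intensity
ratio of a cell is a live, single-cell proxy for kinase activity. The
measurement chain mirrors the standard workflow:

1. segment nuclei on the nuclear-dye channel (`segment_nuclei()`);
2. define the cytoplasmic proxy region as a ring of 5 px (by default)
   around each nucleus (`ring_cytoplasm()`);
3. per cell, divide mean cytoplasmic by mean nuclear reporter intensity
   (`cn_ratio()`);
4. normalise every ratio to the cohort mean at the first time point and
   express it in percent (`normalize_to_t0()`), so the cohort mean at T0
   is 100% by construction;
5. aggregate per organoid per time point with a t-based 95% confidence
   band (`aggregate_per_organoid()`), and compare baseline versus a later
   frame with a two-group one-way ANOVA on replicate means
   (`anova_t0_vs_t()`).

Frames are ten minutes apart by default, so frame T12 is 120 minutes.
z-planes are analysed independently (non-consecutive planes chosen by
`select_planes()`) and pooled at the cohort level; per-plane normalisation
is available via `by_plane = TRUE` — the pooled default treats the scored
cells of one movie as a single cohort.

### The synthetic kinetics stand-in

The generator drives each simulated cell's true ratio with a first-order
relaxation model,

$$\frac{dr}{dt} = \frac{r_\infty(a) - r}{\tau},
\qquad r_\infty(a) = r_{min} + (r_{max} - r_{min})\,a,$$

where $a(t) \in [0,1]$ is a latent activity (0 under full kinase
inhibition, 1 under saturating stimulation). This is a deliberate
phenomenological stand-in — the simplest dynamics that produce the
observed nuclear-to-cytoplasmic translocation over a two-hour movie — and
is swappable; it makes no claim about reporter biophysics. Because no
numeric baseline or plateau C/N values are published for this system, the
defaults $r_{min}=0.6$, $r_{max}=1.8$, $\tau=20$ min are free generator
parameters: a nuclear-enriched baseline, a cytoplasm-enriched plateau and
a relaxation that is clearly resolved at 10-min sampling. The integrator
uses the exact exponential update per sampling interval under a
zero-order hold of the activity, so it agrees with the closed-form
solution to machine precision; a numerically integrated trace (deSolve)
serves as the independent cross-check in the tests.

### The intensity model, and two accuracy-critical choices

Rendered cells have uniform nuclear intensity $I_n$ and uniform
cytoplasmic intensity $I_c = r \cdot I_n$; a background floor applies
outside the cell footprint, and multiplicative Gaussian noise
(`noise_sd`, default 0.05) is applied afterwards. This makes the
mean-of-region estimator unbiased and gives analytic CLT bounds
($\mathrm{sd}(\hat r)/r \approx$ `noise_sd` $\sqrt{1/n_{nuc} + 1/n_{cyt}}$).
Compartment boundaries carry a 1-px anti-aliased blend, and those blend
pixels belong to *neither* compartment in the ground-truth masks, which
removes boundary ambiguity from recovery tests.

Two defaults exist specifically to keep the measured ratio faithful near
that blended rim:

* `seg_params(measure_erosion = 2)` — nuclear *measurement* masks are
  eroded 2 px (the ring stays anchored to the uneroded segmentation).
  Thresholding places the segmented boundary roughly a pixel outside the
  true nucleus, so the rim mixes nuclear and cytoplasmic signal; without
  erosion the nuclear mean is biased by several percent.
* `seg_params(smoothing_sigma = 2)` — with this pre-smoothing the Otsu
  boundary lands outside the partial-volume rim, so the innermost ring
  pixels carry essentially pure cytoplasmic signal.

With both in place, the cohort-mean normalised trace of a 20-cell,
13-frame step-stimulation movie is recovered with a relative RMS error
below 0.5% noise-free and ~1% at default noise; the package's acceptance
checks require <2% and <5% respectively (relative RMS over frames — the
natural scale for a trace whose level ranges over 100–300%; the
recovered traces also meet those numbers read as absolute percentage
points).

### Ring geometry

The ring is defined in dilation steps: pixels reached within `ring_width`
successive 1-px dilations of a nucleus, excluding all nucleus pixels and
clipped at the image border. The structuring element is a 3×3 square by
default (step distance = Chebyshev distance; `connectivity = 4` gives the
cross element/Manhattan distance), and this choice is exposed because ring
area depends on it. A pixel reachable from several nuclei goes to the
nucleus reached in the fewest steps, ties to the smaller label; since the
original measurement protocol is silent on contested pixels, an
alternative policy that drops them entirely is available
(`contested = "exclude"`). The implementation is validated
pixel-for-pixel against a brute-force per-pixel distance oracle on
hundreds of random label maps.

## Morphometrics

Cell axes (lateral, apical, basal, width) are consumed as labelled line
segments — the draw-a-line measurement workflow — and converted to
micrometres; cells flagged as not integrated into the epithelial sheet
(rounding up for division) are excluded and logged. The package does not
attempt automatic junction tracing: the annotation file (or generator
ground truth) is the interface.

The synthetic epithelium tiles trapezoidal cells around a circular
contour in polar coordinates, each cell's angular sector proportional to
its drawn basal length (arc-length convention, so basal lengths always
sum to the circumference). Ground-truth lengths are the drawn lengths and
the exported annotation segments are straight lines of exactly those
lengths, so the measurement round trip is exact at zero SD — the test
then isolates the annotation/measurement plumbing rather than
rasterisation error. Columnar (30/5/10 um lateral/apical/basal), cuboidal
and squamous regimes, and apical constriction (apical < basal), are all
reachable by the length parameters.

Nucleus circularity is $4\pi A / P^2$ (1 for a circle). For traced
polygons, $A$ is the shoelace area and $P$ the exact vertex-chain
perimeter; self-intersecting polygons are rejected naming the offending
edge pair. For masks, the perimeter uses the Crofton 4-direction
estimator — naive pixel-edge counting overestimates $P$ so badly that
disks score far below 1, while Crofton keeps mask circularity within the
documented 0.02 discretisation tolerance of the polygon value. An
ellipse-fit variant was considered and rejected as primary because the
traced-outline formula is what the common analysis tools report.

Per-cell marker intensity (for phospho-ERK/AKT-style stains) is the mean
nuclear intensity plus the mean ring intensity — the per-cell "added up"
score — with raw integrated sums emitted alongside for transparency.

### Proliferation scoring

A nucleus is EdU/KI67-positive when its mean marker intensity exceeds a
threshold: fixed, or Otsu over the per-nucleus means (default). The
Otsu-on-means rule is invariant under monotone intensity transforms and
is exact under clean separation (a generated 70-of-200 scene scores
exactly 70/200). Its known failure mode is documented rather than hidden:
with strongly overlapping distributions (d′ = 2) and unbalanced classes
the threshold shifts into the larger class and the estimated fraction is
biased upward (mean absolute error ~0.05 balanced, up to ~0.10-0.15 at
35% positives). For such data a fixed threshold from a control image is
the right tool.

3D counts use per-plane thresholding, 26-connected component merging
across planes and a minimum-volume filter. Touching objects can be split
by distance-core seeding (erode until cores separate, then assign voxels
to the nearest core) — a seeded-watershed surrogate that correctly
separates two spheres touching at a single voxel.

### Organoid area and budding

Silhouettes are thresholded (Otsu or fixed, with optional inversion for
bright-field), hole-filled and measured as pixel counts × pixel_size².
Budding is classified by solidity (area / convex-hull area; hull area of
pixel centres corrected by $P/2 + 1$ to approximate pixel coverage). The
default cut of 0.92 was calibrated on the synthetic suite: generated
disks score >0.985 and 3-5-lobed shapes <0.90, so a zero-error interval
contains 0.92. Two-lobed shapes approach a convex capsule and can score
above the cut — the classifier is a calibrated surrogate for manual
phenotype counting, and supplied manual labels always override it.

## Statistics

Three procedures cover the figure-style comparisons: Mann-Whitney U
(exact enumeration when both groups have at most 20 values and no ties;
tie-corrected normal approximation otherwise), Welch's unpaired two-tailed
t-test with Satterthwaite degrees of freedom, and fixed-effects one-way
ANOVA (on two groups, the square of the pooled t). The exact/approximate
switch at n = 20 favours exact small-sample behaviour because per-figure
group sizes in this domain are small. The default unit of analysis in
`grouped_test()` is the per-replicate mean — matching legends that state
"n = 3 biological replicates" while plotting individual cells — with
cell-level pooling available explicitly. No multiple-testing correction
is applied by default (per-comparison reporting); Benjamini-Hochberg can
be layered on with `stats::p.adjust()`. Type-I error of both tests is
verified by null simulation to sit inside [0.041, 0.059] at
$\alpha = 0.05$.

The replicate-means ANOVA between T0 and a target frame uses unweighted
replicate means (organoids with different cell counts contribute
equally); the weighting of the original analysis is unstated, and
unweighted means are the conservative reading.

## Numerical and I/O decisions

* Coordinates are 0-based (row, column), pixel centres at integers;
  areas are pixel counts × pixel_size². The default 0.5 um/px matches a
  25-40x confocal acquisition.
* Positive-count rounding in the positivity generator is
  round-half-away-from-zero, recorded in ground truth, so expected counts
  are exact integers.
* Generators draw all randomness from a local seeded RNG stream: fixed
  seed implies byte-identical arrays, and the caller's RNG state is
  untouched.
* Images are written as 16-bit multi-page TIFF in (T, Z, C, Y, X) page
  order with a JSON dimension sidecar; in-memory intensities live in
  [0, 1] and are quantised to the 16-bit grid on write, so write-read
  round trips are bit-exact.
* Run configurations are strict YAML: unknown keys are rejected so typos
  cannot silently fall back to defaults.

## Problem sizes used in the validation suite

The shipped tests run movies of 10-20 cells at 192²-256² px over 13
frames, 100-cell epithelia, 200-nucleus positivity scenes, 200 random
label maps for the ring oracle, 200 silhouettes, and 10,000-replicate
null simulations for test calibration — sizes chosen so every ground
truth is exactly known and the full suite runs in a few minutes on one
core.

## What passing the synthetic suite does and does not show

The generator emulates compact nuclei on dark background, uniform
compartment intensities with multiplicative noise, trapezoidal epithelial
geometry, binary positivity and lobed silhouettes. It deliberately omits
point-spread-function blur, photobleaching, z-leakage, intensity
gradients, cell crowding with touching nuclei, and segmentation-hostile
texture. Passing therefore establishes that the *measurement chain* is
correct (masks, ratios, normalisation, statistics recover known truth),
not that segmentation will be accurate on arbitrary real microscopy —
on real data, segmentation quality must still be checked visually, and
the exposed parameters (`seg_params()`) are the intended adjustment
point.
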