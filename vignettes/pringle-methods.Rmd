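---
title: "Quantifying 3D patterning of cell identity in curved epithelia"
author: "pringle package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D patterning of cell identity in curved epithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pringle)
```

## The problem

Developing epithelia such as the posterior epiblast of the early embryo
are curved sheets of tightly packed cells in which cell identity --
read out as the nuclear levels of transcription factors like SOX2, TBXT
and TBX6 -- is patterned in space. Two kinds of questions arise from
segmented-nuclei data (one 3D centroid plus per-channel mean
fluorescence per nucleus):

* **Where is a cell?** Positions on a curved, variably sized sheet are
  not comparable across embryos until the sheet is flattened and
  registered to anatomical landmarks.
* **What surrounds a cell?** Graded patterns, salt-and-pepper
  (lateral-inhibition-like) patterns and random noise all produce the
  same marginal intensity histograms; they differ only in how a cell's
  level relates to its *neighbors'* levels.

`pringle` implements both halves: landmark-normalized 2D maps of curved
epithelia via principal curves (the PRINGLE projection), and a family
of neighborhood statistics (gradient steepness, local coefficient of
variation, log neighbor ratio against a per-niche synthetic null,
1D earth mover's distance, pseudospace gating, binned condition
comparisons) defined on a pruned 3D Delaunay neighbor graph.

## Data model

A `NucleiSet` extends `SummarizedExperiment` with channels as rows and
nuclei as columns. Centroids are stored in micrometers (`x`, `y`, `z`
in `colData`; z is the optical axis) because confocal voxels are
anisotropic and micrometers are the only safe common frame. The
`"raw"` assay holds mean fluorescence; normalization, smoothing and
every neighborhood statistic add further channel-by-nucleus assays
(`"nfi"`, `"smooth"`, `"cv"`, `"nr"`, `"nr_synthetic"`,
`"steepness"`, ...), so each metric stays aligned with its channel and
nucleus and survives CSV round trips (`writeNucleiTable` /
`readNucleiTable` are lossless at full double precision).

When data arrive as a 3D label image plus intensity stack,
`quantifyFromLabels` computes per-label centroids (unweighted mean of
voxel centers) and two intensity summaries: the nuclear mean and a
peri-nuclear ring mean. The ring -- the dilation of the label by a
ball of `ring_radius_um` minus the voxels of *all* labels -- estimates
cytoplasmic signal for transcript (HCR) stains that are excluded from
the nucleus. The ring thickness default is 1.5 micrometers, roughly a
third of a nuclear radius; it is a configuration choice because no
canonical value exists, and labels fully enclosed by other labels are
flagged rather than silently averaged.

## Normalization (NFI)

Raw intensities are made comparable across embryos as

$$\mathrm{NFI} = \frac{\mathrm{signal} - \mathrm{background}}
{\mathrm{p}_{99} - \mathrm{background}},$$

clipped to [0, 1]. The background is the highest peak of the signal
histogram -- in an embryo image the non-expressing population dominates
-- estimated as the mode of a Gaussian KDE with Silverman's bandwidth
so no histogram bin width has to be chosen; the maximum is the 99th
percentile, which is robust to hot pixels and staining debris. The cap
means values above p99 clip to 1. NFI is exactly invariant to affine
rescaling of the raw values, which the tests assert to 1e-9.

Two optional corrections precede NFI. *Bleed-through unmixing*
subtracts `c` times the source channel from the target (clipped at
zero); with `coefficient = "auto"` the coefficient is the Theil--Sen
slope of target versus source over source-positive/target-negative
nuclei (Otsu gates), the population whose apparent target signal is
pure bleed-through. Theil--Sen was chosen because the eligible
population is small and contaminated; the estimator tolerates up to
~29% outliers. *Depth-attenuation correction* fits an exponential
decay of background-subtracted intensity versus z on binned medians
and divides it out, anchored so the mean of the shallowest z-decile is
preserved. The additive offset subtracted before the log-linear fit is
the 1st percentile (a dark/camera offset that does not attenuate),
not the histogram mode: scattered-light attenuation acts
multiplicatively on the emitted signal, so subtracting a mid-signal
mode would bias the fitted decay. If the fitted trend is not a decay,
the correction falls back to per-z-bin quantile matching against the
shallowest bin, with a warning; both paths preserve the rank order of
nuclei at equal depth.

Positive/negative gating uses an inclusive threshold (`>=`); `"otsu"`
over the pooled replicates is offered as a reproducible stand-in for
manual gating.

## Neighbor graph and smoothing

Neighbors are the edges of the 3D Delaunay tetrahedralization of the
nuclei centroids, restricted to one tissue (only the epiblast is
triangulated for embryos) and computed per embryo. Delaunay
tetrahedralization of a shell-like tissue creates spurious edges that
span the internal cavity, so edges longer than 2.5 times the median
edge length are pruned; the factor is configurable and `Inf` disables
pruning. The triangulation itself is an incremental Bowyer--Watson
implementation in C++ (no R package in scope provides 3D Delaunay);
its edge set is tested against a brute-force empty-circumsphere
enumeration. Monolayer cultures use 2D Delaunay on (x, y); a
(near-)coplanar 3D input is detected and reported with a pointer to
monolayer mode.

Spatial smoothing replaces each nucleus's value by the mean over the
nucleus and its neighbors, synchronously for all nuclei, repeated 10
times by default. The synchronous (Jacobi-style) update makes the
result independent of nucleus order; including the cell in its own
average follows the definition of the smoothing kernel as the niche
mean. Smoothing commutes exactly with affine transforms of the field,
so smoothing NFI equals normalizing smoothed raw values.

## PRINGLE: projection and landmark alignment

Flattening proceeds in two principal-curve passes per embryo:

1. A **sagittal** curve is fitted in the (y, z) plane. Arc length
   along it is the anteroposterior coordinate `ap_um` (zeroed at the
   node, oriented so the primitive-streak tip is positive); the signed
   distance to it is a preliminary dorsoventral offset.
2. Nuclei are cut into overlapping **transverse slabs** along
   `ap_um`; per slab a principal curve is fitted in the
   (x, dv) plane and its arc length is the left--right coordinate
   `lr_um`. Slabs overlap by 50% and are stitched by matching the
   coordinates of shared nuclei; slabs with fewer than 10 nuclei merge
   into their neighbor.

The principal-curve fitter is the classical projection--smoothing
iteration: initialize with the first principal component, alternately
project points onto the polyline and smooth each coordinate against
arc length with `lowess`, stopping when the mean projection
displacement falls below 0.1 micrometers or after 50 iterations
(the best iterate is returned with a warning if unconverged).
Two span defaults matter and differ deliberately:

* sagittal span 0.7 -- the (y, z) cloud of a curved sheet is a thick
  band whose width comes from *lateral* curvature; a small span would
  let the curve wander inside the band and corrupt arc lengths. The
  sagittal pass should capture only the tissue-scale A--P bend.
* transverse span 0.2 -- each slab's cross-section is strongly curved
  (up to half a circle), so the smoother must be local to follow it.

Slab width defaults to five times the median nearest-neighbor spacing
(40 micrometers at the reference packing of 8). Sizing sections in
units of cell diameters rather than absolute micrometers makes the
projected map independent of embryo size, which is what allows maps
from embryos of very different absolute dimensions to be compared
after normalization; an absolute width can still be forced via
`slab_width_um`.

The **midline** is the mean left--right position of the nuclei at or
above the 90th percentile of spatially smoothed TBXT, and `lr_um` is
re-zeroed there; the detector is exactly translation-equivariant and
errors out below 20 marker-high nuclei rather than guessing.
**Landmark normalization** then sets `ap_rel` = 0 at the node and 1 at
the posterior streak tip (anterior nuclei keep negative values; they
are biology, not outliers), and `lr_rel` = `lr_um` divided by the
epiblast half-width at that AP position. The half-width ("edge of the
epiblast") is the 97.5th percentile of |lr| among epiblast nuclei per
AP bin of 0.1 relative units -- a robust maximum that ignores straggler
nuclei -- interpolated linearly between bin centers so that nuclei
near bin boundaries do not jump. Because purely relative widths
distort distances, `lr_scaled` multiplies `lr_rel` by the
across-embryo mean half-width at that AP position, giving a common
frame in micrometer-like units. Multi-embryo maps (`binnedMap`)
average per-embryo maps rather than pooling nuclei, so a large embryo
cannot dominate; folding at the midline (`foldAtMidline`) is
idempotent and records the original side.

On developable test surfaces the projection is accurate to well under
2% RMS of the analytic unrolled coordinates (half-cylinder of radius
100) and under 5% RMS against graph-geodesic distances on a saddle
surface; the acceptance script recomputes both.

## Neighborhood statistics

All statistics are defined on the *niche*: a nucleus together with its
graph neighbors.

* **Local CV** = population standard deviation of the niche's NFI over
  its mean. Population (divide by niche size) rather than sample SD is
  the default because the niche is the entire population of interest,
  not a sample from one; both conventions are available and tested.
  CV uses *unsmoothed* NFI -- smoothing would average away precisely
  the heterogeneity being measured.
* **Neighbor ratio (NR)** = ln(cell / mean of neighbors). The log
  makes the cell and neighborhood contribute symmetrically
  (ln(x/y) = ln x − ln y), so "high cell in low niche" and "low cell
  in high niche" score with opposite signs and equal magnitude. A
  floor of 1e-3 (on the NFI scale) is added to numerator and
  denominator because the ratio is undefined at zero expression; any
  analysis on another intensity scale should scale the floor
  accordingly (the functions accept an `assay` argument and the
  calibration analyses below run on the raw scale, where a floor of
  0.1 plays the same role).
* **Synthetic-null NR**: for each niche, the cell and each neighbor
  are redrawn i.i.d. from a normal with the niche's observed mean and
  population SD, clipped at zero (intensities are nonnegative), and NR
  is recomputed on the redrawn niche. This is the "what if the same
  local statistics were arranged at random" reference. The draw is
  fully reproducible from a seed, and a zero-variance niche
  degenerates to NR = 0 exactly.
* **Gradient**: unit vectors to the neighbors scaled by the change in
  smoothed value and averaged give a directional vector b. On an
  irregular mesh b is not the gradient but M g, with
  M = mean(|d| u uᵀ) the neighborhood direction metric; the default
  estimator solves for g with the pseudo-inverse of M restricted to
  the subspace the neighbors span (exact on linear fields; on a
  monolayer the out-of-sheet component is suppressed instead of being
  amplified by near-singular geometry). The uncorrected
  degree-normalized vector sum is available as
  `method = "vectorsum"`; its magnitude is biased by neighbor
  anisotropy, which is measurable on synthetic linear fields (about
  80% of nuclei within 10 degrees of truth, versus >99% for the
  corrected estimator). Steepness is the gradient magnitude and is
  exactly zero on constant fields.
* **1D EMD** (`emd1d`): Wasserstein-1 between empirical distributions,
  the integral of |CDF difference|. `normalize = TRUE` jointly min-max
  rescales both samples to [0, 1] first, making the distance a
  scale-free fraction of the pooled range; the default is the plain
  distance in the samples' own units.

### Detecting non-random arrangement

Whether a marker is arranged non-randomly (e.g., lateral inhibition)
is asked by comparing observed NR to the synthetic null. Two practical
facts shape the test:

1. The null has small deterministic biases of order 1/k for a niche of
   k cells (the population SD underestimates the generating sigma; the
   cell belongs to its own niche), so a plain ANOVA on embryo means of
   gated cells -- whose standard error shrinks as cell numbers grow --
   eventually "detects" the null's own granularity.
2. The null generates *normal* values; a pattern whose marginal is far
   from normal (e.g., strictly binary) differs from the null in shape
   even when spatially random.

`nrShiftTest` therefore compares, per embryo, the EMD between observed
NR and one null draw against a reference EMD between two further
independent null draws, and runs the ANOVA across embryos on those two
EMD sets. The observed pattern is flagged only when it deviates from
the null by more than the null fluctuates around itself. On i.i.d.
normal fields the test is calibrated (uniform p; the acceptance script
measures ~2--5% at the 0.05 level), while sequential-inhibition spot
patterns (fraction 0.1, contrast 3:1, four pseudo-embryos of 750
nuclei) are detected in effectively 100% of runs. The matched
random-pattern arm uses an i.i.d. normal field: a spatially random
*binary* pattern violates the null's normality assumption by
construction and is deliberately not presented as a calibration case.

`nrProfile` summarizes observed and synthetic NR along pseudospace (or
AP) bins with the embryo as the experimental unit: per-embryo means,
the across-embryo mean with a 1.96·SE band, mean per-embryo EMD, and a
one-way ANOVA between observed and synthetic embryo means per bin.
`boundaryProfile` estimates expression-domain edges per AP bin as the
5th/95th percentiles of the positive nuclei's |lr| (robust against
stray positives, slightly inset relative to the true edges by 5% of
the domain width), computes left and right profiles separately per
embryo and averages them.

## Pseudospace

The cell-state axis is built from log(smoothed value + pseudocount)
across at least three channels: PCA to two components, a principal
curve through the PC1--PC2 cloud, and the normalized arc-length
position of each nucleus's projection, oriented so the anchor
channel's high extreme (SOX2 for the neural end) maps to 0. The
pseudocount default is 0.01 on the NFI scale (10 on a raw scale of
hundreds); PC signs follow a fixed convention (PC1 positively
correlated with the anchor) so the fit is deterministic. A fitted
model transfers to other embryos via `applyPseudospace`, which
projects onto the stored axes and curve -- this is what makes gates
comparable across stages and conditions. This axis orders cell
states; it makes no claim about time.

`gateROI` fits (low, high) pseudospace gates by exhaustively scanning
a 0.01-resolution grid for the pair maximizing the Jaccard index
between the gated set and the nuclei inside user-supplied reference
rectangles in aligned coordinates (e.g., node-width boxes over the
bi-fated regions); ties resolve to the lowest gate pair, the scan is
deterministic, and the reported Jaccard is the grid maximum (asserted
against a brute-force scan in the tests). Under coordinate noise that
flips ~20% of the reference labels, gates are recovered within 0.03.

## Spatial bins and condition comparisons

`kmeansBins` partitions the folded aligned map into regions of
approximately `target_size` (default 100) cells by k-means on
(ap_rel, lr_scaled), pooled over conditions so all conditions share
regions. The two axes are range-normalized before clustering --
ap_rel is unitless while lr_scaled is in micrometers, and without
normalization the bins would stripe along one axis. k-means runs 10
restarts with a fixed seed, so assignments are reproducible.

`binConditionTest` averages the metric per embryo within each bin and
runs a one-way ANOVA across conditions on the embryo means. The
embryo, never the nucleus, is the experimental unit: nuclei within an
embryo are correlated, and treating them as independent would inflate
significance (pseudoreplication). Benjamini--Hochberg adjustment runs
across the testable bins, and both raw and adjusted values are
reported. Bins missing a condition or with fewer than 2 embryos per
condition are excluded from the family. The false-positive rate is
validated at 5% over 200 null simulations, and a 3-sigma shift
confined to a spatial quadrant is recovered with q < 0.05 inside and
few detections outside. `superplotStats` applies the same
embryo-as-unit logic to channel comparisons: per-embryo means,
1.96·SE intervals, pairwise paired t-tests with BH adjustment,
tests suppressed below 3 embryos, and exact-constant paired
differences reported as a degenerate flag (p = 1 for zero difference,
p = 0 otherwise) rather than an error.

## Epiblast classification

For large embryos where manual tissue labeling is impractical,
`computeFeatures` computes per nucleus: the count of other nuclei
within a 15-micrometer sphere (local density; the radius is a
configuration choice), the NFI channels, and the distance below a
dorsal surface. The surface interpolates through the actual XYZ
positions of the dorsal-most nucleus of each 20x20 micrometer lateral
bin (a degree-1 local-regression surface); interpolating positions
rather than bin-center maxima removes the within-bin curvature bias,
leaving only the upward offset from picking the dorsal-most (top of
the jitter) cell, about 1.5 micrometers. Features are deliberately not
z-scored. `classifyEpiblast` k-means-clusters nuclei into
micro-clusters of ~5 cells in feature space, averages features per
cluster, trains a random forest on the clusters containing labeled
nuclei (majority label), reports stratified 5-fold held-out accuracy
over the labeled clusters, and propagates predictions to member
nuclei. On the bilayer fixture (gently undulating sheet with a second
layer 15 micrometers beneath) held-out accuracy is at ceiling.
`postprocessLabels` then iteratively converts any non-epiblast nucleus
with strictly more than 50% epiblast neighbors, flipping
simultaneously per round; the rule is one-directional, so the epiblast
set grows monotonically and convergence within |V| rounds is
guaranteed.

## The synthetic-embryo generator

`syntheticSpec`/`generateEmbryo` define the study conditions for every
test: nuclei Poisson-disk sampled (minimum spacing 8 micrometers,
mimicking nuclear exclusion volumes) on a flat sheet, a cylindrical
section (the idealized curved epiblast, with exact unrolled
coordinates as ground truth), a saddle, or an ellipsoid cap; patterns
painted in surface coordinates (graded, midline ridge, M-shape,
Gaussian bump, stripe with optional linear narrowing,
sequential-inhibition spots that are never adjacent on the
ground-truth graph, random spots, i.i.d. normal, and a three-channel
trajectory driven by a shared latent state); an optional deep layer at
a normal offset; then acquisition artifacts -- 3D jitter (SD 1
micrometer), Gaussian noise (SD 5% of the dynamic range), linear
bleed-through, exponential depth decay -- applied to produce raw
values. Ground-truth columns (true surface coordinates, true pattern
values, spot flags, latent state, layer) ride along in `colData`, and
identical spec + seed is bit-identical.

What the generator does *not* emulate: segmentation errors (merged or
split nuclei), non-Gaussian shot noise, spatially structured staining
artifacts, mitotic/apoptotic intensity outliers, or tissue-scale
shape variability beyond uniform scale. Green tests therefore
demonstrate correctness of the algorithms under clean, known-truth
conditions, not robustness to every real-world failure mode.

A note on fixtures and normalization: the KDE-mode background
estimator presumes a background-dominated histogram, which real
images have but some synthetic patterns (pure gradients, i.i.d.
fields) do not -- there the mode sits mid-signal and NFI clips part
of the field to 0. Analyses validating the *neighborhood* machinery
(null calibration, detection power, gradient recovery) therefore run
on the generator's raw scale via the `assay` argument, with the NR
floor scaled accordingly; analyses validating *normalization* use
fixtures with a genuine background population.

## Problem sizes

The validation suite runs at desk scale on one CPU: 2000-nucleus
cylinder and 1500-nucleus saddle fixtures for projection; two
900-nucleus embryos for scale-invariant alignment; 20 embryos of 500
nuclei for null calibration plus 200 value simulations on a fixed
6-embryo layout for the false-positive rate; 100 seeds of
4x750-nucleus pseudo-embryo sets per arm for detection power; five
1200-nucleus fields for gradient recovery; a 1500-nucleus trajectory
fixture with 20 noise replicates for gating; an 1800-nucleus bilayer
for classification; three 1800-nucleus stripe embryos for boundary
profiles; and a 4-embryos-x-2-conditions pipeline run. Together with
unit tests this completes in roughly ten minutes.

## Known limitations

* The projection assumes the tissue is a single-valued sheet around
  its sagittal spine; fully closed surfaces (vesicles) are out of
  scope, as is pixel-space flattening.
* Arc-length fidelity degrades where the local-regression span cannot
  follow curvature (radius approaching the nuclear spacing).
* The synthetic null inherits the normality assumption of the
  original construction; its comparison is calibrated by the
  double-draw reference in `nrShiftTest`, not by the raw ANOVA.
* Depth correction models a single exponential plus a constant
  offset; layered refractive-index changes violating monotonicity are
  only handled by the quantile-matching fallback.
* `correctDepthAttenuation` and `computeNFI` are per-embryo;
  slide-level batch effects across embryos are assumed to be removed
  by NFI itself.
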