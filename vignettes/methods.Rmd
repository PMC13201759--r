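---
title: "Linking MALDI-MSI pixel grids to IMC single cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking MALDI-MSI pixel grids to IMC single cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msimclink)
```

## The problem

MALDI mass spectrometry imaging (MSI) measures hundreds of analytes —
glycans, lipids, metabolites — but at a 10–100 µm pixel pitch, far above
single-cell resolution. Imaging mass cytometry (IMC) resolves individual
cells (1 µm pixels, up to ~40 antibody channels) but cannot see
untaggable molecules. Combining the two requires registering an MSI
pixel grid onto IMC cell segmentations through whatever images the two
instruments leave behind: brightfield slide scans taken before and after
each acquisition (PreMSI, PostMSI, PreIMC, PostIMC).

`msimclink` implements that chain end to end: MSI spectrum
preprocessing, IMC pixel/cell cleanup, automatic detection of the MSI
ablation-mark grid on the PostMSI scan, grid-to-marks registration,
intensity-based registration of the microscopy chain, registration
quality control, exact cell-to-pixel polygon overlap, and spatial
statistical models of analyte–cell-type association. A synthetic-tissue
simulator generates ground truth for every stage; all tests run on
simulated data.

## Coordinate conventions

All geometry is in micrometres, y-down, origin at the slide-scan
top-left. The centre of raster pixel `(row, col)` sits at
`((col - 0.5) px, (row - 0.5) px)`. Transforms map *moving*-frame
coordinates onto the *fixed* frame and compose left-to-right through
`compose_chain()`; images are resampled once through the composed map
(points exactly, intensities bilinear, label masks nearest-neighbour).
The registration chain is
`MSI -> PostMSI <- PreMSI <- PreIMC <- PostIMC <- IMC`; in single-slice
experiments the PreIMC-to-PreMSI link drops out and the chain still
type-checks.

## MSI preprocessing

Spectra are TIC-normalized, recalibrated against a reference peak list,
binned at the reference m/z values, and log2-transformed.

* **TIC target.** "Normalize by total ion current" leaves the target
  constant open. We rescale each spectrum so its total equals the mean
  pre-normalization total over non-empty spectra: intensities keep
  their original order of magnitude and the operation is idempotent.
  Zero-total spectra pass through flagged.
* **Recalibration model.** A single additive m/z shift per spectrum
  (default) fitted to the local maxima that fall within 0.2 Da of a
  reference; a piecewise-linear warp is available for wider axes. Peaks
  outside the window never influence the fit.
* **Binning.** Channel value = maximum intensity in `[ref − tol,
  ref + tol]` ("peak height"). An empty window is *missing* (`NA`),
  never zero: missing pixels are excluded from model fits downstream,
  which matters because detection power tracks the number of
  non-missing pixels.
* **Log transform.** `log2(x + 1)`; the one-count pseudocount keeps
  zeros at zero.

## IMC cleanup

Hot pixels (more than 50 counts above their 8-neighbour maximum) are
clamped to that local threshold. The documented pixel denoising rule —
zero every value *above* a threshold of 1.5 — is implemented verbatim as
the default (`mode = "as-stated"`); it is appropriate for
probability-like channels where high values flag artefacts. Because the
rule looks inverted for count channels, `mode = "clip"` caps at the
threshold instead. Cell tables carry pixel-count areas, pixel-centre
centroids and per-marker means; marker intensities are
arcsinh-transformed (cofactor 1). Cells are removed when smaller than
10 pixels, touching the image border, silent in every cell-type marker,
or above `median + 5·MAD` (MAD unscaled) in any cell-type marker; a
removal count per rule is attached so filters stay auditable.

## Ablation-mark detection and grid matching

Marks are enhanced on the polarity image (darkness, for brightfield) by
a median filter (square kernel), a rank-threshold filter (pixel minus
the k-th local rank in a disk, clamped at zero — a rank-robust top-hat
that removes slowly varying background), and a cross-kernel mean, then
blended with the raw polarity image as `w·processed + (1 − w)·raw`.
Thresholded components are filtered by size, shape (eccentricity) and a
regular-grid neighbour graph (edges within `[0.5, 1.5]`× pitch along the
estimated grid axes; small subgraphs dropped). Centroids are
score-weighted, which is what makes sub-micron localisation possible on
anti-aliased marks. A `(w, t)` grid search scores each setting by
`n̂ + 4ê + 2d̂` (normalized counts of detections, detections at the
tissue edge, and mean distance to the tissue edge), ties broken to the
smallest `(w, t)` so the search is deterministic. The distance term is
added, following the documented score; the sign is exposed should a
deployment want to flip it.

Grid matching then proceeds: a coarse exhaustive rigid search scored by
in-mask proportion plus normalized match count minus normalized
density-weighted distance; concave hulls of both point sets; angle
windows along the hull boundary as identifiers; identifier matching;
coherent point drift (CPD) on the matched boundary points; and a final
mutual-nearest-neighbour pixel-to-mark assignment within half a pitch,
whose residuals feed QC.

Three design points deserve a note:

* **Boundary rule.** Boundary membership uses *any missing 8-neighbour*
  rather than "fewer than 4 axis neighbours": the reflex corner of a
  notch keeps all four axis neighbours but must appear on the hull for
  the characteristic 270° turns to exist. The hull walk prefers
  single-pitch steps and uses diagonals only to bridge gaps. Interior
  angles are quantized to 45° steps in the grid frame.
* **Identifier uniqueness is local.** Identifiers are compared only
  between points within `max_dist` of each other after the coarse
  transform, and uniqueness is enforced within that gated candidate
  set. Global uniqueness is impossible on symmetric grids (all four
  corners of a full rectangle share every window length).
* **CPD.** Our EM implementation (Gaussian mixture, isotropic variance,
  uniform outlier component, ω = 0.1, tolerance 1e-8, ≤300 iterations)
  normalizes both point sets with one similarity map before iterating —
  without it the outlier constant is scale-sensitive — and uses the
  full quadratic-form variance update in the fixed-scale rigid model
  (the usual optimal-scale shortcut is only valid when the scale is
  estimated). Rigid is the default for grid matching because the MSI
  pitch fixes the physical scale.

## Microscopy chain registration

`register_affine()` is a multi-resolution (3-level) maximization of the
normalized correlation between the fixed image and the resampled moving
image, on a deterministic sample stride (no RNG in the metric). The
coarsest level is initialized by a small rotation sweep with an FFT
cross-correlation translation estimate per angle, which makes ±10° and
±50 µm recoverable; Nelder-Mead then refines (rotation, log-scales,
shear, translation). If the metric cannot beat the identity the
identity is returned with a warning. `register_bspline()` refines an
affine initialization with a cubic B-spline free-form deformation
(control grid in physical units, default bending-energy weight 1e-2
made dimensionless by the control spacing), minimized by L-BFGS with an
analytic gradient over the same 3-level pyramid; folds (negative
Jacobians) are flagged. Internally the deformation is estimated in the
resampling direction (fixed to moving); mapping points the other way
inverts the field by damped fixed-point iteration to 0.01 µm.

The IMC footprint is registered into the PostIMC scan by detecting the
desaturated ablation square (Otsu on the HSV saturation channel,
closing radius 5 µm, component compatible with the known acquisition
area), building inverse-distance images (zero off the mask, maximal at
the boundary), and estimating an Euler transform; a CPD refinement on
regularly spaced boundary points is accepted only when it clearly
tightens the boundary distance, since at sub-pixel residuals it can
chase boundary pixelation instead of pose. A manual mode fits the IMC
rectangle into a user ROI polygon in closed form
(centroid + principal axis).

## Registration QC

The median landmark distance (MLD) is the median of paired landmark
distances (mean of the two central order statistics for even counts);
DICE is `2|S∩T|/(|S|+|T|)`, defined as 1 for two empty masks. Reports
based on fewer than 100 landmark pairs are flagged `excluded`.

Automatic landmarks use a difference-of-Gaussians scale-space detector
with per-tile caps, sub-pixel quadratic refinement, and z-scored patch
descriptors. We chose a classical linear scale space over a nonlinear
(KAZE-style) one: on brightfield slide textures the two localize
equivalently, and the linear version is exactly reproducible with the
installed image stack. Matching applies, in order, a 50 µm physical
gate (the images are already registered; true pairs are close), the
0.8 nearest/second-nearest descriptor ratio test, one-to-one selection
by descriptor distance, a 10 µm same-image spacing rule, and robust
affine inlier selection — RANSAC with progressive quality-ordered
sampling and threshold-marginalized scoring, a deterministic seeded
procedure.

Because ablation marks superimpose a periodic pattern on PostMSI scans,
`suppress_grid_artifact()` removes frequency-domain peaks: locations
where magnitude minus a local-mean threshold exceeds its 99% quantile
*and* stands well above the local level (3×) are masked (never the DC
region), the mask is median-cleaned and dilated, and masked magnitudes
are replaced by the local mean before inverting with the original
phase. The peakiness condition is what keeps smooth aperiodic spectra
untouched (correlation with the input ≥ 0.99 in our tests) while the
planted grid component loses over 90% of its amplitude.

Region-level checks pair segmented tissue structures between modalities
by the summed absolute difference of the seven Hu invariant moments,
gated by area window (36² to 512² µm²), area ratio (< 1.5×), centroid
distance (≤ 50 µm) and overlap (DICE > 0). Nuclei-level checks pair
overlapping labels one-to-one by maximum overlap and report centroid
MLD and the DICE of the paired union.

## Integration: exact polygon overlap

Cell masks are traced along pixel boundaries into polygons (holes kept
as opposite-orientation rings), vertices mapped pointwise through the
transform chain — exact for points, so areas are exactly preserved
under rigid maps — and clipped against each MSI pixel square
(Sutherland–Hodgman against an axis-aligned rectangle, signed shoelace
areas). This is exact arithmetic for this geometry: total intersected
area equals the cell area clipped to the measured region to 1e-6 µm².
MSI pixels are squares of the ablation spot side centred on grid
positions spaced one pitch apart; the spot may be smaller than the
pitch (e.g. 24 µm spots on a 30 µm raster), leaving unmeasured gaps.
Per pixel we derive the design row of the association model: area
fraction per cell type, cell count, and filled fraction; unlabelled
cells contribute to fill but to no type column, and the model intercept
absorbs uncovered area.

## Association models

For one sample and one m/z channel the pixel model is the spatial lag
(simultaneous autoregressive) regression

  y = ρ W y + X β + ε,  ε ~ N(0, σ² I)

with y the (normalized, possibly log2) pixel intensities, W the
row-standardized neighbour matrix (queen adjacency by default; isolated
pixels keep zero rows and act as non-spatial observations), X the
per-type area fractions with intercept (or per-pixel mean IMC channel),
and ρ the strength of spatial dependence. We fit by maximum likelihood:
the likelihood is concentrated in ρ via the eigenvalue expansion of
log|I − ρW|, optimized over the admissible interval, with GLS-type β̂
and asymptotic standard errors from the full (β, ρ, σ²) information
matrix. The fit agrees with a dense brute-force oracle (direct
log-determinant, ρ grid at 1e-4) to 1e-4 in ρ and 1e-5 relative in β;
with W = 0 it reduces exactly to OLS. `tidy()` and `glance()` methods
expose the result in the usual model-tidying shape.

The second stage regresses the per-sample β̂ for each channel on sample
metadata with inverse-variance weights 1/SE(β̂)²; with repeated samples
per patient a random intercept is added (falling back to weighted least
squares, with a warning, when every patient is a singleton). Variances
are floored at 1e-8 so a zero-variance input is down-weighted rather
than infinite. P-values are Wald tests; FDR across channels is
Benjamini–Hochberg (the specific procedure is our choice; only "FDR
corrected" is documented upstream).

Two aggregate alternatives are included. The compositional model turns
per-sample cell-type proportions into pivot (isometric log-ratio)
coordinates, placing each type first in turn and fitting least squares
with non-compositional covariates; each type's own first-coordinate
estimate is reported, and the orthogonality of the rotations makes it
invariant to the order of the remaining parts. Zeros are replaced by
half the smallest positive proportion before closure; always-zero types
are excluded with a message. The domain path assigns each cell a tissue
domain from two antagonist markers (40 µm Gaussian-weighted
neighbourhood intensity with σ = radius/2, each marker scaled by its
0.99 quantile, argmax label, then iterative majority smoothing, ≤10
sweeps; ties go to the first marker and are flagged), propagates
domains to pixels by majority vote (count ties to the nearest cell
centroid; empty pixels inherit the nearest labelled pixel), and tests
per-m/z sample-domain pseudobulk means with a linear model
`value ~ domain + covariates`, dropping single-level covariates, BH
across m/z.

## The simulator

The generator reproduces the reference study conditions and doubles as
the fixture engine for the registration stages.

* A Gaussian random field (exponential covariance, length scale 150 µm
  by default, circulant-embedding sampler with generous padding so
  eigenvalue clipping is negligible) is min-max scaled to [0, 1] over a
  1000 × 1000 µm field.
* A multitype point pattern with simple sequential inhibition places
  exact per-type counts; the inhibition distance is the 0.975 quantile
  of cell radii `sqrt(area/π)`. Type 1 samples with intensity equal to
  the field, all other types with its complement, creating two
  spatially segregated populations.
* Cell areas are negative binomial shifted to ≥ 1 µm² (mean 80 µm²,
  dispersion 2 — stand-ins at realistic scales, since the upstream fit
  to real areas is unpublished; both are configuration knobs). Analyte
  rates per µm² are log-normal per type; the defaults separate the
  types by factors of e so associations are detectable but noisy.
* An MSI grid (default 30 µm pitch, 24 µm spots; 10/20 µm pitches and
  8–30 µm spots supported) aggregates `rate × exact disc-square overlap
  area` into y and per-type overlap fractions into X. A registration
  error is emulated by translating the covariate grid in x by 0, 1, 5
  or 10 µm — y never moves, exactly as a misregistration decouples the
  modalities. Imprecise areas are emulated by randomly reshuffling
  areas (extreme) or reversing rank order within 4 quantile bins
  (mild); the observed-area column affects X only. Adding/removing
  cells is deliberately not implemented.
* Three error terms corrupt y in order: neighbour-mean smoothing with
  weight λ (0.1), additive log-normal noise, and an additive correlated
  GRF error scaled to [0, 500].

Every output is bit-identical given `(config, seed)`. The PostMSI
renderer draws dark discs with exact per-pixel coverage (so rendered
centroids equal the intended ones) over a textured background and
returns the ground-truth centroid list and rigid transform.

What the simulator does *not* emulate: irregular real mark shapes,
staining/matrix appearance differences between the Pre/Post scans,
tissue deformation between adjacent slices beyond what the b-spline
tests construct, and multi-core TMA layouts. Passing tests therefore
demonstrate correctness of the algorithms under controlled geometry and
noise, not robustness to every histological artefact; the QC metrics
(MLD, DICE, landmark counts) are the instrument for judging real data.

## Problem sizes and numerical choices

The test-suite and reproduction-script problem sizes are deliberate
package choices: 10 × 10 to 20 × 20 MSI grids for detection and
matching fixtures; 240 × 240 px textured slides (2 µm pixels) over 50
seeds for affine recovery; a 200 × 200 px slide with a 10 µm sinusoidal
warp for the b-spline check; 500 × 500 µm fields with 180 cells and a
16 × 16 pixel grid, 100 replicates, for the attenuation study; 20 × 20
grids and 100 simulations for SAR coverage. These sizes put every
stochastic check well inside its Monte-Carlo tolerance while keeping a
full run comfortably on a laptop.

Numerical details worth knowing: the SAR ρ interval is bounded away
from the eigenvalue reciprocals by 1e-6 and boundary solutions error
out rather than silently truncating; the b-spline bending penalty is
divided by the control spacing squared so the default weight is
meaningful across resolutions; CPD convergence is relative with an
absolute floor for exact matches; detection ties in the parameter grid
search and all RANSAC sampling are deterministic; empty bins stay `NA`
end to end and are dropped (never imputed) before fitting.

## Known limitations

Multi-region stitched MSI acquisitions with mixed pitches, >2-slice
chains, GPU registration, stain normalization and 3-D overlap across
slice thickness are out of scope. The b-spline inverse is iterative and
assumes a diffeomorphic field (folds are flagged, not repaired). The
identifier-window convention cannot reproduce asymmetric
neighbour-count examples exactly (window length is configurable). The
compositional model assumes strictly positive proportions after zero
replacement and inherits the usual sensitivity of log-ratio methods to
the replacement rule.
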