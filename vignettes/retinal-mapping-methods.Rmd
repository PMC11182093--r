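---
title: "Methods: multimodal retinal mapping and mosaic quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal retinal mapping and mosaic quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retmap)
```

retmap turns multimodal retinal imaging sessions — adaptive-optics
scanning light ophthalmoscope (AOSLO) videos, en-face fundus images and
OCT volumes — into quantitative, micrometre-scale measurements of the
photoreceptor and RPE mosaics and of retinal layer thickness, compared
against normative data. This vignette documents the models behind each
stage, the tunable parameters, the numerical choices, and what the
phantom-based validation does and does not establish.

## Retinal magnification: from biometry to micrometres

Every lateral measurement depends on the retinal magnification factor
(RMF), the millimetres of retina subtended by one degree of visual
angle. retmap computes it from ocular biometry with a paraxial
four-surface schematic eye: the Le Grand full theoretical eye (four
refracting surfaces with standard radii, separations and indices)
individualised by the measured axial length, and by any other measured
anterior-segment parameter the user supplies. The trace propagates a
paraxial ray through the surfaces with the scalar refraction/transfer
recurrences, derives the equivalent power and the second nodal point,
and sets

RMF = (axial length − nodal point position) × π/180 [mm/deg].

The surface set is a deliberate, documented default: individual
biometry rarely includes lens radii, and the standard schematic values
are the accepted substitute. Bennett's reduced-eye closed form,
RMF = 0.01306 × (AL − 1.82), is provided as a cross-check mode
(`model = "reduced"`); for an axial length of 24.46 mm it gives
0.29568 mm/deg, and the four-surface Le Grand eye gives 0.2912 mm/deg
at its native 24.197 mm length, with a total power of 59.94 D.

When images are acquired through a corrective contact lens, lateral
magnification changes. The correction implemented is the paraxial
ratio of equivalent powers, bare eye over eye-plus-lens, with the thin
lens placed at a configurable distance in front of the cornea
(default 0 mm, i.e. a contact lens on the cornea). A zero-power lens is
exactly the identity; plus and minus lenses move the factor to
opposite sides of 1. The published correction this stands in for is
cited, not printed, in the clinical literature, so the package states
its formula explicitly and validates it against an independent
two-element ray-transfer-matrix oracle rather than against a table.

Pixel scale follows as `um/px = RMF × 1000 × field-of-view / pixels`,
per axis; anisotropic scales are allowed because desinusoiding changes
the fast-axis sampling.

## Desinusoiding

A resonant scanner sweeps the fast axis sinusoidally, so equally
spaced recorded pixels correspond to unequally spaced retinal
positions. The calibration image is a Ronchi ruling (a regular grid of
vertical lines of known period). Line centres are detected on the
column-mean profile by matched-filter NCC against a Gaussian line
template with parabolic sub-pixel refinement, gated on amplitude
(NCC alone is scale invariant and would accept interpolation ripples).
The detected centres are fitted to the arcsine position model

u(c) = A·sin(B·(c − c0) + φ) + d,

with `u` the true grid coordinate in line periods and `c` the recorded
column. For a fixed frequency `B` the model is linear in the remaining
parameters, so the fit is a one-dimensional search over `B` with a
linear least-squares solve inside — no starting guesses, no
convergence tuning. The fitted model is inverted onto a uniform grid
of `u` values to give a strictly increasing look-up table of
fractional source columns; monotonicity is asserted on every fit.
Resampling uses Keys cubic convolution (a = −0.5) by default, with
linear interpolation as the configurable fallback; output width equals
input width, and the pixel scale is recomputed accordingly. An exact
integer mapping copies columns bit-exactly, and the docs note that
applying a LUT twice is not the same as applying it once (resampling
composes). The open question of whether the original instrument
resampled to equal angular or equal retinal spacing is resolved here
as equal angular spacing, converted to retinal micrometres through the
RMF afterwards.

## Strip registration and frame averaging

Fixational eye motion displaces each scan line. Frames are first
ranked by whole-frame zero-mean normalised cross-correlation (NCC)
against a manually selected reference (an automatic
maximum-mean-correlation mode exists but is off by default, mirroring
practice); a constant frame has undefined correlation and is flagged
with a −∞ score. Each selected frame is then divided into horizontal
strips (default height 32 px, 50% overlap — a balance between motion
bandwidth and NCC stability), and each strip's translation is the peak
of its NCC surface over a bounded search (default ±12 px), refined to
sub-pixel precision by parabolic interpolation, except when the peak is
numerically perfect, in which case the integer peak is kept (refinement
could only add interpolation noise to an exact alignment).

Three acceptance rules make the estimates trustworthy: strips live in
an interior margin trimmed by the search radius on every side, so any
true displacement within the radius has full support inside the
reference; peaks on the border of the search surface are rejected (the
true shift may lie outside); and a peak must be prominent — at least
0.1 above the best value outside its 5×5 neighbourhood — because a
strip with no true match produces several comparable random peaks.
Below a peak NCC of 0.5 (default) a strip is rejected, which is what
handles blink and tear-film dropout; a frame with no accepted strips
is flagged unusable.

Averaging shifts each accepted strip by the negative of its offset
(bilinear interpolation for fractional shifts, direct indexing for
integer ones) and accumulates a per-pixel mean with a coverage map;
uncovered pixels are NA, never zero-filled silently. The NCC surface
itself is computed exactly — FFT numerator with integral-image
normalisation — and is verified in the tests against a direct
Pearson-correlation evaluation.

## Montage and the common micrometre frame

Tiles are placed initially from their fixation-target coordinates
(degrees × RMF), then refined pairwise: a breadth-first traversal of
the tile overlap graph from the first tile, each tile NCC-matched
against an already placed neighbour over a bounded search. A tile
whose overlap supports no prominent peak keeps its fixation placement
and is flagged rather than guessed. The canvas grid is anchored on the
first tile's pixel grid so integer placements copy pixels without
interpolation blur, and overlaps are blended by linear
distance-to-edge feathering, which avoids seams without inventing
detail.

Cross-modality alignment uses landmark pairs (vessel bifurcations, the
optic disc). Points are mapped into micrometres first — so the
transform only absorbs residual rotation, translation and a small
scale — and fitted in closed form: similarity transforms via complex
linear regression (which cannot produce reflections), affine via
normal equations when anisotropic en-face sampling demands it. The
default is similarity, since RMF scaling has already removed scale
differences; both are supported because the original choice is not
documented. Collinear or coincident landmarks are rejected.

The anatomical foveal centre is marked once (clinically: on the OCT
scan) and stored in the common frame; every other layer's position
follows through the transforms. Eccentricity is Euclidean distance
from the fovea (mm, and degrees through the RMF), labelled by
90-degree angular sector. One design point was genuinely open: the
sign convention for nasal/temporal. retmap defaults to standard
fundus orientation, where the horizontal labels depend on laterality
(+x is nasal for a right eye, temporal for a left eye), because that
is what unflipped clinical images show; an import-time `flipped` flag
restores the "+x temporal for both eyes" analysis convention. The
laterality-aware default is what makes a right and a left eye at the
same common-frame point report opposite horizontal meridians.

Pixel coordinates are (x, y) = (column, row), pixel-centre, 1-based
inside R; serialized transforms state a 0-based convention explicitly
and adjust the translation on write and read.

## Cell mosaics: detection, edits, Voronoi metrics

Detection is a matched band-pass: a difference of Gaussians tuned to
the expected spacing (σ = spacing/6 and spacing/1.5), strict regional
maxima, parabolic sub-pixel refinement, and a greedy minimum-separation
rule (default half the expected spacing) in which the stronger filtered
peak wins and ties break by raster order — detection is fully
deterministic. Spacing below two pixels is rejected as unresolvable.
The peak threshold is relative: candidates below half the median peak
response are discarded. This choice matters: distribution-based
thresholds (median + k·MAD of the filtered image) fail on fully
tessellated mosaics, where almost every pixel is signal and the MAD
approaches the signal amplitude; the relative rule handles both the
sparse and the dense regime, and an exactly constant image still yields
zero detections because it has no strict maxima. The published
semi-automatic detectors this realizes are cited without internals in
the source literature, so this detector is validated by phantom
recall/precision rather than claimed as a byte-level reimplementation.

Split-detection images are signed edge pairs, not spots: the cell
centre is the zero crossing between the bright and dark lobes, so the
pipeline detects on the negated horizontal derivative, whose peak sits
at the centre.

The manual marking workflow is realized without a GUI as an edit list:
added points carry `manual_add` provenance, removals match the nearest
centre within a tolerance (a miss is a logged warning, never an
error), and the edit log stays on the object so any curated mosaic is
reproducible from the auto detection plus its edits.

Metrics are Voronoi-based. Each centre's polygon is computed exactly
by perpendicular-bisector half-plane clipping against its nearest
neighbours (32 by default — far more than the neighbour count of any
physical mosaic); the tessellation includes centres in a guard margin
(default twice the expected spacing) beyond the region of interest so
that cells near the ROI edge have their true neighbours. A cell is
*bounded* iff its polygon lies entirely inside the ROI — the standard
unbiased edge correction, made explicit here because prose
descriptions rarely define it — and

bounded density = n_bounded / Σ(bounded polygon areas),

an identity by construction. On a square lattice with 10 µm spacing
and a 100×100 µm ROI this gives exactly 10,000 cells/mm² and
100 µm² mean cell area; on a hexagonal lattice with spacing s it gives
2/(√3 s²) to machine precision. Spacing is reported as
nearest-neighbour distance (mean ± SD); ROI sizes default to
50×50 µm within 0.3 mm of the fovea and 100×100 µm elsewhere,
overridable.

Dark cones — cells with an intact inner segment on split detection but
no waveguiding reflectance on confocal — are counted by greedy
nearest-pair matching between the two channels within a match radius
(closest pairs first, each centre used once); unmatched
split-detection cells are the dark-cone candidates.

## OCT layers and thickness

Four boundaries are segmented per B-scan: the inner limiting membrane
(ILM), the posterior outer plexiform layer (OPL), the ellipsoid zone
(EZ) centre and the posterior RPE–Bruch's membrane band. Initial
per-A-scan estimates are taken in anatomical order — the ILM is the
*first* strong brightening below the vitreous (a global gradient
maximum would skip to the brighter EZ onset), the RPE-BrM posterior is
the *deepest* strong darkening, the EZ is the intensity ridge between
them with a 9-row exclusion above the RPE band (the two bright outer
bands are axially separated by more than that), and the OPL is the
darkening between ILM and the EZ band onset. A running median across
A-scans suppresses speckle outliers, then each boundary is refined by
an energy-minimising contour: dynamic programming over a band of
candidate rows (default ±8) with an image-gradient data term and a
squared-step smoothness term (default weight 0.5 — the gradient:
curvature ratio of 1 : 0.5 is exposed in the arguments since the
cited contour method's internals are not published). Seed polylines
are hard constraints, interpolated and honoured exactly.

Sub-pixel localisation uses the gradient-centroid rule — the centroid
of the forward differences across the transition, whose positions sit
at half-integer rows — which is *exact* for area-sampled step edges;
the EZ centre is the midpoint of the band's half-rise and half-fall,
exact for a symmetric band (a pure intensity centroid is biased when
the plateaus above and below the band differ, as they do in SD-OCT).
The ordering ILM ≤ OPL ≤ EZ ≤ RPE-BrM is enforced by sorting
violations and flagging the repaired A-scans; contrast-free A-scans
are marked undefined rather than guessed.

Thickness is computed from fractional row positions before any
rounding: RT = (RPE-BrM − ILM) and ORL = (RPE-BrM − OPL), times the
axial scale (default 3.5 µm/px; lateral default 14 µm/px, both typical
SD-OCT sampling in tissue). Windowed extraction averages 10 A-scans
centred at offsets (default 2.5, 3.0 and 3.5 mm) along the nasal
meridian from the fovea; the window is implemented within the B-scan,
with partial windows flagged. A 10-sample window could alternatively
be read as a 2-D region across B-scans; the in-B-scan reading is the
default here because B-scan spacing (≈120 µm) is an order of magnitude
coarser than A-scan spacing.

## Normative statistics

Patient measures are converted to z-scores against an
eccentricity/meridian-indexed normative table:
z = (value − normal mean)/normal SD, with the matching row the nearest
eccentricity within 0.15 mm (no interpolation by default — matching
"corresponding eccentricities" without inventing a model between
them). Abnormality uses the strict rule z < −2; z = −2 exactly is not
abnormal. Age matching is delegated to normative-table construction
(filter the CSV upstream), since no age-band rule is published.

The two-sample comparison is the Wilcoxon rank-sum test with midranks
for ties. Exact mode enumerates all C(n+m, n) assignments of the
pooled midranks (feasible to n+m = 22) and reports the total null
probability of rank sums at least as extreme as observed; for
{1,2,3} vs {4,5,6} that is 2/20 = 0.1. The continuity-corrected
normal approximation with tie correction is the large-sample mode.

Intrarater reliability is ICC(A,1): two-way ANOVA, absolute agreement,
single rater,

ICC = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE)),

with the standard F-based 95% confidence interval (including its
Satterthwaite degrees of freedom). The implementation is authored
in-package (the usual reference implementation is not a dependency
here) and is tested against an independent `aov()` sums-of-squares
decomposition at 1e−10.

## The phantom generators

Every stage is validated on seeded phantoms with machine-readable
ground truth; no test reads truth out of an image. A master seed is
forked per sub-generator by a named key, so one component's parameters
can change without disturbing another's stream, and identical
specifications produce bit-identical outputs.

* **Mosaics**: jittered hexagonal lattices whose spacing matches the
  requested density (centre jitter default 10% of spacing), with an
  optional eccentricity-dependent density profile (lattice radii
  warped so local spacing tracks the profile to first order) and a
  seeded dark-cone fraction.
* **Channels**: confocal = Gaussian spot per waveguiding cell (dark
  cells omitted); split detection = signed horizontal edge pair per
  cell, dark cells included; dark field = broader blobs. Noise is
  additive Gaussian scaled to a peak-signal-to-noise ratio.
* **Frame stacks**: the central crop of a base image translated by a
  sinusoidal horizontal waveform evaluated at each row's acquisition
  time (motion varies within a frame), plus per-frame vertical
  offsets and noise; 150 frames by default, the typical video length.
* **Rulings**: vertical lines rendered through a known sinusoidal
  scan map, with the true forward map and true LUT returned.
* **OCT**: layered B-scans with the usual SD-OCT contrast ordering,
  rendered by exact area coverage so noiseless boundaries are
  recoverable to sub-pixel precision; speckle is multiplicative Gamma
  noise with shape = SNR².
* **Normative tables**: physiologic magnitudes (foveal cone density
  on the order of 1e5 cells/mm² falling steeply with eccentricity,
  RT ≈ 250–335 µm, ORL ≈ 100–147 µm) with seeded perturbations.

What the phantoms do *not* emulate: wave-optical AOSLO image
formation and its speckle statistics, torsional eye motion and
intra-strip shear, vessel shadows and other anatomical clutter,
pathology morphology beyond dark cones and thickness changes, and
vendor file formats. Passing the phantom suite therefore demonstrates
the correctness of the geometry, estimators and statistics — not
clinical-grade robustness on patient images.

The packaged end-to-end session (`build_phantom_session()`) uses two
overlapping 1.75°/512 px AOSLO stacks of 24 frames at a 1° fixation
step, one 512×9 A-scan/B-scan OCT volume, a 15% dark-cone fraction and
a 12,000 cells/mm² mosaic — sizes chosen so the full pipeline, run
twice for the determinism check, completes in about a minute while
still exercising every stage; the validation suite separately covers
150-frame stacks and densities from 1,000 to 170,000 cells/mm²
(the span from severely affected patient regions to peak foveal
density). The session's constant-density mosaic is a simplification;
eccentricity-dependent profiles are exercised by the generator tests.

## Known limitations

* The four-surface eye is paraxial: no chromatic dispersion, no
  off-axis (wide-field) magnification variation, no aberrometry.
* Strip registration estimates pure translation per strip; rotation
  and intra-strip shear are out of scope.
* Montage refinement is pairwise against a spanning tree, not a
  global bundle adjustment; placement residuals are logged per tile.
* The OCT contour assumes the four-band contrast ordering of outer
  retinal SD-OCT; severely disrupted retinas (e.g. full-thickness
  atrophy) will yield flagged/undefined A-scans rather than useful
  boundaries.
* One eye per subject is assumed in statistics (no mixed-effects
  handling of paired eyes), and p-values are reported unadjusted.
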