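# retmap

Quantitative multimodal mapping of the human retina in R.

Cellular-resolution AOSLO (adaptive-optics scanning light
ophthalmoscope) imaging can resolve individual cone photoreceptors and
RPE cells in the living eye, but turning a session's raw material —
video stacks distorted by a resonant scanner and fixational eye
motion, en-face fundus images at different magnifications, an OCT
volume — into numbers that can be compared across patients and against
healthy controls requires a chain of geometry and statistics that is
usually locked inside bespoke lab software. retmap implements that
chain as a tested, scriptable R package for imaging scientists and
reading-centre analysts:

* **Scale** — retinal magnification factor (RMF, mm of retina per
  degree of visual angle) from ocular biometry via a paraxial
  four-surface schematic eye (Le Grand parameters individualised by
  the measured axial length), with Bennett's reduced-eye closed form
  `RMF = 0.01306 (AL − 1.82)` as a cross-check mode and a paraxial
  contact-lens magnification correction; micrometres-per-pixel from
  field of view and pixel count.
* **Desinusoid** — calibration of the sinusoidal fast-axis scan
  distortion from a Ronchi-ruling image: line centres fitted to the
  arcsine position model `u(c) = A sin(B(c − c0) + φ) + d`, inverted
  into a monotone resampling look-up table.
* **Register** — whole-frame NCC ranking against a chosen reference,
  horizontal-strip NCC registration with sub-pixel refinement and
  dropout rejection, and coverage-tracked frame averaging.
* **Montage / map** — tile placement from fixation coordinates with
  NCC refinement and feathered blending; landmark-based similarity or
  affine alignment of AOSLO, FIR, FAF and OCT into one micrometre
  frame; foveal-centre anchoring and eccentricity-by-meridian queries.
* **Mosaic** — matched band-pass cone/RPE detection with a
  deterministic minimum-separation rule, manual-edit bookkeeping,
  exact Voronoi tessellation by half-plane clipping, bounded-cell
  density `n_bounded / Σ(bounded areas)` (on a hexagonal lattice of
  spacing s this equals `2/(√3 s²)` to machine precision), and
  confocal vs split-detection discordance counts ("dark cones").
* **OCT layers** — ILM, posterior OPL, EZ-centre and posterior
  RPE-BrM segmentation by gradient initialisation plus an
  energy-minimising contour, with retinal thickness
  `RT = ILM→RPE-BrM` and outer-retinal thickness `ORL = OPL→RPE-BrM`
  in µm and windowed extraction at nasal offsets.
* **Stats** — eccentricity-matched z-scores against normative tables
  (abnormal iff z < −2, strictly), exact (full-enumeration) and
  normal-approximation Wilcoxon rank-sum tests, and ICC(A,1)
  intrarater reliability with its F-based 95% CI.
* **Synthetic** — seeded phantom generators with machine-readable
  ground truth for every stage (jittered hexagonal mosaics with dark
  cones, three-channel renders, motion-jittered frame stacks,
  distorted rulings, speckled layered OCT volumes, normative tables),
  plus a packaged end-to-end phantom session.

The methods vignette (`vignettes/retinal-mapping-methods.Rmd`)
documents the models, parameter defaults and numerical choices in
detail.

## Worked example

```r
library(retmap)

## scale: biometry -> RMF -> um/px
sm <- compute_rmf(biometry(24.46), model = "four_surface")
sm
#> Retinal scale model (four_surface)
#>   RMF: 0.29578 mm/deg
microns_per_pixel(sm, field_of_view = 1.75, pixels_across = 512)
#> aoslo_confocal: 1.0110 x 1.0110 um/px

## a phantom cone mosaic, rendered and quantified
mo <- gen_mosaic(field_um = c(150, 150), density = 12000,
                 jitter_fraction = 0.1, seed = 1)
rc <- render_channels(mo, um_per_px = 0.75, snr = 10, seed = 1)
cm <- detect_cells(rc$confocal, "cone",
                   expected_spacing_um = mo$spacing_um, scale = rc$scale)
vm <- voronoi_metrics(cm, roi(center_um = c(75, 75), width_um = 100))
vm
#> Voronoi metrics: 122 marked, 90 bounded; density 11960 cells/mm^2;
#> area 83.6 +/- 6.4 um^2; spacing 8.25 +/- 0.79 um

## normative comparison
tab <- gen_normative(seed = 1)
zscore(vm$bounded_density_mm2, tab, "cone_density",
       eccentricity_mm = 1.5, meridian = "nasal")
#> z = -0.835 (value 1.196e+04 vs normal 1.305e+04 +/- 1305)

## small-sample inference
wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p
#> [1] 0.1
icc_a1(cbind(c(152, 131, 148, 122), c(149, 133, 147, 125)))
#> ICC(A,1) = 0.983 [0.761-0.999] (two-way, absolute agreement,
#> single rater; 4 subjects x 2 sessions)
```

The detected bounded density (11,960 cells/mm²) recovers the
generator's 12,000 cells/mm² to within the tessellation's edge
variance; the z-score compares it against the synthetic normative mean
at the matched eccentricity; `p = 0.1` for {1,2,3} vs {4,5,6} is the
exact enumeration value (2 of 20 assignments as extreme).

A complete session — ruling, two overlapping frame stacks, a
split-detection tile, an OCT volume, landmarks and a normative table —
can be produced and analysed end to end:

```r
build_phantom_session("session", seed = 1)
res <- run_pipeline("session")           # writes CSVs + JSONL log
```

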