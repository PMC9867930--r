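---
title: "Quantifying macular deviation maps: models, simulator, and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macular deviation maps: models, simulator, and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macdev)
```

## The scientific problem

Glaucoma destroys retinal ganglion cells, and the macula holds the densest
population of them.  Spectral-domain OCT can segment the ganglion cell layer
(GCL) and the inner plexiform layer (IPL) separately, which raises a
practical question for early-glaucoma diagnostics: does the GCL alone —
where the ganglion cell somas live — discriminate early disease better than
the combined GCIPL (GCL + IPL) that most devices report?

Two complementary measurement channels address this question:

1. **Thickness summaries.** Layer thickness is exported as an 8 × 8 grid of
   64 superpixels (3° × 3° each) centered on the fovea; the central 48
   superpixels are grouped into 5 superior and 5 inferior macular sectors,
   and the global average over the central 18° × 18° (the central 6 × 6
   superpixels) summarizes each eye.
2. **Deviation maps.** Each pixel of a thickness raster is compared with a
   normative database and color-coded: red below the 1st percentile, yellow
   below the 5th, green within the 5–95% interval, blue above the 95th, and
   pink above the 99th.  The percentage of flagged pixels — over the entire
   rectangular scan and within a perifoveal elliptical annulus of
   4.8 × 4.0 mm excluding a central 1.2 × 1.0 mm oval — quantifies the
   extent of damage.

Discrimination is compared with AUROCs; correlated AUROCs measured on the
same eyes (GCL vs GCIPL) are compared with the DeLong test, and group
contrasts of extents use Wilcoxon tests.

This package implements the full quantification chain plus a synthetic-data
module, so that every stage is testable without patient data, which cannot
be shared.

## The normative model and pixel classification

`build_normative()` represents a normative database for one layer as
per-pixel mean and SD surfaces on a fovea-centered raster.  The percentile
model is Gaussian: the cutoffs at a pixel are `mean + z·SD` with
`z = qnorm(p)` for `p ∈ {0.01, 0.05, 0.95, 0.99}` (±2.3263 and ±1.6449).
Device manufacturers do not publish their normative machinery; a pointwise
Gaussian prediction interval is the simplest model consistent with the
"5% to 95% prediction interval" semantics of the device maps, and it is
exactly simulable, which is what makes end-to-end calibration testing
possible.  Whether real devices use pointwise Gaussian or empirical
quantiles is unknowable from the outside; with the Gaussian choice the
package's calibration property (below) is exact rather than approximate.

Boundary conventions follow the strict inequalities of the flagging rules
("P < 5%", "P > 95%"): a value exactly at the 5th or 95th percentile is
within normal limits; exactly at the 1st percentile is borderline (yellow);
exactly at the 99th is blue.  `classify_thickness()` compares thickness
against the cutoff *surfaces* rather than z-scores so that values lying
exactly on a cutoff classify per these conventions without floating-point
surprises.  Negative thickness is the missing-data sentinel and maps to the
`excluded` category.

The GCIPL model is composed from the GCL and IPL models: means add exactly;
SDs combine as `sqrt(SD_g² + SD_i² + 2ρ·SD_g·SD_i)` with an inter-layer
correlation `ρ` (default 0.5).  The layers are anatomically adjacent and
their thicknesses co-vary; `ρ = 0` would understate GCIPL variance and
`ρ = 1` overstate it, and 0.5 is a deliberately unremarkable midpoint — the
simulator generates layer noise with the same `ρ` at every scale, so the
composed model is exactly calibrated for simulated GCIPL maps whatever value
is chosen.

**Calibration property.** When thickness is drawn from the model itself,
each tail (abnormal = red ∪ yellow, supernormal = blue ∪ pink) flags exactly
5% of pixels in expectation.  This is the one quantitative claim about the
deviation-map machinery that is checkable without patient data, and the test
suite checks it by Monte Carlo at both tails.

## The synthetic-eye generator

`simulate_eye()` generates one eye as

```
thickness = normative mean − defect + noise,   clipped at 0
```

* **Defect fields** (`defect_field()`) are smooth non-negative bumps whose
  maximum equals the requested magnitude: an anisotropic Gaussian ridge
  along a circular arc at 2 mm eccentricity (radial SD 0.8 mm, angular
  half-width 60°) for arcuate defects — the qualitative shape of macular
  RNFL-bundle loss — plus a smooth superior-hemifield step and a diffuse
  (uniform) option.  The defect splits 60/40 between GCL and IPL
  (`gcl_fraction = 0.6`): early glaucomatous loss is believed to involve
  somas slightly more than dendrites, but both layers thin, and any split
  strictly inside (0, 1) preserves every ordering the tests rely on.
* **Noise** has per-pixel SD equal to `noise_sd_scale` × the normative SD,
  split into a between-eye common component (weight
  `sqrt(noise_correlation)`, default `noise_correlation = 0.5`) and an
  i.i.d. pixel component.  The split leaves the per-pixel marginal exactly
  `N(mean, SD²)` — so map calibration is untouched — while giving eyes
  realistic global-thickness variability.  Real normative SD mixes
  between-subject anatomy with measurement noise; a fifty-fifty split makes
  the global GCIPL mean vary by a few micrometres across normal eyes, which
  is the regime in which global-thickness AUROCs take plausible values
  instead of degenerating to 1.0 the moment any defect exists.
* **Laterality.** OS eyes are generated in right-eye orientation and
  mirrored left–right; all analysis runs in OD orientation.  Pooling
  mirrored left eyes is the standard convention when laterality itself is
  not under study.

`simulate_cohort()` draws glaucoma defect magnitudes from a lognormal with
configurable median (default 15 µm, log-SD 0.6 — peak focal loss several
times the ~4 µm global GCL loss typical of early disease, since focal
defects concentrate damage), suspects from a half-magnitude lognormal mixed
with zeros, and normals with no defect.  Everything is seeded and
bit-reproducible.

What the generator does **not** emulate: OCT speckle, B-scan acquisition
geometry, segmentation failure, media opacity, age or axial-length effects,
and inter-eye correlation within a patient.  Passing tests therefore
demonstrate the correctness and calibration of the *quantification
machinery*, not device-level performance on real patients.

## Rendered maps, the annulus, and overlay removal

`render_deviation_map()` paints each pixel with its category color
(defaults: red, yellow, green, blue, pink, grey for excluded) and over-draws
the annulus boundaries and sector spokes in a reserved overlay color
(black).  Rendering is exact by construction, and `parse_colors()` inverts
it: nearest palette color within a per-channel tolerance (default 20 of
255), anything farther — overlay graphics, annotations — becomes
`excluded`.  A palette is rejected as ambiguous unless all pairwise color
distances exceed twice the tolerance, which makes the round trip
(render → PNG → parse) bit-exact for non-overlay pixels.

`fit_annulus()` recovers the annulus geometry from the overlay pixels, as
one must when only rendered map images are available: candidate pixels are
split into outer and inner sets by normalized radius under a prior (the nominal 2.4/2.0 and 0.6/0.5 mm semi-axes centered on the fovea),
and each set is fitted with the direct algebraic least-squares ellipse
method (Fitzgibbon's ellipse-specific constraint in the numerically stable
Halir–Flusser formulation).  Fits with fewer than 6 candidate pixels per
boundary are rejected with a diagnostic.  On rendered boundaries the
recovered semi-axes are well within one pixel pitch of truth.

`remove_overlay_lines()` detects the straight sector-divider lines with a
standard (ρ, θ) Hough transform — 1° angular and 1 px radial resolution,
greedy peak extraction at 0.5 × the maximum accumulator count — and
reassigns the pixels residing on each detected line (its supporting mask
pixels dilated by 1 px) to `excluded`.  Reassigning the dilated *supporting
pixels* rather than the full analytic line band keeps the operation local:
no pixel farther than the dilation radius from an actual line pixel is ever
touched, and a map without lines passes through unchanged.

`extent_summary()` counts category pixels inside the region (entire scan, or
annulus membership by the pixel-center rule) and reports percentages.  Two
deliberately exposed policies:

* **Denominator.** Default `"exclude"` removes `excluded` pixels (overlay,
  missing) from the denominator, because overlay pixels carry no thickness
  information; `"raw"` divides by all region pixels, matching a literal
  "total number of pixels in the scan area" reading.  The choice is recorded
  in every summary.
* **Cumulative vs disjoint bands.** Default reports disjoint bands (yellow =
  1–5% band), matching the five-color map; `cumulative = TRUE` reports
  "below 5%" and "above 95%" tails instead.

## Sector aggregation

The exact published membership of the 5+5 sectors exists only as a figure,
so `default_sector_map()` ships a documented approximation honoring every
stated constraint — 48 central superpixels (the 8 × 6 block excluding the
outermost temporal and nasal columns), superior sectors confined to the top
four rows, mirror symmetry about the horizontal midline — with sectors
sweeping arcuate-fashion from the temporal periphery toward the nasal
paracentral region.  The map is an explicit, replaceable input
(`sector_map()`, `read_sector_map_csv()`); all aggregation invariants
(linearity, permutation invariance within sectors, missing-cell handling)
hold for any valid map.  `global_mean()` averages the central 6 × 6
superpixels: the 8 × 8 grid spans 24°, and only the central 36 cells match
the stated 18° × 18° global region.

## Statistics

`auroc()` is the Mann–Whitney construction (ties count ½) with DeLong's
variance from per-case and per-control placement components.
`delong_test()` compares two correlated AUROCs on the same eyes from the
shared placement components; a non-positive variance of the difference is
flagged degenerate and reported as p = 1 rather than a division error.  The
implementation is checked in the test suite against an independent
loop-based evaluation of the structural components and against `pROC`.

Orientation is explicit everywhere: lower thickness indicates disease,
higher abnormal extent indicates disease, and supernormal extents default to
lower-indicates-disease (thinning depletes supernormal pixels), overridable
in `cohort_tables()`.

`wilcoxon_group()` uses the exact null distribution up to n = 25 per group
when the data are tie-free and the tie-corrected normal approximation
otherwise; within-eye GCL-vs-GCIPL contrasts use the paired signed-rank
form, group contrasts the unpaired rank-sum form.  P-values are two-sided
throughout; no multiplicity adjustment is applied by default (a Holm option
exists).  Eyes are treated as independent — a documented limitation shared
with analyses that enroll two eyes of some patients without clustering
adjustment.

## Numerical choices and degenerate inputs

* Percentile cutoffs use `qnorm` at full double precision; the quoted
  2.3263/1.6449 are the conventional 4-decimal renderings.
* Classification at cutoff boundaries is performed on thickness surfaces,
  not z-scores (see above).
* Ellipse fitting centers and scales coordinates before solving the
  generalized eigenproblem; the eigenvector sign is normalized so the conic
  is an ellipse with positive leading coefficient.
* All-missing rasters classify to all-`excluded`, and extent summaries over
  a region with no informative pixels raise an error instead of returning
  NaN.
* Hough peak extraction is capped (default 16 lines) and refines each ρ on
  the supporting pixels before retiring them.
* Empty score groups, degenerate DeLong variances, and all-zero paired
  differences are surfaced as errors or flagged degenerate results, never
  silent NaNs.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run on desk-scale instances chosen
to keep Monte-Carlo error comfortably below the tolerances being asserted:
64 × 64 rasters for calibration and round-trip checks (≥10⁶ pixel draws for
tail calibration), 100–200 simulated eyes for cohort-level properties,
192 × 192 rasters for ellipse-recovery geometry, 2,000 replicates for the
DeLong null rejection rate, and 100 eyes per group over three defect-median
levels for the discrimination-monotonicity check.  The full-resolution
default geometry (384 × 384 over 30° × 25°) is exercised in the Hough
acceptance check, where line geometry is resolution-dependent.

## Known limitations

* The Gaussian percentile model is an idealization of unpublished device
  internals; real normative cutoffs may be empirical quantiles with
  covariate adjustment.
* The shipped sector map is an approximation; sector-level results depend
  on membership and should be re-run with a user-supplied map for studies
  that hinge on specific sectors.
* The simulator's defect library (arcuate/hemifield/diffuse Gaussian
  fields) does not span the full morphology of glaucomatous loss.
* No inter-eye clustering; AUROC variances are mildly optimistic when both
  eyes of a patient enter a cohort.
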