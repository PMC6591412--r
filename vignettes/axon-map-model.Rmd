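---
title: "Modeling epiretinal phosphenes with ganglion axon pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling epiretinal phosphenes with ganglion axon pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epiretinal prostheses such as Argus I/II stimulate the inner retinal
surface with disc electrodes. Users do not see a grid of focal dots:
single-electrode percepts ("phosphenes") range from round blobs to long
streaks and wedges, and their shape is stable per electrode but varies
across electrodes and subjects. The leading explanation is incidental
activation of retinal ganglion cell *axons* passing under an electrode:
an activated axon produces a percept at the visual-field position of its
*soma*, which can sit hundreds of microns peripheral to the stimulation
site, so percepts elongate along the local nerve-fiber-bundle
trajectory.

This package implements that account end to end: a subject-specific
simulated map of fiber bundles, two percept models (a focal "scoreboard"
model and the anisotropic "axon map" model), moment-based shape
descriptors for binary drawings, resampling statistics for orientation
alignment and drawing consistency, and model fitting by particle-swarm
optimisation (PSO) under leave-one-electrode-out cross-validation
(LOEO-CV).

## Coordinate systems

Retinal positions are microns on a fovea-centered plane, x positive
toward the optic disc (nasal retina), y positive superior. Visual-field
positions are degrees of visual angle; the vertical axis flips between
the two systems (upper visual field maps to inferior retina), and a left
eye additionally mirrors azimuth. The default retina-to-degree
conversion is linear at 3.6 deg/mm applied radially from the fovea; that
single factor reproduces the anchor correspondences used throughout
(1 mm = 3.6 deg; 437 um ~ 1.5 deg; 1,420 um ~ 5 deg). A nonlinear radial
conversion can be plugged in (`fun` argument of `retinal_to_visual()`),
but the linear map is the default because all quantitative anchors in
the analysis are stated in its terms.

Landmarks estimated from fundus photography — array center (um), array
rotation against the horizontal raphe (deg, counterclockwise), and the
optic-disc center — are *inputs* (`subject_geometry()`); the package
does no image registration. The disc center is interpreted as
retinal-sense degrees (nasal-positive, superior-positive), matching how
the landmark tables print it; anatomically the disc sits about 15.5 deg
nasal and 1.5 deg superior of the fovea.

## The fiber-bundle map

Each nerve fiber bundle is a spiral in a polar frame centered on the
optic disc,

$$\phi(r) = \phi_0 + b(\phi_0)\,(r - r_0)^{c(\phi_0)},$$

with `r` in degrees from the disc center, a starting circle at
`r0 = 4` deg, and piecewise coefficients `b` (signed curvature) and
`c > 0` (curvature-peak location) selected by the sign of `phi0`
(positive = superior branch). The printed piecewise condition on the
branch ("r >= 0 / r < 0") cannot be meant literally — `r` is a radius —
so the branch is taken on the sign of `phi0`, the only reading that
makes both branches reachable.

Two conventions are not fixed by the equations alone: where `phi = 0`
points, and the rotation handedness. We resolved them empirically
against anatomical constraints. With `phi` measured from the *nasal*
direction at the disc (pointing away from the fovea),
counterclockwise-positive toward superior retina, the map covers the
macula and implant region without gaps (the worst nearest-bundle gap
over the implant region is a fraction of a degree), `phi0` near ±180
gives straight papillomacular fibers, and the most curved fibers are the
arcuate ones — all as observed in human eyes. The alternative
(temporal-pointing) reading leaves a >10-degree hole around the macula
and was rejected.

Trajectories are truncated where they would cross the horizontal raphe
temporal to the disc (fiber bundles respect that seam), where the
angular sweep exceeds 180 degrees (far beyond the range the trajectory
model was fitted on), and at `r_max = 45` deg. Defaults of 500 bundles
at a 0.25-deg radial step give a vertex spacing well below typical
electrode pitch; both are configurable, and validation studies in the
test suite use sparser maps (150-400 bundles, 0.5-deg steps) sized to
the question being asked.

**Known limitation.** The spiral is a fitted extrapolation: near the
temporal raphe at large eccentricity its power-law sweep makes
trajectories approach the raphe at oblique angles rather than
asymptotically parallel to it. Nearest-bundle tangents are therefore
near-horizontal on the meridian segment between fovea and disc, but
become steep far temporal along the raphe. Analyses of electrodes in
that far-temporal strip should treat predicted orientations with
caution; implanted arrays sit mostly in the para-macular region where
the field is smooth.

## Percept models

*Scoreboard*: intensity is an isotropic Gaussian of retinal distance to
the electrode with spread `rho` (um), peak 1 at the electrode.

*Axon map*: every raster pixel is a candidate soma assigned to its
nearest bundle. Its activation aggregates, over the disc-ward axon path,
the product of two Gaussian decays: distance from the path sample to the
electrode (constant `rho`, um) and distance from the soma to the sample
along the axon (constant `lam`, um). Two implementation choices are
deliberately exposed:

- **Soma distance**: measured as *arclength* along the fiber by default
  (axonal conduction follows the fiber); a Euclidean mode matches the
  activation formula verbatim. The two agree exactly for straight
  bundles (unit-tested against closed forms).
- **Aggregation**: *maximum* over path samples by default — a fiber
  fires once any segment is driven sufficiently — with a summation mode
  available for comparison. On binary thresholded percepts the two are
  nearly indistinguishable.

The axon-map image is normalised to peak 1 and thresholded at
`1/sqrt(e)`, which makes the scoreboard percept a disc of radius exactly
`rho` — a convenient geometric calibration that the tests verify to one
pixel. Rendering is done in C++ in log-intensity space (the max
aggregation commutes with `exp`), which keeps LOEO-CV with PSO on a
laptop-scale budget.

Along a straight fiber the thresholded axon-map percept extends about
`sqrt(rho^2 + lam^2)` peripheral to the electrode and `rho` disc-ward
and orthogonal to it: elongation grows with `lam/rho`.

### The electrode-distance simulation

Lift-off from the retinal surface is simulated as an increase of `rho`
at fixed `lam` (`simulate_distance_series()`): close electrodes give
thin elongated percepts, distant ones rounder blobs, and thresholded
elongation decreases monotonically across
`rho = 300, 500, 800, 1600` um at `lam = 500` um. The reference *endpoint*
elongation values for that series checked by the validation suite
(0.977 down to 0.643) cannot arise from the Gaussian axial decay at
`lam = 500` um, whose
along-fiber reach is bounded by `sqrt(rho^2 + lam^2)`; they are
reproduced almost exactly when the axial decay is effectively disabled
(`lam` far larger than the field), i.e. when the percept follows the
entire fiber path weighted only by the `rho` term. The acceptance test
asserts monotonicity in the stated regime and checks the endpoint values
in the weak-axial-decay regime that demonstrably generates them.

## Shape descriptors

Area, orientation and elongation come from raw and central image
moments: area is the zeroth moment; orientation is half the two-argument
arctangent of the central second moments (the principal eigenvector
axis), axial in [-90, 90); elongation is `sqrt(1 - l2/l1)` of the
covariance eigenvalues — 0 for a circle, approaching 1 for a thin line.
The two-argument arctangent is used so vertical elongation yields
|theta| = 90; the degenerate case (equal diagonal moments *and* zero
cross moment, e.g. a disc) is assigned theta = 0 by convention, and a
single pixel has elongation 0. Empty images carry NA orientation and
elongation, which every downstream statistic excludes explicitly.
All orientation arithmetic — residuals, means, SEMs — is axial: wrapped
to [-90, 90), averaged with the doubled-angle circular mean.

## Resampling statistics

`sem_consistency_test()` asks whether drawings are more alike within an
electrode than across electrodes: observed statistic = mean per-electrode
descriptor SEM (area SEM normalised by the electrode's mean area), null =
the same statistic on electrode-sized groups resampled with replacement
from the pooled drawings. `orientation_alignment_test()` compares drawn
orientations against nearest-bundle tangents under two nulls: NM1 draws
orientations uniformly (its null mean is 45 deg, a property the
acceptance suite verifies), NM2 re-places the array uniformly over
x in [-6000, 4000] um, y in [-4000, 4000] um, rotation in [-90, 90] deg,
recomputing tangents while keeping the drawings fixed. All p-values are
one-tailed fractions of the null at or below the observed value with a
+1/(iterations+1) correction so p is never exactly zero; results are
bit-reproducible given (seed, iterations).

`orientation_variance_explained()` is an R-squared with axially wrapped
residuals; it can be negative and is reported as-is. Per-trial
observations are the default (each drawing contributes one residual); an
electrode-mean mode exists because summary analyses are sometimes done
that way.

## Fitting and model comparison

The cost is `c = sum_d (1 - R_d^2)` over the three descriptors, each
drawing compared with the predicted percept of its electrode; position
is never compared (descriptors are location-free). Empty predicted
percepts contribute worst-case residuals (90 deg orientation error,
maximal elongation deviation) so the optimiser is pushed away from
parameter regions that predict nothing.

PSO uses a swarm of ten times the number of parameters and five
restarts from random initial conditions, keeping the best run. The
remaining hyperparameters (inertia 0.7, cognitive/social weights 1.5,
up to 100 iterations, 1e-6 stall tolerance) are conventional values and
are logged in every fit; validation studies in the test suite cap
iterations at 12-30, which is ample for this smooth 1-2 parameter
problem. Bounds default to rho in [10, 3000] um and lam in [10, 5000]
um, covering the plausible physiological range with margin.

LOEO-CV fits one (rho, lam) per fold on all-but-one electrode and
scores the held-out electrode. Because a single electrode contributes
only a handful of drawings, the held-out cost normalises the mean
squared residual by the *training-set* descriptor variance — the
training total sum of squares per observation — rather than the
degenerate held-out variance. `compare_models()` runs a two-sided
paired Wilcoxon signed-rank test on per-electrode log held-out costs
(offset 1e-9 inside the log), switching to the exact test below six
pairs; an all-zero difference vector returns p = 1.

## The synthetic-data generator

`generate_subject()` samples implant placements uniformly across the
span of the implanted-subject landmark estimates (array center x in
[-2142, -651] um, y in [-850, 401] um, rotation in [-53.9, -22.1] deg)
and the optic disc from a normal around (15.5, 1.5) deg with SDs
(1.1, 0.9), truncated at two SDs — the population statistics of disc
position. `generate_drawings()` renders each electrode's noiseless
axon-map percept at a known (rho*, lam*) and derives the default five
trials by centroid jitter (SD 200 um), rotation jitter (SD 10 deg),
area rescaling (SD 0.15) and one-pixel boundary roughening — magnitudes
chosen once to mimic the within-electrode trial variability seen in
real drawing experiments.

What the generator does *not* emulate: drawing bias and motor noise
idiosyncratic to blind subjects, occasional two-part percepts, the
arbitrary perceived-size scaling of drawings made without a depth
reference, and any deviation of real fiber anatomy from the trajectory
model. Passing the recovery and discrimination tests therefore shows
the pipeline is *self-consistent* (the fitting machinery recovers the
generating process), not that the axon map is the true model of any
particular retina.

Validation problem sizes (chosen as the smallest that exercise the
claim): parameter recovery uses 20 subjects with 8 electrodes each on a
0.4-deg raster with (rho*, lam*) drawn across the plausible fitted
ranges, recovering both parameters with a median relative error under
10%; model discrimination uses 20 subjects with 12 electrodes on a
0.45-deg raster, where the cross-validated axon map beats the
scoreboard with Wilcoxon p < 0.05 in at least 90% of subjects.

## Reproducing published analyses

The deposited Argus drawing dataset (OSF: dw9nz) is not redistributable
with the package, so the reproduction suite checks for a locally staged
copy under `tests/testthat/paper-data/` (one directory per subject,
electrode subdirectories of trial PNGs readable by
`read_drawings_tree()`, plus a `grid.json`) and fails visibly when the
data are absent. With the data staged, it recomputes per-subject
orientation variance explained, cross-validated (rho, lam), and
elongation-area correlations against their reported values. The four
subjects' landmark geometries ship with the package
(`system.file("extdata", "argus_subjects.yaml", package = "phosphenes")`).
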