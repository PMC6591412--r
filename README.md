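# phosphenes

Simulation and model-based analysis of the visual percepts
("phosphenes") elicited by epiretinal prostheses such as Argus I/II.

Users of epiretinal implants do not see tidy grids of dots: stimulating
a single electrode typically evokes a blob, streak or wedge whose shape
is stable for that electrode but varies across electrodes and subjects.
The likely culprit is incidental stimulation of retinal ganglion cell
axons passing under the electrode — an activated axon produces a percept
at the visual-field position of its soma, so percepts smear along the
local nerve-fiber-bundle trajectory. This package implements that
account end to end, for researchers modeling prosthetic vision or
analysing phosphene-drawing experiments:

- **Fiber-bundle maps** — ganglion axon trajectories modeled as spirals
  in a polar frame anchored on the optic disc,
  `phi(r) = phi0 + b(phi0) (r - r0)^c(phi0)`, tailored to a subject's
  fundus landmarks (array center/rotation, optic-disc position).
- **Percept models** — the focal *scoreboard* model
  `I = exp(-d^2 / (2 rho^2))` and the anisotropic *axon map* model, in
  which sensitivity decays with constant `rho` (um) orthogonal to the
  axon and `lam` (um) along it; intensity images are thresholded at
  `1/sqrt(e)` to binary percepts.
- **Shape descriptors** — image-moment area, orientation and elongation
  (`E = sqrt(1 - l2/l1)`; 0 = circle, 1 = thin line) for binary
  drawings, with axial-angle statistics throughout.
- **Resampling statistics** — within-electrode drawing-consistency SEM
  tests, orientation-alignment null models (uniform orientations, NM1;
  random array placement, NM2), orientation variance explained, and
  elongation-area correlations.
- **Model fitting** — cost `c = sum_d (1 - R_d^2)` over the three
  descriptors, minimised by particle-swarm optimisation (swarm = 10 x
  parameters, 5 restarts) under leave-one-electrode-out
  cross-validation, plus paired Wilcoxon model comparison.
- **Synthetic data** — a generator producing subjects and trial
  drawings with known ground truth `(rho*, lam*)`, used to validate the
  whole pipeline by parameter recovery.

## Worked example

Place a simulated Argus II array on one of the shipped subject
geometries, render the axon-map percept of electrode B9, and check its
orientation against the local fiber tangent:

```r
library(phosphenes)

subjects <- read_subject_config(
  system.file("extdata", "argus_subjects.yaml", package = "phosphenes"))
geo <- subjects$subject2
map <- build_axon_map(geo, phi0_samples = 300)
arr <- build_array(geo)
e <- arr[arr$name == "B9", ]

grid <- percept_grid(c(-18, 6), c(-12, 9), 0.25)
img <- render_axon(c(e$x, e$y), model_params(rho = 315, lam = 500),
                   map, grid)
describe_shape(threshold_percept(img), pix = grid$pix)
#> area 98.0 px, orientation 18.6 deg, elongation 0.605

tangent_to_visual(nearest_bundle_tangent(c(e$x, e$y), map))
#> [1] 9.640875
```

The percept is elongated (`E = 0.605`) roughly along the underlying
bundle (18.6 deg drawn vs 9.6 deg tangent; the percept integrates over
curving fibers, so a few degrees of offset is expected). Generate a
synthetic drawing experiment at known parameters and recover them by
cross-validated PSO fitting:

```r
cfg <- synth_config(n_electrodes = 8, rho = 315, lam = 500, seed = 1)
gen <- generate_drawings(geo, map, cfg, grid)
loeo_cv("axon_map", ds = gen$ds, map = map, seed = 1,
        control = list(maxit = 25, stall = 10))
#> fit_result (axon_map): 8 folds
#>   rho = 320 +/- 2 um
#>   lam = 490 +/- 10 um
#>   mean held-out cost = 1.432
```

The fitted `rho = 320 +/- 2` um and `lam = 490 +/- 10` um recover the
generating values (315, 500) within a few percent, with tight SEMs
across folds.

A thin command-line front end over the same functions ships in
`inst/cli/phosphenes.R` (`synth`, `describe`, `simulate`, `fit`,
`nulltest`, `compare`).

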