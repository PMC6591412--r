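Package: phosphenes
Title: Simulation and Model-Based Analysis of Epiretinal Prosthesis Percepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing the visual percepts
    ('phosphenes') elicited by epiretinal prostheses such as Argus I/II.
    Implements a subject-specific model of retinal ganglion axon pathways
    (spiral nerve-fiber-bundle trajectories anchored at the optic disc),
    renders predicted percepts under a focal 'scoreboard' model and an
    anisotropic 'axon map' model, quantifies binary phosphene drawings with
    image-moment shape descriptors (area, orientation, elongation), and fits
    and compares the two models with particle-swarm optimisation under
    leave-one-electrode-out cross-validation. Includes resampling statistics
    for within-electrode drawing consistency and for the alignment of
    phosphene orientation with the simulated fiber map, plus a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
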