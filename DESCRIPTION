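Package: cortexfold
Title: Coupled Neuronal-Migration and Morphoelastic Growth Simulation of Cortical Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-element simulation of the developing cortex in which cohorts
    of migrating neurons, tracked as advection-diffusion density fields, drive
    multiplicative (morphoelastic) volumetric growth of a neo-Hookean tissue
    domain. Includes a one-dimensional bar geometry for calibration against
    radial cell-density profiles, a plane-strain half-circle geometry for
    folding (buckling) studies, a real-coded genetic algorithm for inverse
    calibration of proliferation, migration and growth parameters, tools that
    turn neuron coordinate tables into one-dimensional density profiles, a
    synthetic-data generator with known ground truth, and post-processing of
    folding onset, wavelength and radial-fiber orientation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
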