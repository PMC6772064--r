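Package: opmarray
Title: Empirical Bayes Evaluation and Optimisation of Magnetometer Array Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring, comparing and optimising the geometry of
    on-scalp magnetometer (OPM) arrays for MEG source reconstruction.
    Provides spherical and corrected-sphere (single shell) lead-field
    forward models for point magnetometers, Empirical Bayes Beamformer
    source inversion with restricted-maximum-likelihood hyperparameter
    optimisation, variational free-energy model evidence with its
    accuracy/complexity decomposition, geometry-perturbation curves with
    evidence-threshold widths, and a Metropolis pose search with Bayesian
    model averaging that recovers the position of a rigid sensor array
    from the field data themselves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    signal,
    pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'constructors.R'
    'inversion.R'
    'evidence.R'
    'forward-sphere.R'
    'forward-shell.R'
    'geometry.R'
    'io.R'
    'opmarray-package.R'
    'search.R'
    'synthetic.R'
    'runExperiment.R'
    'utils.R'
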