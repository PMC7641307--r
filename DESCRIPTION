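Package: xsijunction
Title: Holliday Junction Conformational Ensembles from X-Ray Scattering
    Interferometry and Single-Molecule FRET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for X-ray scattering interferometry (XSI) of
    gold-labeled nucleic acids, applied to the conformational ensemble of a
    DNA four-way (Holliday) junction. Simulates labeled and unlabeled
    scattering profiles from coarse bead models via the Debye formula,
    extracts the gold-gold interference pattern from a six-profile
    measurement bundle, inverts it into an absolute distance distribution by
    maximum-entropy fitting over sphere-form-factor/sinc basis functions, and
    summarizes the ensemble as peak positions, conformer populations and
    free-energy differences. Includes parametric junction geometry models
    (stacked-X, planar cross, square pyramid, tetrahedral) for model
    discrimination against measured distances, a synthetic-data generator for
    both XSI bundles and two-state single-molecule FRET traces, and
    threshold/dwell-time kinetics for FRET trace analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
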