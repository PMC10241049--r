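Package: aucsas
Title: Aggregate Correction of Small-Angle Scattering Profiles Using
    Analytical Ultracentrifugation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the small-angle X-ray or neutron scattering
    (SAXS/SANS) profile of a target biomacromolecule's monomer from a
    measurement contaminated by oligomeric aggregates, using the species
    distribution (weight fractions, sedimentation coefficients, frictional
    ratio) determined by sedimentation-velocity analytical
    ultracentrifugation (AUC). Implements both the Guinier-connection
    ("first") reconstruction and the improved reconstruction based on the
    decoupling approximation with a random-flight inter-subunit structure
    factor and an ellipsoidal subunit anisotropy factor, together with
    Guinier analysis, a regularized indirect Fourier transform for the pair
    distance distribution P(r), hydrodynamic conversions (molar mass from
    the sedimentation coefficient, axial ratio from the Perrin friction
    factor), and a fully specified synthetic-data generator with a
    brute-force ensemble oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
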