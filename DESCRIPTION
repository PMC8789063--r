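Package: hjdyn
Title: Structure, Deformability and Isomer Thermodynamics of DNA Four-Way Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics ensembles of immobile DNA
    four-way (Holliday) junctions and their topological variants. Implements
    the junction step-labelling scheme, base-pair reference frames and the six
    base-pair step helical parameters (CEHS/3DNA convention) with an exact
    rebuild inverse, per-step covariance and stiffness matrices with
    configurational volumes, essential-dynamics PCA of backbone coordinates
    with projection free-energy surfaces, Schlitter quasiharmonic entropy and
    MM-PBSA end-state bookkeeping, adaptive-biasing-force PMF integration with
    window stitching, blocking-analysis error estimation, and time-resolved
    FRET donor-decay fitting of stacked-isomer fractions. Ships seeded
    synthetic-ensemble generators so every pipeline stage is testable without
    trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
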