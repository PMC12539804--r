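Package: ChannelMech
Title: Force Distribution and Mechanical Analysis of Mechanosensitive Channel Gating
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the mechanics of force-gated ion channels
    from molecular dynamics frames at desk scale: residue-pairwise force
    computation for bonded, Coulomb and Lennard-Jones interactions (force
    distribution analysis), condition-difference net force fields with
    four-fold rotational symmetrisation, torque and membrane-parallel/normal
    force decomposition in per-subunit local frames, torsional and
    compression-twist elasticity fits of the ankyrin-repeat spring,
    hydrogen-bond occupancy matrices and grouped Pearson correlation with
    net forces, simplified pore-radius profiling, and rotation/tilt geometry
    of the TRP helix between gating states. Includes seeded synthetic-data
    generators for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, Software
RoxygenNote: 7.3.3
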