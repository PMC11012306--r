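Package: aptadock
Title: Ensemble Docking of Flexible Receptors and DNA Aptamers with
    Elastic-Network Conformers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale ensemble docking pipeline for predicting complexes
    between a flexible homodimeric two-domain receptor (a VEGF165-like
    protein, whose two heparin-binding domains swing on flexible linkers)
    and mono- or heterodimeric DNA aptamers. Conformational ensembles are
    generated along low-frequency anisotropic-network-model normal modes at
    prescribed centre-of-mass distances, cross-docked by FFT shape
    complementarity with exhaustive rotational sampling, filtered by
    domain-attachment criteria, re-scored with a single-trajectory
    MM/GBSA-style end-point energy (generalized Born plus surface-area
    solvation, entropy omitted), and analysed geometrically: binding-pose
    taxonomy (sandwich/side/hug), hydrogen-bond census under distance and
    angle criteria, G-quadruplex core RMSD, and buried-interface (steric
    clash) area against a reference receptor partner. A seeded synthetic
    structure generator makes every stage testable without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
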