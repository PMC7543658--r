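Package: adpvalid
Title: Global and Local Analysis of Atomic Displacement Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Validation of macromolecular atomic displacement parameters
    (ADPs, B values). Models a structure's B-value distribution as a
    mixture of shifted inverse-gamma distributions fitted by
    expectation-maximization with a peak-height-transform / kernel-density
    / Gaussian-mixture staged initialization, and provides
    resolution-dependent local relative-occupancy estimators that flag
    atoms and ligands whose ADPs are inconsistent with their spatial
    neighbours. Includes a synthetic-fixture generator producing minimal
    coordinate files with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
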