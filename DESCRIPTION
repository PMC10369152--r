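Package: fdopapet
Title: Automated Quantification of Dynamic FDOPA PET with Reference-Region Patlak Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An automated analysis pipeline for dynamic 6-[18F]fluoro-L-dopa
    (FDOPA) PET neuroimaging: reading and writing 4D NIfTI-1 volumes with
    PET-BIDS style frame-timing sidecars, radioisotope decay correction,
    frame-to-frame rigid-body realignment with framewise-displacement and
    motion-spike quality control, Chambolle total-variation denoising,
    Gjedde-Patlak reference-region graphical analysis (region-wise and
    voxel-wise Ki maps) with a cerebellar reference, standardized uptake value
    ratios (SUVr), and test-retest reliability statistics (two-way mixed ICC,
    within-subject percent variability, Bland-Altman limits of agreement).
    Includes a compartmental-kinetics digital phantom generator with known
    ground truth so every pipeline stage can be validated without access to
    clinical archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    deSolve,
    minpack.lm,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
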