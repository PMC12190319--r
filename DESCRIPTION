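Package: larvaquant
Title: Quantification Pipelines for Larval Zebrafish Cardiac, Behavioral
    and Brain Imaging Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable, tested implementations of four quantification
    procedures used in larval zebrafish phenotyping: dual-chamber cardiac
    rhythm analysis with atrioventricular-block classification and
    regime-switch detection from intensity time series; seizure-like
    locomotor episode scoring from 10 Hz tracking using an empirically
    calibrated large-movement threshold; whole-brain dF/F activity
    mapping from slow-rate fluorescence series; and voxel-based
    morphometry statistics on registered log-Jacobian and channel
    intensity maps, including permutation-calibrated cluster inference
    and bilateral symmetrization. A synthetic-data module generates all
    input classes with planted ground truth so that every stage of the
    pipeline can be validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    igraph,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
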