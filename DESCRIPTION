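Package: ctfparc
Title: Cross-Talk-Informed Cortical Parcellation and Simulated Connectomes
    for EEG/MEG Source Space
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Derives cortical parcellations adapted to the spatial
    resolution of linear EEG/MEG source estimates. Cross-talk functions
    (rows of the resolution matrix of an L2 minimum-norm inverse operator)
    drive a non-iterative split-and-merge modification of an initial atlas
    and a region-growing segmentation that needs no atlas at all. Parcel
    resolution matrices summarise between-parcel leakage and yield
    sensitivity and distinguishability indices, rank and condition numbers.
    A simulation suite generates multi-subject synthetic forward models,
    event-related source-space networks with controlled connectivity and
    signal-to-noise ratio, leakage projection through per-subject forward
    and inverse operators, multitaper coherence and imaginary-coherency
    reconstruction, and max-statistic permutation scoring of reconstructed
    network edges against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
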