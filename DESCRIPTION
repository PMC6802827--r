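Package: cartstate
Title: Cartilage State Discrimination from Multiplex Secretome Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling cartilage tissue state from multiplex
    bead-array (xMAP/Luminex) secretome responses to a combinatorial
    cytokine stimulation panel. Implements plate-level preprocessing of
    median fluorescence intensities (blank filtering, nearest-neighbour
    imputation, bounded normalized-difference transformation), effect-size
    ranking of baseline protein releases (Cohen's d with unpaired t-tests),
    unsupervised state assignment (PCA with k-means on leading components),
    sequential Fisher-criterion orthonormal discriminant projections
    (OOS-DA), and exhaustive pairwise protein-subset selection under a
    resampled between/within-class separation score. A synthetic plate
    simulator with lognormal assay noise, blank/saturation artefacts and
    plantable state-dependent responses makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
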