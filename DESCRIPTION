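Package: vipgradient
Title: Seed-Based Functional-Connectivity Gradient Analysis with a Synthetic
    Resting-State Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for seed-based resting-state functional-connectivity
    gradient analysis of the macaque ventral intraparietal area (VIP): time
    series preprocessing (band-pass filtering, nuisance regression, motion
    scrubbing, Gaussian smoothing), per-run seed correlation maps with Fisher
    r-to-z transformation, per-subject t-test aggregation and group averaging,
    volume-to-surface projection, eight-way multi-seed overlap categorization
    with RGB encoding and composition tables, and atlas-parcel statistics
    (Kruskal-Wallis with Benjamini-Hochberg correction, seed-preference
    classification). Ships a multi-subject synthetic resting-state phantom
    generator with planted seed-specific connectivity and ground-truth
    categories so the whole pipeline can be exercised and validated end to
    end without access to animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
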