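Package: daquant
Title: Quantification of Dopamine-System Recordings: Bursts, Surrogate
    Permutation Tests, Photometry and Spine Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke quantification steps used in
    dopamine-system electrophysiology and imaging studies: Grace-style
    burst detection on spike trains with the percent-spikes-within-bursts
    (%SWB) statistic and putative dopamine-neuron inclusion criteria; a
    surrogate-based permutation test for two-group mean differences with
    an exceedance-count significance rule; dual-channel fiber-photometry
    processing (isosbestic correction, dF/F, baseline z-scoring,
    peri-event alignment and 5-s binned AUC); and dendritic spine and
    varicosity morphometry (thin/mushroom classification at 350 nm,
    density normalization). Includes seeded synthetic-data generators
    with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
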