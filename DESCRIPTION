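Package: glacierSIP
Title: Single-Cell and Bulk Stable-Isotope-Probing Rates for Glacier Ice Algae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual 13C/15N stable-isotope-probing
    experiments on supraglacial microbial communities: isotope bookkeeping
    (atom percent, atom percent excess, tracer-pool mixing), bulk EA-IRMS
    assimilation and growth rates, single-cell HR-SIMS region-of-interest
    quantification from ion-count images, cell geometry to dry weight to
    elemental content, per-cell fixation and growth rates, SEM-EDS C:N:P
    stoichiometry, scaling of single-cell rates to the community with
    first-order error propagation, and a synthetic-experiment generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
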