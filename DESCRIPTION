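Package: bbbced
Title: Rule-Based Triage of Chemotherapeutics for Blood-Brain Barrier
    Passage and Convection-Enhanced Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens anticancer drugs for their likelihood of passive
    diffusion across an intact blood-brain barrier and their suitability
    for local administration via convection-enhanced delivery (CED), as
    applied to diffuse intrinsic pontine glioma (DIPG). Three binary
    physicochemical criteria (lipophilicity, molecular weight, molecular
    charge at physiological pH) are summed into a systemic-delivery score
    with configurable thresholds; a separate charge/prodrug/formulation
    rule set classifies CED suitability. Ships a curated knowledge base of
    drugs historically administered to DIPG patients together with efflux
    transporter annotations, a Henderson-Hasselbalch microspecies module
    for computing percent ionization from pKa values, a deterministic
    synthetic record generator for property testing, and reconciliation
    tooling that pins computed labels against the published reference
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
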