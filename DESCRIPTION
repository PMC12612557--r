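Package: crcscreen
Title: Microsimulation of Colorectal Cancer Screening Under Real-World Adherence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An annual-cycle microsimulation of the colorectal-cancer
    adenoma-carcinoma natural history with race- and gender-specific
    real-world screening adherence (initial uptake, repeat adherence,
    modality switching, diagnostic follow-up and surveillance), plus the
    surrounding analysis machinery: calibration of progression and
    adherence parameters to weighted summary targets by adaptive search,
    discounted cost and quality-adjusted life-year accounting, ICER
    ladders with simple and extended dominance, net monetary benefit,
    and one-way and probabilistic sensitivity analyses with
    cost-effectiveness acceptability curves. Ships a synthetic-data
    generator so the full pipeline runs end-to-end from known-truth
    inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
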