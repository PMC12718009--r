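Package: prematingRI
Title: Premating Reproductive Isolation Between Plant Ecotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies premating reproductive isolation between plant
    ecotypes from ecological field data. Provides insect colour-vision
    modelling of floral reflectance spectra (bee colour hexagon and fly
    colour-opponent coding), circular statistics for flowering phenology
    (Mardia-Watson-Wheeler tests), post-processing of habitat-suitability
    surfaces into binary ranges and overlap summaries, pollination-network
    statistics (visitation rate, pollinator importance, H2' specialization),
    and directional barrier-strength (RI) estimation with sequential
    composition of barriers and bootstrap confidence intervals. Includes a
    synthetic ecotype-complex generator with exactly computable ground-truth
    barrier strengths for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
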