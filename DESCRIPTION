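Package: pdfert
Title: Proximate-Determinants Decomposition of Fertility from Survey Microdata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Bongaarts proximate-determinants model of
    fertility for DHS-style woman-level survey microdata: survey-weighted
    age-specific and total fertility rates, the four fertility-inhibiting
    indices (marriage, contraception, induced abortion, postpartum
    infecundability), predicted fertility, residuals and logarithmic
    percent contributions, computed nationally and by population stratum
    with small-cell suppression. Includes a synthetic-cohort generator
    with closed-form true index values for end-to-end validation, an
    allocation of aggregate abortion counts to subgroups proportional to
    unmet need for contraception, and delimited-text input/output for
    microdata and results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
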