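Package: PanelBurden
Title: Carrier-Burden Analysis of Pathogenic Variation in a Hereditary
    Gynecologic Cancer Gene Panel
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-burden analysis of germline pathogenic variation in a
    17-gene hereditary breast, ovarian and endometrial cancer panel. Implements
    a three-stage variant prefilter (functional effect, population frequency,
    ClinVar status, with a known-pathogenic bypass), an ACMG/AMP classification
    engine with ClinGen-style loss-of-function handling and point-based
    evidence combination, and per-gene carrier-burden statistics (carrier
    frequencies, odds ratios with Woolf confidence intervals, two-tailed
    chi-square tests) against a control population. A synthetic-cohort
    generator produces annotated variant tables with configurable per-gene
    carrier prevalences and truth-class annotation regimes so that the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
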