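Package: germscreen
Title: Simulation and Analysis of a High-Throughput Germline Aneuploidy Screen
    in C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse a large-object flow-cytometry
    (worm sorter) screen for environmental chemicals that induce X-chromosome
    nondisjunction in the Caenorhabditis elegans germline, together with its
    follow-up assays. Includes a generative simulator of worm broods, sorter
    event streams (time-of-flight and GFP peak height), germline cytology
    (RAD-51 focus zone profiles, germ-cell corpses, diakinesis DAPI-body
    morphology) and qPCR Ct tables; adult-gate and GFP-threshold calibration
    from reference strains; well scoring, fold-increase aggregation and
    benchmark-based hit calling; exact tie-aware Mann-Whitney and two-sided
    Fisher tests; delta-delta-Ct relative quantification with germline versus
    soma attribution via a temperature-sensitive germline-less mutant; and
    chemical-library dose arithmetic (Hill-notation formula parsing, molar
    mass, micromolar to microgram-per-millilitre conversion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
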