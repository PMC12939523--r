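Package: phycocarbon
Title: Carbon Balance of Phycocyanin Production with Biostimulant Soil
    Carbon Crediting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the integrated carbon-balance assessment of
    phycocyanin (Spirulina blue food colorant) production whose extraction
    waste stream is applied as a soil biostimulant. Implements color-unit
    arithmetic and the product/waste mass balance per functional unit,
    linear life-cycle inventory characterization (GWP100 and other
    categories from user-supplied factor tables), soil organic carbon
    sequestration crediting with reversal buffer and uncertainty margin,
    net per-unit footprints with one-at-a-time sensitivity and scenario
    analysis, product- and corporate-level substitution case studies, and
    nonparametric statistics for two-site soil-core field trials, together
    with a seeded synthetic field-trial generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
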