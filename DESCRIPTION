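Package: emspath
Title: Retrosynthetic Pathway Design in an Extended Metabolic Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design of heterologous biosynthesis pathways for a chassis
    organism such as Escherichia coli. Compounds are coded as molecular
    signatures (multisets of canonical atomic-neighborhood strings at a
    tunable diameter d); reaction rules are derived as signed signature
    differences and applied to all combinations of known metabolites to
    extend a metabolic network with putative promiscuous reactions.
    Target-producing pathways are enumerated as elementary flux modes of
    the retrosynthetic scope and ranked on gene availability, toxicity,
    maximum allowable yield estimated by flux balance analysis, and Gibbs
    free energy, with top gene constructs listed per pathway and SBML
    export of the results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
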