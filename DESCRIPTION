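Package: BiotransMS
Title: Biotransformation-Guided Metabolite Annotation for High-Resolution LC-MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for in vivo / in vitro drug-metabolite identification from
    high-resolution LC-MS peak tables. Provides exact monoisotopic-mass,
    ring-double-bond (RDB) and ppm-error arithmetic on elemental formulas;
    combinatorial enumeration of candidate metabolites from a parent compound
    through a configurable library of biotransformation reactions (hydrolysis,
    glucuronidation, sulfation, hydroxylation, methylation, and composites);
    neutral-loss assignment and diagnostic-ion evidence flags for MS/MS
    fragment ladders; an end-to-end annotation pipeline over multi-matrix
    peak tables with per-matrix presence and peak-area summaries; directed
    metabolic-pathway graph reconstruction; and metabolite-target(-pathway)
    network construction with degree accounting. A seeded synthetic-data
    generator emulates peak tables, MS/MS spectra and target assignments for
    validation, and transcribed reference tables for the stilbene glucoside
    mulberroside A are included as package fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
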