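Package: odmcde
Title: Semantic Comparison of UMLS-Annotated Clinical Forms and Common
    Data Element Extraction
Version: 0.1.0
Authors@R:
    person("odmcde", "maintainers", email = "odmcde@example.org",
           role = c("aut", "cre"))
Description: Tools for semantic comparison of clinical documentation
    forms. Reads and writes CDISC ODM 1.3 metadata files whose item
    definitions carry UMLS concept annotations (CUIs), enforces coding
    principles (pre-/postcoordination, code cleaning via declarative
    remapping), computes concept frequency tables, annotation coverage,
    cumulative coverage curves, and pairwise relative-overlap statistics
    between documentation contexts, and derives a filtered, categorized
    common-data-element (CDE) list. Includes a seeded synthetic
    form-corpus generator with a Zipf concept model for fully
    reproducible, download-free testing, and a command-line interface
    covering the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    yaml,
    digest,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
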