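Package: isardf
Title: Semantic Conversion of ISA-Tab Experimental Metadata to RDF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Parses ISA-Tab archives (investigation, study and assay
    tables) into a faithful in-memory model, recovers the directed
    acyclic experiment graph underlying the tabular representation, and
    converts it to RDF under pluggable ontology mapping files (OBI,
    SIO, PROV-O style or user supplied). IRIs are minted with a
    per-type counter policy, user-provided ontology annotations are
    exploited to type individuals, and study groups (combinations of
    factor values) are inferred and added with their sizes. A suite of
    design-interrogation queries reports factors, levels, group sizes
    and balance, and can annotate balanced designs with a new triple.
    Includes a seeded synthetic ISA-Tab archive generator with
    machine-readable ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
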