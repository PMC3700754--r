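Package: chemblrdf
Title: Convert ChEMBL-Schema Bioactivity Data to Linked Open Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps relational bioactivity data following the ChEMBL 13 schema
    onto RDF triples using community ontologies (CHEMINF, ChEBI, PRO, BFO,
    BIBO, CiTO): molecules and protein targets as ontology classes, assays
    and activities as instances, chemical descriptors via the CHEMINF
    attribute-value pattern, and graded cross-database link-outs (ChemSpider,
    OpenMolecules, Bio2RDF, CrossRef). Includes a synthetic snapshot
    generator emulating the source schema, Turtle and N-Triples
    serialization, SPARQL-style count validation of the conversion,
    a bounded-description dereferencing layer with content negotiation,
    and application queries for compound selectivity and citation counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glue,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    DBI,
    RSQLite,
    httpuv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
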