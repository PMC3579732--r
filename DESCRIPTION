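Package: phenosem
Title: Semantic Annotation and Cross-Species Comparison of GWAS Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for harmonising genome-wide association study (GWAS)
    phenotype descriptions against controlled vocabularies and publishing the
    resulting genotype-phenotype associations as Linked Data. Free-text trait
    descriptions are normalised (value stripping, depluralisation, spelling
    variant neutralisation), lexically matched (exact and wildcard-style
    partial) against OBO-format ontologies and MeSH descriptor tables, and the
    per-vocabulary suitability statistics computed. Disease annotations are
    expanded to inferred phenotypic abnormalities through MeSH-UMLS-HPO and
    HPO-OMIM mapping chains. A four-step human-mouse comparison pipeline
    retrieves ontology-annotated phenotypes for gene orthologs through
    pluggable data-source adapters, and key associations are emitted as RDF
    nanopublications (named graphs, N-Quads/Turtle/RDF-XML) with canned SPARQL
    queries. Synthetic fixture generators exercise every component offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
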