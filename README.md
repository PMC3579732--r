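# phenosem

Semantic annotation and cross-species comparison of GWAS phenotypes.

Genome-wide association studies (GWAS) describe the phenotypes they test as
free text, with all the editorial variation that implies: "Hair color: black
versus red" and "Hair colours" are the same trait to a biologist but not to a
database. `phenosem` implements a complete methodology for harmonising such
descriptions against controlled vocabularies and publishing the resulting
genotype–phenotype associations as Linked Data. It is aimed at curators and
bioinformaticians who maintain genotype–phenotype resources and need to
(a) choose a vocabulary that actually covers their trait list, (b) attach
ontology annotations to experiments and exploit them for querying, and
(c) exchange the key associations in machine-readable RDF.

## What it does

**Trait normalisation.** Free-text phenotype descriptions are converted to
traits in three steps: value clauses are stripped ("Hair color: black versus
red" → "Hair color"), words are singularised by a conservative rule ladder
with an explicit exception list ("Triglycerides" → "Triglyceride", but
"diabetes" is untouched), and British/American spelling differences are
neutralised by generating both forms from a packaged, user-replaceable
variant table ("oesophagus" ↔ "esophagus").

**Lexical matching and vocabulary suitability.** Normalised traits are
matched against OBO-format ontologies and simplified MeSH descriptor tables,
case-insensitively, in two modes: *exact* (string equality against labels and
synonyms) and *partial*, which emulates wildcard search — a `*` is implicitly
appended to every query word, so a hit requires each query token to be a
prefix of a candidate token, in order. For a corpus of `N` traits compared
against vocabularies `V1..Vk`, the suitability table reports per vocabulary
the coverage `100 · n_mapped / N` and the *unique* coverage
`100 · n_unique / n_mapped_anywhere` (a unique mapping is a trait matching in
exactly one vocabulary), for both modes, rounded half-up to one decimal.

**Mapping chains.** MeSH disease Descriptors join to HPO phenotypic
abnormalities through shared UMLS concept unique identifiers (CUIs), and
expand to *inferred* abnormality sets via OMIM
(MeSH → OMIM → HPO). Every phenotype annotation resolves through exactly one
route — direct manual HPO, CUI-mapped HPO, OMIM-inferred set — or is
explicitly tagged `mesh-only`.

**Annotation store.** A light study → experiment → phenotype / marker /
association data model with annotated-hierarchy browsing (pruned to used
terms, with unique-experiment counts), descendant-aware term queries and
auto-suggest over annotated terms only.

**Human–mouse comparison pipeline.** From a list of human gene symbols:
validate symbols, find mouse orthologs, retrieve human GWAS annotations
passing a p-value threshold `10^-e`, and mouse MPO annotations from a mouse
genome database and a high-throughput phenotyping source (the latter filtered
at a significance limit). Data sources are pluggable adapters; offline
fixture adapters ship with the package.

**Nanopublications.** Associations with `p < 1e-5` are wrapped per experiment
into nanopublications — head, assertion, condition and provenance named
graphs — and serialized as N-Quads (or triples-only Turtle/RDF-XML), with two
canned SPARQL queries plus an in-memory evaluator for them.

## Worked example

```r
library(phenosem)

report <- run_comparison(
  pipeline_params("BAZ1B",
                  gwas_threshold_exponent = 7,        # p <= 1e-7
                  europhenome_significance_limit = 0.00001),
  fixture_adapters(make_table2_fixture()))
glance(report)
#> # A tibble: 1 × 5
#>   n_genes n_rejected n_gwas_central n_europhenome n_mgd
#>     <int>      <int>          <int>         <int> <int>
#> 1       1          0              3             3    28
```

The BAZ1B gene yields 3 human GWAS annotations (Plasma; Protein C;
Triglycerides — the last carried by marker rs1178979 at p = 2e-12), 3
high-throughput mouse phenotyping annotations (including decreased
circulating cholesterol at p = 7.76e-7 and decreased circulating HDL
cholesterol at p = 8.20e-6) and 28 literature-derived mouse annotations.
Both species independently point at circulating-lipid phenotypes.

Matching a trait list and scoring vocabularies:

```r
b   <- make_toy_vocabularies()
res <- map_corpus(c("Forced expiratory volumes", "number of teeth"),
                  list(b$mesh, b$hpo))
suitability_table(res)
#>   vocabulary n_exact n_partial pct_exact pct_partial n_unique_exact n_unique_partial pct_unique_exact pct_unique_partial
#> 1 MeSH             1         1        50          50              1                1              100                 50
#> 2 HPO              0         1         0          50              0                1                0                 50
```

"Forced expiratory volumes" exact-matches the MeSH heading after
normalisation; "number of teeth" only partial-matches the HPO term
"Abnormal number of teeth" (the wildcard search tolerates the extra leading
word), so it counts towards partial coverage and is unique to HPO.

## Package layout

| Path | Contents |
| --- | --- |
| `R/ontology_model.R` | OBO / MeSH-table parsing, DAG traversal, validation |
| `R/trait_normalizer.R` | value stripping, depluralisation, spelling variants |
| `R/term_matcher.R` | exact/partial matching, suitability statistics |
| `R/mapping_chain.R` | MeSH↔HPO via UMLS CUIs, OMIM inference, resolution |
| `R/annotation_store.R` | study/experiment/marker/association store |
| `R/crossspecies_pipeline.R` | ortholog pipeline over adapter interfaces |
| `R/nanopub_builder.R` | nanopublication assembly, RDF serialization, queries |
| `R/synthetic_fixtures.R` | offline generators for all of the above |
| `inst/scripts/phenosem.R` | command-line wrapper (`match`, `stats`, `query`, `pipeline`, `nanopub`, `fixtures`) |
| `vignettes/phenosem-methods.Rmd` | the methods vignette |
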