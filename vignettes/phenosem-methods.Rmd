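---
title: "Methods: normalising, matching and publishing GWAS phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalising, matching and publishing GWAS phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosem)
```

# The problem

Genotype–phenotype databases collect association results from many studies,
each describing its phenotypes in free text. Identical traits end up under
different strings — plural vs singular, British vs American spelling, trait
vs trait-with-value ("Hair color: black versus red"). Without harmonisation
a query for a phenotype cannot retrieve all relevant experiments, and
cross-database or cross-species comparison is impossible. `phenosem`
implements the full processing chain: text normalisation, lexical mapping to
candidate vocabularies with suitability scoring, disease-to-abnormality
mapping chains, an ortholog-based human–mouse comparison pipeline, and RDF
nanopublication output.

This vignette documents the models and procedures, the tunable parameters
with their defaults, the numerical choices, and what the synthetic test data
do and do not demonstrate.

# Trait normalisation

Normalisation runs three steps, in order, via `normalize_traits()`:

1. **Value stripping** (`strip_trait_values()`). A phenotype is a trait with
   a value; vocabularies describe traits. The heuristic removes everything
   after the first colon and any trailing "versus …" clause, then collapses
   whitespace. Deciding whether a description is a trait or a phenotype is
   ultimately a curatorial judgement, so this step is deliberately
   conservative and every description it changes is flagged
   (`value_stripped` column) for curator review — the heuristic assists the
   human step rather than replacing it.
2. **Depluralisation** (`depluralize()`). Vocabularies express concepts in
   the singular. Each word passes a rule ladder: `…ies → …y` (words longer
   than four characters, so "caries" is protected by the exception list and
   "dies" by length); sibilant endings `sses/xes/ches/shes/zes` drop `es`;
   otherwise a trailing `s` is dropped unless the word ends in `ss`, `us` or
   `is`. We use the standard sibilant ladder rather than dropping `es` after
   every `…ses` ending because the latter corrupts regular plurals
   ("diseases" must become "disease", not "diseas"). An explicit,
   versioned exception list (`inst/extdata/plural_exceptions.txt`) protects
   disease names and mass nouns ("diabetes", "pertussis", "measles"):
   naive stemming corrupts exactly the vocabulary we care about.
3. **Spelling-variant neutralisation** (`expand_spelling_variants()`).
   British and American spellings are not synonyms in all ontologies (an
   ontology may hold "Abnormality of the esophagus" without the
   "oesophagus" form). A packaged two-column table of ~130 word pairs
   (`inst/extdata/spelling_variants.tsv`, modelled on public
   British/American spelling lists and user-replaceable, since any given
   snapshot of such a list ages) is applied symmetrically: for each word
   with an entry, one alternative term is generated with that single word
   substituted. Alternatives are *queried only when the base form finds
   nothing in a given vocabulary* — the fallback is per-vocabulary, so a
   vocabulary that knows both spellings is never double-counted.

Case is preserved for display; all matching is case-insensitive.
Normalisation is idempotent on its own output, and value-stripping never
lengthens a string — both are enforced by property tests.

# Lexical matching and the suitability statistics

Matching emulates ontology-portal term search. **Exact** mode is
case-insensitive string equality between a trait form and a term's label or
any synonym; synonym scope markers are ignored, every synonym is a
candidate. **Partial** mode emulates wildcard search in which a `*` is
appended to every query word: a candidate matches iff every query token is a
prefix of some candidate token, tokens consumed left-to-right in order, with
extra candidate tokens allowed anywhere. So "number of teeth" hits
"Abnormal number of teeth", and "forced expiratory volume" hits
"Normal forced expiratory volume". Requiring token *order* is a design
choice the portal behaviour leaves open: it reproduces all the worked
partial-match examples while rejecting scrambled false positives, and is
checked against an independent regex oracle in the tests. Greedy left-most
consumption is exact for this containment relation, so matching is linear in
the candidate length.

For a corpus of $N$ traits against vocabularies $V_1..V_k$, a trait *maps*
to a vocabulary if at least one term matches (multiplicity is irrelevant —
the statistics count descriptions, not hits), and maps *uniquely* if it maps
in exactly one vocabulary. `suitability_table()` reports per vocabulary and
mode the coverage $100\,n/N$ and unique coverage $100\,u/M$, where $M$ is
the number of traits mapped in that mode to at least one vocabulary.
Percentages are rounded **half-up** to one decimal (`round_half_up()`), the
convention that reproduces all printed percentage cells from their count
pairs; the arithmetic path is exposed as `suitability_from_counts()` so the
statistics can be recomputed from published counts alone. Note the absolute
counts of any particular historical corpus are reproducible only with that
corpus and those ontology snapshots; what the package guarantees (and
tests, via corpora with planted ground truth) is the statistic computation
itself.

# Mapping chains: MeSH ↔ HPO ↔ OMIM

MeSH describes diseases and traits at every granularity; HPO describes
individual phenotypic abnormalities. The two are joined through the UMLS
concept unique identifier (CUI): an HPO term carries a `UMLS:C…`
cross-reference in its source ontology file, a MeSH-to-CUI table supplies
the other half, and `build_cross_map()` pairs ids that resolve to the same
CUI. UMLS itself is never accessed — licensing cannot be assumed — so the
MeSH–CUI table is a user-supplied or fixture TSV. When one CUI is claimed by
several MeSH descriptors all pairs are kept and a warning names the CUIs:
dropping data silently would hide exactly the cases a curator must decide.

A disease Descriptor has no single HPO equivalent; instead
`inferred_phenotypes()` follows MeSH → OMIM (a small, manually assigned
two-column table) → HPO (the disease-annotation file format:
`database_id`, `disease_name`, `hpo_id`), returning abnormality sets grouped
under the OMIM entry they came from. These phenotypes are *inferred*: study
participants were diagnosed with the disease, but which manifestations each
participant actually had is unknowable from a summary-level report.

`resolve_annotation()` applies the precedence **direct > mapped >
inferred**: a manual HPO annotation is the most specific information
available and beats the automatic routes; the mapped route beats inference
because it is term-to-term rather than term-to-set. Annotations with no HPO
route at all are returned tagged `mesh-only` rather than dropped, so
incomplete mapping tables are visible in the output. Inferred sets are
unions over OMIM entries, hence monotone under table growth.

# The annotation store

The store models the minimal relational subset needed for annotation-driven
querying: studies, experiments (phenotypes are annotated per *experiment*,
not per publication — one study may test many traits), markers and
association p-values in $(0, 1]$. A closest-match annotation (the exact
Descriptor does not exist, so a nearby — usually parent — Descriptor was
chosen) must carry a note and is flagged. Hierarchy browsing
(`annotated_hierarchy()`) prunes a vocabulary to annotated terms plus their
ancestors (marked structural), each carrying its count of distinct
experiments. Whether such counts should be direct or cumulative over
descendants is genuinely ambiguous in the interfaces this models; we default
to **direct** counts, matching the "annotated to that term" reading, and
provide `cumulative = TRUE` for the subtree reading. Auto-suggest only
offers labels and synonyms of terms actually used in annotations, so users
are never led to empty results.

# The human–mouse comparison pipeline

`run_comparison()` executes four steps: validate human gene symbols →
determine mouse orthologs → retrieve human GWAS annotations (MeSH) passing
the p-value threshold → retrieve mouse MPO annotations from the
literature-curated source and from high-throughput phenotyping (the latter
filtered at the significance limit). The original services are volatile web
APIs; the package defines them as an adapter interface of five pure lookup
functions (`fixture_adapters()` builds them from TSVs or in-memory tables),
which makes runs deterministic and testable. Invalid symbols are reported,
not fatal; an all-invalid list is an error.

Parameters: `gwas_threshold_exponent` $e$ (default 7) gives threshold
$10^{-e}$ — we read the conventional "10e-7" shorthand as $1\times10^{-7}$ —
and `europhenome_significance_limit` (default $10^{-5}$). Both boundaries
are **inclusive** ($\le$): a result printed at exactly the threshold is
conventionally reported as passing, and the packaged worked example is
insensitive to the choice since no fixture p-value sits on a boundary. The
packaged fixture reproduces the published BAZ1B example (3 human, 3
high-throughput mouse, 28 literature mouse annotations); the p-values that
example does not print are synthetic values below the respective thresholds
and are tagged in the fixture's `synthetic` column, as are identifiers with
no printed source. Cross-species comparison of the resulting lists remains a
reporting/manual step: no automatic MPO↔HPO equivalence is computed, since
lexical equivalence across species-specific ontologies is exactly what this
class of method cannot assert.

# Nanopublications and RDF

Associations with $p < 10^{-5}$ (strict, per the "less than" convention for
key associations) are wrapped per experiment into a nanopublication of four
named graphs: **assertion** (association nodes linking marker and phenotype
IRIs with `xsd:double` p-value literals, plus MeSH/HPO annotation links),
**condition** (sample panel, analysis method — may be empty, with a
warning), **provenance** (source study, publication reference, title) and a
**head** graph enumerating the parts, following nanopublication guidelines:
without a head, a quad dump of several nanopublications is not
self-describing. IRIs come from a configurable `uri_scheme()`; external
references (MeSH, OBO PURLs, PubMed, gene IRIs) are template prefixes, never
resolved at build time.

Serialization: N-Quads preserves graph structure; Turtle and RDF/XML are
triples-only projections emitted with a warning, since those formats cannot
carry named graphs. P-value literals use the shortest scientific-notation
string that round-trips to the same double, so "2e-12" is preserved
verbatim while arbitrary values survive parse → serialize exactly. The
emitters and the N-Quads parser are written in-package against the subset
they emit (IRIs and optionally datatyped literals; blank nodes are never
generated, which makes dataset equality a sorted-quad comparison rather
than graph isomorphism); the test suite additionally cross-checks the
emitted N-Quads against an independent RDF parser where one is available.

`canned_query()` returns the two supported SPARQL query texts (per-disease
association graph at a threshold; all terms from nanopublications passing a
p-value bound). Because the package does not run a triple store,
`run_canned_query()` evaluates the same two shapes — basic graph pattern
join plus numeric filter over the union of graphs — directly on the quad
table; tests verify it against direct filtering of the relational store.

# Synthetic data: what it shows and what it does not

`make_match_corpus()` builds corpora whose ground truth holds **by
construction**: exact plants copy a vocabulary label verbatim, partial
plants drop the label's distinctive leading token, variant plants swap one
word for its British spelling while the label carries the American form, and
filler traits share no token stem with any label. Planted fractions are
therefore recovered exactly, not in expectation — which is the point: it
tests the counting, not the sampling. `make_gwas_store()` draws p-values
from a two-piece log-uniform model (log10 p uniform on $(-12,-5)$ for key
associations, on $(-5,0)$ otherwise) with a Bernoulli key fraction, so the
sub-threshold proportion is controlled in expectation and checked against
binomial bounds. Test problem sizes — corpora of 100–200 traits, stores of
up to $10^4$ associations, oracle sweeps of $\le 10^4$ query×candidate
pairs — were chosen as the smallest sizes at which the properties are
non-trivial while keeping the full suite under a minute.

What passing these tests does **not** show: real trait lists contain typos,
abbreviations and clause structures the three-step normaliser does not
model (no lemmatisation, no abbreviation expansion, no spell checking);
real ontologies have much deeper hierarchies and denser synonymy than the
toy bundle; and real portal search may rank or tokenise differently than
the documented containment rule. The matcher's behaviour on the published
worked examples is pinned by tests, but corpus-level coverage numbers on
historical data depend on that data and those ontology snapshots.

# Known limitations

- Value stripping is a heuristic stand-in for curatorial trait/phenotype
  judgement; it flags its edits but cannot recognise clause structures
  beyond "colon value" and "versus".
- The depluralisation ladder is a reconstruction; irregular plurals outside
  the exception list ("analyses") are singularised mechanically.
- The CUI join is only as complete as the supplied MeSH–CUI table; absent
  rows silently shift annotations to the inferred or `mesh-only` routes
  (visible in the resolution report).
- RDF support covers the emitted subset (no blank nodes, no language tags);
  the canned-query evaluator handles the two shipped query shapes, not
  arbitrary SPARQL.
- Ontology files are read in an OBO 1.2-like dialect and a documented MeSH
  TSV dialect; native UMLS RRF and SNOMED RF2 distributions are out of
  scope.
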