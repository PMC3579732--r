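#' Genotype-phenotype associations as RDF nanopublications
#'
#' A nanopublication wraps one experiment's key associations into four
#' named graphs: a head graph linking the nanopublication to its parts,
#' an assertion graph (marker-phenotype associations with typed p-value
#' literals), a condition graph (sample panel and analysis method
#' context) and a provenance graph (source study, publication link,
#' attribution). Key associations are those with p-value strictly below
#' 1e-5. Datasets serialize to N-Quads; Turtle and RDF/XML are available
#' as triples-only projections (those formats cannot represent named
#' graphs).
#'
#' @name nanopub_builder
NULL

#' URI scheme for generated resources
#'
#' Templates for nanopublication, marker, phenotype and experiment IRIs
#' and the external-resource prefixes (MeSH, HPO, PubMed, genes). All
#' generated IRIs are absolute and stable across runs.
#'
#' @param base Absolute base IRI, slash-terminated.
#' @param mesh_prefix,hpo_prefix,pubmed_prefix,gene_prefix External IRI
#'   prefixes; HPO ids have their colon replaced by `_` under
#'   `hpo_prefix` (OBO PURL convention).
#' @return A `phenosem_uri_scheme` list.
#' @export
uri_scheme <- function(base = "http://example.org/gwas/",
                       mesh_prefix = "http://id.nlm.nih.gov/mesh/",
                       hpo_prefix = "http://purl.obolibrary.org/obo/",
                       pubmed_prefix = "http://www.ncbi.nlm.nih.gov/pubmed/",
                       gene_prefix = "http://bio2rdf.org/geneid:") {
  if (!grepl("^[a-z][a-z0-9+.-]*://", base)) abort("base must be an absolute IRI")
  if (!endsWith(base, "/")) base <- paste0(base, "/")
  structure(list(base = base, mesh_prefix = mesh_prefix,
                 hpo_prefix = hpo_prefix, pubmed_prefix = pubmed_prefix,
                 gene_prefix = gene_prefix),
            class = "phenosem_uri_scheme")
}

NS <- list(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  np = "http://www.nanopub.org/nschema#",
  dct = "http://purl.org/dc/terms/",
  prov = "http://www.w3.org/ns/prov#",
  xsd = "http://www.w3.org/2001/XMLSchema#"
)

scheme_iri <- function(scheme, what, id) {
  switch(what,
    nanopub = paste0(scheme$base, "nanopub/", id),
    marker = paste0(scheme$base, "marker/", id),
    phenotype = paste0(scheme$base, "phenotype/", id),
    experiment = paste0(scheme$base, "experiment/", id),
    study = paste0(scheme$base, "study/", id),
    vocab = paste0(scheme$base, "vocab#", id),
    mesh = paste0(scheme$mesh_prefix, id),
    hpo = paste0(scheme$hpo_prefix, gsub(":", "_", id)),
    pubmed = paste0(scheme$pubmed_prefix, id),
    abort(paste0("unknown resource kind: ", what))
  )
}

# shortest scientific-notation string that round-trips to the same double,
# so "2e-12" stays "2e-12" but nothing loses precision
format_double <- function(x) {
  vapply(x, function(v) {
    for (d in c(1:7, 15, 17)) {
      s <- format(v, scientific = TRUE, digits = d)
      if (as.numeric(s) == v) return(s)
    }
    format(v, scientific = TRUE, digits = 17)
  }, character(1))
}

empty_quads <- function() {
  dplyr::tibble(subject = character(), predicate = character(),
                object = character(), object_type = character(),
                datatype = character(), graph = character())
}

quad <- function(s, p, o, g, type = "iri", datatype = NA_character_) {
  dplyr::tibble(subject = s, predicate = p, object = o,
                object_type = type, datatype = datatype, graph = g)
}

#' Keep only key associations for nanopublishing
#'
#' Results with a p-value strictly below 1e-5 are deemed to show an
#' association and are included in nanopublications; everything else is
#' dropped.
#'
#' @param results Tibble of association results with a `p_value` column.
#' @param cutoff Inclusion cutoff (strict less-than), default 1e-5.
#' @return The filtered tibble.
#' @examples
#' filter_for_nanopubs(tibble::tibble(p_value = c(2e-12, 1e-5, 0.5)))
#' @export
filter_for_nanopubs <- function(results, cutoff = 1e-5) {
  stopifnot(is.data.frame(results), "p_value" %in% names(results))
  results[results$p_value < cutoff, , drop = FALSE]
}

#' Build one experiment's nanopublication
#'
#' @param experiment One-row tibble (or list) with `experiment_id`,
#'   `study_id`, `mesh_id`, optional `hpo_id`, `sample_panel`,
#'   `analysis_method`.
#' @param associations Pre-filtered associations for this experiment:
#'   `marker_accession`, `p_value`, optional `rs_id`, `gene_symbols`.
#' @param scheme A [uri_scheme()].
#' @param study Optional one-row study tibble (`study_id`, `pubmed_id`,
#'   `title`) for the provenance graph.
#' @return A `phenosem_nanopub`: list with `id` and `quads` (the four
#'   named graphs). An empty condition graph triggers a warning.
#' @export
build_nanopub <- function(experiment, associations, scheme = uri_scheme(),
                          study = NULL) {
  if (is.data.frame(experiment)) {
    stopifnot(nrow(experiment) == 1L)
    experiment <- as.list(experiment)
  }
  mesh_id <- experiment$mesh_id
  if (is.null(mesh_id) || is.na(mesh_id) || !nzchar(mesh_id)) {
    abort("experiment lacks a phenotype annotation (MeSH id required)")
  }
  if (!nrow(associations)) {
    abort("no associations supplied; filter first and skip empty experiments")
  }
  exp_id <- experiment$experiment_id
  np_iri <- scheme_iri(scheme, "nanopub", exp_id)
  g <- paste0(np_iri, "#", c("head", "assertion", "condition", "provenance"))
  names(g) <- c("head", "assertion", "condition", "provenance")
  gc_ <- function(x) scheme_iri(scheme, "vocab", x)
  pheno_iri <- scheme_iri(scheme, "phenotype", exp_id)
  exp_iri <- scheme_iri(scheme, "experiment", exp_id)

  head_q <- dplyr::bind_rows(
    quad(np_iri, paste0(NS$rdf, "type"), paste0(NS$np, "Nanopublication"), g[["head"]]),
    quad(np_iri, paste0(NS$np, "hasAssertion"), g[["assertion"]], g[["head"]]),
    quad(np_iri, gc_("hasCondition"), g[["condition"]], g[["head"]]),
    quad(np_iri, paste0(NS$np, "hasProvenance"), g[["provenance"]], g[["head"]])
  )

  assertion <- list(
    quad(pheno_iri, gc_("meshAnnotation"), scheme_iri(scheme, "mesh", mesh_id),
         g[["assertion"]])
  )
  hpo_id <- experiment$hpo_id
  if (!is.null(hpo_id) && !is.na(hpo_id) && nzchar(hpo_id)) {
    assertion <- c(assertion, list(
      quad(pheno_iri, gc_("hpoAnnotation"), scheme_iri(scheme, "hpo", hpo_id),
           g[["assertion"]])))
  }
  for (i in seq_len(nrow(associations))) {
    a <- associations[i, ]
    assoc_iri <- paste0(np_iri, "/association/", i)
    m_iri <- scheme_iri(scheme, "marker", a$marker_accession)
    assertion <- c(assertion, list(
      quad(assoc_iri, paste0(NS$rdf, "type"), gc_("Association"), g[["assertion"]]),
      quad(assoc_iri, gc_("involvesMarker"), m_iri, g[["assertion"]]),
      quad(assoc_iri, gc_("involvesPhenotype"), pheno_iri, g[["assertion"]]),
      quad(assoc_iri, gc_("pValue"), format_double(a$p_value),
           g[["assertion"]], type = "literal",
           datatype = paste0(NS$xsd, "double"))
    ))
    rs <- if ("rs_id" %in% names(a)) a$rs_id else NULL
    if (!is.null(rs) && length(rs) && !is.na(rs) && nzchar(rs)) {
      assertion <- c(assertion, list(
        quad(m_iri, gc_("rsId"), rs, g[["assertion"]], type = "literal")))
    }
    genes <- if ("gene_symbols" %in% names(a)) unlist(a$gene_symbols) else
      character()
    for (gs in genes) {
      assertion <- c(assertion, list(
        quad(m_iri, gc_("geneSymbol"), gs, g[["assertion"]], type = "literal")))
    }
  }
  assertion_q <- dplyr::bind_rows(assertion)

  condition <- list()
  for (fld in c("sample_panel", "analysis_method")) {
    v <- experiment[[fld]]
    if (!is.null(v) && !is.na(v) && nzchar(v)) {
      condition <- c(condition, list(
        quad(exp_iri, gc_(to_camel(fld)), v, g[["condition"]],
             type = "literal")))
    }
  }
  condition_q <- if (length(condition)) dplyr::bind_rows(condition) else {
    warn(sprintf("nanopub %s has an empty condition graph", exp_id))
    empty_quads()
  }

  prov <- list(
    quad(np_iri, paste0(NS$prov, "wasDerivedFrom"),
         scheme_iri(scheme, "study", experiment$study_id), g[["provenance"]])
  )
  if (!is.null(study)) {
    if (is.data.frame(study)) study <- as.list(study[1, ])
    if (!is.null(study$pubmed_id) && !is.na(study$pubmed_id) &&
        nzchar(study$pubmed_id)) {
      prov <- c(prov, list(
        quad(scheme_iri(scheme, "study", experiment$study_id),
             paste0(NS$dct, "references"),
             scheme_iri(scheme, "pubmed", study$pubmed_id), g[["provenance"]])))
    }
    if (!is.null(study$title) && !is.na(study$title) && nzchar(study$title)) {
      prov <- c(prov, list(
        quad(scheme_iri(scheme, "study", experiment$study_id),
             paste0(NS$dct, "title"), study$title, g[["provenance"]],
             type = "literal")))
    }
  }
  prov_q <- dplyr::bind_rows(prov)

  structure(list(id = np_iri,
                 quads = dplyr::bind_rows(head_q, assertion_q, condition_q,
                                          prov_q)),
            class = "phenosem_nanopub")
}

to_camel <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)[[1]]
  paste0(parts[1], paste0(toupper(substring(parts[-1], 1, 1)),
                          substring(parts[-1], 2), collapse = ""))
}

#' @export
print.phenosem_nanopub <- function(x, ...) {
  cat(sprintf("<phenosem_nanopub> %s: %d quads in %d graphs\n",
              x$id, nrow(x$quads), length(unique(x$quads$graph))))
  invisible(x)
}

#' Build nanopublications for every qualifying experiment in a store
#'
#' Applies the p < 1e-5 inclusion filter per experiment; experiments with
#' no passing association emit no nanopublication.
#'
#' @param store A [gwas_store()].
#' @param scheme A [uri_scheme()].
#' @return A `phenosem_nanopub_set`: list of `phenosem_nanopub` objects
#'   with the combined quad tibble available via [quad_dataset()].
#' @export
build_nanopubs <- function(store, scheme = uri_scheme()) {
  stopifnot(inherits(store, "phenosem_store"))
  key <- filter_for_nanopubs(store$associations)
  out <- list()
  for (i in seq_len(nrow(store$experiments))) {
    e <- store$experiments[i, ]
    assoc <- key[key$experiment_id == e$experiment_id, ]
    if (!nrow(assoc)) next
    mi <- match(assoc$marker_accession, store$markers$accession)
    assoc$rs_id <- store$markers$rs_id[mi]
    assoc$gene_symbols <- store$markers$gene_symbols[mi]
    study <- store$studies[store$studies$study_id == e$study_id, ]
    out <- c(out, list(build_nanopub(e, assoc, scheme,
                                     study = if (nrow(study)) study else NULL)))
  }
  structure(out, class = "phenosem_nanopub_set")
}

#' @export
print.phenosem_nanopub_set <- function(x, ...) {
  cat(sprintf("<phenosem_nanopub_set> %d nanopublication(s)\n", length(x)))
  invisible(x)
}

#' Combined quad tibble of a nanopublication (set)
#'
#' @param x A `phenosem_nanopub`, `phenosem_nanopub_set` or quad tibble.
#' @return Tibble with columns `subject`, `predicate`, `object`,
#'   `object_type`, `datatype`, `graph`.
#' @export
quad_dataset <- function(x) {
  if (inherits(x, "phenosem_nanopub")) return(x$quads)
  if (inherits(x, "phenosem_nanopub_set")) {
    if (!length(x)) return(empty_quads())
    return(dplyr::bind_rows(lapply(x, `[[`, "quads")))
  }
  stopifnot(is.data.frame(x))
  tibble::as_tibble(x)
}

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\r", "\r", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

term_nq <- function(value, type, datatype) {
  if (type == "iri") return(paste0("<", value, ">"))
  lit <- paste0("\"", escape_literal(value), "\"")
  if (!is.na(datatype)) lit <- paste0(lit, "^^<", datatype, ">")
  lit
}

#' Serialize quads to N-Quads, Turtle or RDF/XML
#'
#' N-Quads preserves the named-graph structure; Turtle and RDF/XML are
#' triples-only projections and a warning is raised when named graphs
#' would be flattened.
#'
#' @param x Quads (tibble, nanopub or nanopub set).
#' @param format One of `"nquads"`, `"turtle"`, `"rdfxml"`.
#' @return A single string of serialized RDF.
#' @export
serialize_rdf <- function(x, format = c("nquads", "turtle", "rdfxml")) {
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("nquads", "turtle", "rdfxml")) {
    abort(paste0("unknown format '", paste(format, collapse = ","),
                 "': use one of nquads, turtle, rdfxml"))
  }
  quads <- quad_dataset(x)
  switch(format,
    nquads = serialize_nquads(quads),
    turtle = serialize_turtle(quads),
    rdfxml = serialize_rdfxml(quads))
}

serialize_nquads <- function(quads) {
  if (!nrow(quads)) return("")
  lines <- paste(
    paste0("<", quads$subject, ">"),
    paste0("<", quads$predicate, ">"),
    mapply(term_nq, quads$object, quads$object_type, quads$datatype,
           USE.NAMES = FALSE),
    paste0("<", quads$graph, ">"),
    "."
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

warn_projection <- function(quads, format) {
  if (length(unique(quads$graph[!is.na(quads$graph)])) > 1L) {
    warn(paste0(format, " cannot represent named graphs; ",
                "emitting a triples-only projection"))
  }
}

serialize_turtle <- function(quads) {
  if (!nrow(quads)) return("")
  warn_projection(quads, "turtle")
  triples <- dplyr::distinct(quads, .data$subject, .data$predicate,
                             .data$object, .data$object_type, .data$datatype)
  lines <- paste(
    paste0("<", triples$subject, ">"),
    paste0("<", triples$predicate, ">"),
    mapply(term_nq, triples$object, triples$object_type, triples$datatype,
           USE.NAMES = FALSE),
    "."
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

split_iri <- function(iri) {
  m <- regmatches(iri, regexpr("^.*[#/]", iri))
  if (!length(m) || m == iri) abort(paste0("cannot split predicate IRI: ", iri))
  c(ns = m, local = substring(iri, nchar(m) + 1L))
}

serialize_rdfxml <- function(quads) {
  warn_projection(quads, "rdfxml")
  triples <- dplyr::distinct(quads, .data$subject, .data$predicate,
                             .data$object, .data$object_type, .data$datatype)
  pred_parts <- lapply(triples$predicate, split_iri)
  nss <- unique(c(NS$rdf, vapply(pred_parts, `[[`, character(1), "ns")))
  prefixes <- setNames(c("rdf", paste0("ns", seq_along(setdiff(nss, NS$rdf)))),
                       c(NS$rdf, setdiff(nss, NS$rdf)))
  xml_escape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  header <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n<rdf:RDF",
    paste0("\n  xmlns:", unname(prefixes), "=\"", xml_escape(names(prefixes)),
           "\"", collapse = ""),
    ">\n")
  body <- character()
  for (s in unique(triples$subject)) {
    rows <- which(triples$subject == s)
    props <- vapply(rows, function(i) {
      pp <- pred_parts[[i]]
      tag <- paste0(prefixes[[pp[["ns"]]]], ":", pp[["local"]])
      if (triples$object_type[i] == "iri") {
        paste0("    <", tag, " rdf:resource=\"",
               xml_escape(triples$object[i]), "\"/>")
      } else if (!is.na(triples$datatype[i])) {
        paste0("    <", tag, " rdf:datatype=\"",
               xml_escape(triples$datatype[i]), "\">",
               xml_escape(triples$object[i]), "</", tag, ">")
      } else {
        paste0("    <", tag, ">", xml_escape(triples$object[i]),
               "</", tag, ">")
      }
    }, character(1))
    body <- c(body,
              paste0("  <rdf:Description rdf:about=\"", xml_escape(s), "\">"),
              props, "  </rdf:Description>")
  }
  out <- paste0(header, paste(body, collapse = "\n"), "\n</rdf:RDF>\n")
  xml2::read_xml(out)  # raises if the document is malformed
  out
}

#' Parse an N-Quads document into a quad tibble
#'
#' Supports IRI and (optionally datatyped) literal objects, the subset the
#' package emits.
#'
#' @param text N-Quads text (single string or lines) or a file path.
#' @return Quad tibble as in [quad_dataset()].
#' @export
parse_nquads <- function(text) {
  lines <- read_text_lines(text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_quads())
  pat <- paste0(
    "^<([^>]*)>\\s+<([^>]*)>\\s+",
    "(<[^>]*>|\"(?:[^\"\\\\]|\\\\.)*\"(?:\\^\\^<[^>]*>)?)\\s+",
    "<([^>]*)>\\s*\\.$")
  m <- stringr::str_match(lines, pat)
  bad <- which(is.na(m[, 1]))
  if (length(bad)) {
    abort(sprintf("cannot parse N-Quads line %d: %s", bad[1], lines[bad[1]]))
  }
  obj <- m[, 4]
  is_iri <- startsWith(obj, "<")
  value <- character(length(obj))
  datatype <- rep(NA_character_, length(obj))
  value[is_iri] <- sub("^<(.*)>$", "\\1", obj[is_iri])
  lit <- obj[!is_iri]
  dt <- stringr::str_match(lit, "\\^\\^<([^>]*)>$")[, 2]
  lit_body <- sub("\\^\\^<[^>]*>$", "", lit)
  value[!is_iri] <- unescape_literal(sub("^\"(.*)\"$", "\\1", lit_body))
  datatype[!is_iri] <- dt
  dplyr::tibble(subject = m[, 2], predicate = m[, 3], object = value,
                object_type = ifelse(is_iri, "iri", "literal"),
                datatype = datatype, graph = m[, 5])
}

#' Canned SPARQL queries over the nanopublication dataset
#'
#' Use case 1: an RDF graph of genes, their associated markers and the
#' p-values for all key associations at a p-value threshold, restricted
#' to nanopublications about one MeSH Descriptor. Use case 2: all MeSH
#' and HPO terms (with external marker ids) from nanopublications with at
#' least one p-value at or below a bound.
#'
#' @param use_case `1` or `2`.
#' @param mesh_id MeSH Descriptor id (use case 1).
#' @param exponent Threshold exponent, p <= 10^-exponent (use case 1).
#' @param bound Numeric p-value bound (use case 2).
#' @param scheme A [uri_scheme()].
#' @return A single SPARQL query string.
#' @export
canned_query <- function(use_case, mesh_id = NULL, exponent = 7,
                         bound = 1e-10, scheme = uri_scheme()) {
  if (!use_case %in% c(1L, 2L)) {
    abort("unknown use case: only use cases 1 and 2 are provided")
  }
  gc_ <- function(x) scheme_iri(scheme, "vocab", x)
  if (use_case == 1L) {
    if (is.null(mesh_id) || !grepl("^D[0-9]+$", mesh_id)) {
      abort("use case 1 needs a MeSH Descriptor id (D-number)")
    }
    threshold <- 10^(-exponent)
    sprintf(paste0(
      "PREFIX gc: <%svocab#>\n",
      "SELECT ?marker ?gene ?pvalue WHERE {\n",
      "  ?assoc a gc:Association ;\n",
      "         gc:involvesMarker ?marker ;\n",
      "         gc:involvesPhenotype ?phenotype ;\n",
      "         gc:pValue ?pvalue .\n",
      "  ?phenotype gc:meshAnnotation <%s> .\n",
      "  OPTIONAL { ?marker gc:geneSymbol ?gene }\n",
      "  FILTER (?pvalue <= %s)\n",
      "}\n"),
      scheme$base, scheme_iri(scheme, "mesh", mesh_id),
      format(threshold, scientific = TRUE))
  } else {
    if (!is.numeric(bound) || bound <= 0) abort("use case 2 needs a positive bound")
    sprintf(paste0(
      "PREFIX gc: <%svocab#>\n",
      "SELECT DISTINCT ?phenotype ?term ?marker ?rsid WHERE {\n",
      "  ?assoc a gc:Association ;\n",
      "         gc:involvesMarker ?marker ;\n",
      "         gc:involvesPhenotype ?phenotype ;\n",
      "         gc:pValue ?pvalue .\n",
      "  { ?phenotype gc:meshAnnotation ?term }\n",
      "  UNION { ?phenotype gc:hpoAnnotation ?term }\n",
      "  OPTIONAL { ?marker gc:rsId ?rsid }\n",
      "  FILTER (?pvalue <= %s)\n",
      "}\n"),
      scheme$base, format(bound, scientific = TRUE))
  }
}

#' Evaluate a canned query shape over an in-memory quad dataset
#'
#' A quad-pattern evaluator implementing the two canned query shapes
#' (basic graph pattern join + numeric filter over the union of graphs),
#' so emitted datasets can be queried without a triple store.
#'
#' @param x Quads (tibble, nanopub or nanopub set).
#' @inheritParams canned_query
#' @return Use case 1: tibble `marker`, `p_value`, `gene_symbols`
#'   (list-column). Use case 2: tibble `phenotype`, `term`, `marker`,
#'   `rs_id`.
#' @export
run_canned_query <- function(x, use_case, mesh_id = NULL, exponent = 7,
                             bound = 1e-10, scheme = uri_scheme()) {
  if (!use_case %in% c(1L, 2L)) {
    abort("unknown use case: only use cases 1 and 2 are provided")
  }
  quads <- quad_dataset(x)
  gc_ <- function(p) scheme_iri(scheme, "vocab", p)
  po <- function(p) quads[quads$predicate == p,
                          c("subject", "object"), drop = FALSE]
  assoc_marker <- setNames(po(gc_("involvesMarker")),
                           c("assoc", "marker"))
  assoc_pheno <- setNames(po(gc_("involvesPhenotype")),
                          c("assoc", "phenotype"))
  assoc_p <- setNames(po(gc_("pValue")), c("assoc", "p_value"))
  assoc_p$p_value <- as.numeric(assoc_p$p_value)
  joined <- dplyr::inner_join(assoc_marker, assoc_pheno, by = "assoc") |>
    dplyr::inner_join(assoc_p, by = "assoc")
  if (use_case == 1L) {
    if (is.null(mesh_id)) abort("use case 1 needs a MeSH Descriptor id")
    mesh_iri <- scheme_iri(scheme, "mesh", mesh_id)
    pheno_mesh <- setNames(po(gc_("meshAnnotation")), c("phenotype", "mesh"))
    keep <- joined |>
      dplyr::inner_join(pheno_mesh[pheno_mesh$mesh == mesh_iri, ],
                        by = "phenotype") |>
      dplyr::filter(.data$p_value <= 10^(-exponent))
    gene_q <- po(gc_("geneSymbol"))
    keep$gene_symbols <- lapply(keep$marker, function(m)
      sort(unique(gene_q$object[gene_q$subject == m])))
    dplyr::arrange(dplyr::as_tibble(keep[, c("marker", "p_value",
                                             "gene_symbols")]),
                   .data$marker, .data$p_value)
  } else {
    terms <- dplyr::bind_rows(
      setNames(po(gc_("meshAnnotation")), c("phenotype", "term")),
      setNames(po(gc_("hpoAnnotation")), c("phenotype", "term")))
    rs_q <- po(gc_("rsId"))
    keep <- joined[joined$p_value <= bound, ]
    out <- dplyr::inner_join(keep, terms, by = "phenotype",
                             relationship = "many-to-many")
    out$rs_id <- rs_q$object[match(out$marker, rs_q$subject)]
    dplyr::distinct(dplyr::arrange(
      dplyr::as_tibble(out[, c("phenotype", "term", "marker", "rs_id")]),
      .data$phenotype, .data$term, .data$marker))
  }
}
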