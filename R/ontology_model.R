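#' Controlled vocabularies as traversable term graphs
#'
#' A `phenosem_vocabulary` holds the terms of one controlled vocabulary
#' (an HPO-style ontology, a MeSH descriptor set, ...) as a tibble with one
#' row per term and list-columns for synonyms, cross-references and parent
#' links. The parent links induce a directed acyclic graph used for
#' hierarchy browsing and closest-match annotation.
#'
#' @param name Vocabulary name (e.g. `"HPO"`, `"MeSH"`).
#' @param terms Tibble with columns `id` (character, unique, non-empty),
#'   `label` (character, non-empty), and list-columns `synonyms`, `xrefs`,
#'   `parents` (each a character vector per row).
#' @return A `phenosem_vocabulary` object.
#' @export
new_vocabulary <- function(name, terms) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  terms <- tibble::as_tibble(terms)
  needed <- c("id", "label", "synonyms", "xrefs", "parents")
  missing <- setdiff(needed, names(terms))
  if (length(missing)) {
    abort(paste0("vocabulary terms lack column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("synonyms", "xrefs", "parents")) {
    terms[[col]] <- lapply(terms[[col]], function(x) as.character(x %||% character()))
  }
  structure(list(name = name, terms = terms), class = "phenosem_vocabulary")
}

#' @export
print.phenosem_vocabulary <- function(x, ...) {
  cat(sprintf("<phenosem_vocabulary> %s: %d terms\n", x$name, nrow(x$terms)))
  invisible(x)
}

#' @rdname new_vocabulary
#' @param x A `phenosem_vocabulary`.
#' @param ... Unused.
#' @export
tidy.phenosem_vocabulary <- function(x, ...) {
  dplyr::mutate(x$terms, vocabulary = x$name, .before = 1L)
}

#' Parse an OBO 1.2-style ontology into a vocabulary
#'
#' Reads `[Term]` stanzas with `id`, `name`, `synonym`, `xref` and `is_a`
#' lines. Obsolete terms are skipped (they cannot be annotation targets).
#' Synonym scope markers (EXACT, BROAD, ...) are ignored: every synonym is a
#' match candidate. CURIE prefixes are preserved verbatim.
#'
#' @param obo Path to an OBO file, or a character vector of OBO lines.
#' @param name Vocabulary name; defaults to the `ontology:` header tag or
#'   `"OBO"` when absent.
#' @return A [new_vocabulary()] object.
#' @examples
#' obo <- c("[Term]", "id: HP:0000001", "name: All")
#' parse_obo(obo)
#' @export
parse_obo <- function(obo, name = NULL) {
  lines <- read_text_lines(obo)
  # split into stanzas; lines before the first stanza are the header
  stanza_starts <- grep("^\\[", lines)
  header <- if (length(stanza_starts)) lines[seq_len(max(stanza_starts[1] - 1L, 0L))] else lines
  if (is.null(name)) {
    ont <- stringr::str_match(header, "^ontology:\\s*(\\S+)")[, 2]
    ont <- ont[!is.na(ont)]
    name <- if (length(ont)) toupper(ont[[1]]) else "OBO"
  }
  if (!length(stanza_starts)) {
    return(new_vocabulary(name, empty_terms()))
  }
  bounds <- c(stanza_starts, length(lines) + 1L)
  rows <- vector("list", length(stanza_starts))
  for (i in seq_along(stanza_starts)) {
    first <- stanza_starts[i]
    body <- lines[seq(first, bounds[i + 1L] - 1L)]
    if (!identical(trimws(body[1]), "[Term]")) next
    rows[[i]] <- parse_obo_stanza(body[-1], line_offset = first)
  }
  rows <- purrr::compact(rows)
  terms <- if (length(rows)) dplyr::bind_rows(rows) else empty_terms()
  if (anyDuplicated(terms$id)) {
    abort(paste0("duplicate term id(s): ",
                 paste(unique(terms$id[duplicated(terms$id)]), collapse = ", ")))
  }
  vocab <- new_vocabulary(name, terms)
  rep <- validate_vocabulary(vocab)
  cyc <- rep$issue[rep$kind == "cycle"]
  if (length(cyc)) abort(paste0("cyclic is_a hierarchy: ", paste(cyc, collapse = "; ")))
  vocab
}

parse_obo_stanza <- function(body, line_offset) {
  tag_val <- function(tag) {
    hits <- stringr::str_match(body, paste0("^", tag, ":\\s*(.*?)\\s*(?:!.*)?$"))[, 2]
    hits[!is.na(hits)]
  }
  if (length(tag_val("is_obsolete")) && any(tolower(tag_val("is_obsolete")) == "true")) {
    return(NULL)
  }
  id <- tag_val("id")
  nm <- tag_val("name")
  if (!length(id) || !nzchar(id[[1]])) {
    abort(sprintf("malformed [Term] stanza near line %d: missing id", line_offset))
  }
  if (!length(nm) || !nzchar(nm[[1]])) {
    abort(sprintf("malformed [Term] stanza near line %d (%s): missing name",
                  line_offset, id[[1]]))
  }
  # synonym lines carry the text in the first quoted span
  syn <- stringr::str_match(tag_val("synonym"), '^"((?:[^"\\\\]|\\\\.)*)"')[, 2]
  syn <- gsub('\\\\(["\\\\])', "\\1", syn[!is.na(syn)])
  tibble::tibble(
    id = id[[1]], label = nm[[1]],
    synonyms = list(unique(syn)),
    xrefs = list(unique(tag_val("xref"))),
    parents = list(unique(tag_val("is_a")))
  )
}

#' Parse a simplified MeSH descriptor table
#'
#' MeSH groups strictly synonymous Terms into Concepts under a hierarchical
#' Descriptor (Heading). This reader takes a TSV carrying that structure, one
#' row per Term, with columns `descriptor_id` (D-number), `heading`,
#' `tree_numbers` (`;`-separated dotted paths), `concept_id`, `preferred`
#' (TRUE/FALSE) and `term`. The descriptor hierarchy is induced by
#' tree-number prefixes (C01 is the parent of C01.100).
#'
#' @param tsv Path to the TSV, or a character vector of its lines.
#' @param name Vocabulary name, default `"MeSH"`.
#' @return A [new_vocabulary()] object; the assembled descriptor records
#'   (one row per descriptor, concepts as a nested tibble) are attached as
#'   attribute `"descriptors"`.
#' @export
parse_mesh_table <- function(tsv, name = "MeSH") {
  lines <- read_text_lines(tsv)
  df <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  needed <- c("descriptor_id", "heading", "tree_numbers", "concept_id",
              "preferred", "term")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(paste0("MeSH table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  df$preferred <- toupper(df$preferred) %in% c("TRUE", "T", "1", "Y", "YES")

  hd <- dplyr::distinct(df, .data$descriptor_id, .data$heading)
  dup <- hd$descriptor_id[duplicated(hd$descriptor_id)]
  if (length(dup)) {
    abort(paste0("conflicting heading for descriptor(s): ",
                 paste(unique(dup), collapse = ", ")))
  }

  groups <- split(df, factor(df$descriptor_id, levels = unique(df$descriptor_id)))
  descriptors <- dplyr::bind_rows(lapply(groups, function(g) {
    cids <- unique(g$concept_id)
    dplyr::tibble(
      descriptor_id = g$descriptor_id[[1]],
      heading = g$heading[[1]],
      tree_numbers = list(unique(unlist(strsplit(
        stats::na.omit(g$tree_numbers), ";", fixed = TRUE)))),
      concepts = list(dplyr::tibble(
        concept_id = cids,
        preferred = vapply(cids, function(ci)
          any(g$preferred[g$concept_id == ci]), logical(1)),
        terms = lapply(cids, function(ci)
          unique(g$term[g$concept_id == ci]))
      ))
    )
  }))
  n_pref <- vapply(descriptors$concepts, function(cc) sum(cc$preferred), integer(1))
  bad <- descriptors$descriptor_id[n_pref != 1L]
  if (length(bad)) {
    abort(paste0("descriptor(s) without exactly one preferred concept: ",
                 paste(bad, collapse = ", ")))
  }

  # hierarchy from tree-number prefixes: parent tree number = path minus last node
  tn_owner <- df |>
    dplyr::mutate(tn = strsplit(.data$tree_numbers, ";", fixed = TRUE)) |>
    tidyr::unnest("tn") |>
    dplyr::distinct(tn = .data$tn, descriptor_id = .data$descriptor_id) |>
    dplyr::filter(!is.na(.data$tn), nzchar(.data$tn))
  tn_map <- setNames(tn_owner$descriptor_id, tn_owner$tn)
  parents_of <- function(tns) {
    up <- sub("\\.[^.]+$", "", tns)
    up <- up[up != tns]
    unique(stats::na.omit(unname(tn_map[up])))
  }

  terms <- dplyr::tibble(
    id = descriptors$descriptor_id,
    label = descriptors$heading,
    # projection: heading -> label, all concept terms -> synonyms
    synonyms = purrr::map2(descriptors$concepts, descriptors$heading, function(cc, h) {
      setdiff(unique(unlist(cc$terms)), h)
    }),
    xrefs = rep(list(character()), nrow(descriptors)),
    parents = lapply(descriptors$tree_numbers, parents_of)
  )
  vocab <- new_vocabulary(name, terms)
  attr(vocab, "descriptors") <- descriptors
  rep <- validate_vocabulary(vocab)
  cyc <- rep$issue[rep$kind == "cycle"]
  if (length(cyc)) abort(paste0("cyclic tree-number hierarchy: ", paste(cyc, collapse = "; ")))
  vocab
}

#' Transitive ancestors of a term
#'
#' Walks the parent links upward and returns every transitive parent once,
#' ordered nearest-first with roots last (breadth-first layering).
#'
#' @param vocab A [new_vocabulary()] object.
#' @param id Term id present in the vocabulary.
#' @return Character vector of ancestor ids; empty for a root.
#' @export
ancestors_of <- function(vocab, id) {
  stopifnot(inherits(vocab, "phenosem_vocabulary"))
  if (!id %in% vocab$terms$id) {
    abort(sprintf("unknown term id '%s' in vocabulary '%s'", id, vocab$name))
  }
  parent_map <- setNames(vocab$terms$parents, vocab$terms$id)
  seen <- character()
  frontier <- unlist(parent_map[[id]])
  while (length(frontier)) {
    frontier <- setdiff(intersect(frontier, vocab$terms$id), seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
    frontier <- unique(unlist(parent_map[frontier]))
  }
  seen
}

#' Transitive descendants of a term
#'
#' @inheritParams ancestors_of
#' @return Character vector of descendant ids (excluding `id` itself).
#' @export
descendants_of <- function(vocab, id) {
  stopifnot(inherits(vocab, "phenosem_vocabulary"))
  if (!id %in% vocab$terms$id) {
    abort(sprintf("unknown term id '%s' in vocabulary '%s'", id, vocab$name))
  }
  kids <- children_map(vocab)
  seen <- character()
  frontier <- kids[[id]] %||% character()
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    if (!length(frontier)) break
    seen <- c(seen, frontier)
    frontier <- unique(unlist(kids[frontier]))
  }
  seen
}

children_map <- function(vocab) {
  edges <- dplyr::tibble(child = vocab$terms$id, parent = vocab$terms$parents) |>
    tidyr::unnest("parent")
  split(edges$child, factor(edges$parent, levels = unique(edges$parent)))
}

#' Validate a vocabulary's structural invariants
#'
#' Reports dangling parent references, cycles in the parent graph and
#' duplicate ids. An empty report means the invariants hold.
#'
#' @param vocab A [new_vocabulary()] object.
#' @return Tibble with columns `kind` (`dangling`, `cycle`, `duplicate_id`)
#'   and `issue` (human-readable description).
#' @export
validate_vocabulary <- function(vocab) {
  stopifnot(inherits(vocab, "phenosem_vocabulary"))
  terms <- vocab$terms
  issues <- list()
  dup <- unique(terms$id[duplicated(terms$id)])
  if (length(dup)) {
    issues <- c(issues, list(dplyr::tibble(
      kind = "duplicate_id", issue = paste("duplicate id:", dup))))
  }
  ids <- unique(terms$id)
  dangling <- dplyr::tibble(id = terms$id, parent = terms$parents) |>
    tidyr::unnest("parent") |>
    dplyr::filter(!.data$parent %in% ids)
  if (nrow(dangling)) {
    issues <- c(issues, list(dplyr::tibble(
      kind = "dangling",
      issue = sprintf("term %s references missing parent %s",
                      dangling$id, dangling$parent))))
  }
  # Kahn's algorithm on the in-vocabulary edges; leftover nodes sit on cycles
  edges <- dplyr::tibble(id = terms$id, parent = terms$parents) |>
    tidyr::unnest("parent") |>
    dplyr::filter(.data$parent %in% ids)
  indeg <- table(factor(edges$id, levels = ids))  # edges point child -> parent
  adj <- split(edges$id, factor(edges$parent, levels = ids))
  queue <- ids[indeg == 0L]
  indeg <- as.integer(indeg)
  names(indeg) <- ids
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    removed <- removed + 1L
    for (child in adj[[v]] %||% character()) {
      indeg[[child]] <- indeg[[child]] - 1L
      if (indeg[[child]] == 0L) queue <- c(queue, child)
    }
  }
  if (removed < length(ids)) {
    cyc_ids <- names(indeg)[indeg > 0L]
    issues <- c(issues, list(dplyr::tibble(
      kind = "cycle",
      issue = paste("cycle involving:", paste(sort(cyc_ids), collapse = ", ")))))
  }
  if (length(issues)) dplyr::bind_rows(issues) else
    dplyr::tibble(kind = character(), issue = character())
}

#' Dump / reload a vocabulary as JSON (debug round-trip)
#'
#' @param vocab A vocabulary.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `vocabulary_to_json()`: JSON string (invisibly when written to a
#'   file); `vocabulary_from_json()`: a vocabulary.
#' @export
vocabulary_to_json <- function(vocab, path = NULL) {
  stopifnot(inherits(vocab, "phenosem_vocabulary"))
  payload <- list(name = vocab$name, terms = vocab$terms)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname vocabulary_to_json
#' @param json JSON string or file path produced by [vocabulary_to_json()].
#' @export
vocabulary_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE, simplifyVector = TRUE)
  terms <- tibble::as_tibble(obj$terms)
  for (col in c("synonyms", "xrefs", "parents")) {
    if (!is.list(terms[[col]])) terms[[col]] <- as.list(terms[[col]])
  }
  new_vocabulary(obj$name, terms)
}

empty_terms <- function() {
  dplyr::tibble(id = character(), label = character(),
                synonyms = list(), xrefs = list(), parents = list())
}

read_text_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readr::read_lines(x, progress = FALSE)
  } else {
    unlist(strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE))
  }
}
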