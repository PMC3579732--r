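#' The GWAS annotation store
#'
#' A light in-memory subset of a GWAS database's relational model:
#' studies, experiments (each carrying exactly one phenotype annotation —
#' phenotypes are annotated at the level of individual experiments),
#' genetic markers and association results (marker p-values per
#' experiment). The store round-trips through JSON and imports association
#' results from TSV.
#'
#' @param studies Tibble: `study_id`, `pubmed_id` (optional, `NA` allowed),
#'   `title`.
#' @param experiments Tibble: `experiment_id`, `study_id`, `mesh_id`,
#'   `hpo_id` (`NA` allowed), `closest_match` (logical), `annotation_note`
#'   (`NA` allowed), `sample_panel`, `analysis_method`.
#' @param markers Tibble: `accession`, `rs_id` (`NA` allowed),
#'   `gene_symbols` (list-column of character vectors).
#' @param associations Tibble: `experiment_id`, `marker_accession`,
#'   `p_value` in (0, 1].
#' @return A `phenosem_store` object.
#' @export
gwas_store <- function(studies = NULL, experiments = NULL, markers = NULL,
                       associations = NULL) {
  studies <- default_tbl(studies, c(study_id = "c", pubmed_id = "c", title = "c"))
  experiments <- default_tbl(experiments, c(
    experiment_id = "c", study_id = "c", mesh_id = "c", hpo_id = "c",
    closest_match = "l", annotation_note = "c", sample_panel = "c",
    analysis_method = "c"))
  markers <- default_tbl(markers, c(accession = "c", rs_id = "c"))
  if (!"gene_symbols" %in% names(markers)) {
    markers$gene_symbols <- rep(list(character()), nrow(markers))
  }
  markers$gene_symbols <- lapply(markers$gene_symbols, as.character)
  associations <- default_tbl(associations, c(
    experiment_id = "c", marker_accession = "c", p_value = "d"))

  if (anyDuplicated(studies$study_id)) abort("duplicate study_id")
  if (anyDuplicated(experiments$experiment_id)) abort("duplicate experiment_id")
  if (anyDuplicated(markers$accession)) abort("duplicate marker accession")
  orphan <- setdiff(experiments$study_id, studies$study_id)
  if (length(orphan)) {
    abort(paste0("experiment references unknown study: ",
                 paste(orphan, collapse = ", ")))
  }
  if (nrow(associations)) {
    if (any(!associations$experiment_id %in% experiments$experiment_id)) {
      abort("association references unknown experiment")
    }
    if (any(!associations$marker_accession %in% markers$accession)) {
      abort("association references unknown marker")
    }
    if (any(!(associations$p_value > 0 & associations$p_value <= 1))) {
      abort("association p-values must lie in (0, 1]")
    }
  }
  if (any(experiments$closest_match &
          (is.na(experiments$annotation_note) |
             !nzchar(experiments$annotation_note)))) {
    abort("closest_match = TRUE requires an annotation note")
  }
  structure(list(studies = studies, experiments = experiments,
                 markers = markers, associations = associations),
            class = "phenosem_store")
}

default_tbl <- function(x, spec) {
  if (is.null(x)) {
    cols <- lapply(spec, function(t) switch(t, c = character(),
                                            l = logical(), d = numeric()))
    return(tibble::as_tibble(cols))
  }
  x <- tibble::as_tibble(x)
  for (nm in names(spec)) {
    if (!nm %in% names(x)) {
      x[[nm]] <- switch(spec[[nm]],
                        c = NA_character_, l = FALSE, d = NA_real_)
    }
    # all-NA columns lose their type through JSON; coerce back
    x[[nm]] <- switch(spec[[nm]], c = as.character(x[[nm]]),
                      l = as.logical(x[[nm]]), d = as.numeric(x[[nm]]))
  }
  x[unique(c(names(spec), names(x)))]
}

#' @export
print.phenosem_store <- function(x, ...) {
  cat(sprintf(paste0("<phenosem_store> %d studies, %d experiments, ",
                     "%d markers, %d associations\n"),
              nrow(x$studies), nrow(x$experiments), nrow(x$markers),
              nrow(x$associations)))
  invisible(x)
}

#' @rdname gwas_store
#' @param x A `phenosem_store`.
#' @param ... Unused.
#' @export
glance.phenosem_store <- function(x, ...) {
  dplyr::tibble(n_studies = nrow(x$studies),
                n_experiments = nrow(x$experiments),
                n_markers = nrow(x$markers),
                n_associations = nrow(x$associations),
                n_key_associations = sum(x$associations$p_value < 1e-5))
}

#' Annotate an experiment's phenotype
#'
#' Replaces the experiment's phenotype annotation. The MeSH Descriptor id
#' must exist in the supplied MeSH vocabulary; a closest-match annotation
#' (the exact Descriptor does not exist, so the nearest, usually parent,
#' Descriptor was chosen) must carry a note and is flagged in the store.
#'
#' @param store A [gwas_store()].
#' @param experiment_id Experiment to (re-)annotate.
#' @param mesh_id MeSH Descriptor id.
#' @param hpo_id Optional direct HPO annotation.
#' @param closest_match Flag the annotation as a closest (not exact) match.
#' @param annotation_note Free-text note; required when `closest_match`.
#' @param mesh_vocab The MeSH [new_vocabulary()] to validate against.
#' @return The updated store.
#' @export
add_annotation <- function(store, experiment_id, mesh_id, hpo_id = NA_character_,
                           closest_match = FALSE, annotation_note = NA_character_,
                           mesh_vocab) {
  stopifnot(inherits(store, "phenosem_store"),
            inherits(mesh_vocab, "phenosem_vocabulary"))
  if (!mesh_id %in% mesh_vocab$terms$id) {
    abort(sprintf("unknown MeSH Descriptor '%s'", mesh_id))
  }
  i <- match(experiment_id, store$experiments$experiment_id)
  if (is.na(i)) abort(sprintf("unknown experiment '%s'", experiment_id))
  if (closest_match && (is.na(annotation_note) || !nzchar(annotation_note))) {
    abort("a closest-match annotation requires an annotation note")
  }
  store$experiments$mesh_id[i] <- mesh_id
  store$experiments$hpo_id[i] <- hpo_id
  store$experiments$closest_match[i] <- closest_match
  store$experiments$annotation_note[i] <- annotation_note
  store
}

#' Experiments annotated to a term
#'
#' Looks the term up in whichever vocabulary contains it and returns the
#' experiments annotated to it — optionally including experiments
#' annotated to any descendant term — deduplicated, in stable
#' experiment-id order.
#'
#' @param store A [gwas_store()].
#' @param term_id MeSH Descriptor or HPO term id.
#' @param vocabs List of vocabularies to resolve the term (and its
#'   descendants) in.
#' @param include_descendants Also collect experiments annotated to
#'   descendant terms.
#' @return Tibble of experiment rows.
#' @export
experiments_for_term <- function(store, term_id, vocabs,
                                 include_descendants = FALSE) {
  stopifnot(inherits(store, "phenosem_store"))
  if (inherits(vocabs, "phenosem_vocabulary")) vocabs <- list(vocabs)
  home <- NULL
  for (v in vocabs) if (term_id %in% v$terms$id) { home <- v; break }
  if (is.null(home)) abort(sprintf("term '%s' not found in any vocabulary", term_id))
  wanted <- term_id
  if (include_descendants) wanted <- c(wanted, descendants_of(home, term_id))
  hit <- store$experiments$mesh_id %in% wanted |
    (!is.na(store$experiments$hpo_id) & store$experiments$hpo_id %in% wanted)
  out <- store$experiments[hit, ]
  out <- out[!duplicated(out$experiment_id), ]
  dplyr::arrange(out, .data$experiment_id)
}

#' Annotated hierarchy with unique-experiment counts
#'
#' Prunes a vocabulary to the terms used in annotations, keeping their
#' ancestors for connectivity (marked `structural`). Each retained term
#' carries the number of distinct experiments annotated directly to it;
#' cumulative subtree counts are available behind `cumulative = TRUE`.
#'
#' @param vocab A [new_vocabulary()].
#' @param store A [gwas_store()].
#' @param cumulative Count experiments annotated to the term or any
#'   descendant instead of direct annotations only.
#' @return Tibble `term_id`, `label`, `parents` (list-column restricted to
#'   retained terms), `n_experiments`, `structural`.
#' @export
annotated_hierarchy <- function(vocab, store, cumulative = FALSE) {
  stopifnot(inherits(vocab, "phenosem_vocabulary"),
            inherits(store, "phenosem_store"))
  ann <- store$experiments
  direct <- c(ann$mesh_id, ann$hpo_id[!is.na(ann$hpo_id)])
  annotated <- intersect(unique(direct), vocab$terms$id)
  if (!length(annotated)) {
    return(dplyr::tibble(term_id = character(), label = character(),
                         parents = list(), n_experiments = integer(),
                         structural = logical()))
  }
  keep <- unique(c(annotated,
                   unlist(lapply(annotated, ancestors_of, vocab = vocab))))
  count_for <- function(id) {
    ids <- id
    if (cumulative) ids <- c(ids, descendants_of(vocab, id))
    length(unique(ann$experiment_id[
      ann$mesh_id %in% ids |
        (!is.na(ann$hpo_id) & ann$hpo_id %in% ids)]))
  }
  idx <- match(keep, vocab$terms$id)
  dplyr::tibble(
    term_id = keep,
    label = vocab$terms$label[idx],
    parents = lapply(vocab$terms$parents[idx], function(p) intersect(p, keep)),
    n_experiments = vapply(keep, count_for, integer(1), USE.NAMES = FALSE),
    structural = !keep %in% annotated
  ) |> dplyr::arrange(.data$term_id)
}

#' Auto-suggest query strings over annotated terms
#'
#' Case-insensitive prefix search across the labels and synonyms of terms
#' that are actually used in annotations — unannotated terms are never
#' suggested.
#'
#' @param prefix Non-empty query prefix.
#' @param store A [gwas_store()].
#' @param vocabs Vocabularies whose terms may be suggested.
#' @param limit Maximum number of suggestions.
#' @return Sorted character vector of suggested term strings.
#' @export
autosuggest_terms <- function(prefix, store, vocabs, limit = 10L) {
  if (is.null(prefix) || is.na(prefix) || !nzchar(prefix)) {
    abort("autosuggest needs a non-empty prefix")
  }
  if (inherits(vocabs, "phenosem_vocabulary")) vocabs <- list(vocabs)
  ann <- store$experiments
  used <- unique(c(ann$mesh_id, ann$hpo_id[!is.na(ann$hpo_id)]))
  strings <- unlist(lapply(vocabs, function(v) {
    t <- v$terms[v$terms$id %in% used, ]
    unlist(purrr::map2(t$label, t$synonyms, c), use.names = FALSE)
  }), use.names = FALSE)
  hits <- sort(unique(strings[startsWith(tolower(strings), tolower(prefix))]))
  head(hits, limit)
}

#' Serialize / load a store as JSON
#'
#' @param store A [gwas_store()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string, or (for `store_from_json`) a store.
#' @export
store_to_json <- function(store, path = NULL) {
  stopifnot(inherits(store, "phenosem_store"))
  json <- jsonlite::toJSON(unclass(store), auto_unbox = FALSE, digits = NA,
                           null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' @rdname store_to_json
#' @param json JSON string or file path.
#' @export
store_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  markers <- tibble::as_tibble(obj$markers)
  if (nrow(markers) && !is.list(markers$gene_symbols)) {
    markers$gene_symbols <- as.list(markers$gene_symbols)
  }
  gwas_store(studies = obj$studies, experiments = obj$experiments,
             markers = markers, associations = obj$associations)
}

#' Import association results from TSV
#'
#' Columns: `experiment_id`, `marker_accession`, `rs_id`, `p_value`.
#' Unknown markers are added to the marker table.
#'
#' @param store A [gwas_store()].
#' @param tsv Path or character vector of TSV lines.
#' @return The updated store.
#' @export
import_associations_tsv <- function(store, tsv) {
  lines <- read_text_lines(tsv)
  df <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                        col_types = readr::cols(p_value = "d", .default = "c"),
                        progress = FALSE)
  new_markers <- setdiff(df$marker_accession, store$markers$accession)
  if (length(new_markers)) {
    rs <- df$rs_id[match(new_markers, df$marker_accession)]
    store$markers <- dplyr::bind_rows(store$markers, dplyr::tibble(
      accession = new_markers, rs_id = rs,
      gene_symbols = rep(list(character()), length(new_markers))))
  }
  assoc <- dplyr::tibble(experiment_id = df$experiment_id,
                         marker_accession = df$marker_accession,
                         p_value = df$p_value)
  gwas_store(store$studies, store$experiments, store$markers,
             dplyr::bind_rows(store$associations, assoc))
}
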