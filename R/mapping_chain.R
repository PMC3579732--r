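#' MeSH-HPO-OMIM mapping chains
#'
#' MeSH disease Descriptors are joined to HPO phenotypic-abnormality terms
#' through a shared UMLS concept unique identifier (CUI): the HPO term
#' carries a `UMLS:C...` cross-reference, and a MeSH-to-CUI table supplies
#' the other half of the join. Disease Descriptors are further expanded to
#' inferred phenotypic abnormalities through OMIM: MeSH -> OMIM (manually
#' assigned table) -> HPO (the HPO disease-annotation file). An inferred
#' phenotype may or may not be present in actual study participants; it
#' records which clinical manifestations could have contributed to the
#' disease diagnosis.
#'
#' @name mapping_chain
NULL

#' Build the MeSH-HPO cross map from shared UMLS CUIs
#'
#' A (MeSH, HPO) pair is created whenever both resolve to the same CUI.
#' When one CUI is claimed by several MeSH descriptors the join is
#' ambiguous; all pairs are kept and a warning names the CUIs, leaving the
#' decision to curators.
#'
#' @param hpo A [new_vocabulary()] whose terms carry `UMLS:C...` xrefs.
#' @param mesh_cui Tibble (or TSV path) with columns `mesh_id`, `cui`.
#' @return A `phenosem_cross_map`: tibble `pairs` with `mesh_id`, `hpo_id`,
#'   `cui`, `provenance`.
#' @export
build_cross_map <- function(hpo, mesh_cui) {
  stopifnot(inherits(hpo, "phenosem_vocabulary"))
  mesh_cui <- read_two_col(mesh_cui, c("mesh_id", "cui"))
  hpo_cui <- dplyr::tibble(hpo_id = hpo$terms$id, xref = hpo$terms$xrefs) |>
    tidyr::unnest("xref") |>
    dplyr::filter(stringr::str_detect(.data$xref, "^UMLS:C")) |>
    dplyr::mutate(cui = sub("^UMLS:", "", .data$xref)) |>
    dplyr::distinct(.data$hpo_id, .data$cui)
  mesh_cui <- dplyr::distinct(mesh_cui, .data$mesh_id, .data$cui)
  dup_cui <- unique(mesh_cui$cui[duplicated(mesh_cui$cui)])
  if (length(dup_cui)) {
    warn(paste0("CUI(s) claimed by multiple MeSH descriptors (all pairs kept): ",
                paste(dup_cui, collapse = ", ")))
  }
  pairs <- dplyr::inner_join(mesh_cui, hpo_cui, by = "cui",
                             relationship = "many-to-many") |>
    dplyr::transmute(.data$mesh_id, .data$hpo_id, .data$cui,
                     provenance = "cui_table") |>
    dplyr::distinct() |>
    dplyr::arrange(.data$mesh_id, .data$hpo_id)
  structure(list(pairs = pairs), class = "phenosem_cross_map")
}

#' @export
print.phenosem_cross_map <- function(x, ...) {
  cat(sprintf("<phenosem_cross_map> %d MeSH-HPO pairs\n", nrow(x$pairs)))
  invisible(x)
}

#' @rdname build_cross_map
#' @param x A `phenosem_cross_map`.
#' @param ... Unused.
#' @export
tidy.phenosem_cross_map <- function(x, ...) x$pairs

#' Forward / inverse lookups on a cross map
#'
#' @param cross A [build_cross_map()] result.
#' @param mesh_id,hpo_id Single id.
#' @return Character vector of mapped ids (possibly empty).
#' @export
mesh_to_hpo <- function(cross, mesh_id) {
  sort(unique(cross$pairs$hpo_id[cross$pairs$mesh_id == mesh_id]))
}

#' @rdname mesh_to_hpo
#' @export
hpo_to_mesh <- function(cross, hpo_id) {
  sort(unique(cross$pairs$mesh_id[cross$pairs$hpo_id == hpo_id]))
}

#' Parse the HPO disease-annotation file (OMIM rows)
#'
#' TSV dialect of the HPO annotation format: columns `database_id`
#' (`OMIM:nnnnnn`), `disease_name`, `hpo_id`. Duplicate rows collapse.
#'
#' @param tsv Path or character vector of TSV lines (with header).
#' @return Tibble `omim_id`, `disease_name`, `hpo_id` (distinct rows).
#' @export
parse_hpo_omim_annotations <- function(tsv) {
  lines <- read_text_lines(tsv)
  df <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  needed <- c("database_id", "disease_name", "hpo_id")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort(paste0("HPO-OMIM annotation file lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(!grepl("^OMIM:[0-9]+$", df$database_id))
  if (length(bad)) {
    abort(sprintf("malformed OMIM id '%s' at data line %d",
                  df$database_id[bad[1]], bad[1]))
  }
  bad_hp <- which(!grepl("^HP:[0-9]+$", df$hpo_id))
  if (length(bad_hp)) {
    abort(sprintf("malformed HPO id '%s' at data line %d",
                  df$hpo_id[bad_hp[1]], bad_hp[1]))
  }
  df |>
    dplyr::transmute(omim_id = .data$database_id,
                     disease_name = .data$disease_name,
                     hpo_id = .data$hpo_id) |>
    dplyr::distinct()
}

#' Assemble the OMIM-centred mapping bundle
#'
#' @param hpo_omim Tibble from [parse_hpo_omim_annotations()] (or TSV path).
#' @param omim_mesh Tibble (or TSV path) with columns `omim_id`, `mesh_id`
#'   (the manually assigned disease mapping).
#' @return A `phenosem_omim_mapping`: list of tibbles `omim_to_hpo`
#'   (`omim_id`, `disease_name`, `hpo_id`) and `omim_to_mesh`
#'   (`omim_id`, `mesh_id`).
#' @export
omim_mapping <- function(hpo_omim, omim_mesh) {
  if (!is.data.frame(hpo_omim)) hpo_omim <- parse_hpo_omim_annotations(hpo_omim)
  omim_mesh <- read_two_col(omim_mesh, c("omim_id", "mesh_id"))
  ok <- grepl("^OMIM:[0-9]+$", omim_mesh$omim_id) &
    grepl("^D[0-9]+$", omim_mesh$mesh_id)
  if (any(!ok)) {
    abort(sprintf("malformed OMIM-MeSH row: %s / %s",
                  omim_mesh$omim_id[!ok][1], omim_mesh$mesh_id[!ok][1]))
  }
  structure(list(omim_to_hpo = hpo_omim,
                 omim_to_mesh = dplyr::distinct(omim_mesh)),
            class = "phenosem_omim_mapping")
}

#' @export
print.phenosem_omim_mapping <- function(x, ...) {
  cat(sprintf("<phenosem_omim_mapping> %d OMIM-HPO rows, %d OMIM-MeSH rows\n",
              nrow(x$omim_to_hpo), nrow(x$omim_to_mesh)))
  invisible(x)
}

#' Inferred phenotypic abnormalities for a MeSH disease Descriptor
#'
#' Follows MeSH -> OMIM -> HPO and returns the abnormality set grouped
#' under the OMIM entry it came from, as in a Phenotype Report. A MeSH id
#' with no OMIM link yields an empty result (not an error).
#'
#' @param mesh_disease_id MeSH Descriptor id (D-number).
#' @param maps A [omim_mapping()] bundle.
#' @return Tibble `omim_id`, `disease_name`, `hpo_id`, one row per
#'   (OMIM entry, abnormality).
#' @export
inferred_phenotypes <- function(mesh_disease_id, maps) {
  stopifnot(inherits(maps, "phenosem_omim_mapping"))
  omims <- maps$omim_to_mesh$omim_id[maps$omim_to_mesh$mesh_id == mesh_disease_id]
  maps$omim_to_hpo |>
    dplyr::filter(.data$omim_id %in% omims) |>
    dplyr::arrange(.data$omim_id, .data$hpo_id)
}

#' Resolve a phenotype annotation to its HPO route
#'
#' Every phenotype carries a required MeSH annotation; the HPO side may be
#' (in precedence order) a direct manual annotation, a term mapped through
#' the shared-CUI cross map, or an inferred abnormality set via OMIM. When
#' none applies the annotation is tagged `mesh-only` rather than silently
#' dropped, so incomplete mapping tables are visible.
#'
#' @param phenotype List or one-row data frame with `mesh_id` (required)
#'   and optional `hpo_id`.
#' @param cross A [build_cross_map()] result.
#' @param omim A [omim_mapping()] bundle.
#' @return Tibble with `mesh_id`, `route` (`direct`, `mapped`, `inferred`,
#'   `mesh-only`), `hpo_id`, `omim_id` (`NA` except for inferred rows).
#' @export
resolve_annotation <- function(phenotype, cross, omim) {
  if (is.data.frame(phenotype)) {
    stopifnot(nrow(phenotype) == 1L)
    phenotype <- as.list(phenotype)
  }
  mesh_id <- phenotype$mesh_id
  if (is.null(mesh_id) || is.na(mesh_id) || !nzchar(mesh_id)) {
    abort("phenotype annotation lacks the required MeSH id")
  }
  hpo_id <- phenotype$hpo_id
  if (!is.null(hpo_id) && !is.na(hpo_id) && nzchar(hpo_id)) {
    return(dplyr::tibble(mesh_id = mesh_id, route = "direct",
                         hpo_id = hpo_id, omim_id = NA_character_))
  }
  mapped <- mesh_to_hpo(cross, mesh_id)
  if (length(mapped)) {
    return(dplyr::tibble(mesh_id = mesh_id, route = "mapped",
                         hpo_id = mapped, omim_id = NA_character_))
  }
  inf <- inferred_phenotypes(mesh_id, omim)
  if (nrow(inf)) {
    return(dplyr::tibble(mesh_id = mesh_id, route = "inferred",
                         hpo_id = inf$hpo_id, omim_id = inf$omim_id))
  }
  dplyr::tibble(mesh_id = mesh_id, route = "mesh-only",
                hpo_id = NA_character_, omim_id = NA_character_)
}

read_two_col <- function(x, cols) {
  if (is.data.frame(x)) {
    df <- tibble::as_tibble(x)
  } else {
    lines <- read_text_lines(x)
    df <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0("table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  df[cols]
}
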