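#' Human-mouse phenotype comparison pipeline
#'
#' Four steps over pluggable data-source adapters: (1) validate the human
#' gene symbols, (2) determine the mouse gene orthologs, (3) retrieve
#' human GWAS phenotype annotations (MeSH) passing a p-value threshold and
#' mouse MPO annotations from the mouse genome database, (4) retrieve
#' high-throughput phenotyping MPO annotations passing a statistical
#' significance limit. The resulting lists present the ontology
#' annotations made for the gene-ortholog dataset; comparing them across
#' species remains a reporting/manual step.
#'
#' @name crossspecies_pipeline
NULL

#' Pipeline parameters
#'
#' @param gene_symbols Non-empty character vector of human gene symbols.
#' @param gwas_threshold_exponent Positive number `e`; the GWAS p-value
#'   threshold is `10^-e` (entering "7" means 1e-7), boundary inclusive.
#' @param europhenome_significance_limit Significance limit in (0, 1) for
#'   the high-throughput phenotyping source, boundary inclusive.
#' @return A `phenosem_pipeline_params` list.
#' @export
pipeline_params <- function(gene_symbols,
                            gwas_threshold_exponent = 7,
                            europhenome_significance_limit = 0.00001) {
  if (!length(gene_symbols)) abort("gene list must be non-empty")
  if (!is.numeric(gwas_threshold_exponent) || gwas_threshold_exponent <= 0) {
    abort("gwas_threshold_exponent must be positive")
  }
  lim <- europhenome_significance_limit
  if (!is.numeric(lim) || lim <= 0 || lim >= 1) {
    abort("europhenome_significance_limit must lie in (0, 1)")
  }
  structure(list(gene_symbols = as.character(gene_symbols),
                 gwas_threshold_exponent = gwas_threshold_exponent,
                 europhenome_significance_limit = lim),
            class = "phenosem_pipeline_params")
}

#' GWAS / high-throughput significance filters
#'
#' `passes_gwas_threshold()` is true iff `p <= 10^-exponent`;
#' `passes_europhenome_limit()` is true iff `p <= limit`. Both boundaries
#' are inclusive.
#'
#' @param p_value Numeric vector of p-values in (0, 1].
#' @param exponent Positive threshold exponent.
#' @return Logical vector.
#' @examples
#' passes_gwas_threshold(2e-12, 7)
#' passes_gwas_threshold(1e-6, 7)
#' @export
passes_gwas_threshold <- function(p_value, exponent) {
  stopifnot(all(p_value > 0 & p_value <= 1))
  p_value <= 10^(-exponent)
}

#' @rdname passes_gwas_threshold
#' @param limit Significance limit in (0, 1).
#' @export
passes_europhenome_limit <- function(p_value, limit) {
  stopifnot(all(p_value > 0 & p_value <= 1))
  p_value <= limit
}

#' Build adapters over an offline fixture bundle
#'
#' Live gene-registry/ortholog/phenotype web services are represented by
#' an adapter interface: five pure lookup functions over fixed tables, so
#' a pipeline run is deterministic. The bundle is a list of tibbles:
#' \describe{
#'   \item{genes}{`symbol`, `gene_id` — the validation registry.}
#'   \item{orthologs}{`human_symbol`, `mouse_symbol`.}
#'   \item{human_annotations}{`symbol`, `mesh_id`, `label`, `marker`,
#'     `p_value`.}
#'   \item{mgd_annotations}{`mouse_symbol`, `mpo_id`, `label`.}
#'   \item{europhenome_annotations}{`mouse_symbol`, `mpo_id`, `label`,
#'     `p_value`.}
#' }
#'
#' @param bundle Fixture bundle (list of tibbles as above), or a directory
#'   containing the corresponding TSV files (`genes.tsv`, ...).
#' @return A `phenosem_adapters` list of functions:
#'   `gene_validator(symbols)`, `ortholog_source(symbols)`,
#'   `human_phenotype_source(symbols, threshold)`,
#'   `mgd_source(mouse_symbols)`,
#'   `europhenome_source(mouse_symbols, limit)`.
#' @export
fixture_adapters <- function(bundle) {
  if (is.character(bundle)) bundle <- read_fixture_bundle(bundle)
  needed <- c("genes", "orthologs", "human_annotations", "mgd_annotations",
              "europhenome_annotations")
  missing <- setdiff(needed, names(bundle))
  if (length(missing)) {
    abort(paste0("fixture bundle lacks table(s): ",
                 paste(missing, collapse = ", ")))
  }
  b <- lapply(bundle[needed], tibble::as_tibble)
  structure(list(
    gene_validator = function(symbols) {
      dplyr::tibble(symbol = symbols,
                    valid = symbols %in% b$genes$symbol,
                    gene_id = b$genes$gene_id[match(symbols, b$genes$symbol)])
    },
    ortholog_source = function(symbols) {
      dplyr::filter(b$orthologs, .data$human_symbol %in% symbols)
    },
    human_phenotype_source = function(symbols, threshold) {
      dplyr::filter(b$human_annotations, .data$symbol %in% symbols,
                    passes_gwas_threshold(.data$p_value, threshold))
    },
    mgd_source = function(mouse_symbols) {
      dplyr::filter(b$mgd_annotations, .data$mouse_symbol %in% mouse_symbols)
    },
    europhenome_source = function(mouse_symbols, limit) {
      dplyr::filter(b$europhenome_annotations,
                    .data$mouse_symbol %in% mouse_symbols,
                    passes_europhenome_limit(.data$p_value, limit))
    }
  ), class = "phenosem_adapters")
}

read_fixture_bundle <- function(dir) {
  read1 <- function(nm, types) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(path)) abort(paste0("missing fixture file: ", path))
    readr::read_tsv(path, col_types = types, progress = FALSE)
  }
  list(
    genes = read1("genes", "cc"),
    orthologs = read1("orthologs", "cc"),
    human_annotations = read1("human_annotations",
                              readr::cols(p_value = "d", .default = "c")),
    mgd_annotations = read1("mgd_annotations", "ccc"),
    europhenome_annotations = read1("europhenome_annotations",
                                    readr::cols(p_value = "d", .default = "c"))
  )
}

#' Run the four-step comparison pipeline
#'
#' Genes failing validation are reported (`rejected`), not fatal; an
#' all-invalid gene list is an error. Human annotations are filtered by
#' the GWAS threshold inside the source adapter, EuroPhenome-style
#' annotations by the significance limit.
#'
#' @param params A [pipeline_params()] (or a character vector of gene
#'   symbols, promoted with default thresholds).
#' @param adapters A [fixture_adapters()]-style adapter set.
#' @return A `phenosem_comparison_report`: list with `params`, `genes`
#'   (symbol, gene_id, mouse_symbol), `rejected`, and the three annotation
#'   tibbles `human_annotations`, `mgd_annotations`,
#'   `europhenome_annotations`, each with a `provenance` column naming its
#'   source.
#' @export
run_comparison <- function(params, adapters) {
  if (is.character(params)) params <- pipeline_params(params)
  stopifnot(inherits(params, "phenosem_pipeline_params"),
            inherits(adapters, "phenosem_adapters"))
  call_adapter <- function(name, f, ...) {
    tryCatch(f(...), error = function(e) {
      abort(sprintf("adapter '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  validated <- call_adapter("gene_validator", adapters$gene_validator,
                            params$gene_symbols)
  rejected <- validated$symbol[!validated$valid]
  valid <- validated$symbol[validated$valid]
  if (!length(valid)) {
    abort(paste0("no valid genes in the input list (rejected: ",
                 paste(rejected, collapse = ", "), ")"))
  }
  orthologs <- call_adapter("ortholog_source", adapters$ortholog_source, valid)
  genes <- dplyr::tibble(
    symbol = valid,
    gene_id = validated$gene_id[match(valid, validated$symbol)],
    mouse_symbol = orthologs$mouse_symbol[match(valid, orthologs$human_symbol)])
  mouse <- genes$mouse_symbol[!is.na(genes$mouse_symbol)]

  human <- call_adapter("human_phenotype_source",
                        adapters$human_phenotype_source,
                        valid, params$gwas_threshold_exponent)
  mgd <- call_adapter("mgd_source", adapters$mgd_source, mouse)
  euro <- call_adapter("europhenome_source", adapters$europhenome_source,
                       mouse, params$europhenome_significance_limit)
  human$provenance <- rep("GWAS Central", nrow(human))
  mgd$provenance <- rep("MGD", nrow(mgd))
  euro$provenance <- rep("EuroPhenome", nrow(euro))
  structure(list(params = params, genes = genes, rejected = rejected,
                 human_annotations = tibble::as_tibble(human),
                 mgd_annotations = tibble::as_tibble(mgd),
                 europhenome_annotations = tibble::as_tibble(euro)),
            class = "phenosem_comparison_report")
}

#' @export
print.phenosem_comparison_report <- function(x, ...) {
  cat(sprintf(paste0("<phenosem_comparison_report> %d gene(s): ",
                     "%d GWAS, %d EuroPhenome, %d MGD annotations\n"),
              nrow(x$genes), nrow(x$human_annotations),
              nrow(x$europhenome_annotations), nrow(x$mgd_annotations)))
  if (length(x$rejected)) {
    cat("rejected symbols:", paste(x$rejected, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname run_comparison
#' @param x A `phenosem_comparison_report`.
#' @param ... Unused.
#' @export
tidy.phenosem_comparison_report <- function(x, ...) {
  h <- dplyr::transmute(x$human_annotations, source = .data$provenance,
                        gene = .data$symbol, term_id = .data$mesh_id,
                        label = .data$label, marker = .data$marker,
                        p_value = .data$p_value)
  e <- dplyr::transmute(x$europhenome_annotations, source = .data$provenance,
                        gene = .data$mouse_symbol, term_id = .data$mpo_id,
                        label = .data$label, marker = NA_character_,
                        p_value = .data$p_value)
  m <- dplyr::transmute(x$mgd_annotations, source = .data$provenance,
                        gene = .data$mouse_symbol, term_id = .data$mpo_id,
                        label = .data$label, marker = NA_character_,
                        p_value = NA_real_)
  dplyr::bind_rows(h, e, m)
}

#' @rdname run_comparison
#' @export
glance.phenosem_comparison_report <- function(x, ...) {
  dplyr::tibble(n_genes = nrow(x$genes),
                n_rejected = length(x$rejected),
                n_gwas_central = nrow(x$human_annotations),
                n_europhenome = nrow(x$europhenome_annotations),
                n_mgd = nrow(x$mgd_annotations))
}

#' Plot annotation counts per source for a comparison report
#'
#' @param object A `phenosem_comparison_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phenosem_comparison_report <- function(object, ...) {
  counts <- dplyr::count(tidy(object), .data$source, name = "n")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$source, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "annotations") +
    ggplot2::theme_minimal()
}

#' Serialize a comparison report to JSON
#'
#' @param report A `phenosem_comparison_report`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  payload <- list(
    params = unclass(report$params), genes = report$genes,
    rejected = report$rejected,
    human_annotations = report$human_annotations,
    mgd_annotations = report$mgd_annotations,
    europhenome_annotations = report$europhenome_annotations)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
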