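#' Synthetic fixtures for offline use
#'
#' Generators for everything the other modules consume: a mutually
#' consistent bundle of toy vocabularies and mapping tables, matching
#' corpora with planted ground truth, synthetic GWAS stores with a
#' controlled fraction of key associations, and the packaged worked
#' example for the human-mouse comparison pipeline. All generators are
#' seed-deterministic; corpus ground truth holds by construction, not by
#' sampling.
#'
#' @name synthetic_fixtures
NULL

#' Toy vocabulary and mapping-table bundle
#'
#' A mini HPO-like ontology (OBO text, parsed), a mini MeSH-like
#' descriptor table, and mutually consistent MeSH-CUI, HPO-OMIM and
#' OMIM-MeSH tables. The bundle includes the field's well-known anchors
#' (coronary artery disease D003324, Gaucher disease D005776, coronary
#' artery calcification HP:0001717, abnormality of the esophagus
#' HP:0002031) and a complete Creutzfeldt-Jakob disease chain
#' (MeSH descriptor -> OMIM entry -> HPO abnormalities including
#' "Confusion" and "Loss of facial expression"). Identifiers without a
#' public printed source are synthetic but syntactically valid.
#'
#' @param seed Unused entropy hook (the bundle is fully fixed); kept so
#'   every generator shares one signature.
#' @return List with `hpo`, `mesh` (vocabularies), `hpo_obo`,
#'   `mesh_table` (source text), `mesh_cui`, `hpo_omim`, `omim_mesh`
#'   (tibbles).
#' @export
make_toy_vocabularies <- function(seed = 1L) {
  hpo_obo <- c(
    "format-version: 1.2",
    "ontology: hp-toy",
    "",
    "[Term]", "id: HP:0000001", "name: All",
    "",
    "[Term]", "id: HP:0000118", "name: Phenotypic abnormality",
    "is_a: HP:0000001",
    "",
    "[Term]", "id: HP:0002031", "name: Abnormality of the esophagus",
    "is_a: HP:0000118", "xref: UMLS:C0014852",
    "",
    "[Term]", "id: HP:0001717", "name: Coronary artery calcification",
    "is_a: HP:0000118", "xref: UMLS:C0342649",
    "",
    "[Term]", "id: HP:0001289", "name: Confusion",
    "synonym: \"Disorientation\" EXACT []",
    "is_a: HP:0000118", "xref: UMLS:C0009676",
    "",
    "[Term]", "id: HP:0004328", "name: Loss of facial expression",
    "is_a: HP:0000118",
    "",
    "[Term]", "id: HP:0006483", "name: Abnormal number of teeth",
    "synonym: \"Abnormal tooth count\" EXACT []",
    "is_a: HP:0000118",
    "",
    "[Term]", "id: HP:0002185", "name: Neurofibrillary tangles",
    "is_a: HP:0000118",
    "",
    "[Term]", "id: HP:0003124", "name: Hypercholesterolemia",
    "is_a: HP:0000118", "xref: UMLS:C0020443",
    "",
    "[Term]", "id: HP:0000999", "name: Obsolete example", "is_obsolete: true"
  )
  mesh_rows <- c(
    "descriptor_id\theading\ttree_numbers\tconcept_id\tpreferred\tterm",
    "D002318\tCardiovascular Diseases\tC14\tM0003560\tTRUE\tCardiovascular Diseases",
    "D003327\tCoronary Disease\tC14.280\tM0005355\tTRUE\tCoronary Disease",
    "D003324\tCoronary Artery Disease\tC14.280.647\tM0005346\tTRUE\tCoronary Artery Disease",
    "D003324\tCoronary Artery Disease\tC14.280.647\tM0005347\tFALSE\tCoronary Arteriosclerosis",
    "D005776\tGaucher Disease\tC16.320.565.595\tM0009001\tTRUE\tGaucher Disease",
    "D005776\tGaucher Disease\tC16.320.565.595\tM0009001\tTRUE\tGlucosylceramide Beta-Glucosidase Deficiency Disease",
    "D007562\tCreutzfeldt-Jakob Syndrome\tC10.228.228.245\tM0011862\tTRUE\tCreutzfeldt-Jakob Syndrome",
    "D007562\tCreutzfeldt-Jakob Syndrome\tC10.228.228.245\tM0011862\tTRUE\tCreutzfeldt-Jakob Disease",
    "D005541\tForced Expiratory Volume\tE01.370.386.700.485\tM0008703\tTRUE\tForced Expiratory Volume",
    "D014280\tTriglycerides\tD10.251.355\tM0021985\tTRUE\tTriglycerides",
    "D006200\tHair Color\tG07.345\tM0009750\tTRUE\tHair Color",
    "D004935\tEsophageal Diseases\tC06.405.117\tM0007731\tTRUE\tEsophageal Diseases",
    "D010949\tPlasma\tA12.207.152.693\tM0017002\tTRUE\tPlasma",
    "D011326\tProtein C\tD12.776.124.125.662\tM0017552\tTRUE\tProtein C"
  )
  hpo <- parse_obo(hpo_obo, name = "HPO")
  mesh <- parse_mesh_table(mesh_rows, name = "MeSH")
  mesh_cui <- dplyr::tibble(
    mesh_id = c("D004935", "D007562", "D003324"),
    cui = c("C0014852", "C0022336", "C0010054"))
  hpo_omim <- dplyr::tibble(
    database_id = rep("OMIM:123400", 4),
    disease_name = rep("Creutzfeldt-Jakob Disease", 4),
    hpo_id = c("HP:0001289", "HP:0004328", "HP:0002185", "HP:0000118")
  ) |> parse_hpo_omim_annotations_df()
  omim_mesh <- dplyr::tibble(omim_id = "OMIM:123400", mesh_id = "D007562")
  list(hpo = hpo, mesh = mesh, hpo_obo = hpo_obo, mesh_table = mesh_rows,
       mesh_cui = mesh_cui, hpo_omim = hpo_omim, omim_mesh = omim_mesh)
}

# in-memory variant of parse_hpo_omim_annotations for already-tabular input
parse_hpo_omim_annotations_df <- function(df) {
  parse_hpo_omim_annotations(c(
    paste(c("database_id", "disease_name", "hpo_id"), collapse = "\t"),
    vapply(seq_len(nrow(df)), function(i)
      paste(df$database_id[i], df$disease_name[i], df$hpo_id[i], sep = "\t"),
      character(1))))
}

#' Specification for a planted matching corpus
#'
#' @param n_traits Corpus size.
#' @param planted Tibble with columns `vocabulary`, `exact_fraction`,
#'   `partial_fraction` (per-vocabulary planted fractions; exact +
#'   partial must not exceed 1 per vocabulary and totals must fit in
#'   `n_traits`).
#' @param variant_rate Fraction of planted traits written in the
#'   alternative spelling so they match only through the spelling-variant
#'   path, between 0 and 1.
#' @param seed Integer seed.
#' @return A `phenosem_corpus_spec` list.
#' @export
corpus_spec <- function(n_traits, planted, variant_rate = 0, seed = 1L) {
  planted <- tibble::as_tibble(planted)
  stopifnot(n_traits > 0,
            all(c("vocabulary", "exact_fraction", "partial_fraction") %in%
                  names(planted)))
  frac <- planted$exact_fraction + planted$partial_fraction
  if (any(planted$exact_fraction < 0 | planted$partial_fraction < 0 |
            frac > 1)) {
    abort("planted fractions must be in [0,1] with exact+partial <= 1")
  }
  if (variant_rate < 0 || variant_rate > 1) abort("variant_rate must be in [0,1]")
  structure(list(n_traits = as.integer(n_traits), planted = planted,
                 variant_rate = variant_rate, seed = as.integer(seed)),
            class = "phenosem_corpus_spec")
}

#' Generate a matching corpus with planted ground truth
#'
#' Builds one synthetic vocabulary per planted row plus a trait list such
#' that the exact/partial/unmatched status of every trait is provable by
#' construction: exact plants copy a label verbatim, partial plants drop
#' the label's distinctive leading token, variant plants swap one word
#' for its British spelling (the label carries the American form), and
#' filler traits share no token stem with any label.
#'
#' @param spec A [corpus_spec()].
#' @param variant_table A [spelling_variant_table()] used for variant
#'   plants.
#' @return List: `traits` (tibble with `description`), `vocabs` (list of
#'   vocabularies), `ground_truth` (tibble `description`, `vocabulary`,
#'   `mode`, `via_variant`).
#' @export
make_match_corpus <- function(spec, variant_table = spelling_variant_table()) {
  stopifnot(inherits(spec, "phenosem_corpus_spec"))
  set.seed(spec$seed)
  n <- spec$n_traits
  planted <- spec$planted
  counts <- dplyr::tibble(
    vocabulary = planted$vocabulary,
    n_exact = round(planted$exact_fraction * n),
    n_partial = round(planted$partial_fraction * n))
  if (sum(counts$n_exact + counts$n_partial) > n) {
    abort("planted counts exceed corpus size after rounding")
  }
  # variant word pair: label carries the American form, trait the British
  vw <- c(british = "colour", american = "color")
  traits <- character()
  truth <- list()
  vocabs <- list()
  for (i in seq_len(nrow(counts))) {
    v <- counts$vocabulary[i]
    vtag <- gsub("[^[:alnum:]]", "", tolower(v))
    terms <- list()
    for (j in seq_len(counts$n_exact[i])) {
      use_variant <- runif(1) < spec$variant_rate
      core <- paste0(vtag, " ", "ex", j, " ",
                     if (use_variant) vw[["american"]] else paste0("word", j))
      label <- core
      trait <- if (use_variant) sub(vw[["american"]], vw[["british"]], core,
                                    fixed = TRUE) else core
      terms <- c(terms, list(label))
      traits <- c(traits, trait)
      truth <- c(truth, list(dplyr::tibble(
        description = trait, vocabulary = v, mode = "exact",
        via_variant = use_variant)))
    }
    for (j in seq_len(counts$n_partial[i])) {
      use_variant <- runif(1) < spec$variant_rate
      core <- paste0(vtag, " ", "pa", j, " ",
                     if (use_variant) vw[["american"]] else paste0("item", j))
      label <- paste0("lead", j, " ", core)  # extra leading token: partial only
      trait <- if (use_variant) sub(vw[["american"]], vw[["british"]], core,
                                    fixed = TRUE) else core
      terms <- c(terms, list(label))
      traits <- c(traits, trait)
      truth <- c(truth, list(dplyr::tibble(
        description = trait, vocabulary = v, mode = "partial",
        via_variant = use_variant)))
    }
    term_tbl <- dplyr::tibble(
      id = sprintf("%s:%04d", toupper(vtag), seq_along(terms)),
      label = unlist(terms) %||% character(),
      synonyms = rep(list(character()), length(terms)),
      xrefs = rep(list(character()), length(terms)),
      parents = rep(list(character()), length(terms)))
    vocabs <- c(vocabs, list(new_vocabulary(v, term_tbl)))
  }
  n_fill <- n - length(traits)
  if (n_fill > 0) {
    traits <- c(traits, paste("zz filler trait", seq_len(n_fill)))
  }
  list(traits = dplyr::tibble(description = traits),
       vocabs = vocabs,
       ground_truth = if (length(truth)) dplyr::bind_rows(truth) else
         dplyr::tibble(description = character(), vocabulary = character(),
                       mode = character(), via_variant = logical()))
}

#' Specification for a synthetic GWAS store
#'
#' Association p-values follow a two-piece log-uniform model: with
#' probability `fraction_below`, log10(p) is uniform on
#' `(log10_range_key)` (all below the 1e-5 nanopublication cutoff),
#' otherwise uniform on `(log10_range_null)` (all above it).
#'
#' @param n_studies,n_experiments,n_markers Positive counts; one
#'   association is drawn per marker.
#' @param fraction_below Expected fraction of key associations, between 0
#'   and 1.
#' @param log10_range_key,log10_range_null Two-element log10(p) supports.
#' @param seed Integer seed.
#' @return A `phenosem_gwas_spec` list.
#' @export
gwas_spec <- function(n_studies = 2L, n_experiments = 6L, n_markers = 100L,
                      fraction_below = 0.3,
                      log10_range_key = c(-12, -5),
                      log10_range_null = c(-5, 0),
                      seed = 1L) {
  stopifnot(n_studies > 0, n_experiments > 0, n_markers > 0,
            fraction_below >= 0, fraction_below <= 1)
  structure(list(n_studies = as.integer(n_studies),
                 n_experiments = as.integer(n_experiments),
                 n_markers = as.integer(n_markers),
                 fraction_below = fraction_below,
                 log10_range_key = log10_range_key,
                 log10_range_null = log10_range_null,
                 seed = as.integer(seed)),
            class = "phenosem_gwas_spec")
}

#' Generate a synthetic annotation store
#'
#' Experiments are annotated to vocabulary terms drawn from the bundle's
#' MeSH table (a random subset also receives a direct HPO annotation);
#' markers carry dbSNP-style rs ids and synthetic gene symbols.
#'
#' @param spec A [gwas_spec()].
#' @param bundle A [make_toy_vocabularies()] bundle.
#' @return A [gwas_store()].
#' @export
make_gwas_store <- function(spec, bundle = make_toy_vocabularies()) {
  stopifnot(inherits(spec, "phenosem_gwas_spec"))
  set.seed(spec$seed)
  studies <- dplyr::tibble(
    study_id = sprintf("HGVST%03d", seq_len(spec$n_studies)),
    pubmed_id = sprintf("2%07d", seq_len(spec$n_studies)),
    title = paste("Synthetic genome-wide association study", seq_len(spec$n_studies)))
  mesh_ids <- bundle$mesh$terms$id
  hpo_ids <- setdiff(bundle$hpo$terms$id, c("HP:0000001", "HP:0000118"))
  with_hpo <- runif(spec$n_experiments) < 0.5
  experiments <- dplyr::tibble(
    experiment_id = sprintf("HGVE%04d", seq_len(spec$n_experiments)),
    study_id = sample(studies$study_id, spec$n_experiments, replace = TRUE),
    mesh_id = sample(mesh_ids, spec$n_experiments, replace = TRUE),
    hpo_id = ifelse(with_hpo,
                    sample(hpo_ids, spec$n_experiments, replace = TRUE),
                    NA_character_),
    closest_match = FALSE,
    annotation_note = NA_character_,
    sample_panel = paste("panel", sample(1:3, spec$n_experiments, replace = TRUE)),
    analysis_method = paste("method", sample(1:2, spec$n_experiments, replace = TRUE)))
  markers <- dplyr::tibble(
    accession = sprintf("HGVM%06d", seq_len(spec$n_markers)),
    rs_id = sprintf("rs%07d", sample.int(9999999, spec$n_markers)),
    gene_symbols = lapply(seq_len(spec$n_markers), function(i)
      paste0("GENE", sample.int(50, sample(0:2, 1)))))
  key <- rbinom(spec$n_markers, 1L, spec$fraction_below) == 1L
  lp <- numeric(spec$n_markers)
  lp[key] <- runif(sum(key), spec$log10_range_key[1], spec$log10_range_key[2])
  lp[!key] <- runif(sum(!key), spec$log10_range_null[1], spec$log10_range_null[2])
  associations <- dplyr::tibble(
    experiment_id = sample(experiments$experiment_id, spec$n_markers,
                           replace = TRUE),
    marker_accession = markers$accession,
    p_value = pmin(10^lp, 1))
  gwas_store(studies, experiments, markers, associations)
}

#' The packaged human-mouse pipeline worked example
#'
#' Adapter fixture bundle reproducing the published BAZ1B comparison:
#' three GWAS Central annotations (Plasma; Protein C; Triglycerides, the
#' last carrying marker rs1178979 at p = 2e-12), three EuroPhenome
#' annotations (decreased body weight; decreased circulating cholesterol
#' level at p = 7.76e-7; decreased circulating HDL cholesterol level at
#' p = 8.20e-6) and the 28 MGD annotations. Identifiers and the p-values
#' the published example does not print (Plasma, Protein C, decreased
#' body weight) are synthetic, chosen below the worked example's
#' thresholds, and tagged in the `synthetic` column. The bundle is
#' byte-stable across calls.
#'
#' @return Fixture bundle (list of tibbles) accepted by
#'   [fixture_adapters()].
#' @export
make_table2_fixture <- function() {
  mgd_labels <- c(
    "Short mandible", "Abnormal myocardial trabeculae morphology",
    "Abnormal myocardium layer morphology", "Malocclusion", "Broad head",
    "Short snout", "Decreased body size", "Decreased litter size",
    "Postnatal lethality", "Micrognathia", "Decreased fetal size",
    "Small parietal bone", "Short nasal bone",
    "Abnormal palatine bone morphology", "Hypercalcemia",
    "Abnormal heart morphology", "Double outlet right ventricle",
    "Dilated heart left ventricle", "Dilated heart right ventricle",
    "Aorta coarctation", "Abnormal fourth branchial arch morphology",
    "Decreased birth body size", "Atrial septal defect",
    "Muscular ventricular septal defect",
    "Increased heart right ventricle size",
    "Increased heart left ventricle size",
    "Abnormal double-strand DNA break repair", "Complete postnatal lethality")
  list(
    genes = dplyr::tibble(symbol = "BAZ1B", gene_id = "9031"),
    orthologs = dplyr::tibble(human_symbol = "BAZ1B", mouse_symbol = "Baz1b"),
    human_annotations = dplyr::tibble(
      symbol = "BAZ1B",
      mesh_id = c("D010949", "D011326", "D014280"),
      label = c("Plasma", "Protein C", "Triglycerides"),
      marker = c("rs2073963", "rs867186", "rs1178979"),
      p_value = c(5.0e-8, 3.1e-9, 2e-12),
      synthetic = c(TRUE, TRUE, FALSE)),
    mgd_annotations = dplyr::tibble(
      mouse_symbol = "Baz1b",
      mpo_id = sprintf("MP:%07d", 9000000L + seq_along(mgd_labels)),
      label = mgd_labels),
    europhenome_annotations = dplyr::tibble(
      mouse_symbol = "Baz1b",
      mpo_id = c("MP:0001262", "MP:0005439", "MP:0000184"),
      label = c("Decreased body weight",
                "Decreased circulating cholesterol level",
                "Decreased circulating HDL cholesterol level"),
      p_value = c(3.0e-6, 7.76e-7, 8.20e-6),
      synthetic = c(TRUE, FALSE, FALSE))
  )
}

#' Write a pipeline fixture bundle as TSV files
#'
#' @param bundle A fixture bundle (list of tibbles).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(bundle)) {
    readr::write_tsv(bundle[[nm]], file.path(dir, paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  invisible(dir)
}
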