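demo_store <- function() {
  gwas_store(
    studies = tibble::tibble(
      study_id = c("HGVST626", "HGVST001"),
      pubmed_id = c("22156575", NA),
      title = c("Triglyceride GWAS", "Coronary GWAS")),
    experiments = tibble::tibble(
      experiment_id = c("E1", "E2", "E3"),
      study_id = c("HGVST626", "HGVST001", "HGVST001"),
      mesh_id = c("D014280", "D003324", "D003324"),
      hpo_id = c(NA, NA, "HP:0001717"),
      closest_match = FALSE, annotation_note = NA_character_,
      sample_panel = "panel 1", analysis_method = "method 1"),
    markers = tibble::tibble(
      accession = "HGVM1", rs_id = "rs1178979",
      gene_symbols = list("BAZ1B")),
    associations = tibble::tibble(
      experiment_id = "E1", marker_accession = "HGVM1", p_value = 2e-12))
}

test_that("store construction enforces referential integrity", {
  s <- demo_store()
  expect_s3_class(s, "phenosem_store")
  expect_error(gwas_store(
    experiments = tibble::tibble(
      experiment_id = "E1", study_id = "NOPE", mesh_id = "D1",
      hpo_id = NA_character_, closest_match = FALSE,
      annotation_note = NA_character_, sample_panel = "p",
      analysis_method = "m")), "unknown study")
  bad <- demo_store()
  bad$associations$p_value <- 0
  expect_error(do.call(gwas_store, unclass(bad)), "p-values")
})

test_that("annotation replaces the phenotype and validates the Descriptor", {
  b <- toy_bundle()
  s <- demo_store()
  # a trait like sporadic ALS gets the closest available Descriptor,
  # flagged with a note
  s2 <- add_annotation(s, "E1", "D007562", closest_match = TRUE,
                       annotation_note = "closest parent Descriptor chosen",
                       mesh_vocab = b$mesh)
  e <- s2$experiments[s2$experiments$experiment_id == "E1", ]
  expect_equal(e$mesh_id, "D007562")
  expect_true(e$closest_match)
  expect_error(add_annotation(s, "E1", "D999999", mesh_vocab = b$mesh),
               "unknown MeSH")
  expect_error(add_annotation(s, "E1", "D007562", closest_match = TRUE,
                              mesh_vocab = b$mesh), "note")
  # re-annotation replaces, never duplicates
  s3 <- add_annotation(s2, "E1", "D014280", mesh_vocab = b$mesh)
  expect_equal(sum(s3$experiments$experiment_id == "E1"), 1L)
  expect_equal(s3$experiments$mesh_id[s3$experiments$experiment_id == "E1"],
               "D014280")
})

test_that("experiments are retrieved by term, optionally with descendants", {
  b <- toy_bundle()
  s <- demo_store()
  direct <- experiments_for_term(s, "D003324", list(b$mesh, b$hpo))
  expect_equal(direct$experiment_id, c("E2", "E3"))
  # D002318 (root of the cardiovascular branch) has no direct annotations
  expect_equal(nrow(experiments_for_term(s, "D002318", b$mesh)), 0L)
  with_desc <- experiments_for_term(s, "D002318", b$mesh,
                                    include_descendants = TRUE)
  expect_equal(with_desc$experiment_id, c("E2", "E3"))
  # an experiment annotated under both hierarchies is counted once
  hpo_hit <- experiments_for_term(s, "HP:0001717", list(b$mesh, b$hpo))
  expect_equal(hpo_hit$experiment_id, "E3")
  expect_error(experiments_for_term(s, "NOPE", b$mesh), "not found")
})

test_that("deduplication holds on diamond hierarchies", {
  diamond <- parse_obo(c(
    "[Term]", "id: HP:A", "name: leaf", "is_a: HP:B", "is_a: HP:C",
    "", "[Term]", "id: HP:B", "name: left", "is_a: HP:D",
    "", "[Term]", "id: HP:C", "name: right", "is_a: HP:D",
    "", "[Term]", "id: HP:D", "name: root"))
  s <- gwas_store(
    studies = tibble::tibble(study_id = "S", pubmed_id = NA, title = "t"),
    experiments = tibble::tibble(
      experiment_id = "E", study_id = "S", mesh_id = "HP:A",
      hpo_id = NA_character_, closest_match = FALSE,
      annotation_note = NA_character_, sample_panel = "p",
      analysis_method = "m"))
  out <- experiments_for_term(s, "HP:D", diamond, include_descendants = TRUE)
  expect_equal(out$experiment_id, "E")
})

test_that("the annotated hierarchy is pruned with per-term counts", {
  b <- toy_bundle()
  empty <- gwas_store(
    studies = tibble::tibble(study_id = "S", pubmed_id = NA, title = "t"))
  expect_equal(nrow(annotated_hierarchy(b$mesh, empty)), 0L)

  s <- demo_store()
  h <- annotated_hierarchy(b$mesh, s)
  # annotated terms plus their ancestors, nothing else
  expect_setequal(h$term_id, c("D014280", "D003324", "D003327", "D002318"))
  expect_equal(h$n_experiments[h$term_id == "D003324"], 2L)
  expect_equal(h$n_experiments[h$term_id == "D014280"], 1L)
  # ancestors kept for connectivity are marked structural with no direct count
  expect_true(h$structural[h$term_id == "D002318"])
  expect_equal(h$n_experiments[h$term_id == "D002318"], 0L)
  hc <- annotated_hierarchy(b$mesh, s, cumulative = TRUE)
  expect_equal(hc$n_experiments[hc$term_id == "D002318"], 2L)
})

test_that("autosuggest only offers annotated terms and synonyms", {
  b <- toy_bundle()
  s <- demo_store()
  expect_true(any(grepl("Coronary Artery",
                        autosuggest_terms("coronary", s, b$mesh))))
  # synonyms of annotated Descriptors are offered too
  expect_true("Coronary Arteriosclerosis" %in%
                autosuggest_terms("coronary a", s, b$mesh, limit = 10))
  # Gaucher Disease exists in the vocabulary but is not annotated
  expect_equal(autosuggest_terms("gaucher", s, b$mesh), character())
  expect_error(autosuggest_terms("", s, b$mesh), "non-empty")
})

test_that("stores round-trip losslessly through JSON and import TSV", {
  s <- demo_store()
  s2 <- store_from_json(store_to_json(s))
  expect_equal(s2$studies, s$studies)
  expect_equal(s2$experiments, s$experiments)
  expect_equal(s2$associations$p_value, s$associations$p_value)
  expect_equal(s2$markers$gene_symbols, s$markers$gene_symbols)

  s3 <- import_associations_tsv(s, c(
    "experiment_id\tmarker_accession\trs_id\tp_value",
    "E2\tHGVM2\trs123\t3.5e-9"))
  expect_equal(nrow(s3$associations), 2L)
  expect_true("HGVM2" %in% s3$markers$accession)
})
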