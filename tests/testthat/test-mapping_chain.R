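hpo_with_xrefs <- function(ids, xrefs) {
  new_vocabulary("HPO", tibble::tibble(
    id = ids, label = paste("term", ids),
    synonyms = rep(list(character()), length(ids)),
    xrefs = xrefs, parents = rep(list(character()), length(ids))))
}

test_that("cross map joins MeSH and HPO on shared CUIs", {
  hpo <- hpo_with_xrefs(c("HP:1", "HP:2", "HP:3"),
                        list("UMLS:C1", "UMLS:C2", character()))
  cross <- build_cross_map(hpo, tibble::tibble(mesh_id = "D1", cui = "C1"))
  expect_equal(mesh_to_hpo(cross, "D1"), "HP:1")
  expect_equal(hpo_to_mesh(cross, "HP:1"), "D1")
  # an HPO term without a UMLS xref pairs with nothing
  expect_equal(hpo_to_mesh(cross, "HP:3"), character())
  # two HPO terms sharing one CUI both pair with the MeSH id
  hpo2 <- hpo_with_xrefs(c("HP:1", "HP:2"), list("UMLS:C9", "UMLS:C9"))
  cross2 <- build_cross_map(hpo2, tibble::tibble(mesh_id = "D9", cui = "C9"))
  expect_setequal(mesh_to_hpo(cross2, "D9"), c("HP:1", "HP:2"))
})

test_that("ambiguous CUI claims warn but keep all pairs", {
  hpo <- hpo_with_xrefs("HP:1", list("UMLS:C1"))
  expect_warning(
    cross <- build_cross_map(hpo, tibble::tibble(
      mesh_id = c("D1", "D2"), cui = c("C1", "C1"))),
    "multiple MeSH")
  expect_setequal(hpo_to_mesh(cross, "HP:1"), c("D1", "D2"))
})

test_that("cross map round-trips on bijective toy tables", {
  set.seed(5)
  n <- 20L
  mesh_ids <- sprintf("D%03d", 1:n)
  hpo_ids <- sprintf("HP:%04d", sample(1:9999, n))
  cuis <- sprintf("C%05d", sample(1:99999, n))
  hpo <- hpo_with_xrefs(hpo_ids, as.list(paste0("UMLS:", cuis)))
  cross <- build_cross_map(hpo, tibble::tibble(mesh_id = mesh_ids, cui = cuis))
  for (i in seq_len(n)) {
    expect_equal(hpo_to_mesh(cross, mesh_to_hpo(cross, mesh_ids[i])),
                 mesh_ids[i])
  }
  # inverse consistency over the whole pair table
  p <- tidy(cross)
  expect_true(all(vapply(seq_len(nrow(p)), function(i)
    p$mesh_id[i] %in% hpo_to_mesh(cross, p$hpo_id[i]), logical(1))))
})

test_that("the HPO-OMIM annotation file parses and deduplicates", {
  tsv <- c("database_id\tdisease_name\thpo_id",
           "OMIM:123456\tSome disease\tHP:0000001",
           "OMIM:123456\tSome disease\tHP:0000002",
           "OMIM:123456\tSome disease\tHP:0000002")
  ann <- parse_hpo_omim_annotations(tsv)
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$hpo_id, c("HP:0000001", "HP:0000002"))
  expect_error(parse_hpo_omim_annotations(c(
    "database_id\tdisease_name\thpo_id",
    "MIM:12\tbad\tHP:0000001")), "line 1")
})

test_that("the packaged disease fixture carries the expected abnormalities", {
  b <- toy_bundle()
  labels <- b$hpo$terms$label[match(b$hpo_omim$hpo_id, b$hpo$terms$id)]
  expect_true(all(c("Confusion", "Loss of facial expression") %in% labels))
})

test_that("inferred phenotypes follow MeSH -> OMIM -> HPO, grouped by OMIM", {
  b <- toy_bundle()
  maps <- omim_mapping(b$hpo_omim, b$omim_mesh)
  inf <- inferred_phenotypes("D007562", maps)
  expect_true("HP:0001289" %in% inf$hpo_id)  # Confusion
  expect_equal(unique(inf$omim_id), "OMIM:123400")
  # MeSH id with no OMIM link: empty result, not an error
  expect_equal(nrow(inferred_phenotypes("D014280", maps)), 0L)
  # two OMIM entries with overlapping sets are both returned intact
  hpo_omim2 <- parse_hpo_omim_annotations(c(
    "database_id\tdisease_name\thpo_id",
    "OMIM:100000\tdisease one\tHP:0000001",
    "OMIM:100000\tdisease one\tHP:0000002",
    "OMIM:200000\tdisease two\tHP:0000002"))
  maps2 <- omim_mapping(hpo_omim2, tibble::tibble(
    omim_id = c("OMIM:100000", "OMIM:200000"), mesh_id = c("D1", "D1")))
  inf2 <- inferred_phenotypes("D1", maps2)
  expect_equal(nrow(inf2), 3L)
  expect_setequal(inf2$hpo_id[inf2$omim_id == "OMIM:100000"],
                  c("HP:0000001", "HP:0000002"))
  # monotonicity: adding an OMIM entry never removes an HPO term
  maps1 <- omim_mapping(hpo_omim2, tibble::tibble(
    omim_id = "OMIM:100000", mesh_id = "D1"))
  inf1 <- inferred_phenotypes("D1", maps1)
  expect_true(all(paste(inf1$omim_id, inf1$hpo_id) %in%
                    paste(inf2$omim_id, inf2$hpo_id)))
})

test_that("annotation resolution applies direct > mapped > inferred", {
  b <- toy_bundle()
  cross <- build_cross_map(b$hpo, b$mesh_cui)
  maps <- omim_mapping(b$hpo_omim, b$omim_mesh)
  # direct manual HPO annotation wins without consulting the maps
  r1 <- resolve_annotation(list(mesh_id = "D004935", hpo_id = "HP:0003124"),
                           cross, maps)
  expect_equal(r1$route, "direct")
  expect_equal(r1$hpo_id, "HP:0003124")
  # MeSH with a shared-CUI pair resolves through the cross map
  r2 <- resolve_annotation(list(mesh_id = "D004935"), cross, maps)
  expect_equal(unique(r2$route), "mapped")
  expect_equal(r2$hpo_id, "HP:0002031")
  # disease Descriptor with only OMIM links resolves to the inferred set
  r3 <- resolve_annotation(list(mesh_id = "D007562"), cross, maps)
  expect_equal(unique(r3$route), "inferred")
  expect_true("HP:0001289" %in% r3$hpo_id)
  expect_true(all(!is.na(r3$omim_id)))
  # no route at all is tagged, never silently dropped
  r4 <- resolve_annotation(list(mesh_id = "D014280"), cross, maps)
  expect_equal(r4$route, "mesh-only")
  expect_error(resolve_annotation(list(mesh_id = NA_character_), cross, maps),
               "MeSH id")
})
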