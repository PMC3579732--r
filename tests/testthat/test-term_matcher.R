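mini_vocab <- function(name, labels, synonyms = NULL) {
  n <- length(labels)
  new_vocabulary(name, tibble::tibble(
    id = sprintf("%s:%03d", toupper(name), seq_len(n)),
    label = labels,
    synonyms = if (is.null(synonyms)) rep(list(character()), n) else synonyms,
    xrefs = rep(list(character()), n),
    parents = rep(list(character()), n)))
}

test_that("exact matching is case-insensitive over labels and synonyms", {
  mesh <- mini_vocab("mesh", "Forced Expiratory Volume")
  hits <- exact_match("forced expiratory volume", mesh)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$term_id, "MESH:001")
  expect_false(hits$via_variant)

  hpo <- mini_vocab("hpo", "Abnormal number of teeth")
  expect_equal(nrow(exact_match("number of teeth", hpo)), 0L)
  expect_equal(nrow(exact_match("", hpo)), 0L)

  syn <- mini_vocab("v", "Heading", synonyms = list("entry term"))
  expect_equal(exact_match("ENTRY TERM", syn)$matched_string, "entry term")
})

test_that("partial matching implements per-word wildcard containment", {
  hpo <- mini_vocab("hpo", "Abnormal number of teeth")
  expect_equal(nrow(partial_match("number of teeth", hpo)), 1L)
  sct <- mini_vocab("sct", c("Ventricular conduction pattern",
                             "Normal forced expiratory volume"))
  expect_equal(partial_match("ventricular conduction", sct)$term_id, "SCT:001")
  expect_equal(partial_match("forced expiratory volume", sct)$term_id, "SCT:002")
  # token order is required; scrambled queries do not hit
  expect_equal(nrow(partial_match("teeth number of", hpo)), 0L)
  # each query token must prefix some candidate token
  expect_equal(nrow(partial_match("number of tusks", hpo)), 0L)
})

test_that("spelling variants are tried only when the base form misses", {
  v <- mini_vocab("hpo", "Abnormality of the esophagus")
  trait <- normalize_traits("Abnormality of the oesophagus")[1, ]
  hits <- exact_match(trait, v)
  expect_equal(nrow(hits), 1L)
  expect_true(hits$via_variant)
  expect_equal(hits$query_form, "Abnormality of the esophagus")

  # when the base form already hits, the variant is not consulted
  both <- mini_vocab("both", c("Hair colour", "Hair color"))
  trait2 <- normalize_traits("Hair colour")[1, ]
  hits2 <- exact_match(trait2, both)
  expect_false(any(hits2$via_variant))
  expect_equal(hits2$term_id, "BOTH:001")
})

test_that("every exact hit is reproduced by partial matching", {
  set.seed(11)
  labels <- replicate(30, paste(sample(letters, sample(1:3, 1), TRUE),
                                collapse = " "))
  v <- mini_vocab("rand", unique(labels))
  for (q in sample(unique(labels), 10)) {
    ex <- exact_match(q, v)
    pa <- partial_match(q, v)
    expect_true(all(ex$term_id %in% pa$term_id))
  }
})

test_that("partial matcher agrees with the regex brute-force oracle", {
  set.seed(23)
  words <- c("ab", "abc", "abd", "xy", "xyz", "q", "qu", "number", "of",
             "teeth", "tooth", "volume")
  queries <- replicate(40, paste(sample(words, sample(1:3, 1), TRUE),
                                 collapse = " "))
  cands <- replicate(60, paste(sample(words, sample(1:4, 1), TRUE),
                               collapse = " "))
  v <- mini_vocab("orc", unique(cands))
  idx_labels <- v$terms$label
  for (q in unique(queries)) {
    got <- partial_match(q, v)$matched_string
    want <- idx_labels[vapply(idx_labels, regex_partial_oracle,
                              logical(1), query = q)]
    expect_setequal(got, unique(want))
  }
})

test_that("map_corpus counts unique mappings per vocabulary", {
  va <- mini_vocab("A", "alpha trait")
  vb <- mini_vocab("B", c("alpha trait", "beta trait"))
  vc <- mini_vocab("C", "gamma trait")
  res <- map_corpus(c("alpha trait", "beta trait", "delta trait"),
                    list(va, vb, vc))
  tab <- suitability_table(res)
  # "alpha trait" maps to A and B (no unique credit), "beta trait" only to B
  expect_equal(tab$n_exact[tab$vocabulary == "A"], 1L)
  expect_equal(tab$n_unique_exact[tab$vocabulary == "A"], 0L)
  expect_equal(tab$n_exact[tab$vocabulary == "B"], 2L)
  expect_equal(tab$n_unique_exact[tab$vocabulary == "B"], 1L)
  expect_equal(tab$n_exact[tab$vocabulary == "C"], 0L)
  expect_equal(tab$pct_exact[tab$vocabulary == "C"], 0)
  # sum of unique counts never exceeds the number of mapped traits
  g <- glance(res)
  expect_lte(sum(tab$n_unique_exact), g$n_exact_mapped)
  expect_lte(sum(tab$n_unique_partial), g$n_partial_mapped)
  expect_error(map_corpus("x", list()), "at least one vocabulary")
  expect_error(map_corpus("x", list(va, va)), "distinct")
})

test_that("percentages round half-up at one decimal", {
  expect_equal(round_half_up(20.3632, 1), 20.4)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(0.349999, 1), 0.3)
  expect_equal(round_half_up(c(10.85, 10.84), 1), c(10.9, 10.8))
  row <- suitability_from_counts("V", 213, 256, 51, 29, 1046, 332, 434)
  expect_equal(row$pct_exact, 20.4)
  expect_equal(row$pct_unique_exact, 15.4)
})

test_that("hits round-trip through the TSV exchange format", {
  va <- mini_vocab("A", "alpha trait")
  res <- map_corpus("alpha trait", list(va))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(tidy(res), path)
  back <- read_hits_tsv(path)
  expect_equal(back$term_id, tidy(res)$term_id)
  expect_equal(back$mode, tidy(res)$mode)
})
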