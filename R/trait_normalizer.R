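#' Normalise free-text GWAS phenotype descriptions
#'
#' GWAS reports describe phenotypes with a value attached ("Hair color:
#' black versus red"); vocabularies describe traits ("Hair color") in the
#' singular, usually in one national spelling. Normalisation runs three
#' steps before lexical matching: (1) strip trait values, (2) depluralise,
#' (3) generate spelling-variant alternatives so that British and American
#' spellings are both queried.
#'
#' @name trait_normalizer
NULL

#' Strip the value clause from a phenotype description
#'
#' Removes everything after the first colon and any trailing
#' "versus ..."/"vs ..." clause, then collapses whitespace. This is a
#' heuristic stand-in for a curator's judgement; [normalize_traits()] flags
#' every description it changes so the list can be reviewed.
#'
#' @param description Character vector of free-text descriptions.
#' @return Character vector of trait strings.
#' @examples
#' strip_trait_values("Hair color: black versus red")
#' @export
strip_trait_values <- function(description) {
  x <- sub(":.*$", "", description)
  x <- stringr::str_replace(x, stringr::regex("\\s+(versus|vs\\.?)\\s.*$",
                                              ignore_case = TRUE), "")
  stringr::str_squish(x)
}

#' Singularise each word of a trait description
#'
#' Applies a rule ladder per word: `...ies` -> `...y`; sibilant endings
#' (`sses`, `xes`, `ches`, `shes`, `zes`) drop `es`; otherwise a trailing
#' `s` is dropped unless the word ends in `ss`, `us` or `is`. Words on the
#' exception list (disease names such as "diabetes" whose final s is not a
#' plural) are left untouched. The ladder is deliberately conservative:
#' naive stemming corrupts disease names.
#'
#' @param term Character vector of trait strings.
#' @param exceptions Lowercased words to leave untouched; defaults to the
#'   packaged list ([plural_exceptions()]).
#' @return Character vector with each word singularised.
#' @examples
#' depluralize("Triglycerides")
#' depluralize("diabetes")
#' @export
depluralize <- function(term, exceptions = plural_exceptions()) {
  one_word <- function(w) {
    lw <- tolower(w)
    if (lw %in% exceptions || nchar(w) < 3L) return(w)
    if (grepl("ies$", lw) && nchar(w) > 4L) return(sub("ies$", "y", w))
    if (grepl("(sses|xes|ches|shes|zes)$", lw)) return(sub("es$", "", w))
    if (grepl("[^su]s$", lw) && !grepl("is$", lw)) return(sub("s$", "", w))
    w
  }
  vapply(term, function(t) {
    if (is.na(t) || !nzchar(t)) return(t)
    words <- strsplit(t, " ", fixed = TRUE)[[1]]
    paste(vapply(words, one_word, character(1)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Packaged depluralisation exception list
#'
#' Lowercased words ending in s that are not plurals (mostly disease names).
#' The list ships as a plain-text file under `extdata` and is
#' user-replaceable.
#'
#' @param path Optional path to an alternative exception file (one word per
#'   line, `#` comments allowed).
#' @return Character vector of lowercased words.
#' @export
plural_exceptions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "plural_exceptions.txt",
                                package = "phenosem", mustWork = TRUE)
  x <- readr::read_lines(path, progress = FALSE)
  x <- trimws(sub("#.*$", "", x))
  tolower(x[nzchar(x)])
}

#' Load a spelling-variant word table
#'
#' Two-column TSV (`word`, `variant`), lowercased, modelled on public lists
#' of British/American spelling differences. The mapping is symmetric:
#' either spelling yields the other. The packaged table is user-replaceable
#' because spelling-variant inventories drift over time.
#'
#' @param path Path to a TSV; defaults to the packaged table.
#' @return A named character vector (the symmetric closure: both
#'   directions present), classed `phenosem_variant_table`.
#' @export
spelling_variant_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "spelling_variants.tsv",
                                package = "phenosem", mustWork = TRUE)
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  w <- tolower(df[[1]]); v <- tolower(df[[2]])
  keep <- w != v
  w <- w[keep]; v <- v[keep]
  tab <- c(setNames(v, w), setNames(w, v))
  tab <- tab[!duplicated(names(tab))]
  structure(tab, class = "phenosem_variant_table")
}

#' Spelling-variant alternatives of a trait string
#'
#' Splits the term into words and, for each word with an entry in the
#' variant table, emits one alternative term with that single word replaced
#' (sentence capitalisation preserved). Returns an empty vector when no
#' word has a variant.
#'
#' @param term A single trait string.
#' @param table A [spelling_variant_table()].
#' @return Character vector of alternative spellings (possibly empty),
#'   never containing `term` itself.
#' @examples
#' tab <- spelling_variant_table()
#' expand_spelling_variants("Abnormality of the oesophagus", tab)
#' @export
expand_spelling_variants <- function(term, table = spelling_variant_table()) {
  stopifnot(length(term) == 1L)
  if (is.na(term) || !nzchar(term)) return(character())
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  out <- character()
  for (i in seq_along(words)) {
    alt <- unname(table[tolower(words[i])])
    if (!is.na(alt) && length(alt)) {
      repl <- if (grepl("^[A-Z]", words[i])) {
        paste0(toupper(substr(alt, 1, 1)), substr(alt, 2, nchar(alt)))
      } else alt
      cand <- words
      cand[i] <- repl
      out <- c(out, paste(cand, collapse = " "))
    }
  }
  setdiff(unique(out), term)
}

#' Normalise one description through all three steps
#'
#' `base` is the value-stripped, depluralised form; `variant_forms` are its
#' spelling alternatives. Matching is case-insensitive downstream, so case
#' is preserved here for display.
#'
#' @param description A single free-text phenotype description.
#' @param table A [spelling_variant_table()].
#' @param exceptions Depluralisation exceptions, see [depluralize()].
#' @return A list with `original`, `base`, `variant_forms`.
#' @export
normalize_description <- function(description, table = spelling_variant_table(),
                                  exceptions = plural_exceptions()) {
  stopifnot(length(description) == 1L)
  if (is.na(description) || !nzchar(trimws(description))) {
    abort("cannot normalize an empty phenotype description")
  }
  base <- depluralize(strip_trait_values(description), exceptions)
  list(original = description, base = base,
       variant_forms = expand_spelling_variants(base, table))
}

#' Normalise a whole trait list
#'
#' Tidy entry point over a data frame of descriptions (or a bare character
#' vector). One row per input; `value_stripped` flags descriptions the
#' value-stripping heuristic changed, for curator review.
#'
#' @param traits Data frame with a `description` column, or a character
#'   vector of descriptions.
#' @param table A [spelling_variant_table()].
#' @param exceptions Depluralisation exceptions.
#' @return Tibble with columns `original`, `base`, `variant_forms`
#'   (list-column), `value_stripped`.
#' @examples
#' normalize_traits(c("Hair colours: brown", "Triglycerides"))
#' @export
normalize_traits <- function(traits, table = spelling_variant_table(),
                             exceptions = plural_exceptions()) {
  if (is.data.frame(traits)) {
    if (!"description" %in% names(traits)) {
      abort("`traits` data frame needs a `description` column")
    }
    desc <- as.character(traits$description)
  } else {
    desc <- as.character(traits)
  }
  if (!length(desc)) abort("no trait descriptions supplied")
  norm <- lapply(desc, normalize_description, table = table,
                 exceptions = exceptions)
  dplyr::tibble(
    original = desc,
    base = vapply(norm, `[[`, character(1), "base"),
    variant_forms = lapply(norm, `[[`, "variant_forms"),
    value_stripped = vapply(norm, function(n)
      !identical(strip_trait_values(n$original), stringr::str_squish(n$original)),
      logical(1))
  )
}

#' Read / write trait lists in the tab-separated exchange layout
#'
#' The input layout is one description per line; the output layout is the
#' original description, the normalised base and any spelling variants,
#' tab-separated on one line.
#'
#' @param path File path.
#' @return `read_trait_list()`: tibble with a `description` column.
#' @export
read_trait_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  dplyr::tibble(description = vapply(strsplit(lines, "\t", fixed = TRUE),
                                     `[[`, character(1), 1L))
}

#' @rdname read_trait_list
#' @param normalized Tibble from [normalize_traits()].
#' @export
write_trait_list <- function(normalized, path) {
  lines <- vapply(seq_len(nrow(normalized)), function(i) {
    paste(c(normalized$original[i], normalized$base[i],
            normalized$variant_forms[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
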