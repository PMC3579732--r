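#' Lexical matching of traits against vocabularies
#'
#' Reproduces BioPortal-style term search: case-insensitive exact matching
#' of a trait against term labels and synonyms, and partial matching in
#' which a wildcard is implicitly appended to every query word. A partial
#' hit requires every query token to be a prefix of some candidate token,
#' tokens consumed left to right in order; the candidate may contain extra
#' tokens anywhere. Spelling-variant forms are tried only when the base
#' form finds nothing in that vocabulary.
#'
#' @name term_matcher
NULL

match_tokens <- function(x) {
  toks <- strsplit(tolower(x), "[^[:alnum:]]+")
  lapply(toks, function(t) t[nzchar(t)])
}

# every query token is a prefix of a candidate token, in order (greedy
# left-most matching is exact for subsequence-with-prefix containment)
partial_tokens_match <- function(qtok, ctok) {
  if (!length(qtok)) return(FALSE)
  j <- 1L
  nc <- length(ctok)
  for (q in qtok) {
    found <- FALSE
    while (j <= nc) {
      if (startsWith(ctok[[j]], q)) {
        found <- TRUE
        j <- j + 1L
        break
      }
      j <- j + 1L
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# one row per candidate string (label or synonym) of a vocabulary
candidate_index <- function(vocab) {
  stopifnot(inherits(vocab, "phenosem_vocabulary"))
  terms <- vocab$terms
  idx <- dplyr::tibble(
    term_id = rep(terms$id, times = 1L + lengths(terms$synonyms)),
    string = as.character(unlist(purrr::map2(terms$label, terms$synonyms, c),
                                 use.names = FALSE))
  )
  idx$lower <- tolower(idx$string)
  idx$tokens <- match_tokens(idx$string)
  idx
}

match_one_form <- function(form, idx, mode) {
  if (is.na(form) || !nzchar(form)) {
    return(idx[0, c("term_id", "string")])
  }
  if (mode == "exact") {
    keep <- idx$lower == tolower(form)
  } else {
    qtok <- match_tokens(form)[[1]]
    keep <- vapply(idx$tokens, partial_tokens_match, logical(1), qtok = qtok)
  }
  idx[keep, c("term_id", "string")]
}

match_trait_forms <- function(base, variant_forms, idx, mode) {
  hits <- match_one_form(base, idx, mode)
  if (nrow(hits)) {
    hits$via_variant <- FALSE
    hits$query_form <- base
    return(hits)
  }
  # variant fallback: tried per vocabulary, only when the base form missed
  out <- list()
  for (vf in variant_forms) {
    h <- match_one_form(vf, idx, mode)
    if (nrow(h)) {
      h$via_variant <- TRUE
      h$query_form <- vf
      out <- c(out, list(h))
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    hits$via_variant <- logical()
    hits$query_form <- character()
    hits
  }
}

#' Exact or partial hits of one trait in one vocabulary
#'
#' @param trait A one-row tibble from [normalize_traits()], or a list with
#'   `base` and `variant_forms`, or a bare string (taken as an already
#'   normalised base form).
#' @param vocab A [new_vocabulary()] object.
#' @return Tibble of hits: `vocabulary`, `term_id`, `matched_string`,
#'   `mode`, `via_variant`, `query_form`.
#' @examples
#' v <- new_vocabulary("toy", tibble::tibble(
#'   id = "D005541", label = "Forced Expiratory Volume",
#'   synonyms = list(character()), xrefs = list(character()),
#'   parents = list(character())))
#' exact_match("forced expiratory volume", v)
#' @export
exact_match <- function(trait, vocab) {
  match_trait(trait, vocab, mode = "exact")
}

#' @rdname exact_match
#' @export
partial_match <- function(trait, vocab) {
  match_trait(trait, vocab, mode = "partial")
}

match_trait <- function(trait, vocab, mode = c("exact", "partial")) {
  mode <- match.arg(mode)
  if (is.character(trait)) trait <- list(base = trait, variant_forms = character())
  if (is.data.frame(trait)) {
    stopifnot(nrow(trait) == 1L)
    trait <- list(base = trait$base[[1]],
                  variant_forms = trait$variant_forms[[1]])
  }
  idx <- candidate_index(vocab)
  hits <- match_trait_forms(trait$base, trait$variant_forms %||% character(),
                            idx, mode)
  dplyr::tibble(vocabulary = rep(vocab$name, nrow(hits)),
                term_id = hits$term_id,
                matched_string = hits$string,
                mode = rep(mode, nrow(hits)),
                via_variant = hits$via_variant,
                query_form = hits$query_form)
}

#' Map a trait corpus against a set of vocabularies
#'
#' Runs both exact and partial matching for every trait in every
#' vocabulary. A trait "maps" to a vocabulary when at least one term
#' matches; multiplicity does not affect the coverage statistics. A unique
#' mapping is a trait that maps (in the given mode) to exactly one of the
#' compared vocabularies.
#'
#' @param traits Tibble from [normalize_traits()] (or anything it accepts).
#' @param vocabs List of [new_vocabulary()] objects with distinct names.
#' @param ... Passed on to [normalize_traits()] when `traits` is raw text.
#' @return A `phenosem_mapping_result`: list with `traits`, `hits`
#'   (tibble of every hit, deterministic order) and `vocabularies`.
#' @export
map_corpus <- function(traits, vocabs, ...) {
  if (!length(vocabs)) abort("at least one vocabulary is required")
  if (inherits(vocabs, "phenosem_vocabulary")) vocabs <- list(vocabs)
  vnames <- vapply(vocabs, function(v) v$name, character(1))
  if (anyDuplicated(vnames)) abort("vocabulary names must be distinct")
  if (!is.data.frame(traits) || !"base" %in% names(traits)) {
    traits <- normalize_traits(traits, ...)
  }
  idxs <- lapply(vocabs, candidate_index)
  hit_rows <- vector("list", nrow(traits) * length(vocabs) * 2L)
  k <- 0L
  for (i in seq_len(nrow(traits))) {
    base <- traits$base[[i]]
    vf <- traits$variant_forms[[i]]
    for (j in seq_along(vocabs)) {
      for (mode in c("exact", "partial")) {
        h <- match_trait_forms(base, vf, idxs[[j]], mode)
        if (nrow(h)) {
          k <- k + 1L
          hit_rows[[k]] <- dplyr::tibble(
            trait_index = i, original = traits$original[[i]], base = base,
            vocabulary = vnames[[j]], term_id = h$term_id,
            matched_string = h$string, mode = mode,
            via_variant = h$via_variant, query_form = h$query_form)
        }
      }
    }
  }
  hits <- if (k) dplyr::bind_rows(hit_rows[seq_len(k)]) else dplyr::tibble(
    trait_index = integer(), original = character(), base = character(),
    vocabulary = character(), term_id = character(),
    matched_string = character(), mode = character(),
    via_variant = logical(), query_form = character())
  hits <- dplyr::arrange(hits, .data$trait_index, .data$vocabulary,
                         .data$mode, .data$term_id, .data$matched_string)
  structure(list(traits = traits, hits = hits, vocabularies = vnames),
            class = "phenosem_mapping_result")
}

#' @export
print.phenosem_mapping_result <- function(x, ...) {
  cat(sprintf("<phenosem_mapping_result> %d traits x %d vocabularies, %d hits\n",
              nrow(x$traits), length(x$vocabularies), nrow(x$hits)))
  invisible(x)
}

#' @rdname map_corpus
#' @param x A `phenosem_mapping_result`.
#' @export
tidy.phenosem_mapping_result <- function(x, ...) x$hits

#' @rdname map_corpus
#' @export
glance.phenosem_mapping_result <- function(x, ...) {
  dplyr::tibble(n_traits = nrow(x$traits),
                n_vocabularies = length(x$vocabularies),
                n_hits = nrow(x$hits),
                n_exact_mapped = length(mapped_trait_set(x, "exact")),
                n_partial_mapped = length(mapped_trait_set(x, "partial")))
}

# trait indices mapped (>=1 hit) in the given mode, any vocabulary
mapped_trait_set <- function(result, mode) {
  unique(result$hits$trait_index[result$hits$mode == mode])
}

#' Round half-up at a given number of decimals
#'
#' Commercial rounding (0.05 -> 0.1), unlike base R's round-half-even;
#' used for all printed coverage percentages.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(round(x * p, 6) + 0.5) / p
}

#' One vocabulary-suitability row from raw counts
#'
#' Computes the four coverage percentages exactly as the suitability table
#' does: exact/partial coverage over the full trait list, unique coverage
#' over the traits mapped (in that mode) to at least one vocabulary.
#' Percentages are rounded half-up to one decimal.
#'
#' @param vocabulary Vocabulary name.
#' @param n_exact,n_partial Traits mapped to this vocabulary per mode.
#' @param n_unique_exact,n_unique_partial Of those, traits mapped to this
#'   vocabulary only.
#' @param n_traits Total traits in the corpus.
#' @param n_exact_mapped,n_partial_mapped Traits mapped to >=1 vocabulary
#'   per mode (the unique-coverage denominators).
#' @return One-row tibble with counts and percentages.
#' @export
suitability_from_counts <- function(vocabulary, n_exact, n_partial,
                                    n_unique_exact, n_unique_partial,
                                    n_traits, n_exact_mapped,
                                    n_partial_mapped) {
  pct <- function(num, den) {
    if (den == 0) return(0)
    round_half_up(100 * num / den, 1)
  }
  dplyr::tibble(
    vocabulary = vocabulary,
    n_exact = n_exact, n_partial = n_partial,
    pct_exact = pct(n_exact, n_traits),
    pct_partial = pct(n_partial, n_traits),
    n_unique_exact = n_unique_exact, n_unique_partial = n_unique_partial,
    pct_unique_exact = pct(n_unique_exact, n_exact_mapped),
    pct_unique_partial = pct(n_unique_partial, n_partial_mapped)
  )
}

#' Vocabulary suitability statistics for a mapping result
#'
#' One row per vocabulary: how many traits it covers exactly and
#' partially (as counts and as percentages of the whole corpus), and how
#' many of the mapped traits it alone covers (unique mappings, as
#' percentages of all traits mapped in that mode).
#'
#' @param result A [map_corpus()] result.
#' @return Tibble (classed `phenosem_suitability`) with the columns of
#'   [suitability_from_counts()].
#' @export
suitability_table <- function(result) {
  stopifnot(inherits(result, "phenosem_mapping_result"))
  n_traits <- nrow(result$traits)
  if (!n_traits) abort("mapping result contains zero traits")
  per_mode <- function(mode) {
    h <- dplyr::distinct(result$hits[result$hits$mode == mode, ],
                         .data$trait_index, .data$vocabulary)
    nv <- dplyr::count(h, .data$trait_index, name = "n_vocab")
    h <- dplyr::left_join(h, nv, by = "trait_index")
    list(cov = table(factor(h$vocabulary, levels = result$vocabularies)),
         uni = table(factor(h$vocabulary[h$n_vocab == 1L],
                            levels = result$vocabularies)),
         mapped = nrow(nv))
  }
  ex <- per_mode("exact")
  pa <- per_mode("partial")
  rows <- lapply(result$vocabularies, function(v) {
    suitability_from_counts(
      vocabulary = v,
      n_exact = as.integer(ex$cov[[v]]), n_partial = as.integer(pa$cov[[v]]),
      n_unique_exact = as.integer(ex$uni[[v]]),
      n_unique_partial = as.integer(pa$uni[[v]]),
      n_traits = n_traits,
      n_exact_mapped = ex$mapped, n_partial_mapped = pa$mapped)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("phenosem_suitability", class(out))
  attr(out, "n_traits") <- n_traits
  attr(out, "n_exact_mapped") <- ex$mapped
  attr(out, "n_partial_mapped") <- pa$mapped
  out
}

#' Plot vocabulary coverage from a suitability table
#'
#' Bar chart of exact and partial corpus coverage per vocabulary.
#'
#' @param object A [suitability_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phenosem_suitability <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::as_tibble(object)[, c("vocabulary", "pct_exact", "pct_partial")],
    cols = c("pct_exact", "pct_partial"),
    names_to = "mode", values_to = "coverage")
  long$mode <- ifelse(long$mode == "pct_exact", "exact", "partial")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$vocabulary,
                                     y = .data$coverage,
                                     fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "corpus coverage (%)", fill = "match mode") +
    ggplot2::theme_minimal()
}

#' Write / read match hits as TSV
#'
#' @param hits Hits tibble (from `tidy()` on a mapping result).
#' @param path File path.
#' @return The path (write) or a tibble (read).
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    trait_index = "i", via_variant = "l", .default = "c"), progress = FALSE)
}
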