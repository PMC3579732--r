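# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# brute-force transitive reachability over parent links: repeatedly expand
# the parent sets until a fixpoint
brute_force_ancestors <- function(terms, id) {
  parent_map <- setNames(terms$parents, terms$id)
  reach <- character()
  repeat {
    nxt <- unique(c(reach, unlist(parent_map[c(id, reach)])))
    nxt <- intersect(nxt, terms$id)
    if (setequal(nxt, reach)) return(reach)
    reach <- nxt
  }
}

# regex oracle for wildcard partial matching: each query token becomes a
# token-prefix pattern, joined in order by ".*"
regex_partial_oracle <- function(query, candidate) {
  tok <- function(x) {
    t <- strsplit(tolower(x), "[^[:alnum:]]+")[[1]]
    t[nzchar(t)]
  }
  qt <- tok(query)
  if (!length(qt)) return(FALSE)
  cand <- paste(tok(candidate), collapse = " ")
  pat <- paste0("\\b", qt, "[[:alnum:]]*", collapse = ".*")
  grepl(pat, cand)
}

# deterministic random DAG on n nodes: node i may only point at lower-index
# nodes, so acyclicity holds by construction
random_dag_terms <- function(n, p_edge = 0.3) {
  ids <- sprintf("T%03d", seq_len(n))
  parents <- lapply(seq_len(n), function(i) {
    if (i == 1L) return(character())
    ids[which(runif(i - 1L) < p_edge)]
  })
  tibble::tibble(id = ids, label = paste("node", ids),
                 synonyms = rep(list(character()), n),
                 xrefs = rep(list(character()), n),
                 parents = parents)
}

toy_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_toy_vocabularies()
    cache
  }
})
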