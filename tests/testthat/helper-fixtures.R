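# In-code builders for small deterministic test inputs.

tiny_network <- function() {
  doi_network(
    nodes = data.frame(id = c("a", "b", "c", "d"),
                       pval = c(0.01, 0.05, 0.5, NA)),
    edges = data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"),
                       correlation = c(0.9, -0.4, 0.2),
                       abs_correlation = c(0.9, 0.4, 0.2)),
    node_orientation = c(pval = "lower"),
    edge_orientation = c(correlation = "higher", abs_correlation = "higher")
  )
}

tiny_source <- function(source_id = "KEGG",
                        terms = list(P1 = c("a", "b"), P2 = c("b", "c"))) {
  netdoi:::knowledge_source(source_id, tibble::tibble(
    term_id = names(terms),
    name = paste("pathway", names(terms)),
    members = unname(terms)
  ))
}

# uniform random network with a p-value-like node attribute and a
# correlation-like edge attribute, plus one annotation source
random_network <- function(n = 30, density = 0.15, seed = 1) {
  withr::local_seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < density
  edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep])
  if (nrow(edges)) {
    edges$correlation <- stats::runif(nrow(edges), -1, 1)
    edges$abs_correlation <- abs(edges$correlation)
  }
  nodes <- data.frame(id = ids, pval = stats::runif(n, 0.001, 1))
  doi_network(nodes, if (nrow(edges)) edges else NULL,
              node_orientation = c(pval = "lower"),
              edge_orientation = c(correlation = "higher",
                                   abs_correlation = "higher"))
}

random_source <- function(network, n_terms = 4, seed = 1, source_id = "SRC") {
  withr::local_seed(seed)
  ids <- network$nodes$id
  terms <- lapply(seq_len(n_terms), function(i) {
    sort(sample(ids, sample(2:max(3, length(ids) %/% 3), 1)))
  })
  names(terms) <- sprintf("T%02d", seq_len(n_terms))
  tiny_source(source_id, terms)
}

# random annotation context for subset-graph tests: n_genes genes, each
# assigned a random subset of n_terms terms
random_selection <- function(n_genes = 20, n_terms = 5, seed = 1,
                             p_member = 0.3) {
  withr::local_seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  term_keys <- sprintf("S:T%02d", seq_len(n_terms))
  members <- lapply(seq_len(n_terms), function(t) {
    genes[stats::runif(n_genes) < p_member]
  })
  sel <- tibble::tibble(
    term_key = term_keys, source_id = "S",
    term_id = sprintf("T%02d", seq_len(n_terms)),
    name = term_keys, members = members, size = lengths(members)
  )
  net <- doi_network(nodes = data.frame(id = genes))
  list(network = net, selection = sel, genes = genes)
}

# brute-force covering relation over realized signatures, independent of
# build_subset_graph: all strict-inclusion pairs minus transitive ones
brute_force_hasse <- function(signatures) {
  sigs <- unique(signatures[lengths(signatures) > 0])
  keys <- vapply(sigs, paste, "", collapse = "+")
  o <- order(keys); sigs <- sigs[o]; keys <- keys[o]
  n <- length(sigs)
  strict <- function(a, b) length(a) < length(b) && all(a %in% b)
  out <- character()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && strict(sigs[[i]], sigs[[j]])) {
      covered <- any(vapply(seq_len(n), function(k) {
        k != i && k != j && strict(sigs[[i]], sigs[[k]]) &&
          strict(sigs[[k]], sigs[[j]])
      }, TRUE))
      if (!covered) out <- c(out, paste(keys[i], keys[j], sep = " -> "))
    }
  }
  sort(out)
}

subset_edges_as_strings <- function(sg) {
  if (!nrow(sg$edges)) return(character())
  sort(paste(sg$edges$from, sg$edges$to, sep = " -> "))
}

expect_identical_files <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
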