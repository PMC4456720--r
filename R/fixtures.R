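# Deterministic synthetic integrated data-knowledge networks with planted
# annotation structure, plus an independent straight-line DoI oracle used to
# cross-check the field algebra. The generator emulates the statistical
# shape the DoI machinery consumes — a block of jointly interesting genes
# (low p-values, strong correlations, shared annotations) on a noisy
# background — not any particular microarray noise model.

#' Specification of a synthetic fixture
#'
#' Defaults describe a mid-sized integrated network: hundreds of genes,
#' edge density giving on the order of ten thousand relationships, several
#' knowledge sources with overlapping terms, a p-value-like node attribute
#' and correlation-like edge attributes, with a planted block of interesting
#' genes so that thresholding at 0.5 on |correlation| (and p <= 0.05)
#' yields a non-trivial subnetwork.
#'
#' @param n_genes Number of genes.
#' @param edge_density Fraction of all unordered pairs that get an edge
#'   (ignored when `n_edges` is given).
#' @param n_edges Exact relationship count, or `NULL` to use `edge_density`.
#' @param n_sources Number of knowledge sources. Source 1 carries the
#'   planted selection used for layout ground truth.
#' @param terms_per_source Terms per source.
#' @param term_size_range Member-count range for non-planted terms; default
#'   `c(10, 40)` clipped to `n_genes`.
#' @param overlap_profile Probabilities of planted signature sizes 0, 1, 2,
#'   ... (a gene's signature is that many terms of source 1).
#' @param seed Integer seed; the fixture is fully determined by it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 300, edge_density = 0.25, n_edges = NULL,
                         n_sources = 4, terms_per_source = 5,
                         term_size_range = NULL,
                         overlap_profile = c(0.35, 0.35, 0.2, 0.1),
                         seed = 1) {
  if (is.null(term_size_range)) {
    term_size_range <- c(min(10, n_genes), min(40, n_genes))
  }
  stopifnot(n_genes >= 3, n_sources >= 1, terms_per_source >= 1,
            length(term_size_range) == 2,
            term_size_range[1] >= 1,
            edge_density > 0, edge_density <= 1,
            all(overlap_profile >= 0), sum(overlap_profile) > 0,
            length(overlap_profile) >= 2,
            length(overlap_profile) - 1 <= terms_per_source)
  if (term_size_range[2] > n_genes) {
    abort("term sizes exceed gene count: infeasible spec")
  }
  max_pairs <- n_genes * (n_genes - 1) / 2
  if (is.null(n_edges)) n_edges <- round(edge_density * max_pairs)
  if (n_edges > max_pairs) abort("more edges requested than gene pairs exist")
  structure(list(n_genes = n_genes, n_edges = as.integer(n_edges),
                 n_sources = n_sources, terms_per_source = terms_per_source,
                 term_size_range = term_size_range,
                 overlap_profile = overlap_profile / sum(overlap_profile),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# the DoI configuration under which the ground truth is computed
fixture_doi_config <- function() {
  list(
    continuous = list(
      list(attribute = "pval", element_kind = "node",
           transform = "one_minus", theta = 0.95),
      list(attribute = "abs_correlation", element_kind = "edge",
           transform = "identity", theta = 0.5)
    ),
    cont_op = "AND",
    discrete = list(list(source_id = "K1")),
    disc_op = "OR"
  )
}

#' Generate a synthetic data-knowledge network with ground truth
#'
#' Draws gene ids, a planted per-gene annotation signature over the terms of
#' source `K1` (signature sizes follow `overlap_profile`), random terms for
#' the remaining sources, an edge set of exactly `n_edges` unordered pairs,
#' and attributes: node `pval` in (0,1] (planted genes small), edge
#' `correlation` in \[-1,1\] (strong within the planted block) plus its
#' magnitude `abs_correlation`. Evidence types record data and per-source
#' knowledge support. The ground truth contains the planted signatures, the
#' per-element DoI under [fixture_doi_config()] computed by an independent
#' straight-line oracle ([oracle_doi()]), and the expected subset graph of
#' the filtered subnetwork under the planted selection.
#'
#' With `dir` set, writes `network.graphml`, `network.sif`, `nodes.tsv`,
#' `edges.tsv`, one `<source>.gmt` per source and `ground_truth.json`;
#' outputs are byte-identical across runs with the same spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory, or `NULL` to skip writing files.
#' @return List with `network` (`doi_network`), `sources` (list of
#'   `knowledge_source`), `selection` (annotation-group tibble for source
#'   K1), `config`, `ground_truth`, `spec` and (if written) `paths`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::local_seed(spec$seed)
  n <- spec$n_genes
  ids <- sprintf("g%04d", seq_len(n))

  # planted signatures over the terms of source 1
  sizes <- sample(seq_along(spec$overlap_profile) - 1L, n, replace = TRUE,
                  prob = spec$overlap_profile)
  sel_terms <- sprintf("T%02d", seq_len(spec$terms_per_source))
  signatures <- lapply(sizes, function(k) sort(sample(sel_terms, k)))
  names(signatures) <- ids
  planted <- ids[sizes > 0]

  sources <- vector("list", spec$n_sources)
  k1_terms <- lapply(sel_terms, function(t) {
    ids[vapply(signatures, function(s) t %in% s, TRUE)]
  })
  sources[[1]] <- knowledge_source("K1", tibble(
    term_id = sel_terms,
    name = paste("planted term", sel_terms),
    members = k1_terms
  ))
  for (k in seq_len(spec$n_sources)[-1]) {
    sz <- sample(spec$term_size_range[1]:spec$term_size_range[2],
                 spec$terms_per_source, replace = TRUE)
    sources[[k]] <- knowledge_source(paste0("K", k), tibble(
      term_id = sprintf("T%02d", seq_len(spec$terms_per_source)),
      name = sprintf("random term %d of K%d", seq_len(spec$terms_per_source), k),
      members = lapply(sz, function(s) sort(sample(ids, s)))
    ))
  }
  names(sources) <- vapply(sources, function(s) s$source_id, "")

  # edges: exact count, sampled from all unordered pairs
  pair_idx <- sort(sample.int(n * (n - 1) / 2, spec$n_edges))
  # invert the column-major lower-triangle linear index
  j <- ceiling((sqrt(8 * pair_idx + 1) + 1) / 2)
  i <- pair_idx - (j - 1) * (j - 2) / 2
  from <- ids[pmin(i, j)]
  to <- ids[pmax(i, j)]

  in_block <- (from %in% planted) & (to %in% planted)
  m <- length(from)
  sign_ <- sample(c(-1, 1), m, replace = TRUE)
  correlation <- ifelse(in_block,
                        sign_ * stats::runif(m, 0.6, 0.95),
                        stats::runif(m, -0.49, 0.49))
  pval <- ifelse(ids %in% planted,
                 stats::runif(n, 0.001, 0.04),
                 stats::runif(n, 0.06, 1))

  evidence <- knowledge_evidence(ids, from, to, sources)
  nodes <- tibble(id = ids, pval = pval)
  edges <- tibble(from = from, to = to, evidence = evidence,
                  correlation = correlation,
                  abs_correlation = abs(correlation))
  network <- doi_network(nodes, edges,
                         node_orientation = c(pval = "lower"),
                         edge_orientation = c(correlation = "higher",
                                              abs_correlation = "higher"))

  config <- fixture_doi_config()
  truth_doi <- oracle_doi(network$nodes, network$edges, sources, config)
  # signatures keyed the same way the layout module keys selected terms
  signatures <- lapply(signatures, function(s)
    if (length(s)) paste0("K1:", s) else character())
  truth_subset <- oracle_subset_graph(signatures, truth_doi)

  ground_truth <- list(
    signatures = signatures,
    doi = truth_doi,
    subset_graph = truth_subset,
    config = config
  )
  selection <- tibble(
    term_key = paste("K1", sel_terms, sep = ":"),
    source_id = "K1", term_id = sel_terms,
    name = sources[["K1"]]$terms$name,
    members = k1_terms,
    size = lengths(k1_terms)
  )

  out <- list(network = network, sources = sources, selection = selection,
              config = config, ground_truth = ground_truth, spec = spec)
  if (!is.null(dir)) out$paths <- write_fixture_files(out, dir)
  out
}

knowledge_evidence <- function(ids, from, to, sources) {
  ev <- rep(list("data-correlation"), length(from))
  i <- match(from, ids); j <- match(to, ids)
  for (src in sources) {
    memb <- membership_matrix(ids, src$terms$members)
    shared <- rowSums(memb[i, , drop = FALSE] & memb[j, , drop = FALSE]) > 0
    if (any(shared)) {
      tag <- paste0("knowledge:", src$source_id)
      ev[shared] <- lapply(ev[shared], c, tag)
    }
  }
  ev
}

write_fixture_files <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(
    graphml = file.path(dir, "network.graphml"),
    sif = file.path(dir, "network.sif"),
    nodes = file.path(dir, "nodes.tsv"),
    edges = file.path(dir, "edges.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_graphml(fx$network, p[["graphml"]])
  write_sif(fx$network, p[["sif"]])
  nt <- fx$network$nodes[, c("id", "pval")]
  et <- fx$network$edges[, c("from", "to", "correlation", "abs_correlation")]
  readr::write_tsv(nt, p[["nodes"]], progress = FALSE)
  readr::write_tsv(et, p[["edges"]], progress = FALSE)
  for (src in fx$sources) {
    gp <- file.path(dir, paste0(src$source_id, ".gmt"))
    write_gmt(src, gp)
    p[[paste0("gmt_", src$source_id)]] <- gp
  }
  jsonlite::write_json(fx$ground_truth, p[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  p
}

# ---- independent oracle ----------------------------------------------------

#' Straight-line DoI oracle
#'
#' Re-derives the final DoI of every node and edge directly from the raw
#' attribute tables and annotation memberships with plain loops — min over
#' the two endpoints for node-derived values, max over incident edges for
#' edge-derived values, per-function thresholding, fuzzy AND/OR combination
#' and the final discrete-AND-continuous rule. Shares no code with the field
#' algebra; used as the cross-check in the package's own tests.
#'
#' @param nodes,edges Attribute tibbles as in a `doi_network`.
#' @param sources Named list of `knowledge_source`s.
#' @param config A DoI configuration (see [fixture_doi_config()]).
#' @return List with numeric vectors `node_doi`, `edge_doi` (aligned to the
#'   input rows) and logical `node_visible`, `edge_visible`.
#' @export
oracle_doi <- function(nodes, edges, sources, config) {
  n <- nrow(nodes); m <- nrow(edges)
  ia <- match(edges$from, nodes$id)  # endpoint row indices, computed once
  ib <- match(edges$to, nodes$id)
  incident <- split(rep(seq_len(m), 2), c(ia, ib))  # node row -> edge rows
  tf_apply <- function(x, transform) {
    if (is.na(x)) return(0)
    switch(transform,
           identity = x,
           one_minus = 1 - x,
           neg_log10_capped = min(-log10(x) / 10, 1))
  }

  cont_n <- list(); cont_e <- list()
  for (s in config$continuous) {
    nv <- numeric(n); ev <- numeric(m)
    if (s$element_kind == "node") {
      for (i in seq_len(n)) nv[i] <- tf_apply(nodes[[s$attribute]][i], s$transform)
      for (j in seq_len(m)) ev[j] <- min(nv[ia[j]], nv[ib[j]])
    } else {
      for (j in seq_len(m)) ev[j] <- tf_apply(edges[[s$attribute]][j], s$transform)
      for (i in seq_len(n)) {
        inc <- incident[[as.character(i)]]
        nv[i] <- if (length(inc)) max(ev[inc]) else 0
      }
    }
    nv[nv < s$theta] <- 0
    ev[ev < s$theta] <- 0
    cont_n[[length(cont_n) + 1]] <- nv
    cont_e[[length(cont_e) + 1]] <- ev
  }
  comb_all <- function(fields, len, op) {
    if (!length(fields)) return(rep(1, len))
    out <- numeric(len)
    for (i in seq_len(len)) {
      vals <- vapply(fields, `[`, 0, i)
      out[i] <- if (op == "AND") min(vals) else max(vals)
    }
    out
  }
  cn <- comb_all(cont_n, n, config$cont_op)
  ce <- comb_all(cont_e, m, config$cont_op)

  disc_n <- list(); disc_e <- list()
  for (s in config$discrete) {
    src <- sources[[s$source_id]]
    in_term <- lapply(src$terms$members, function(t) nodes$id %in% t)
    nv <- numeric(n); ev <- numeric(m)
    for (i in seq_len(n)) {
      nv[i] <- as.numeric(any(vapply(in_term, `[`, TRUE, i)))
    }
    for (j in seq_len(m)) {
      share <- any(vapply(in_term, function(t) t[ia[j]] && t[ib[j]], TRUE))
      ev[j] <- as.numeric(share)
    }
    disc_n[[length(disc_n) + 1]] <- nv
    disc_e[[length(disc_e) + 1]] <- ev
  }
  dn <- comb_all(disc_n, n, config$disc_op)
  de <- comb_all(disc_e, m, config$disc_op)

  node_doi <- pmin(dn, cn)
  edge_doi <- pmin(de, ce)
  list(node_doi = node_doi, edge_doi = edge_doi,
       node_visible = node_doi > 0, edge_visible = edge_doi > 0)
}

# expected subset graph of the filtered subnetwork under the planted
# selection: realized signatures among visible genes, covering edges by a
# direct double loop over signature pairs
oracle_subset_graph <- function(signatures, truth_doi) {
  vis <- names(signatures)[truth_doi$node_visible]
  sigs <- signatures[vis]
  keys <- vapply(sigs, paste, "", collapse = "+")
  keep <- keys != ""
  groups <- split(names(sigs)[keep], keys[keep])
  gid <- names(groups)
  parts <- strsplit(gid, "+", fixed = TRUE)
  edges <- character(0)
  for (a in seq_along(gid)) {
    for (b in seq_along(gid)) {
      if (a == b) next
      strict <- length(parts[[a]]) < length(parts[[b]]) &&
        all(parts[[a]] %in% parts[[b]])
      if (!strict) next
      covered <- FALSE
      for (c_ in seq_along(gid)) {
        if (c_ == a || c_ == b) next
        if (length(parts[[a]]) < length(parts[[c_]]) &&
            all(parts[[a]] %in% parts[[c_]]) &&
            length(parts[[c_]]) < length(parts[[b]]) &&
            all(parts[[c_]] %in% parts[[b]])) {
          covered <- TRUE; break
        }
      }
      if (!covered) edges <- c(edges, paste(gid[a], gid[b], sep = " -> "))
    }
  }
  list(
    groups = lapply(groups, sort),
    residual = sort(setdiff(vis, unlist(groups))),
    edges = sort(edges)
  )
}

#' Case-study-scale fixtures
#'
#' Two fixtures matching the sizes of the published analyses this package's
#' workflow targets: fixture `"A"` with exactly 711 genes and 74,373
#' relationships, fixture `"B"` with exactly 328 genes and 11,081
#' relationships, each with 10 knowledge sources. Used by the end-to-end
#' smoke test.
#'
#' @param seed Integer seed.
#' @param which `"A"` or `"B"`.
#' @param dir Optional output directory (see [generate_fixture()]).
#' @return As [generate_fixture()].
#' @export
case_study_fixture <- function(seed = 1, which = c("A", "B"), dir = NULL) {
  which <- match.arg(which)
  spec <- if (which == "A") {
    fixture_spec(n_genes = 711, n_edges = 74373, n_sources = 10,
                 terms_per_source = 8, term_size_range = c(10, 60),
                 overlap_profile = c(0.55, 0.25, 0.12, 0.08), seed = seed)
  } else {
    fixture_spec(n_genes = 328, n_edges = 11081, n_sources = 10,
                 terms_per_source = 8, term_size_range = c(10, 40),
                 overlap_profile = c(0.55, 0.25, 0.12, 0.08), seed = seed)
  }
  generate_fixture(spec, dir = dir)
}
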