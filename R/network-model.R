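#' netdoi: degree-of-interest analysis of integrated data-knowledge networks
#'
#' Tools to filter dense gene networks that mix experimental evidence
#' (correlations, p-values, expression changes) with curated knowledge
#' (pathway and ontology gene sets), using combinable degree-of-interest
#' (DoI) functions; to lay the filtered subnetworks out by annotation-set
#' structure; to compare several subnetworks in one reference-anchored
#' super-graph; and to export static figures and heatmaps.
#'
#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange left_join bind_rows
#'   distinct pull everything
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# ---- container -------------------------------------------------------------

#' Construct an integrated data-knowledge network
#'
#' The central container: a set of genes (vertices) and undirected
#' relationships (edges) between them, each carrying numeric attributes, plus
#' registries declaring which attributes exist on nodes and edges and whether
#' higher or lower values are the interesting end of the scale.
#'
#' Relationships are undirected and keyed by unordered gene pair: `from` is
#' always the lexicographically smaller id. Each relationship carries a set of
#' evidence-type labels (e.g. `"data-correlation"`, `"knowledge:KEGG"`)
#' recording why the edge exists; duplicate pairs supplied to the constructor
#' are merged by taking the union of their evidence types, and conflicting
#' numeric attribute values for the same pair are an error.
#'
#' @param nodes Data frame with a character `id` column (unique), an optional
#'   `symbol` column (display label, defaults to `id`), and any number of
#'   numeric attribute columns. `NA` means "no value for this gene".
#' @param edges Data frame with character `from` and `to` columns, an optional
#'   `evidence` list-column of character vectors, and numeric attribute
#'   columns. Self-loops are rejected.
#' @param node_orientation,edge_orientation Named character vectors mapping
#'   attribute names to `"higher"` or `"lower"` (which end of the scale is
#'   interesting); unnamed attributes get `NA` orientation.
#' @return A `doi_network` object: a list with tibbles `nodes` and `edges` and
#'   registry tibbles `node_registry`, `edge_registry` (columns `name`,
#'   `orientation`).
#' @examples
#' net <- doi_network(
#'   nodes = data.frame(id = c("a", "b", "c"), pval = c(0.01, 0.2, NA)),
#'   edges = data.frame(from = c("a", "b"), to = c("b", "c"),
#'                      correlation = c(0.9, -0.4)),
#'   node_orientation = c(pval = "lower"),
#'   edge_orientation = c(correlation = "higher")
#' )
#' net
#' @export
doi_network <- function(nodes, edges = NULL,
                        node_orientation = character(),
                        edge_orientation = character()) {
  nodes <- as_tibble(nodes)
  if (!"id" %in% names(nodes)) abort("`nodes` must have an `id` column")
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) abort("gene ids must be unique")
  if (!"symbol" %in% names(nodes)) nodes$symbol <- nodes$id
  nodes <- select(nodes, "id", "symbol", everything())

  if (is.null(edges)) {
    edges <- tibble(from = character(), to = character(),
                    evidence = list())
  } else {
    edges <- as_tibble(edges)
    if (!all(c("from", "to") %in% names(edges))) {
      abort("`edges` must have `from` and `to` columns")
    }
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (any(edges$from == edges$to)) abort("self-loops are not allowed")
    missing_end <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(missing_end)) {
      abort(paste0("edge references absent gene(s): ",
                   paste(utils::head(missing_end, 5), collapse = ", ")))
    }
    # canonical unordered key: from < to
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    if (!"evidence" %in% names(edges)) {
      edges$evidence <- rep(list(character()), nrow(edges))
    } else if (is.character(edges$evidence)) {
      edges$evidence <- as.list(edges$evidence)
    }
    edges <- merge_duplicate_edges(edges)
    edges <- select(edges, "from", "to", "evidence", everything())
  }

  attr_cols <- function(tb, skip) setdiff(names(tb), skip)
  ncols <- attr_cols(nodes, c("id", "symbol"))
  ecols <- attr_cols(edges, c("from", "to", "evidence"))
  for (cl in ncols) {
    if (!is.numeric(nodes[[cl]])) abort(paste0("node attribute `", cl, "` must be numeric"))
    if (any(is.infinite(nodes[[cl]]), na.rm = TRUE)) abort(paste0("node attribute `", cl, "` has non-finite values"))
  }
  for (cl in ecols) {
    if (!is.numeric(edges[[cl]])) abort(paste0("edge attribute `", cl, "` must be numeric"))
    if (any(is.infinite(edges[[cl]]), na.rm = TRUE)) abort(paste0("edge attribute `", cl, "` has non-finite values"))
  }

  structure(
    list(
      nodes = nodes,
      edges = edges,
      node_registry = make_registry(ncols, node_orientation),
      edge_registry = make_registry(ecols, edge_orientation)
    ),
    class = "doi_network"
  )
}

make_registry <- function(attr_names, orientation) {
  ori <- rep(NA_character_, length(attr_names))
  hit <- match(attr_names, names(orientation))
  ori[!is.na(hit)] <- unname(orientation[hit[!is.na(hit)]])
  bad <- !is.na(ori) & !ori %in% c("higher", "lower")
  if (any(bad)) abort("orientation must be \"higher\" or \"lower\"")
  tibble(name = attr_names, orientation = ori)
}

merge_duplicate_edges <- function(edges) {
  key <- paste(edges$from, edges$to, sep = "\r")
  if (!anyDuplicated(key)) return(edges)
  acols <- setdiff(names(edges), c("from", "to", "evidence"))
  pieces <- split(seq_len(nrow(edges)), key)
  out <- lapply(pieces, function(ix) {
    row <- edges[ix[1], ]
    row$evidence <- list(sort(unique(unlist(edges$evidence[ix]))))
    for (cl in acols) {
      vals <- unique(edges[[cl]][ix][!is.na(edges[[cl]][ix])])
      if (length(vals) > 1) {
        abort(paste0("conflicting values for edge attribute `", cl,
                     "` on pair ", row$from, "-", row$to))
      }
      row[[cl]] <- if (length(vals)) vals else NA_real_
    }
    row
  })
  bind_rows(out)
}

#' @export
print.doi_network <- function(x, ...) {
  cat("<doi_network> ", nrow(x$nodes), " genes, ", nrow(x$edges),
      " relationships\n", sep = "")
  if (nrow(x$node_registry)) {
    cat("  node attributes: ", paste(x$node_registry$name, collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$edge_registry)) {
    cat("  edge attributes: ", paste(x$edge_registry$name, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.doi_network <- function(x, ...) {
  sprintf("<doi_network: %d genes, %d relationships>", nrow(x$nodes), nrow(x$edges))
}

edge_key <- function(from, to) paste(pmin(from, to), pmax(from, to), sep = "\r")

n_genes <- function(network) nrow(network$nodes)
n_relationships <- function(network) nrow(network$edges)

# ---- readers ---------------------------------------------------------------

#' Load a network from SIF or GraphML with optional attribute tables
#'
#' SIF rows are `source <TAB> interaction-type <TAB> target`; the interaction
#' type becomes an evidence label. GraphML files are parsed with
#' \pkg{igraph}; numeric vertex/edge attributes populate the registries, a
#' string edge attribute `evidence` (entries separated by `;`) restores
#' evidence-type sets. Attribute tables are TSV with a header: node tables
#' keyed by an `id` column, edge tables by `from`/`to` columns (unordered
#' pair). Rows referencing genes or pairs absent from the graph are an error.
#'
#' @param graph_file Path to a `.sif` or `.graphml` file.
#' @param node_table,edge_table Optional TSV paths.
#' @param node_orientation,edge_orientation Passed to [doi_network()].
#' @return A `doi_network`.
#' @export
load_network <- function(graph_file, node_table = NULL, edge_table = NULL,
                         node_orientation = character(),
                         edge_orientation = character()) {
  ext <- tolower(tools::file_ext(graph_file))
  parsed <- switch(ext,
    "sif" = read_sif(graph_file),
    "graphml" = read_graphml(graph_file),
    abort(paste0("unknown graph format: .", ext, " (expected .sif or .graphml)"))
  )
  nodes <- parsed$nodes
  edges <- parsed$edges

  if (!is.null(node_table)) {
    tb <- readr::read_tsv(node_table, show_col_types = FALSE, progress = FALSE)
    if (!"id" %in% names(tb)) abort("node table must have an `id` column")
    tb$id <- as.character(tb$id)
    unknown <- setdiff(tb$id, nodes$id)
    if (length(unknown)) {
      abort(paste0("unknown gene in node table: ",
                   paste(utils::head(unknown, 5), collapse = ", ")))
    }
    nodes <- left_join(nodes, tb, by = "id")
  }
  if (!is.null(edge_table)) {
    tb <- readr::read_tsv(edge_table, show_col_types = FALSE, progress = FALSE)
    if (!all(c("from", "to") %in% names(tb))) {
      abort("edge table must have `from` and `to` columns")
    }
    tb$from <- as.character(tb$from); tb$to <- as.character(tb$to)
    kf <- edge_key(tb$from, tb$to)
    ke <- edge_key(edges$from, edges$to)
    if (!all(kf %in% ke)) {
      bad <- tb[!(kf %in% ke), c("from", "to")][1, ]
      abort(paste0("unknown edge in edge table: ", bad$from, "-", bad$to))
    }
    tb$from <- sub("\r.*", "", kf); tb$to <- sub(".*\r", "", kf)
    edges <- left_join(edges, tb, by = c("from", "to"))
  }
  doi_network(nodes, edges,
              node_orientation = node_orientation,
              edge_orientation = edge_orientation)
}

read_sif <- function(path) {
  ln <- readLines(path, warn = FALSE, encoding = "UTF-8")
  ln <- ln[nzchar(trimws(ln))]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) abort(paste0("SIF line ", which(bad)[1], " has fewer than 3 columns"))
  # lines with >3 columns name several targets for one source (SIF dialect)
  rows <- lapply(parts, function(p) {
    tibble(from = p[1], evidence = p[2], to = p[3:length(p)])
  })
  ed <- bind_rows(rows)
  ed$evidence <- as.list(ed$evidence)
  ids <- sort(unique(c(ed$from, ed$to)))
  list(nodes = tibble(id = ids), edges = ed[, c("from", "to", "evidence")])
}

read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  id <- va$name %||% va$id
  if (is.null(id)) id <- as.character(seq_len(igraph::vcount(g)))
  nodes <- tibble(id = as.character(id))
  if (!is.null(va$symbol)) nodes$symbol <- as.character(va$symbol)
  for (nm in setdiff(names(va), c("id", "name", "symbol"))) {
    if (is.numeric(va[[nm]])) nodes[[nm]] <- va[[nm]]
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  ea <- igraph::edge_attr(g)
  edges <- tibble(from = nodes$id[el[, 1]], to = nodes$id[el[, 2]])
  if (!is.null(ea$evidence)) {
    edges$evidence <- lapply(strsplit(as.character(ea$evidence), ";", fixed = TRUE),
                             function(v) sort(v[nzchar(v)]))
  }
  for (nm in setdiff(names(ea), "evidence")) {
    if (is.numeric(ea[[nm]])) edges[[nm]] <- ea[[nm]]
  }
  # absent per-element values come back from igraph as NaN; restore NA
  nodes[] <- lapply(nodes, function(v) { if (is.numeric(v)) v[is.nan(v)] <- NA; v })
  edges[] <- lapply(edges, function(v) { if (is.numeric(v)) v[is.nan(v)] <- NA; v })
  list(nodes = nodes, edges = edges)
}

# ---- GMT annotations -------------------------------------------------------

#' Load an annotation knowledge source from a GMT file
#'
#' One gene set per line: `term-id <TAB> description <TAB> member <TAB> ...`
#' (Broad GMT dialect). Members are deduplicated within a term.
#'
#' @param gmt_file Path to a GMT file.
#' @param source_id Identifier for the knowledge source (e.g. `"KEGG"`).
#' @return A `knowledge_source`: list with `source_id` and a `terms` tibble
#'   (`term_id`, `name`, `members` list-column).
#' @export
load_annotations <- function(gmt_file, source_id) {
  ln <- readLines(gmt_file, warn = FALSE, encoding = "UTF-8")
  ln <- ln[nzchar(trimws(ln))]
  if (!length(ln)) {
    warn(paste0("GMT file ", gmt_file, " contains no terms"))
    return(knowledge_source(source_id, tibble(term_id = character(),
                                              name = character(),
                                              members = list())))
  }
  parts <- strsplit(ln, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) abort(paste0("GMT line ", which(bad)[1], " has fewer than 3 columns"))
  terms <- tibble(
    term_id = vapply(parts, `[`, "", 1),
    name = vapply(parts, `[`, "", 2),
    members = lapply(parts, function(p) unique(p[-(1:2)]))
  )
  if (anyDuplicated(terms$term_id)) {
    abort(paste0("duplicate term id in ", gmt_file, ": ",
                 terms$term_id[duplicated(terms$term_id)][1]))
  }
  knowledge_source(source_id, terms)
}

knowledge_source <- function(source_id, terms) {
  stopifnot(is.character(source_id), length(source_id) == 1)
  structure(list(source_id = source_id, terms = as_tibble(terms)),
            class = "knowledge_source")
}

#' @export
print.knowledge_source <- function(x, ...) {
  cat("<knowledge_source> ", x$source_id, ": ", nrow(x$terms), " terms\n", sep = "")
  invisible(x)
}

#' Restrict a knowledge source to the genes of a network
#'
#' Intersects every term's member set with the network's gene ids and drops
#' terms whose intersection is empty. Idempotent; the input is not modified.
#'
#' @param source A `knowledge_source`.
#' @param network A `doi_network`.
#' @return A pruned `knowledge_source`.
#' @export
prune_annotations <- function(source, network) {
  ids <- network$nodes$id
  terms <- source$terms
  terms$members <- lapply(terms$members, intersect, y = ids)
  terms <- terms[lengths(terms$members) > 0, , drop = FALSE]
  knowledge_source(source$source_id, terms)
}

#' Write a GMT file
#'
#' @param source A `knowledge_source`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(source, path) {
  ln <- vapply(seq_len(nrow(source$terms)), function(i) {
    paste(c(source$terms$term_id[i], source$terms$name[i],
            source$terms$members[[i]]), collapse = "\t")
  }, "")
  writeLines(ln, path, useBytes = TRUE)
  invisible(path)
}

# ---- writers ---------------------------------------------------------------

num_chr <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a network as GraphML
#'
#' Full-precision serializer (attributes written with 17 significant digits)
#' producing GraphML 1.0 readable by [load_network()] and by igraph.
#'
#' @param network A `doi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  nodes <- network$nodes
  edges <- network$edges
  ncols <- setdiff(names(nodes), c("id", "symbol"))
  ecols <- setdiff(names(edges), c("from", "to", "evidence"))

  keys <- c(
    '  <key id="v_name" for="node" attr.name="name" attr.type="string"/>',
    '  <key id="v_symbol" for="node" attr.name="symbol" attr.type="string"/>',
    sprintf('  <key id="v_%s" for="node" attr.name="%s" attr.type="double"/>', ncols, ncols),
    '  <key id="e_evidence" for="edge" attr.name="evidence" attr.type="string"/>',
    sprintf('  <key id="e_%s" for="edge" attr.name="%s" attr.type="double"/>', ecols, ecols)
  )

  node_data <- paste0('      <data key="v_name">', xml_esc(nodes$id), "</data>\n",
                      '      <data key="v_symbol">', xml_esc(nodes$symbol), "</data>")
  for (cl in ncols) {
    v <- num_chr(nodes[[cl]])
    keep <- nzchar(v)
    add <- ifelse(keep, paste0('\n      <data key="v_', cl, '">', v, "</data>"), "")
    node_data <- paste0(node_data, add)
  }
  node_xml <- if (nrow(nodes)) {
    paste0('    <node id="', xml_esc(nodes$id), '">\n',
           node_data, "\n    </node>")
  } else character()

  ev <- vapply(edges$evidence %||% rep(list(character()), nrow(edges)),
               paste, "", collapse = ";")
  edge_data <- paste0('      <data key="e_evidence">', xml_esc(ev), "</data>")
  for (cl in ecols) {
    v <- num_chr(edges[[cl]])
    keep <- nzchar(v)
    add <- ifelse(keep, paste0('\n      <data key="e_', cl, '">', v, "</data>"), "")
    edge_data <- paste0(edge_data, add)
  }
  edge_xml <- if (nrow(edges)) {
    paste0('    <edge source="', xml_esc(edges$from), '" target="',
           xml_esc(edges$to), '">\n', edge_data, "\n    </edge>")
  } else character()

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    keys,
    '  <graph id="G" edgedefault="undirected">',
    node_xml,
    edge_xml,
    "  </graph>",
    "</graphml>"
  )
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Write a SIF file (one row per relationship and evidence type)
#'
#' @param network A `doi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  edges <- network$edges
  rows <- unlist(lapply(seq_len(nrow(edges)), function(i) {
    ev <- edges$evidence[[i]]
    if (!length(ev)) ev <- "interacts"
    paste(edges$from[i], ev, edges$to[i], sep = "\t")
  }))
  writeLines(rows %||% character(), path, useBytes = TRUE)
  invisible(path)
}

#' Export the visible subgraph of a filtered network
#'
#' Writes `<out_prefix>.graphml` (the subgraph of elements with DoI > 0, DoI
#' attached as attribute `doi`) plus `<out_prefix>_nodes.tsv` and
#' `<out_prefix>_edges.tsv` with per-element DoI values. The GraphML
#' round-trips through [load_network()] at full precision.
#'
#' @param network A `doi_network`.
#' @param visible A final `doi_field` over the network (see [final_doi()]).
#' @param out_prefix Path prefix for the three output files.
#' @return Character vector of the written paths, invisibly.
#' @export
write_subnetwork <- function(network, visible, out_prefix) {
  sub <- apply_filter(network, visible)
  paths <- c(
    graphml = paste0(out_prefix, ".graphml"),
    nodes = paste0(out_prefix, "_nodes.tsv"),
    edges = paste0(out_prefix, "_edges.tsv")
  )
  write_graphml(sub, paths[["graphml"]])
  nt <- sub$nodes[, c("id", "doi")]
  et <- sub$edges[, c("from", "to", "doi")]
  readr::write_tsv(nt, paths[["nodes"]], progress = FALSE)
  readr::write_tsv(et, paths[["edges"]], progress = FALSE)
  invisible(paths)
}

#' Tidy a network into a node or edge tibble
#'
#' @param x A `doi_network`.
#' @param what `"nodes"` or `"edges"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.doi_network <- function(x, what = c("nodes", "edges"), ...) {
  switch(match.arg(what), nodes = x$nodes, edges = x$edges)
}

#' @export
glance.doi_network <- function(x, ...) {
  tibble(n_genes = nrow(x$nodes), n_relationships = nrow(x$edges),
         n_node_attributes = nrow(x$node_registry),
         n_edge_attributes = nrow(x$edge_registry))
}

#' Turn a model object into a tidy tibble
#'
#' Generic re-exported in the broom style for netdoi result objects.
#' @param x Object to tidy.
#' @param ... Method-specific arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a netdoi result object
#'
#' @param x Object to summarise.
#' @param ... Method-specific arguments.
#' @export
glance <- function(x, ...) UseMethod("glance")
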