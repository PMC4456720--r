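# Annotation-based two-step layout.
#
# Step 1 partitions the filtered subnetwork's genes by annotation signature
# (the exact set of selected terms each gene belongs to), builds the subset
# graph — one node per realized non-empty signature, Hasse (covering) edges
# of strict signature inclusion, weights inversely proportional to the two
# group sizes — and places it with a weighted Fruchterman-Reingold layout.
# Step 2 lays each group's genes out independently inside a disc around its
# subset-node position.

#' Extract the annotation groups present in a filtered subnetwork
#'
#' Returns every term of the given knowledge sources that annotates at least
#' one gene of the subnetwork, with members restricted to subnetwork genes.
#'
#' @param subnetwork A `doi_network` (normally the output of [apply_filter()]).
#' @param sources A `knowledge_source` or list of them.
#' @return Tibble with columns `term_key` (`"<source>:<term_id>"`),
#'   `source_id`, `term_id`, `name`, `members` (list-column) and `size`.
#' @export
extract_annotation_groups <- function(subnetwork, sources) {
  if (inherits(sources, "knowledge_source")) sources <- list(sources)
  ids <- subnetwork$nodes$id
  rows <- lapply(sources, function(src) {
    pruned <- prune_annotations(src, subnetwork)
    tb <- pruned$terms
    tibble(term_key = paste(src$source_id, tb$term_id, sep = ":"),
           source_id = src$source_id, term_id = tb$term_id,
           name = tb$name,
           members = lapply(tb$members, function(m) sort(intersect(m, ids))))
  })
  out <- bind_rows(rows)
  out$size <- lengths(out$members)
  out
}

# per-gene signature: sorted term keys of the selected groups containing it
gene_signatures <- function(gene_ids, selection) {
  sig <- stats::setNames(vector("list", length(gene_ids)), gene_ids)
  for (i in seq_along(gene_ids)) sig[[i]] <- character()
  for (t in seq_len(nrow(selection))) {
    for (g in intersect(selection$members[[t]], gene_ids)) {
      sig[[g]] <- c(sig[[g]], selection$term_key[t])
    }
  }
  lapply(sig, sort)
}

#' Build the subset graph of a subnetwork for a selection of annotation groups
#'
#' Every gene is assigned its signature — the exact set of selected terms it
#' belongs to — so member sets of distinct subset nodes are disjoint (each
#' gene lives in exactly one group). Subset nodes are the realized non-empty
#' signatures; genes matched by no selected term form a residual pool rather
#' than a node. Edges are the covering (Hasse) pairs of the realized
#' signatures ordered by strict set inclusion, which also yields direct links
#' between groups more than one level apart whenever the intermediate
#' signatures are not realized. Edge weight is `2 / (|members1| + |members2|)`
#' — inversely proportional to the sizes of the two groups, in `(0, 1]`.
#'
#' @param subnetwork A `doi_network`.
#' @param selection Rows of [extract_annotation_groups()] output: the chosen
#'   annotation groups (columns `term_key`, `members` required).
#' @return A `subset_graph`: list with tibbles `nodes` (`group_id`,
#'   `signature` list, `members` list, `size`, `level`, `x`, `y`), `edges`
#'   (`from`, `to`, `weight`; `from` is the smaller signature), character
#'   vector `residual`, and the `selection`.
#' @export
build_subset_graph <- function(subnetwork, selection) {
  selection <- as_tibble(selection)
  if (!nrow(selection)) abort("`selection` must contain at least one annotation group")
  if (anyDuplicated(selection$term_key)) abort("duplicate term_key in selection")
  ids <- subnetwork$nodes$id
  sigs <- gene_signatures(ids, selection)
  key <- vapply(sigs, paste, "", collapse = "+")
  annotated <- key != ""
  residual <- ids[!annotated]

  groups <- split(ids[annotated], key[annotated])
  gid <- names(groups)
  signature <- strsplit(gid, "+", fixed = TRUE)
  nodes <- tibble(
    group_id = gid,
    signature = signature,
    members = unname(lapply(groups, function(g) sort(g))),
    size = unname(lengths(groups)),
    level = lengths(signature),
    x = NA_real_, y = NA_real_
  )
  nodes <- nodes[order(nodes$level, nodes$group_id), , drop = FALSE]

  edges <- hasse_edges(nodes$signature)
  if (nrow(edges)) {
    edges$from <- nodes$group_id[edges$i]
    edges$to <- nodes$group_id[edges$j]
    s <- nodes$size
    edges$weight <- pmin(2 / (s[edges$i] + s[edges$j]), 1)
    edges <- edges[, c("from", "to", "weight")]
  } else {
    edges <- tibble(from = character(), to = character(), weight = numeric())
  }

  structure(list(nodes = nodes, edges = edges, residual = residual,
                 selection = selection),
            class = "subset_graph")
}

# covering pairs of strict set inclusion among signatures (transitive
# reduction computed by brute force; signature families here are small)
hasse_edges <- function(signatures) {
  n <- length(signatures)
  subset_of <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j &&
          length(signatures[[i]]) < length(signatures[[j]]) &&
          all(signatures[[i]] %in% signatures[[j]])) {
        subset_of[i, j] <- TRUE
      }
    }
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (subset_of[i, j]) {
        between <- any(subset_of[i, ] & subset_of[, j])
        if (!between) out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (!length(out)) return(tibble(i = integer(), j = integer()))
  m <- do.call(rbind, out)
  tibble(i = m[, 1], j = m[, 2])
}

#' @export
print.subset_graph <- function(x, ...) {
  cat("<subset_graph> ", nrow(x$nodes), " groups, ", nrow(x$edges),
      " edges, ", length(x$residual), " residual genes\n", sep = "")
  invisible(x)
}

#' @export
tidy.subset_graph <- function(x, ...) {
  mutate(x$nodes, signature = vapply(.data$signature, paste, "", collapse = "+"))
}

#' @export
glance.subset_graph <- function(x, ...) {
  tibble(n_groups = nrow(x$nodes), n_edges = nrow(x$edges),
         n_residual = length(x$residual),
         n_genes = sum(x$nodes$size) + length(x$residual),
         max_level = if (nrow(x$nodes)) max(x$nodes$level) else 0L)
}

# ---- layout ----------------------------------------------------------------

default_layout_params <- function(params = list()) {
  utils::modifyList(list(niter = 500, r0 = 0.3, shrink = 0.9,
                         grid = "nogrid"), params)
}

#' Place the subset graph with a weighted force-directed layout
#'
#' Fruchterman-Reingold with the subset-graph edge weights scaling the
#' attractive force: heavier edges (small groups) pull their endpoints
#' closer. Deterministic for a given seed. Entries of `fixed_positions` are
#' pinned exactly, supporting manual adjustment of the intermediate result.
#'
#' @param graph A `subset_graph`.
#' @param params List of layout parameters (`niter`, default 500).
#' @param seed Integer seed.
#' @param fixed_positions Optional data frame `group_id`, `x`, `y` of pinned
#'   nodes.
#' @return The `subset_graph` with `x`, `y` filled in; layout parameters and
#'   seed stored in `attr(, "params")`.
#' @export
layout_subset_graph <- function(graph, params = list(), seed = 1,
                                fixed_positions = NULL) {
  params <- default_layout_params(params)
  nodes <- graph$nodes
  n <- nrow(nodes)
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = nodes$group_id
  )
  minx <- rep(-Inf, n); maxx <- rep(Inf, n)
  miny <- rep(-Inf, n); maxy <- rep(Inf, n)
  withr::local_seed(seed)
  coords <- matrix(stats::runif(2 * n, -1, 1), ncol = 2)
  if (!is.null(fixed_positions)) {
    fixed_positions <- as_tibble(fixed_positions)
    hit <- match(fixed_positions$group_id, nodes$group_id)
    if (anyNA(hit)) abort("fixed_positions references unknown group_id")
    coords[hit, 1] <- fixed_positions$x
    coords[hit, 2] <- fixed_positions$y
    minx[hit] <- maxx[hit] <- fixed_positions$x
    miny[hit] <- maxy[hit] <- fixed_positions$y
  }
  pos <- if (n == 1L) {
    coords
  } else {
    igraph::layout_with_fr(
      ig, coords = coords,
      weights = if (nrow(graph$edges)) graph$edges$weight else NULL,
      niter = params$niter, grid = params$grid,
      minx = minx, maxx = maxx, miny = miny, maxy = maxy
    )
  }
  if (n == 1L && is.null(fixed_positions)) pos[1, ] <- c(0, 0)
  graph$nodes$x <- pos[, 1]
  graph$nodes$y <- pos[, 2]
  attr(graph, "params") <- c(params, seed = seed)
  graph
}

#' Lay genes out inside their subset groups
#'
#' Second layout step: each group's member genes get an independent
#' force-directed placement using only the subnetwork edges internal to the
#' group, rescaled into a disc of radius `r0 * sqrt(size)` centred on the
#' group's subset-node position (area proportional to membership). A
#' singleton group's gene sits exactly on its subset node. Residual-pool
#' genes (no selected annotation) are placed in a row along the bottom
#' margin of the canvas.
#'
#' @param subnetwork A `doi_network`.
#' @param graph A laid-out `subset_graph` (see [layout_subset_graph()]).
#' @param params List: `r0` (base disc radius, default 0.3), `shrink`
#'   (fraction of the disc actually used, default 0.9), `niter`.
#' @param seed Integer seed.
#' @return A `doi_layout`: list with tibbles `genes` (`id`, `x`, `y`,
#'   `group_id`; residual genes have `group_id` `NA`) and `groups`
#'   (`group_id`, `x`, `y`, `radius`), plus `params`.
#' @export
layout_within_groups <- function(subnetwork, graph, params = list(), seed = 1) {
  params <- default_layout_params(params)
  nodes <- graph$nodes
  if (anyNA(nodes$x)) abort("subset graph must be laid out first")
  ek_from <- subnetwork$edges$from
  ek_to <- subnetwork$edges$to

  place_group <- function(i) {
    members <- nodes$members[[i]]
    cx <- nodes$x[i]; cy <- nodes$y[i]
    r <- params$r0 * sqrt(length(members))
    if (length(members) == 1L) {
      return(tibble(id = members, x = cx, y = cy, group_id = nodes$group_id[i]))
    }
    keep <- ek_from %in% members & ek_to %in% members
    ig <- igraph::graph_from_data_frame(
      data.frame(from = ek_from[keep], to = ek_to[keep]),
      directed = FALSE, vertices = sort(members)
    )
    withr::local_seed(seed + i)
    init <- matrix(stats::runif(2 * length(members), -1, 1), ncol = 2)
    pos <- igraph::layout_with_fr(ig, coords = init, niter = params$niter,
                                  grid = params$grid)
    # centre on the group's subset node and fit strictly inside the disc
    pos <- sweep(pos, 2, colMeans(pos))
    rad <- sqrt(rowSums(pos^2))
    if (max(rad) > 0) pos <- pos * (params$shrink * r / max(rad))
    tibble(id = igraph::V(ig)$name, x = cx + pos[, 1], y = cy + pos[, 2],
           group_id = nodes$group_id[i])
  }

  genes <- bind_rows(lapply(seq_len(nrow(nodes)), place_group))

  if (length(graph$residual)) {
    rr <- params$r0 * sqrt(pmax(nodes$size, 1))
    xr <- range(nodes$x); yr <- range(nodes$y)
    span <- max(diff(xr), 1)
    ymargin <- min(nodes$y) - max(rr) - 0.15 * max(diff(yr), 1) - params$r0
    res <- sort(graph$residual)
    genes <- bind_rows(genes, tibble(
      id = res,
      x = seq(xr[1], xr[1] + span, length.out = length(res) + 1)[-1] - span / (length(res) + 1),
      y = ymargin,
      group_id = NA_character_
    ))
  }

  groups <- tibble(group_id = nodes$group_id, x = nodes$x, y = nodes$y,
                   radius = params$r0 * sqrt(nodes$size))
  structure(list(genes = genes, groups = groups,
                 params = c(params, seed = seed)),
            class = "doi_layout")
}

#' @export
print.doi_layout <- function(x, ...) {
  cat("<doi_layout> ", nrow(x$genes), " genes in ", nrow(x$groups),
      " groups\n", sep = "")
  invisible(x)
}

#' Two-step annotation-based layout in one call
#'
#' Convenience wrapper: [build_subset_graph()], [layout_subset_graph()],
#' [layout_within_groups()].
#'
#' @inheritParams build_subset_graph
#' @inheritParams layout_subset_graph
#' @return A `doi_layout` with the laid-out `subset_graph` attached as
#'   `$subset_graph`.
#' @export
layout_by_annotation <- function(subnetwork, selection, params = list(),
                                 seed = 1, fixed_positions = NULL) {
  sg <- build_subset_graph(subnetwork, selection)
  sg <- layout_subset_graph(sg, params = params, seed = seed,
                            fixed_positions = fixed_positions)
  out <- layout_within_groups(subnetwork, sg, params = params, seed = seed)
  out$subset_graph <- sg
  out
}
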