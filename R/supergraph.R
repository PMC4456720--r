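# Reference-anchored comparison of subnetworks.
#
# Several subset graphs are merged into one super-graph: the largest
# subnetwork is the reference and keeps its layout frozen; groups from the
# other subnetworks are attached to the groups they overlap with (weights
# proportional to overlap size) and only those added groups move during
# layout, preserving the analyst's mental map of the reference.

subnet_gene_count <- function(sg) {
  length(unique(unlist(sg$nodes$members))) + length(sg$residual)
}

#' Choose the reference subnetwork for a comparison
#'
#' The reference is the subnetwork with the most genes; ties are broken by
#' more subset nodes, then by input order.
#'
#' @param subsets Named list of `subset_graph`s (length >= 2).
#' @return The name (or index, if unnamed) of the reference.
#' @export
select_reference <- function(subsets) {
  if (length(subsets) < 2) abort("need at least 2 subnetworks to compare")
  ids <- names(subsets) %||% as.character(seq_along(subsets))
  genes <- vapply(subsets, subnet_gene_count, 0L)
  groups <- vapply(subsets, function(s) nrow(s$nodes), 0L)
  ord <- order(-genes, -groups, seq_along(subsets))
  ids[ord[1]]
}

# number of subnetwork edges joining two gene sets
count_connecting_edges <- function(edges, a, b) {
  if (is.null(edges) || !nrow(edges)) return(0L)
  sum((edges$from %in% a & edges$to %in% b) |
        (edges$from %in% b & edges$to %in% a))
}

#' Build the comparison super-graph
#'
#' Starts from a copy of the laid-out reference subset graph. Each group of
#' every other subnetwork is then processed in order: a group whose signature
#' and member set already exist in the super-graph is deduplicated (the
#' existing node is tagged with the additional subnetwork id); otherwise the
#' group is added and connected to every existing node it shares genes with,
#' with weight `|overlap| / max |overlap|` over that node's overlaps (so
#' weights lie in `(0, 1]`). Among overlaps of equal size, neighbors are
#' ranked by the number of subnetwork edges joining the two member sets
#' (recorded in the `conn` column). A group overlapping nothing is connected
#' to the existing node with the most connecting edges, or left isolated if
#' there are none.
#'
#' @param subsets Named list of `subset_graph`s; the reference must be laid
#'   out ([layout_subset_graph()]).
#' @param networks Optional named list of the filtered `doi_network`s (same
#'   names) used to count connecting edges; without it ties keep input order
#'   and no-overlap groups stay isolated.
#' @param reference Name of the reference subnetwork; default
#'   [select_reference()].
#' @return A `super_graph`: list with `reference` (name), tibbles `nodes`
#'   (`group_id`, `signature`, `members`, `size`, `level`, `x`, `y`,
#'   `networks` list-column, `added` flag) and `edges` (`from`, `to`,
#'   `weight`, `overlap`, `conn`).
#' @export
build_supergraph <- function(subsets, networks = NULL, reference = NULL) {
  if (is.null(names(subsets))) names(subsets) <- as.character(seq_along(subsets))
  if (is.null(reference)) reference <- select_reference(subsets)
  if (!reference %in% names(subsets)) abort("unknown reference id")
  ref <- subsets[[reference]]
  if (anyNA(ref$nodes$x)) abort("reference subset graph must be laid out")

  all_edges <- if (!is.null(networks)) {
    bind_rows(lapply(networks, function(nw) nw$edges[, c("from", "to")]))
  } else NULL

  nodes <- ref$nodes
  nodes$group_id <- paste(reference, nodes$group_id, sep = "/")
  nodes$networks <- rep(list(reference), nrow(nodes))
  nodes$added <- FALSE
  edges <- ref$edges
  if (nrow(edges)) {
    edges$from <- paste(reference, edges$from, sep = "/")
    edges$to <- paste(reference, edges$to, sep = "/")
  }
  edges$overlap <- rep(NA_integer_, nrow(edges))
  edges$conn <- rep(NA_integer_, nrow(edges))

  for (sid in setdiff(names(subsets), reference)) {
    for (i in seq_len(nrow(subsets[[sid]]$nodes))) {
      nd <- subsets[[sid]]$nodes[i, ]
      dup <- which(vapply(seq_len(nrow(nodes)), function(j) {
        setequal(nodes$signature[[j]], nd$signature[[1]]) &&
          setequal(nodes$members[[j]], nd$members[[1]])
      }, TRUE))
      if (length(dup)) {
        nodes$networks[[dup[1]]] <- c(nodes$networks[[dup[1]]], sid)
        next
      }
      gid <- paste(sid, nd$group_id, sep = "/")
      ov <- vapply(nodes$members, function(m) length(intersect(m, nd$members[[1]])), 0L)
      conn <- vapply(nodes$members, function(m)
        count_connecting_edges(all_edges, m, nd$members[[1]]), 0L)
      new_edges <- NULL
      if (any(ov > 0)) {
        hit <- which(ov > 0)
        w <- ov[hit] / max(ov[hit])
        ord <- order(-ov[hit], -conn[hit])
        hit <- hit[ord]; w <- w[ord]
        new_edges <- tibble(from = nodes$group_id[hit], to = gid,
                            weight = w, overlap = ov[hit], conn = conn[hit])
      } else if (any(conn > 0)) {
        j <- which.max(conn)
        new_edges <- tibble(from = nodes$group_id[j], to = gid,
                            weight = min(2 / (nodes$size[j] + nd$size), 1),
                            overlap = 0L, conn = conn[j])
      }
      nodes <- bind_rows(nodes, tibble(
        group_id = gid, signature = nd$signature, members = nd$members,
        size = nd$size, level = nd$level, x = NA_real_, y = NA_real_,
        networks = list(sid), added = TRUE
      ))
      if (!is.null(new_edges)) edges <- bind_rows(edges, new_edges)
    }
  }
  structure(list(reference = reference, nodes = nodes, edges = edges,
                 subsets = subsets),
            class = "super_graph")
}

#' @export
print.super_graph <- function(x, ...) {
  cat("<super_graph> reference ", x$reference, ": ", nrow(x$nodes),
      " groups (", sum(x$nodes$added), " added), ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' @export
tidy.super_graph <- function(x, ...) {
  mutate(x$nodes,
         signature = vapply(.data$signature, paste, "", collapse = "+"),
         networks = vapply(.data$networks, paste, "", collapse = ","))
}

#' @export
glance.super_graph <- function(x, ...) {
  tibble(reference = x$reference, n_groups = nrow(x$nodes),
         n_added = sum(x$nodes$added), n_edges = nrow(x$edges))
}

#' Lay out a super-graph with the reference frozen
#'
#' Step 1: weighted Fruchterman-Reingold placement of the subset-level
#' super-graph in which every reference node is pinned to its original
#' position (bit-identical on output) and only added nodes move. Step 2:
#' within-group gene layout run only for the added groups; genes that
#' already have a position in the reference layout keep it exactly.
#'
#' @param sg A `super_graph`.
#' @param reference_layout The reference's `doi_layout`
#'   (see [layout_within_groups()]).
#' @param subnetworks Named list of filtered `doi_network`s (used for
#'   intra-group edges of added groups); at least the non-reference ones.
#' @param params,seed As in [layout_subset_graph()].
#' @return A `doi_layout` whose `genes` tibble covers all placed genes and
#'   whose `groups` tibble carries the final super-graph positions, with the
#'   positioned `super_graph` attached as `$super_graph`.
#' @export
layout_supergraph <- function(sg, reference_layout, subnetworks,
                              params = list(), seed = 1) {
  params <- default_layout_params(params)
  nodes <- sg$nodes
  fixed <- nodes[!nodes$added, c("group_id", "x", "y")]
  tmp <- structure(list(nodes = nodes, edges = sg$edges[, c("from", "to", "weight")],
                        residual = character(), selection = NULL),
                   class = "subset_graph")
  laid <- layout_subset_graph(tmp, params = params, seed = seed,
                              fixed_positions = fixed)
  nodes$x <- laid$nodes$x[match(nodes$group_id, laid$nodes$group_id)]
  nodes$y <- laid$nodes$y[match(nodes$group_id, laid$nodes$group_id)]
  stopifnot(identical(nodes$x[!nodes$added], fixed$x),
            identical(nodes$y[!nodes$added], fixed$y))
  sg$nodes <- nodes

  union_net <- list(edges = bind_rows(lapply(subnetworks, function(nw)
    nw$edges[, c("from", "to")])))

  genes <- reference_layout$genes
  added <- nodes[nodes$added, , drop = FALSE]
  for (i in seq_len(nrow(added))) {
    members <- added$members[[i]]
    r <- params$r0 * sqrt(length(members))
    if (length(members) == 1L) {
      pos <- tibble(id = members, x = added$x[i], y = added$y[i],
                    group_id = added$group_id[i])
    } else {
      keep <- union_net$edges$from %in% members & union_net$edges$to %in% members
      ig <- igraph::graph_from_data_frame(
        union_net$edges[keep, ], directed = FALSE, vertices = sort(members))
      withr::local_seed(seed + 1000L + i)
      init <- matrix(stats::runif(2 * length(members), -1, 1), ncol = 2)
      p <- igraph::layout_with_fr(ig, coords = init, niter = params$niter,
                                  grid = params$grid)
      p <- sweep(p, 2, colMeans(p))
      rad <- sqrt(rowSums(p^2))
      if (max(rad) > 0) p <- p * (params$shrink * r / max(rad))
      pos <- tibble(id = igraph::V(ig)$name, x = added$x[i] + p[, 1],
                    y = added$y[i] + p[, 2], group_id = added$group_id[i])
    }
    # genes already placed in the reference keep their reference position
    pos <- pos[!pos$id %in% genes$id, , drop = FALSE]
    genes <- bind_rows(genes, pos)
  }

  groups <- tibble(group_id = nodes$group_id, x = nodes$x, y = nodes$y,
                   radius = params$r0 * sqrt(nodes$size))
  structure(list(genes = genes, groups = groups,
                 params = c(params, seed = seed), super_graph = sg),
            class = "doi_layout")
}

#' Genes shared by a selection of subnetworks
#'
#' Intersection of the gene sets of the selected subnetworks; with a single
#' selected subnetwork, all of its genes. Used for highlighting and export.
#'
#' @param subnetworks Named list of `doi_network`s (or character vectors of
#'   gene ids).
#' @param selection Character vector of subnetwork names (default: all).
#' @return Sorted character vector of shared gene ids.
#' @export
shared_elements <- function(subnetworks, selection = names(subnetworks)) {
  if (!length(selection)) abort("`selection` must name at least one subnetwork")
  unknown <- setdiff(selection, names(subnetworks))
  if (length(unknown)) {
    abort(paste0("unknown subnetwork id: ", paste(unknown, collapse = ", ")))
  }
  sets <- lapply(subnetworks[selection], function(s) {
    if (inherits(s, "doi_network")) s$nodes$id else as.character(s)
  })
  sort(Reduce(intersect, sets))
}
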