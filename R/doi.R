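# Degree-of-interest fields and their algebra.
#
# A DoI field assigns every node and every edge of a network a value:
# continuous fields live in [0,1], discrete fields in {0,1}. Node-derived
# fields are extended to edges with min (an edge is only as interesting as
# its least interesting endpoint); edge-derived fields are extended to nodes
# with max (a node stays interesting while any incident edge is).

doi_field <- function(kind, nodes, edges, provenance = list()) {
  kind <- match.arg(kind, c("continuous", "discrete", "final"))
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("id", "doi") %in% names(nodes)),
            all(c("from", "to", "doi") %in% names(edges)))
  check_doi_bounds(kind, c(nodes$doi, edges$doi))
  structure(list(kind = kind, nodes = nodes[, c("id", "doi")],
                 edges = edges[, c("from", "to", "doi")],
                 provenance = provenance),
            class = "doi_field")
}

check_doi_bounds <- function(kind, v) {
  if (anyNA(v)) abort("DoI values must not be missing")
  if (any(v < 0 | v > 1)) abort("DoI values must lie in [0, 1]")
  if (kind == "discrete" && any(v != 0 & v != 1)) {
    abort("discrete DoI values must be 0 or 1")
  }
  invisible(TRUE)
}

#' @export
print.doi_field <- function(x, ...) {
  cat("<doi_field> ", x$kind, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges; ",
      sum(x$nodes$doi > 0), " / ", sum(x$edges$doi > 0), " visible\n", sep = "")
  if (!is.null(x$provenance$what)) cat("  ", x$provenance$what, "\n", sep = "")
  invisible(x)
}

#' Tidy a DoI field into one long tibble
#'
#' @param x A `doi_field`.
#' @param ... Unused.
#' @return Tibble with columns `element` (`"node"`/`"edge"`), `id`
#'   (gene id, or `"from|to"` for edges) and `doi`.
#' @export
tidy.doi_field <- function(x, ...) {
  bind_rows(
    tibble(element = "node", id = x$nodes$id, doi = x$nodes$doi),
    tibble(element = "edge", id = paste(x$edges$from, x$edges$to, sep = "|"),
           doi = x$edges$doi)
  )
}

#' @export
glance.doi_field <- function(x, ...) {
  tibble(kind = x$kind,
         n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         visible_nodes = sum(x$nodes$doi > 0),
         visible_edges = sum(x$edges$doi > 0),
         mean_node_doi = mean(x$nodes$doi))
}

# ---- construction ----------------------------------------------------------

#' Continuous DoI field from a numeric attribute
#'
#' Transforms a registered node or edge attribute to the `[0,1]` interest
#' scale, then extends node-based values to edges with the minimum of the two
#' endpoints and edge-based values to nodes with the maximum over incident
#' edges. A missing raw value yields DoI 0, as does a node with no incident
#' edges under an edge-based field.
#'
#' Transforms: `"identity"` (values already in `[0,1]`), `"one_minus"`
#' (`1 - x`, for p-value-like attributes where small is interesting) and
#' `"neg_log10_capped"` (`min(-log10(x)/cap, 1)`, default `cap = 10`).
#' Transformed values outside `[0,1]` are an error.
#'
#' @param network A `doi_network`.
#' @param attribute Registered attribute name.
#' @param element_kind `"node"` or `"edge"`: where the attribute lives.
#' @param transform One of `"identity"`, `"one_minus"`, `"neg_log10_capped"`.
#' @param cap Cap for `neg_log10_capped`.
#' @return A continuous `doi_field`.
#' @export
continuous_doi <- function(network, attribute,
                           element_kind = c("node", "edge"),
                           transform = c("identity", "one_minus",
                                         "neg_log10_capped"),
                           cap = 10) {
  element_kind <- match.arg(element_kind)
  transform <- match.arg(transform)
  registry <- if (element_kind == "node") network$node_registry else network$edge_registry
  if (!attribute %in% registry$name) {
    abort(paste0("unknown ", element_kind, " attribute: ", attribute))
  }
  tf <- switch(transform,
    identity = function(x) x,
    one_minus = function(x) 1 - x,
    neg_log10_capped = function(x) pmin(-log10(x) / cap, 1)
  )
  apply_tf <- function(raw) {
    v <- tf(raw)
    ok <- is.na(v) | (v >= 0 & v <= 1)
    if (!all(ok)) {
      abort(paste0("transform `", transform, "` maps attribute `", attribute,
                   "` outside [0, 1]"))
    }
    v[is.na(v)] <- 0
    v
  }
  prov <- list(what = paste0("continuous(", attribute, ", ", element_kind,
                             ", ", transform, ")"),
               attribute = attribute, element_kind = element_kind,
               transform = transform, cap = cap)

  if (element_kind == "node") {
    nd <- apply_tf(network$nodes[[attribute]])
    names(nd) <- network$nodes$id
    ed <- pmin(nd[network$edges$from], nd[network$edges$to])
    doi_field("continuous",
              tibble(id = network$nodes$id, doi = unname(nd)),
              tibble(from = network$edges$from, to = network$edges$to,
                     doi = unname(ed)),
              prov)
  } else {
    ed <- apply_tf(network$edges[[attribute]])
    nd <- max_over_incident(network, ed)
    doi_field("continuous",
              tibble(id = network$nodes$id, doi = nd),
              tibble(from = network$edges$from, to = network$edges$to,
                     doi = ed),
              prov)
  }
}

# max over incident edges; isolated nodes get 0 (empty-max convention)
max_over_incident <- function(network, edge_values) {
  inc <- c(tapply(rep(edge_values, 2),
                  c(network$edges$from, network$edges$to), max))
  out <- rep(0, nrow(network$nodes))
  hit <- match(network$nodes$id, names(inc))
  out[!is.na(hit)] <- inc[hit[!is.na(hit)]]
  out
}

#' Discrete DoI field from an annotation knowledge source
#'
#' A gene scores 1 when it belongs to at least one term of the source; an
#' edge scores 1 when its two endpoints share at least one common term.
#'
#' @param network A `doi_network`.
#' @param source A `knowledge_source` (pruned or not; members outside the
#'   network are ignored).
#' @return A discrete `doi_field`.
#' @export
discrete_doi <- function(network, source) {
  ids <- network$nodes$id
  terms <- source$terms$members
  memb <- membership_matrix(ids, terms)
  nd <- as.numeric(rowSums(memb) > 0)
  if (nrow(network$edges)) {
    i <- match(network$edges$from, ids)
    j <- match(network$edges$to, ids)
    shared <- rowSums(memb[i, , drop = FALSE] & memb[j, , drop = FALSE])
    ed <- as.numeric(shared > 0)
  } else {
    ed <- numeric()
  }
  doi_field("discrete",
            tibble(id = ids, doi = nd),
            tibble(from = network$edges$from, to = network$edges$to, doi = ed),
            list(what = paste0("discrete(", source$source_id, ")"),
                 source_id = source$source_id))
}

membership_matrix <- function(ids, term_members) {
  m <- matrix(FALSE, nrow = length(ids), ncol = length(term_members))
  rownames(m) <- ids
  for (t in seq_along(term_members)) {
    hit <- match(term_members[[t]], ids)
    m[hit[!is.na(hit)], t] <- TRUE
  }
  m
}

#' Importance-weighted knowledge DoI
#'
#' Combines several discrete knowledge fields into one continuous field using
#' analyst-assigned importance weights. Weights are normalized to sum to 1;
#' an element annotated by sources `k` in `S` gets
#' `doi = 1 - prod_{k in S}(1 - imp_k)`, and 0 when `S` is empty.
#'
#' @param network A `doi_network`.
#' @param weights Named numeric vector of raw importances (one per source).
#' @param discrete_fields Named list of discrete `doi_field`s, names matching
#'   `weights`.
#' @return A continuous `doi_field`.
#' @export
knowledge_importance_doi <- function(network, weights, discrete_fields) {
  if (!length(weights) || all(weights == 0)) abort("importance weights are all zero")
  if (any(weights < 0)) abort("importance weights must be non-negative")
  if (is.null(names(weights)) || !setequal(names(weights), names(discrete_fields))) {
    abort("`weights` names must match `discrete_fields` names")
  }
  imp <- weights / sum(weights)
  ks <- names(discrete_fields)
  nmat <- vapply(ks, function(k) discrete_fields[[k]]$nodes$doi,
                 numeric(nrow(network$nodes)))
  emat <- vapply(ks, function(k) discrete_fields[[k]]$edges$doi,
                 numeric(nrow(network$edges)))
  nmat <- matrix(nmat, nrow = nrow(network$nodes), dimnames = list(NULL, ks))
  emat <- matrix(emat, nrow = nrow(network$edges), dimnames = list(NULL, ks))
  compose <- function(m) {
    if (!nrow(m)) return(numeric())
    apply(m, 1, function(d) {
      v <- imp[ks][d != 0]
      # single annotating source: exactly imp_k (avoids 1-(1-x) round-off)
      if (length(v) == 1) v else 1 - prod(1 - v)
    })
  }
  doi_field("continuous",
            tibble(id = network$nodes$id, doi = compose(nmat)),
            tibble(from = network$edges$from, to = network$edges$to,
                   doi = compose(emat)),
            list(what = paste0("knowledge_importance(",
                               paste(ks, collapse = ", "), ")"),
                 weights = as.list(imp)))
}

# ---- combination -----------------------------------------------------------

align_fields <- function(fields) {
  ref <- fields[[1]]
  for (f in fields[-1]) {
    if (!identical(f$nodes$id, ref$nodes$id) ||
        !identical(f$edges[c("from", "to")], ref$edges[c("from", "to")])) {
      abort("DoI fields cover different element sets")
    }
  }
  ref
}

constant_field <- function(network, value, kind = "continuous") {
  doi_field(kind,
            tibble(id = network$nodes$id, doi = rep(value, nrow(network$nodes))),
            tibble(from = network$edges$from, to = network$edges$to,
                   doi = rep(value, nrow(network$edges))),
            list(what = paste0("constant(", value, ")")))
}

#' Threshold and combine continuous DoI fields with fuzzy logic
#'
#' Each field is first thresholded (values below its `theta` are set to 0),
#' then the fields are combined elementwise with fuzzy AND (min) or OR (max).
#' An empty field list yields the constant-1 field (no continuous filter).
#'
#' @param network A `doi_network` (defines the element sets).
#' @param fields List of continuous `doi_field`s.
#' @param thresholds Numeric vector of per-field thresholds in `[0,1]`
#'   (recycled if length 1; default 0).
#' @param op `"AND"` (min, the default) or `"OR"` (max).
#' @return A continuous `doi_field`.
#' @export
combine_continuous <- function(network, fields, thresholds = 0,
                               op = c("AND", "OR")) {
  op <- match.arg(op)
  if (!length(fields)) return(constant_field(network, 1))
  thresholds <- rep_len(thresholds, length(fields))
  if (any(thresholds < 0 | thresholds > 1)) abort("thresholds must lie in [0, 1]")
  for (f in fields) {
    if (f$kind != "continuous") abort("combine_continuous() needs continuous fields")
  }
  ref <- align_fields(fields)
  thr <- function(v, th) { v[v < th] <- 0; v }
  nmat <- matrix(0, nrow = nrow(ref$nodes), ncol = length(fields))
  emat <- matrix(0, nrow = nrow(ref$edges), ncol = length(fields))
  for (l in seq_along(fields)) {
    nmat[, l] <- thr(fields[[l]]$nodes$doi, thresholds[l])
    emat[, l] <- thr(fields[[l]]$edges$doi, thresholds[l])
  }
  red <- if (op == "AND") pmin else pmax
  rowred <- function(m) {
    if (!nrow(m)) return(numeric())
    Reduce(red, lapply(seq_len(ncol(m)), function(j) m[, j]))
  }
  doi_field("continuous",
            tibble(id = ref$nodes$id, doi = rowred(nmat)),
            tibble(from = ref$edges$from, to = ref$edges$to, doi = rowred(emat)),
            list(what = paste0("combine_continuous(", op, ")"),
                 op = op, thresholds = thresholds,
                 inputs = lapply(fields, function(f) f$provenance)))
}

#' Combine discrete DoI fields with boolean logic
#'
#' Elementwise conjunction (`"AND"`) or disjunction (`"OR"`, the default
#' preference for knowledge filters). An empty list yields the constant-1
#' field.
#'
#' @param network A `doi_network`.
#' @param fields List of discrete `doi_field`s.
#' @param op `"OR"` (default) or `"AND"`.
#' @return A discrete `doi_field`.
#' @export
combine_discrete <- function(network, fields, op = c("OR", "AND")) {
  op <- match.arg(op)
  if (!length(fields)) return(constant_field(network, 1, kind = "discrete"))
  for (f in fields) {
    if (f$kind != "discrete") abort("combine_discrete() needs discrete fields")
  }
  ref <- align_fields(fields)
  nmat <- matrix(vapply(fields, function(f) f$nodes$doi,
                        numeric(nrow(ref$nodes))), nrow = nrow(ref$nodes))
  emat <- matrix(vapply(fields, function(f) f$edges$doi,
                        numeric(nrow(ref$edges))), nrow = nrow(ref$edges))
  red <- if (op == "AND") pmin else pmax
  rowred <- function(m) {
    if (!nrow(m)) return(numeric())
    Reduce(red, lapply(seq_len(ncol(m)), function(j) m[, j]))
  }
  doi_field("discrete",
            tibble(id = ref$nodes$id, doi = rowred(nmat)),
            tibble(from = ref$edges$from, to = ref$edges$to, doi = rowred(emat)),
            list(what = paste0("combine_discrete(", op, ")"),
                 op = op, inputs = lapply(fields, function(f) f$provenance)))
}

#' Final DoI: AND of the discrete and continuous filters
#'
#' `doi = min(doi_disc, doi_cont)` per element: an element is visible only if
#' its discrete DoI is 1, and then carries the continuous value. Passing
#' `NULL` for either side means "no filter of that type" (constant 1); with
#' both `NULL` every element is visible with DoI 1.
#'
#' @param network A `doi_network`.
#' @param disc A discrete `doi_field` or `NULL`.
#' @param cont A continuous `doi_field` or `NULL`.
#' @return A `doi_field` of kind `"final"`; elements with `doi > 0` are
#'   visible.
#' @export
final_doi <- function(network, disc = NULL, cont = NULL) {
  if (is.null(disc)) disc <- constant_field(network, 1, kind = "discrete")
  if (is.null(cont)) cont <- constant_field(network, 1)
  ref <- align_fields(list(disc, cont))
  doi_field("final",
            tibble(id = ref$nodes$id,
                   doi = pmin(disc$nodes$doi, cont$nodes$doi)),
            tibble(from = ref$edges$from, to = ref$edges$to,
                   doi = pmin(disc$edges$doi, cont$edges$doi)),
            list(what = "final = min(discrete, continuous)",
                 discrete = disc$provenance, continuous = cont$provenance))
}

#' Extract the visible subnetwork under a final DoI field
#'
#' Keeps exactly the elements with `doi > 0` and attaches the retained DoI as
#' a `doi` attribute column on nodes and edges. Because node-based fields are
#' extended to edges with the endpoint minimum, every visible edge must have
#' two visible endpoints; this is asserted, and a violation signals a bug in
#' the field's construction, not a repairable state.
#'
#' @param network A `doi_network`.
#' @param doi A `doi_field` (normally kind `"final"`).
#' @return A `doi_network` restricted to the visible elements, with `doi`
#'   columns on `nodes` and `edges`.
#' @export
apply_filter <- function(network, doi) {
  stopifnot(inherits(doi, "doi_field"))
  nvis <- doi$nodes$id[doi$nodes$doi > 0]
  evis <- doi$edges[doi$edges$doi > 0, , drop = FALSE]
  if (!all(evis$from %in% nvis & evis$to %in% nvis)) {
    abort("internal error: a visible edge has a hidden endpoint")
  }
  nodes <- network$nodes[network$nodes$id %in% nvis, , drop = FALSE]
  nodes$doi <- doi$nodes$doi[match(nodes$id, doi$nodes$id)]
  ek <- edge_key(network$edges$from, network$edges$to)
  keep <- ek %in% edge_key(evis$from, evis$to)
  edges <- network$edges[keep, , drop = FALSE]
  edges$doi <- evis$doi[match(edge_key(edges$from, edges$to),
                              edge_key(evis$from, evis$to))]
  out <- doi_network(
    nodes, edges,
    node_orientation = stats::setNames(network$node_registry$orientation,
                                       network$node_registry$name),
    edge_orientation = stats::setNames(network$edge_registry$orientation,
                                       network$edge_registry$name)
  )
  out$node_registry$orientation[out$node_registry$name == "doi"] <- "higher"
  out$edge_registry$orientation[out$edge_registry$name == "doi"] <- "higher"
  out
}
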