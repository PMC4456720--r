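# Workflow orchestration: filter -> layout -> compare -> render, driven by a
# declarative config (YAML/JSON or list). Each stage consumes the previous
# stage's outputs; a machine-readable manifest records versions, seeds and
# the provenance of every DoI field so a run can be re-derived from it.

config_error <- function(msg) {
  abort(msg, class = "netdoi_config_error")
}

#' Validate a run configuration
#'
#' Checks the schema and the existence of every referenced file before any
#' computation. See [run_pipeline()] for the schema.
#'
#' @param config List, or path to a YAML/JSON file.
#' @return The normalized config list, invisibly classed `netdoi_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) config_error(paste0("config file not found: ", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) config_error("config must be a list or a YAML/JSON file")
  if (is.null(config$fixture) && is.null(config$input)) {
    config_error("config needs either `input` (graph + annotations) or `fixture`")
  }
  if (!is.null(config$input)) {
    if (is.null(config$input$graph)) config_error("input$graph is required")
    for (p in c(config$input$graph, config$input$node_table,
                config$input$edge_table,
                vapply(config$input$annotations %||% list(),
                       function(a) a$gmt %||% "", ""))) {
      if (nzchar(p) && !file.exists(p)) {
        config_error(paste0("referenced file does not exist: ", p))
      }
    }
  }
  for (s in config$doi$continuous %||% list()) {
    if (is.null(s$attribute)) config_error("continuous DoI spec needs `attribute`")
    th <- s$theta %||% 0
    if (th < 0 || th > 1) config_error("theta must lie in [0, 1]")
    if (!(s$element_kind %||% "node") %in% c("node", "edge")) {
      config_error("element_kind must be \"node\" or \"edge\"")
    }
    if (!(s$transform %||% "identity") %in%
        c("identity", "one_minus", "neg_log10_capped")) {
      config_error(paste0("unknown transform: ", s$transform))
    }
  }
  if (!is.null(config$doi$cont_op) && !config$doi$cont_op %in% c("AND", "OR")) {
    config_error("doi$cont_op must be AND or OR")
  }
  if (!is.null(config$doi$disc_op) && !config$doi$disc_op %in% c("AND", "OR")) {
    config_error("doi$disc_op must be AND or OR")
  }
  config$seed <- as.integer(config$seed %||% 1L)
  class(config) <- c("netdoi_config", "list")
  invisible(config)
}

pipeline_inputs <- function(config) {
  if (!is.null(config$fixture)) {
    spec <- do.call(fixture_spec,
                    c(config$fixture, list(seed = config$seed)))
    fx <- generate_fixture(spec)
    return(list(network = fx$network, sources = fx$sources, fixture = fx))
  }
  inp <- config$input
  network <- load_network(
    inp$graph, node_table = inp$node_table, edge_table = inp$edge_table,
    node_orientation = unlist(inp$node_orientation) %||% character(),
    edge_orientation = unlist(inp$edge_orientation) %||% character()
  )
  sources <- list()
  for (a in inp$annotations %||% list()) {
    src <- load_annotations(a$gmt, a$source_id)
    sources[[src$source_id]] <- src
  }
  list(network = network, sources = sources)
}

build_doi_fields <- function(network, sources, doi_cfg) {
  cont_fields <- list(); thetas <- numeric()
  for (s in doi_cfg$continuous %||% list()) {
    cont_fields[[length(cont_fields) + 1]] <- continuous_doi(
      network, s$attribute, element_kind = s$element_kind %||% "node",
      transform = s$transform %||% "identity", cap = s$cap %||% 10)
    thetas <- c(thetas, s$theta %||% 0)
  }
  disc_fields <- list()
  for (s in doi_cfg$discrete %||% list()) {
    if (is.null(sources[[s$source_id]])) {
      config_error(paste0("discrete DoI references unknown source: ", s$source_id))
    }
    disc_fields[[s$source_id]] <- discrete_doi(network, sources[[s$source_id]])
  }
  if (!is.null(doi_cfg$importance)) {
    w <- unlist(doi_cfg$importance)
    kw_fields <- lapply(names(w), function(k) {
      disc_fields[[k]] %||% discrete_doi(network, sources[[k]])
    })
    names(kw_fields) <- names(w)
    cont_fields[[length(cont_fields) + 1]] <-
      knowledge_importance_doi(network, w, kw_fields)
    thetas <- c(thetas, doi_cfg$importance_theta %||% 0)
  }
  cont <- combine_continuous(network, cont_fields, thetas,
                             op = doi_cfg$cont_op %||% "AND")
  disc <- combine_discrete(network, unname(disc_fields),
                           op = doi_cfg$disc_op %||% "OR")
  final_doi(network, disc, cont)
}

resolve_selection <- function(subnetwork, sources, sel_cfg) {
  groups <- extract_annotation_groups(subnetwork, unname(sources))
  if (is.null(sel_cfg)) return(groups)
  if (!is.null(sel_cfg$source_id)) {
    groups <- groups[groups$source_id %in% sel_cfg$source_id, , drop = FALSE]
  }
  if (!is.null(sel_cfg$term_ids)) {
    groups <- groups[groups$term_id %in% unlist(sel_cfg$term_ids), , drop = FALSE]
  }
  if (!is.null(sel_cfg$top_n)) {
    groups <- groups[order(-groups$size, groups$term_key), , drop = FALSE]
    groups <- utils::head(groups, sel_cfg$top_n)
  }
  if (!nrow(groups)) config_error("annotation selection matches no groups")
  groups
}

#' Run the filter / layout / compare / render workflow
#'
#' Config schema (YAML, JSON or list): `seed`; `out_dir`; either `input`
#' (`graph` SIF/GraphML, optional `node_table`/`edge_table` TSV,
#' `annotations` as a list of `{gmt, source_id}`, optional orientation maps)
#' or `fixture` ([fixture_spec()] arguments); `doi` with `continuous`
#' (`{attribute, element_kind, transform, theta}` each), `discrete`
#' (`{source_id}` each), operators `cont_op`/`disc_op`, optional
#' `importance` weights; optional `layout` (`selection` with `source_id` /
#' `term_ids` / `top_n`, `r0`, `niter`); optional `compare` with
#' `subnetworks` (each `{id, doi, selection}`); optional `render`
#' (`node_color`, `edge_color`, `contours`, `format`, optional `heatmap`
#' with a conditions-by-genes TSV and gene list). Stages run in that order;
#' omitted stages are skipped. Outputs and a `manifest.json` are written to
#' `out_dir`; partial outputs are removed if any stage fails.
#'
#' @param config List or path (see [validate_config()]).
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the computed objects (`network`, `doi`,
#'   `subnetwork`, `layout`, `supergraph`, ...) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) config_error("no output directory given")
  existed_before <- dir.exists(out_dir)
  pre_existing <- if (existed_before) list.files(out_dir, full.names = TRUE) else character()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  res <- tryCatch(
    run_pipeline_stages(config, out_dir),
    error = function(e) {
      created <- setdiff(list.files(out_dir, full.names = TRUE), pre_existing)
      unlink(created, recursive = TRUE)
      if (!existed_before) unlink(out_dir, recursive = TRUE)
      stop(e)
    }
  )
  invisible(res)
}

run_pipeline_stages <- function(config, out_dir) {
  seed <- config$seed
  manifest <- list(
    tool = "netdoi",
    version = as.character(utils::packageVersion("netdoi")),
    seed = seed,
    stages = list()
  )
  out <- list()

  inputs <- pipeline_inputs(config)
  network <- inputs$network
  sources <- inputs$sources
  if (!is.null(inputs$fixture)) {
    manifest$stages$fixture <- list(
      spec = unclass(inputs$fixture$spec),
      n_genes = n_genes(network), n_relationships = n_relationships(network))
  }
  out$network <- network

  # --- filter ---------------------------------------------------------------
  doi <- build_doi_fields(network, sources, config$doi %||% list())
  subnetwork <- apply_filter(network, doi)
  sub_prefix <- file.path(out_dir, "subnetwork")
  write_subnetwork(network, doi, sub_prefix)
  manifest$stages$filter <- list(
    seed = seed,
    provenance = doi$provenance,
    visible_genes = n_genes(subnetwork),
    visible_relationships = n_relationships(subnetwork),
    outputs = paste0(sub_prefix, c(".graphml", "_nodes.tsv", "_edges.tsv"))
  )
  out$doi <- doi
  out$subnetwork <- subnetwork

  # --- layout ---------------------------------------------------------------
  if (!is.null(config$layout)) {
    params <- config$layout[intersect(names(config$layout),
                                      c("r0", "niter", "shrink"))]
    selection <- resolve_selection(subnetwork, sources, config$layout$selection)
    layout <- layout_by_annotation(subnetwork, selection,
                                   params = params, seed = seed)
    pos_path <- file.path(out_dir, "positions.tsv")
    readr::write_tsv(layout$genes, pos_path, progress = FALSE)
    sg_path <- file.path(out_dir, "subset_graph.tsv")
    sg_tab <- tidy(layout$subset_graph)[, c("group_id", "signature", "size",
                                            "level", "x", "y")]
    readr::write_tsv(sg_tab, sg_path, progress = FALSE)
    se_path <- file.path(out_dir, "subset_edges.tsv")
    readr::write_tsv(layout$subset_graph$edges, se_path, progress = FALSE)
    manifest$stages$layout <- list(
      seed = seed, params = layout$params,
      selection = selection$term_key,
      n_groups = nrow(layout$subset_graph$nodes),
      n_residual = length(layout$subset_graph$residual),
      outputs = c(pos_path, sg_path, se_path)
    )
    out$layout <- layout
    out$selection <- selection
  }

  # --- compare --------------------------------------------------------------
  if (!is.null(config$compare)) {
    subnets <- list(); sublayouts <- list(); subgraphs <- list()
    for (sn in config$compare$subnetworks) {
      id <- sn$id %||% config_error("compare subnetwork needs an `id`")
      d <- build_doi_fields(network, sources, sn$doi %||% config$doi)
      nw <- apply_filter(network, d)
      sel <- resolve_selection(nw, sources, sn$selection)
      lay <- layout_by_annotation(nw, sel, seed = seed)
      subnets[[id]] <- nw
      sublayouts[[id]] <- lay
      subgraphs[[id]] <- lay$subset_graph
    }
    ref <- select_reference(subgraphs)
    sg <- build_supergraph(subgraphs, networks = subnets, reference = ref)
    slay <- layout_supergraph(sg, sublayouts[[ref]], subnets, seed = seed)
    comp_pos <- file.path(out_dir, "supergraph_positions.tsv")
    readr::write_tsv(slay$genes, comp_pos, progress = FALSE)
    comp_groups <- file.path(out_dir, "supergraph_groups.tsv")
    readr::write_tsv(tidy(sg)[, c("group_id", "signature", "size", "level",
                                  "x", "y", "networks", "added")],
                     comp_groups, progress = FALSE)
    shared <- shared_elements(subnets)
    shared_path <- file.path(out_dir, "intersection.tsv")
    readr::write_tsv(tibble(id = shared), shared_path, progress = FALSE)
    manifest$stages$compare <- list(
      seed = seed, reference = ref,
      subnetworks = names(subnets),
      n_shared_genes = length(shared),
      outputs = c(comp_pos, comp_groups, shared_path)
    )
    out$supergraph <- sg
    out$supergraph_layout <- slay
    out$compare_subnetworks <- subnets
    out$shared <- shared
  }

  # --- render ---------------------------------------------------------------
  if (!is.null(config$render)) {
    rc <- config$render
    fmt_ <- rc$format %||% "svg"
    rendered <- character()
    if (!is.null(out$layout)) {
      fig <- file.path(out_dir, paste0("subnetwork.", fmt_))
      render_network(out$layout, subnetwork, fig, format = fmt_,
                     node_color_attribute = rc$node_color,
                     edge_color_attribute = rc$edge_color,
                     highlight = unlist(rc$highlight) %||% character(),
                     contour_groups = if (isTRUE(rc$contours)) TRUE else rc$contours)
      rendered <- c(rendered, fig)
    }
    if (!is.null(out$supergraph_layout)) {
      fig <- file.path(out_dir, paste0("supergraph.", fmt_))
      union_net <- out$compare_subnetworks[[1]]
      for (nw in out$compare_subnetworks[-1]) {
        union_net <- merge_networks(union_net, nw)
      }
      render_network(out$supergraph_layout, union_net, fig, format = fmt_,
                     node_color_attribute = rc$node_color,
                     edge_color_attribute = rc$edge_color,
                     highlight = out$shared %||% character())
      rendered <- c(rendered, fig)
    }
    if (!is.null(rc$heatmap)) {
      hm <- rc$heatmap
      mat <- as.data.frame(readr::read_tsv(hm$data, show_col_types = FALSE,
                                           progress = FALSE))
      rownames(mat) <- mat[[1]]
      mat <- as.matrix(mat[, -1, drop = FALSE])
      genes <- unlist(hm$genes) %||% colnames(mat)
      fig <- file.path(out_dir, paste0("heatmap.", fmt_))
      render_heatmap(mat, genes, fig, format = fmt_)
      rendered <- c(rendered, fig)
    }
    manifest$stages$render <- list(format = fmt_, outputs = rendered)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  out$manifest <- manifest
  out$manifest_path <- manifest_path
  out
}

# union of two filtered networks (genes and relationships; attributes merged,
# conflicts resolved in favor of the first)
merge_networks <- function(a, b) {
  nodes <- bind_rows(a$nodes, b$nodes[!b$nodes$id %in% a$nodes$id, , drop = FALSE])
  kb <- edge_key(b$edges$from, b$edges$to)
  ka <- edge_key(a$edges$from, a$edges$to)
  edges <- bind_rows(a$edges, b$edges[!kb %in% ka, , drop = FALSE])
  ori <- function(ra, rb) {
    v <- c(stats::setNames(ra$orientation, ra$name),
           stats::setNames(rb$orientation, rb$name))
    v[!duplicated(names(v))]
  }
  doi_network(nodes, edges,
              node_orientation = ori(a$node_registry, b$node_registry),
              edge_orientation = ori(a$edge_registry, b$edge_registry))
}
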