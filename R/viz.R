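# Static rendering: diverging color mapping, SVG/PNG network figures with
# group isocontours, legends and highlights, and condition-by-gene heatmaps.
#
# SVG is written directly so identical inputs give byte-identical files.
# Group outlines are smooth isocontours of a sum-of-Gaussians field over the
# member positions (marching squares via grDevices::contourLines) — a
# deliberately simple stand-in for obstacle-avoiding set outlines: members
# are always enclosed, exclusion of non-members is measured and reported,
# not guaranteed.

#' Map numeric values to colors on a diverging scale
#'
#' Diverging palettes are anchored at 0: the domain is symmetric,
#' `(-max(|values|), 0, +max(|values|))`, 0 maps to the palette midpoint and
#' the extremes to the palette endpoints, so sign is always distinguishable.
#' Missing values map to neutral gray.
#'
#' @param values Numeric vector (NA allowed).
#' @param palette ColorBrewer palette name; diverging `"RdBu"` by default
#'   (rendered blue for negative, red for positive).
#' @param domain Optional `c(min, mid, max)` override; diverging palettes
#'   require symmetry about the midpoint.
#' @param na_color Color for missing values.
#' @return Character vector of hex colors.
#' @export
map_colors <- function(values, palette = "RdBu", domain = NULL,
                       na_color = "#BDBDBD") {
  info <- RColorBrewer::brewer.pal.info[palette, ]
  if (is.na(info$category)) abort(paste0("unknown palette: ", palette))
  diverging <- info$category == "div"
  if (!diverging && any(values < 0, na.rm = TRUE)) {
    warn("non-diverging palette used with signed data")
  }
  cols <- RColorBrewer::brewer.pal(info$maxcolors, palette)
  if (palette == "RdBu") cols <- rev(cols)  # negative -> blue, positive -> red
  if (is.null(domain)) {
    if (diverging) {
      m <- max(abs(values), na.rm = TRUE)
      if (!is.finite(m) || m == 0) m <- 1
      domain <- c(-m, 0, m)
    } else {
      lo <- suppressWarnings(min(values, na.rm = TRUE))
      hi <- suppressWarnings(max(values, na.rm = TRUE))
      if (!is.finite(lo)) { lo <- 0; hi <- 1 }
      if (lo == hi) hi <- lo + 1
      domain <- c(lo, (lo + hi) / 2, hi)
    }
  }
  if (diverging && abs((domain[3] + domain[1])) > 1e-9 * max(abs(domain[c(1, 3)]), 1)) {
    abort("diverging domain must be symmetric about the midpoint 0")
  }
  ramp <- grDevices::colorRamp(cols)
  t <- (values - domain[1]) / (domain[3] - domain[1])
  t <- pmin(pmax(t, 0), 1)
  out <- rep(na_color, length(values))
  ok <- !is.na(t)
  if (any(ok)) {
    rgb <- ramp(t[ok])
    out[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
  out
}

qualitative_colors <- function(n, palette = "Set2") {
  base <- RColorBrewer::brewer.pal(max(3, min(n, 8)), palette)
  rep_len(base, n)
}

# ---- isocontours -----------------------------------------------------------

# smooth outline around a set of points: sum of Gaussian bumps evaluated on
# a grid, traced at a fixed iso-level; every member has field >= 1 > iso at
# its own position, so members are always inside some returned polygon
group_isocontour <- function(px, py, bandwidth, iso = 0.5, grid_n = 80) {
  pad <- 3.5 * bandwidth
  xs <- seq(min(px) - pad, max(px) + pad, length.out = grid_n)
  ys <- seq(min(py) - pad, max(py) + pad, length.out = grid_n)
  f <- matrix(0, grid_n, grid_n)
  for (k in seq_along(px)) {
    dx2 <- outer((xs - px[k])^2, (ys - py[k])^2, "+")
    f <- f + exp(-dx2 / (2 * bandwidth^2))
  }
  grDevices::contourLines(xs, ys, f, levels = iso)
}

# even-odd ray casting; polygon given as x/y vectors (closed implicitly)
point_in_polygon <- function(x, y, poly_x, poly_y) {
  n <- length(poly_x)
  j <- n
  inside <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    cross <- (poly_y[i] > y) != (poly_y[j] > y)
    xin <- x < (poly_x[j] - poly_x[i]) * (y - poly_y[i]) /
      (poly_y[j] - poly_y[i]) + poly_x[i]
    inside <- xor(inside, cross & xin)
    j <- i
  }
  inside
}

points_in_contours <- function(x, y, contours) {
  hit <- rep(FALSE, length(x))
  for (cl in contours) {
    hit <- hit | point_in_polygon(x, y, cl$x, cl$y)
  }
  hit
}

# ---- figure spec + SVG -----------------------------------------------------

fmt <- function(x) sprintf("%.3f", x)

svg_header <- function(w, h) c(
  '<?xml version="1.0" encoding="UTF-8"?>',
  sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">', w, h, w, h),
  sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>', w, h)
)

# map data coordinates into the drawing area, preserving aspect ratio
make_scaler <- function(x, y, width, height, margin) {
  xr <- range(x); yr <- range(y)
  if (diff(xr) == 0) xr <- xr + c(-1, 1)
  if (diff(yr) == 0) yr <- yr + c(-1, 1)
  s <- min((width - 2 * margin) / diff(xr), (height - 2 * margin) / diff(yr))
  list(
    x = function(v) margin + (v - xr[1]) * s +
      (width - 2 * margin - diff(xr) * s) / 2,
    y = function(v) height - margin - (v - yr[1]) * s -
      (height - 2 * margin - diff(yr) * s) / 2,  # flip: svg y grows downward
    s = s
  )
}

#' Render a laid-out (sub)network to SVG or PNG
#'
#' One circle per placed gene and one line per visible edge. Node and edge
#' colors come from [map_colors()] applied to the named attributes (diverging,
#' anchored at 0). Selected groups are wrapped in translucent isocontours in
#' qualitative colors; highlighted genes are drawn 1.3x size with a thick
#' black border. The legend lists the annotation groups (with their source
#' ids) of the contoured groups and, for super-graph layouts, the subnetwork
#' labels.
#'
#' @param layout A `doi_layout` (from [layout_within_groups()],
#'   [layout_by_annotation()] or [layout_supergraph()]).
#' @param network The `doi_network` providing edges and attributes (for
#'   super-graph figures: the union of the compared subnetworks, or any
#'   network covering the placed genes).
#' @param out Output path.
#' @param format `"svg"` (default) or `"png"`.
#' @param node_color_attribute,edge_color_attribute Optional attribute names
#'   mapped to node fill / edge stroke color.
#' @param highlight Character vector of gene ids drawn enlarged with a black
#'   border (e.g. from [shared_elements()]).
#' @param contour_groups Group ids to wrap in isocontours; `TRUE` for all.
#' @param legend Named character vector of extra legend entries
#'   (label = color), e.g. subnetwork labels for a super-graph.
#' @param width,height Canvas size in pixels.
#' @param palette Diverging palette for attribute colors.
#' @return Invisibly, a list with the output `path` and `contour_metrics`
#'   (per contoured group: members enclosed — always all — and non-member
#'   positions also enclosed, since the simplified outline does not route
#'   around obstacles).
#' @export
render_network <- function(layout, network, out, format = c("svg", "png"),
                           node_color_attribute = NULL,
                           edge_color_attribute = NULL,
                           highlight = character(),
                           contour_groups = NULL,
                           legend = NULL,
                           width = 800, height = 800,
                           palette = "RdBu") {
  format <- match.arg(format)
  genes <- layout$genes
  if (length(highlight) && !all(highlight %in% genes$id)) {
    abort("highlighted gene not placed in this layout")
  }
  edges <- network$edges[network$edges$from %in% genes$id &
                           network$edges$to %in% genes$id, , drop = FALSE]
  sc <- make_scaler(genes$x, genes$y, width, height, margin = 40)
  gx <- sc$x(genes$x); gy <- sc$y(genes$y)
  names(gx) <- names(gy) <- genes$id

  node_fill <- rep("#999999", nrow(genes))
  if (!is.null(node_color_attribute)) {
    vals <- network$nodes[[node_color_attribute]][match(genes$id, network$nodes$id)]
    node_fill <- map_colors(vals, palette)
  }
  edge_col <- rep("#CCCCCC", nrow(edges))
  if (!is.null(edge_color_attribute) && nrow(edges)) {
    edge_col <- map_colors(edges[[edge_color_attribute]], palette)
  }

  if (isTRUE(contour_groups)) contour_groups <- layout$groups$group_id
  contour_groups <- intersect(contour_groups, unique(genes$group_id))
  ccols <- qualitative_colors(length(contour_groups))
  names(ccols) <- contour_groups

  contours <- list()
  metrics <- list()
  for (g in contour_groups) {
    memb <- genes$group_id %in% g
    bw <- max(0.35 * layout$groups$radius[layout$groups$group_id == g], 1e-3)
    cl <- group_isocontour(genes$x[memb], genes$y[memb], bandwidth = bw)
    contours[[g]] <- cl
    inside_members <- points_in_contours(genes$x[memb], genes$y[memb], cl)
    others <- !memb
    inside_others <- if (any(others)) {
      sum(points_in_contours(genes$x[others], genes$y[others], cl))
    } else 0L
    metrics[[g]] <- tibble(group_id = g, members = sum(memb),
                           members_enclosed = sum(inside_members),
                           non_members_enclosed = inside_others)
  }

  hi <- genes$id %in% highlight
  r_base <- max(3, min(7, 200 / sqrt(nrow(genes) + 1)))

  if (format == "png") {
    grDevices::png(out, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, width), ylim = c(height, 0), asp = 1)
    for (g in names(contours)) {
      for (cl in contours[[g]]) {
        graphics::polygon(sc$x(cl$x), sc$y(cl$y),
                          col = grDevices::adjustcolor(ccols[g], 0.25),
                          border = ccols[g])
      }
    }
    if (nrow(edges)) {
      graphics::segments(gx[edges$from], gy[edges$from],
                         gx[edges$to], gy[edges$to], col = edge_col)
    }
    graphics::points(gx, gy, pch = 21, bg = node_fill,
                     col = ifelse(hi, "black", "#555555"),
                     lwd = ifelse(hi, 3, 1),
                     cex = ifelse(hi, 1.3, 1) * r_base / 3)
    return(invisible(list(path = out, contour_metrics = bind_rows(metrics))))
  }

  lines <- svg_header(width, height)
  for (g in names(contours)) {
    for (cl in contours[[g]]) {
      pts <- paste(fmt(sc$x(cl$x)), fmt(sc$y(cl$y)), sep = ",", collapse = " ")
      lines <- c(lines, sprintf(
        '<polygon class="contour" points="%s" fill="%s" fill-opacity="0.25" stroke="%s"/>',
        pts, ccols[g], ccols[g]))
    }
  }
  if (nrow(edges)) {
    lines <- c(lines, sprintf(
      '<line class="edge" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
      fmt(gx[edges$from]), fmt(gy[edges$from]),
      fmt(gx[edges$to]), fmt(gy[edges$to]), edge_col))
  }
  lines <- c(lines, sprintf(
    '<circle class="gene%s" cx="%s" cy="%s" r="%s" fill="%s" stroke="%s" stroke-width="%s"/>',
    ifelse(hi, " highlight", ""), fmt(gx), fmt(gy),
    fmt(ifelse(hi, 1.3, 1) * r_base), node_fill,
    ifelse(hi, "black", "#555555"), ifelse(hi, "2.5", "0.75")))

  # legend: contoured annotation groups (with source ids) + extra entries
  ly <- 20
  for (g in contour_groups) {
    lines <- c(lines, sprintf(
      '<rect class="legend-swatch" x="10" y="%d" width="12" height="12" fill="%s"/><text class="legend" x="27" y="%d" font-size="11" font-family="sans-serif">%s</text>',
      ly - 10, ccols[g], ly, xml_esc(g)))
    ly <- ly + 16
  }
  for (nm in names(legend %||% character())) {
    lines <- c(lines, sprintf(
      '<rect class="legend-swatch" x="10" y="%d" width="12" height="12" fill="%s"/><text class="legend" x="27" y="%d" font-size="11" font-family="sans-serif">%s</text>',
      ly - 10, legend[[nm]], ly, xml_esc(nm)))
    ly <- ly + 16
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, out, useBytes = TRUE)
  invisible(list(path = out, contour_metrics = bind_rows(metrics)))
}

#' Render a condition-by-gene heatmap
#'
#' Rows are conditions (patients, treatments, time points), columns are the
#' selected genes in selection order; cell colors use the same diverging,
#' zero-anchored mapping as the network figures.
#'
#' @param data Numeric matrix (rows = conditions, columns = genes, dimnames
#'   required) or a long data frame with columns `condition`, `gene`,
#'   `value`.
#' @param selected_genes Genes (columns) to draw, in order.
#' @param out Output path.
#' @param format `"svg"` or `"png"`.
#' @param palette Diverging palette.
#' @param cell Cell size in pixels.
#' @return Invisibly, the output path.
#' @export
render_heatmap <- function(data, selected_genes, out, format = c("svg", "png"),
                           palette = "RdBu", cell = 22) {
  format <- match.arg(format)
  if (is.data.frame(data) && !is.matrix(data)) {
    stopifnot(all(c("condition", "gene", "value") %in% names(data)))
    data <- stats::xtabs(value ~ condition + gene, data = data)
    data <- matrix(as.numeric(data), nrow = nrow(data), dimnames = dimnames(data))
  }
  if (!all(selected_genes %in% colnames(data))) {
    abort(paste0("unknown gene id: ",
                 paste(setdiff(selected_genes, colnames(data)), collapse = ", ")))
  }
  m <- data[, selected_genes, drop = FALSE]
  cols <- map_colors(as.numeric(m), palette)
  cm <- matrix(cols, nrow = nrow(m))
  left <- 10 + 7 * max(nchar(rownames(m)))
  top <- 10 + 7 * max(nchar(colnames(m)))
  width <- left + cell * ncol(m) + 10
  height <- top + cell * nrow(m) + 10

  if (format == "png") {
    grDevices::png(out, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, width), ylim = c(height, 0), asp = 1)
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      graphics::rect(left + (j - 1) * cell, top + (i - 1) * cell,
                     left + j * cell, top + i * cell, col = cm[i, j], border = "white")
    }
    graphics::text(left - 4, top + (seq_len(nrow(m)) - 0.5) * cell,
                   rownames(m), adj = 1, cex = 0.8)
    graphics::text(left + (seq_len(ncol(m)) - 0.5) * cell, top - 4,
                   colnames(m), adj = 0, srt = 90, cex = 0.8)
    return(invisible(out))
  }

  lines <- svg_header(width, height)
  for (i in seq_len(nrow(m))) {
    lines <- c(lines, sprintf(
      '<rect class="cell" x="%s" y="%s" width="%d" height="%d" fill="%s" stroke="white"/>',
      fmt(left + (seq_len(ncol(m)) - 1) * cell), fmt(top + (i - 1) * cell),
      cell, cell, cm[i, ]))
  }
  lines <- c(lines, sprintf(
    '<text class="row-label" x="%s" y="%s" text-anchor="end" font-size="11" font-family="sans-serif">%s</text>',
    fmt(left - 4), fmt(top + (seq_len(nrow(m)) - 0.5) * cell + 4),
    xml_esc(rownames(m))))
  lines <- c(lines, sprintf(
    '<text class="col-label" x="%s" y="%s" transform="rotate(-90 %s %s)" font-size="11" font-family="sans-serif">%s</text>',
    fmt(left + (seq_len(ncol(m)) - 0.5) * cell + 4), fmt(top - 4),
    fmt(left + (seq_len(ncol(m)) - 0.5) * cell + 4), fmt(top - 4),
    xml_esc(colnames(m))))
  lines <- c(lines, "</svg>")
  writeLines(lines, out, useBytes = TRUE)
  invisible(out)
}

# ---- ggplot2 views ---------------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_text
#'   coord_equal theme_void labs
NULL

#' Plot a subset graph
#'
#' Groups as points sized by membership, Hasse edges shaded by weight.
#'
#' @param object A laid-out `subset_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.subset_graph <- function(object, ...) {
  nd <- tidy(object)
  ed <- object$edges
  ed$x <- nd$x[match(ed$from, nd$group_id)]
  ed$y <- nd$y[match(ed$from, nd$group_id)]
  ed$xend <- nd$x[match(ed$to, nd$group_id)]
  ed$yend <- nd$y[match(ed$to, nd$group_id)]
  ggplot(nd, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = ed, aes(xend = .data$xend, yend = .data$yend,
                                alpha = .data$weight), color = "grey30") +
    geom_point(aes(size = .data$size), color = "steelblue") +
    geom_text(aes(label = .data$group_id), vjust = -1.1, size = 3) +
    coord_equal() + theme_void() +
    labs(alpha = "edge weight", size = "genes")
}

#' Plot a two-step layout
#'
#' @param object A `doi_layout`.
#' @param network Optional `doi_network` whose edges are drawn.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.doi_layout <- function(object, network = NULL, ...) {
  p <- ggplot(object$genes, aes(x = .data$x, y = .data$y))
  if (!is.null(network)) {
    ed <- network$edges[network$edges$from %in% object$genes$id &
                          network$edges$to %in% object$genes$id, , drop = FALSE]
    ed$x <- object$genes$x[match(ed$from, object$genes$id)]
    ed$y <- object$genes$y[match(ed$from, object$genes$id)]
    ed$xend <- object$genes$x[match(ed$to, object$genes$id)]
    ed$yend <- object$genes$y[match(ed$to, object$genes$id)]
    p <- p + geom_segment(data = ed, aes(xend = .data$xend, yend = .data$yend),
                          color = "grey80", linewidth = 0.2)
  }
  p + geom_point(aes(color = .data$group_id), size = 1.5, show.legend = FALSE) +
    coord_equal() + theme_void()
}

#' Plot a super-graph at the group level
#'
#' Reference groups as circles, added groups as triangles.
#'
#' @param object A positioned `super_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.super_graph <- function(object, ...) {
  nd <- tidy(object)
  ed <- object$edges
  ed$x <- nd$x[match(ed$from, nd$group_id)]
  ed$y <- nd$y[match(ed$from, nd$group_id)]
  ed$xend <- nd$x[match(ed$to, nd$group_id)]
  ed$yend <- nd$y[match(ed$to, nd$group_id)]
  ggplot(nd, aes(x = .data$x, y = .data$y)) +
    geom_segment(data = ed, aes(xend = .data$xend, yend = .data$yend,
                                alpha = .data$weight), color = "grey30") +
    geom_point(aes(size = .data$size, shape = .data$added), color = "tomato") +
    coord_equal() + theme_void() +
    labs(shape = "added", size = "genes", alpha = "edge weight")
}
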