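make_subset <- function(groups, edges = NULL, residual = character()) {
  # groups: named list group_id -> members; signature derived from the id
  nodes <- tibble::tibble(
    group_id = names(groups),
    signature = strsplit(names(groups), "+", fixed = TRUE),
    members = unname(lapply(groups, sort)),
    size = lengths(groups),
    level = lengths(strsplit(names(groups), "+", fixed = TRUE)),
    x = NA_real_, y = NA_real_
  )
  ed <- if (is.null(edges)) {
    tibble::tibble(from = character(), to = character(), weight = numeric())
  } else edges
  structure(list(nodes = nodes, edges = ed, residual = residual,
                 selection = NULL), class = "subset_graph")
}

test_that("the largest subnetwork is the reference, with the stated tie-breaks", {
  a <- make_subset(list(A1 = sprintf("g%d", 1:6), A2 = sprintf("g%d", 7:10)))
  b <- make_subset(list(B1 = sprintf("h%d", 1:6)))
  expect_identical(select_reference(list(first = a, second = b)), "first")

  # equal gene counts: more subset nodes wins
  c1 <- make_subset(list(C1 = sprintf("g%d", 1:8)))
  c2 <- make_subset(list(D1 = sprintf("g%d", 1:4), D2 = sprintf("g%d", 5:7),
                         D3 = "g8"))
  expect_identical(select_reference(list(one = c1, two = c2)), "two")

  # full tie: input order
  expect_identical(select_reference(list(x = c1, y = c1)), "x")
  expect_error(select_reference(list(only = a)), "at least 2")
})

test_that("identical subnetworks collapse onto the reference", {
  a <- layout_subset_graph(
    make_subset(list(A1 = c("g1", "g2"), A2 = c("g3"))), seed = 1)
  sg <- build_supergraph(list(ref = a, dup = a))
  expect_equal(sum(sg$nodes$added), 0)
  expect_equal(nrow(sg$nodes), 2)
  expect_true(all(vapply(sg$nodes$networks, length, 0L) == 2))
})

test_that("added groups connect by overlap with per-node normalized weights", {
  ref <- layout_subset_graph(make_subset(list(
    A1 = c("g1", "g2", "g3", "g4"), A2 = c("g5", "g6"))), seed = 1)
  other <- make_subset(list(B1 = c("g2", "g3", "g4", "g5")))
  sg <- build_supergraph(list(R = ref, O = other), reference = "R")
  added <- sg$edges[sg$edges$to == "O/B1", ]
  expect_equal(nrow(added), 2)
  w <- stats::setNames(added$weight, added$from)
  expect_equal(unname(w["R/A1"]), 1)        # overlap 3 / max 3
  expect_equal(unname(w["R/A2"]), 1 / 3)    # overlap 1 / max 3

  # disjoint group with no connecting edges stays isolated
  lone <- make_subset(list(Z1 = c("z1", "z2")))
  sg2 <- build_supergraph(list(R = ref, L = lone), reference = "R")
  expect_equal(nrow(sg2$edges[sg2$edges$to == "L/Z1", ]), 0)
  expect_true("L/Z1" %in% sg2$nodes$group_id)
})

test_that("a no-overlap group with topological connections attaches to the best-connected node", {
  ref <- layout_subset_graph(make_subset(list(
    A1 = c("g1", "g2"), A2 = c("g3", "g4"))), seed = 1)
  other <- make_subset(list(B1 = c("h1", "h2")))
  nw <- doi_network(
    nodes = data.frame(id = c(sprintf("g%d", 1:4), "h1", "h2")),
    edges = data.frame(from = c("g3", "g4", "g1"), to = c("h1", "h1", "h2"))
  )
  sg <- build_supergraph(list(R = ref, O = other), networks = list(R = nw, O = nw),
                         reference = "R")
  att <- sg$edges[sg$edges$to == "O/B1", ]
  expect_equal(nrow(att), 1)
  expect_identical(att$from, "R/A2")  # 2 connecting edges beat 1
})

test_that("reference positions are immutable under supergraph layout", {
  for (s in 1:5) {
    ctx <- random_selection(n_genes = 25, n_terms = 4, seed = 600 + s)
    lay_ref <- layout_by_annotation(ctx$network, ctx$selection, seed = s)
    ctx2 <- random_selection(n_genes = 25, n_terms = 3, seed = 700 + s)
    lay_oth <- layout_by_annotation(ctx2$network, ctx2$selection, seed = s)
    sg <- build_supergraph(list(A = lay_ref$subset_graph,
                                B = lay_oth$subset_graph),
                           reference = "A")
    res <- layout_supergraph(sg, lay_ref,
                             list(A = ctx$network, B = ctx2$network),
                             seed = 1000 + s)
    nd <- res$super_graph$nodes
    ref_rows <- !nd$added
    orig <- lay_ref$subset_graph$nodes
    m <- match(sub("^A/", "", nd$group_id[ref_rows]), orig$group_id)
    expect_identical(nd$x[ref_rows], orig$x[m])
    expect_identical(nd$y[ref_rows], orig$y[m])
    # genes placed in the reference keep their positions exactly
    common <- intersect(res$genes$id, lay_ref$genes$id)
    expect_identical(
      res$genes[match(common, res$genes$id), c("x", "y")],
      lay_ref$genes[match(common, lay_ref$genes$id), c("x", "y")]
    )
  }
})

test_that("an added node converges nearer its strong neighbor than a non-neighbor", {
  ref <- layout_subset_graph(make_subset(list(
    A1 = c("g1", "g2", "g3"), A2 = c("g4", "g5", "g6"))), seed = 3)
  other <- make_subset(list(B1 = c("g1", "g2", "g3", "x1")))
  sg <- build_supergraph(list(R = ref, O = other), reference = "R")
  lay_ref <- list(genes = tibble::tibble(id = character(), x = numeric(),
                                         y = numeric(), group_id = character()),
                  groups = NULL, params = NULL)
  res <- layout_supergraph(sg, lay_ref, list(R = NULL, O = NULL) |>
                             lapply(function(x) doi_network(data.frame(id = c(
                               sprintf("g%d", 1:6), "x1")))), seed = 2)
  nd <- res$super_graph$nodes
  p <- function(g) c(nd$x[nd$group_id == g], nd$y[nd$group_id == g])
  d1 <- sqrt(sum((p("O/B1") - p("R/A1"))^2))  # overlap 3
  d2 <- sqrt(sum((p("O/B1") - p("R/A2"))^2))  # overlap 0
  expect_lt(d1, d2)
})

test_that("shared_elements intersects the selected subnetworks symmetrically", {
  nets <- list(A = c("g1", "g2"), B = c("g2", "g3"), C = c("g4"))
  expect_identical(shared_elements(nets, c("A", "B")), "g2")
  expect_identical(shared_elements(nets, c("B", "A")), "g2")
  expect_identical(shared_elements(nets, c("A", "C")), character(0))
  expect_identical(shared_elements(nets, "A"), c("g1", "g2"))
  expect_error(shared_elements(nets, "Z"), "unknown subnetwork")
  expect_error(shared_elements(nets, character(0)), "at least one")
})

test_that("every input gene appears exactly once in the supergraph placement", {
  ctx <- random_selection(n_genes = 20, n_terms = 3, seed = 81)
  layA <- layout_by_annotation(ctx$network, ctx$selection, seed = 1)
  ctx2 <- random_selection(n_genes = 20, n_terms = 3, seed = 82)
  layB <- layout_by_annotation(ctx2$network, ctx2$selection, seed = 1)
  sg <- build_supergraph(list(A = layA$subset_graph, B = layB$subset_graph),
                         reference = "A")
  res <- layout_supergraph(sg, layA, list(A = ctx$network, B = ctx2$network),
                           seed = 9)
  expect_false(anyDuplicated(res$genes$id) > 0)
  expect_true(all(unlist(sg$nodes$members) %in% res$genes$id))
})
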