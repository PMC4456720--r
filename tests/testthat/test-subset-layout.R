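test_that("annotation groups are extracted from the subnetwork only", {
  net <- tiny_network()
  src <- tiny_source(terms = list(P1 = c("a", "b"), P2 = c("zz", "yy"),
                                  P3 = c("c", "zz")))
  groups <- extract_annotation_groups(net, src)
  expect_setequal(groups$term_id, c("P1", "P3"))  # P2 has no member in net
  expect_identical(groups$members[[which(groups$term_id == "P3")]], "c")

  # invariant under gene order permutation
  net2 <- doi_network(net$nodes[c(3, 1, 4, 2), ], net$edges)
  groups2 <- extract_annotation_groups(net2, src)
  expect_identical(groups$members, groups2$members)

  one <- doi_network(data.frame(id = "a"))
  g1 <- extract_annotation_groups(one, src)
  expect_identical(g1$term_id, "P1")
})

test_that("subset graph realizes the signature partition with Hasse edges", {
  # v1:{A1}, v2:{A1,A2}, v3:{A2} -> 3 groups, edges only along inclusion
  net <- doi_network(data.frame(id = c("v1", "v2", "v3")))
  sel <- tibble::tibble(
    term_key = c("S:A1", "S:A2"), source_id = "S", term_id = c("A1", "A2"),
    name = c("A1", "A2"),
    members = list(c("v1", "v2"), c("v2", "v3")), size = c(2L, 2L)
  )
  sg <- build_subset_graph(net, sel)
  expect_equal(nrow(sg$nodes), 3)
  expect_setequal(subset_edges_as_strings(sg),
                  c("S:A1 -> S:A1+S:A2", "S:A2 -> S:A1+S:A2"))
  # member sets are disjoint and cover all annotated genes
  expect_equal(sum(sg$nodes$size), 3)
  expect_length(sg$residual, 0)
})

test_that("unrealized intermediate signatures yield direct skip-level edges", {
  net <- doi_network(data.frame(id = c("v1", "v2")))
  sel <- tibble::tibble(
    term_key = paste0("S:A", 1:3), source_id = "S",
    term_id = paste0("A", 1:3), name = paste0("A", 1:3),
    members = list(c("v1", "v2"), "v2", "v2"), size = c(2L, 1L, 1L)
  )
  sg <- build_subset_graph(net, sel)  # signatures {A1} and {A1,A2,A3}
  expect_equal(nrow(sg$nodes), 2)
  expect_identical(subset_edges_as_strings(sg), "S:A1 -> S:A1+S:A2+S:A3")
  expect_equal(sg$edges$weight, 2 / (1 + 1))
})

test_that("edge weights are 2 / (size1 + size2)", {
  net <- doi_network(data.frame(id = sprintf("v%d", 1:5)))
  sel <- tibble::tibble(
    term_key = c("S:A1", "S:A2"), source_id = "S", term_id = c("A1", "A2"),
    name = c("A1", "A2"),
    members = list(c("v1", "v2", "v3", "v4", "v5"), c("v4", "v5", "v3")),
    size = c(5L, 3L)
  )
  sg <- build_subset_graph(net, sel)  # groups {v1,v2} (size 2), {v3,v4,v5} (size 3)
  expect_equal(sort(sg$nodes$size), c(2L, 3L))
  expect_equal(sg$edges$weight, 2 / (2 + 3))
})

test_that("single selected term gives one group and no edges; empty selection errors", {
  net <- doi_network(data.frame(id = c("a", "b")))
  sel <- tibble::tibble(term_key = "S:A1", source_id = "S", term_id = "A1",
                        name = "A1", members = list(c("a", "b")), size = 2L)
  sg <- build_subset_graph(net, sel)
  expect_equal(nrow(sg$nodes), 1)
  expect_equal(nrow(sg$edges), 0)
  expect_error(build_subset_graph(net, sel[0, ]), "at least one")
})

test_that("subset edges equal the brute-force covering relation on random contexts", {
  for (s in 1:25) {
    ctx <- random_selection(n_genes = sample(5:40, 1), n_terms = sample(2:8, 1),
                            seed = 400 + s)
    sg <- build_subset_graph(ctx$network, ctx$selection)
    sigs <- lapply(seq_along(ctx$genes), function(i) {
      sort(ctx$selection$term_key[vapply(ctx$selection$members,
                                         function(m) ctx$genes[i] %in% m, TRUE)])
    })
    expect_identical(subset_edges_as_strings(sg), brute_force_hasse(sigs))
    # partition property
    all_members <- unlist(sg$nodes$members)
    expect_false(anyDuplicated(all_members) > 0)
    expect_setequal(c(all_members, sg$residual), ctx$genes)
    # level strictly increases along every edge
    lv <- stats::setNames(sg$nodes$level, sg$nodes$group_id)
    if (nrow(sg$edges)) expect_true(all(lv[sg$edges$from] < lv[sg$edges$to]))
  }
})

test_that("a union-signature hub group is adjacent to both constituent groups", {
  net <- doi_network(data.frame(id = c("v1", "v2", "v3")))
  sel <- tibble::tibble(
    term_key = c("S:A1", "S:A2"), source_id = "S", term_id = c("A1", "A2"),
    name = c("A1", "A2"),
    members = list(c("v1", "v3"), c("v2", "v3")), size = c(2L, 2L)
  )
  sg <- build_subset_graph(net, sel)  # v3 has the union signature {A1,A2}
  hub <- sg$nodes$group_id[vapply(sg$nodes$members, identical, TRUE, "v3")]
  nb <- c(sg$edges$to[sg$edges$from == hub], sg$edges$from[sg$edges$to == hub])
  expect_setequal(nb, setdiff(sg$nodes$group_id, hub))
})

test_that("subset-graph layout is seeded-deterministic and honors pins", {
  ctx <- random_selection(n_genes = 25, n_terms = 4, seed = 42)
  sg <- build_subset_graph(ctx$network, ctx$selection)
  l1 <- layout_subset_graph(sg, seed = 7)
  l2 <- layout_subset_graph(sg, seed = 7)
  expect_identical(l1$nodes[, c("x", "y")], l2$nodes[, c("x", "y")])
  l3 <- layout_subset_graph(sg, seed = 8)
  expect_false(identical(l1$nodes$x, l3$nodes$x))

  pins <- tibble::tibble(group_id = l1$nodes$group_id,
                         x = l1$nodes$x, y = l1$nodes$y)
  l4 <- layout_subset_graph(sg, seed = 99, fixed_positions = pins)
  expect_identical(l4$nodes$x, l1$nodes$x)  # all pinned: returned unchanged
  expect_identical(l4$nodes$y, l1$nodes$y)
})

test_that("heavier subset edges pull their endpoints closer", {
  net <- doi_network(data.frame(id = c("a", "b", "c", "d")))
  dist_for <- function(w) {
    sg <- structure(list(
      nodes = tibble::tibble(group_id = c("p", "q"),
                             signature = list("A", c("A", "B")),
                             members = list(c("a", "b"), c("c", "d")),
                             size = c(2L, 2L), level = c(1L, 2L),
                             x = NA_real_, y = NA_real_),
      edges = tibble::tibble(from = "p", to = "q", weight = w),
      residual = character(), selection = NULL), class = "subset_graph")
    l <- layout_subset_graph(sg, seed = 5)
    sqrt(diff(l$nodes$x)^2 + diff(l$nodes$y)^2)
  }
  d <- vapply(c(0.1, 0.5, 1), dist_for, 0)
  expect_true(all(diff(d) < 0))
})

test_that("genes stay inside their group disc; singletons sit on the subset node", {
  for (s in 1:5) {
    ctx <- random_selection(n_genes = 30, n_terms = 4, seed = 500 + s)
    net <- ctx$network
    sg <- layout_subset_graph(build_subset_graph(net, ctx$selection), seed = s)
    lay <- layout_within_groups(net, sg, seed = s)
    r0 <- lay$params$r0
    for (i in seq_len(nrow(sg$nodes))) {
      g <- sg$nodes$group_id[i]
      memb <- lay$genes[!is.na(lay$genes$group_id) & lay$genes$group_id == g, ]
      r <- r0 * sqrt(nrow(memb))
      d <- sqrt((memb$x - sg$nodes$x[i])^2 + (memb$y - sg$nodes$y[i])^2)
      expect_true(all(d <= r + 1e-9))
      if (nrow(memb) == 1) expect_equal(d, 0)
    }
    # residual genes are placed, tagged NA
    expect_setequal(lay$genes$id, net$nodes$id)
  }
})

test_that("well-separated groups do not interleave members", {
  ctx <- random_selection(n_genes = 24, n_terms = 3, seed = 77)
  sg <- build_subset_graph(ctx$network, ctx$selection)
  # place subset nodes far apart by hand
  n <- nrow(sg$nodes)
  pins <- tibble::tibble(group_id = sg$nodes$group_id,
                         x = 10 * seq_len(n), y = 0)
  sgl <- layout_subset_graph(sg, seed = 1, fixed_positions = pins)
  lay <- layout_within_groups(ctx$network, sgl, seed = 1)
  placed <- lay$genes[!is.na(lay$genes$group_id), ]
  centers <- sgl$nodes
  nearest <- vapply(seq_len(nrow(placed)), function(i) {
    d <- sqrt((centers$x - placed$x[i])^2 + (centers$y - placed$y[i])^2)
    centers$group_id[which.min(d)]
  }, "")
  expect_identical(nearest, placed$group_id)
})
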