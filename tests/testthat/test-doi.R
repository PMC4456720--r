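test_that("node-based fields extend to edges with min, edge-based to nodes with max", {
  net <- doi_network(
    nodes = data.frame(id = c("a", "b", "c"), score = c(0.3, 0.7, 0.5)),
    edges = data.frame(from = c("a", "b"), to = c("b", "c"),
                       w = c(0.2, 0.9))
  )
  f <- continuous_doi(net, "score", "node")
  expect_equal(f$edges$doi[f$edges$from == "a"], 0.3)  # min(0.3, 0.7)
  expect_equal(f$edges$doi[f$edges$from == "b"], 0.5)

  g <- continuous_doi(net, "w", "edge")
  expect_equal(g$nodes$doi[g$nodes$id == "b"], 0.9)  # max(0.2, 0.9)
  expect_equal(g$nodes$doi[g$nodes$id == "a"], 0.2)
})

test_that("isolated nodes and missing values default to DoI 0", {
  net <- doi_network(
    nodes = data.frame(id = c("a", "b", "iso"), pval = c(0.05, NA, 0.2)),
    edges = data.frame(from = "a", to = "b", w = 0.4)
  )
  f <- continuous_doi(net, "pval", "node", "one_minus")
  expect_equal(f$nodes$doi[f$nodes$id == "a"], 0.95)  # 1 - 0.05
  expect_equal(f$nodes$doi[f$nodes$id == "b"], 0)     # missing raw value
  g <- continuous_doi(net, "w", "edge")
  expect_equal(g$nodes$doi[g$nodes$id == "iso"], 0)   # empty incident set
})

test_that("transforms are validated against the unit interval", {
  net <- doi_network(nodes = data.frame(id = c("a", "b"), x = c(2, 0.5)),
                     edges = data.frame(from = "a", to = "b"))
  expect_error(continuous_doi(net, "x", "node"), "outside")
  expect_error(continuous_doi(net, "nope", "node"), "unknown")
  net2 <- doi_network(nodes = data.frame(id = c("a", "b"), p = c(1e-3, 1)),
                      edges = data.frame(from = "a", to = "b"))
  f <- continuous_doi(net2, "p", "node", "neg_log10_capped")
  expect_equal(f$nodes$doi, c(0.3, 0))  # -log10(1e-3)/10, -log10(1)/10
})

test_that("discrete DoI: membership for nodes, shared term for edges", {
  net <- doi_network(
    nodes = data.frame(id = c("a", "b", "c", "d")),
    edges = data.frame(from = c("a", "a", "c"), to = c("b", "c", "d"))
  )
  # a,b share P1; a and c are annotated but in disjoint terms; d unannotated
  src <- tiny_source(terms = list(P1 = c("a", "b"), P2 = c("c")))
  f <- discrete_doi(net, src)
  expect_equal(f$nodes$doi, c(1, 1, 1, 0))
  expect_equal(f$edges$doi[f$edges$to == "b"], 1)   # share P1
  expect_equal(f$edges$doi[f$edges$to == "c"], 0)   # disjoint terms
  expect_equal(f$edges$doi[f$edges$to == "d"], 0)   # one side unannotated

  empty <- tiny_source(terms = list())
  z <- discrete_doi(net, empty)
  expect_true(all(z$nodes$doi == 0) && all(z$edges$doi == 0))
})

test_that("knowledge-importance DoI follows 1 - prod(1 - imp_k)", {
  net <- doi_network(
    nodes = data.frame(id = c("both", "only1", "none")),
    edges = data.frame(from = "both", to = "only1")
  )
  s1 <- tiny_source("K1", list(T1 = c("both", "only1")))
  s2 <- tiny_source("K2", list(T1 = "both"))
  fields <- list(K1 = discrete_doi(net, s1), K2 = discrete_doi(net, s2))
  f <- knowledge_importance_doi(net, c(K1 = 2, K2 = 2), fields)
  expect_equal(f$nodes$doi[f$nodes$id == "both"], 1 - 0.5 * 0.5)  # 0.75
  expect_equal(f$nodes$doi[f$nodes$id == "only1"], 0.5)           # single source
  expect_equal(f$nodes$doi[f$nodes$id == "none"], 0)              # empty product
  expect_equal(f$edges$doi, 0.5)  # endpoints share a term in K1 only
  expect_error(knowledge_importance_doi(net, c(K1 = 0, K2 = 0), fields),
               "zero")
})

test_that("fuzzy combination thresholds each field before min/max", {
  net <- doi_network(nodes = data.frame(id = c("a", "b"),
                                        u = c(0.6, 0.4), v = c(0.8, 0.8)),
                     edges = data.frame(from = "a", to = "b"))
  fu <- continuous_doi(net, "u", "node")
  fv <- continuous_doi(net, "v", "node")
  and0 <- combine_continuous(net, list(fu, fv), c(0, 0), "AND")
  expect_equal(and0$nodes$doi[and0$nodes$id == "a"], 0.6)  # min(0.6, 0.8)
  andth <- combine_continuous(net, list(fu, fv), c(0.5, 0), "AND")
  expect_equal(andth$nodes$doi[andth$nodes$id == "b"], 0)  # 0.4 -> 0, min = 0
  or0 <- combine_continuous(net, list(fu, fv), c(0, 0), "OR")
  expect_equal(or0$nodes$doi[or0$nodes$id == "b"], 0.8)    # max
  expect_error(combine_continuous(net, list(fu), 1.5), "\\[0, 1\\]")
  expect_error(combine_continuous(net, list(discrete_doi(net, tiny_source())),
                                  0), "continuous")
})

test_that("boolean combination of discrete fields", {
  net <- doi_network(nodes = data.frame(id = c("a", "b")),
                     edges = data.frame(from = "a", to = "b"))
  f1 <- discrete_doi(net, tiny_source("K1", list(T = "a")))
  f0 <- discrete_doi(net, tiny_source("K2", list(T = "b")))
  and <- combine_discrete(net, list(f1, f0), "AND")
  expect_equal(and$nodes$doi, c(0, 0))  # (1,0) AND / (0,1) AND
  or <- combine_discrete(net, list(f1, f0), "OR")
  expect_equal(or$nodes$doi, c(1, 1))
  single <- combine_discrete(net, list(f1))
  expect_identical(single$nodes$doi, f1$nodes$doi)

  net2 <- doi_network(nodes = data.frame(id = c("a", "b"), s = c(0.2, 0.8)),
                      edges = data.frame(from = "a", to = "b"))
  expect_error(combine_discrete(net2, list(continuous_doi(net2, "s", "node"))),
               "discrete")
})

test_that("final DoI is min(discrete, continuous) and drives visibility", {
  net <- doi_network(nodes = data.frame(id = c("a", "b"), s = c(0.6, 0.9)),
                     edges = data.frame(from = "a", to = "b"))
  cont <- combine_continuous(net, list(continuous_doi(net, "s", "node")), 0)
  disc <- discrete_doi(net, tiny_source("K", list(T = "a")))
  f <- final_doi(net, disc, cont)
  expect_equal(f$nodes$doi[f$nodes$id == "a"], 0.6)  # disc 1, cont 0.6
  expect_equal(f$nodes$doi[f$nodes$id == "b"], 0)    # disc 0 hides despite 0.9

  all_vis <- final_doi(net)  # no DoI functions selected at all
  expect_true(all(all_vis$nodes$doi == 1) && all(all_vis$edges$doi == 1))
})

test_that("apply_filter keeps exactly the doi > 0 elements", {
  net <- tiny_network()
  full <- apply_filter(net, final_doi(net))
  expect_equal(nrow(full$nodes), nrow(net$nodes))
  expect_equal(nrow(full$edges), nrow(net$edges))
  none <- apply_filter(net, netdoi:::constant_field(net, 0))
  expect_equal(nrow(none$nodes), 0)

  # brute-force recomputation on a random fixture, single node field
  net_r <- random_network(n = 40, seed = 11)
  theta <- 0.5
  f <- combine_continuous(net_r,
                          list(continuous_doi(net_r, "pval", "node", "one_minus")),
                          theta)
  sub <- apply_filter(net_r, final_doi(net_r, cont = f))
  expected <- net_r$nodes$id[!is.na(net_r$nodes$pval) &
                               (1 - net_r$nodes$pval) >= theta &
                               (1 - net_r$nodes$pval) > 0]
  expect_setequal(sub$nodes$id, expected)
})

test_that("field bounds and extension consistency hold on random fixtures", {
  for (s in 1:10) {
    net <- random_network(n = 25, density = 0.2, seed = s)
    fn <- continuous_doi(net, "pval", "node", "one_minus")
    fe <- continuous_doi(net, "abs_correlation", "edge")
    for (f in list(fn, fe)) {
      expect_true(all(f$nodes$doi >= 0 & f$nodes$doi <= 1))
      expect_true(all(f$edges$doi >= 0 & f$edges$doi <= 1))
    }
    nv <- stats::setNames(fn$nodes$doi, fn$nodes$id)
    expect_true(all(fn$edges$doi <= nv[fn$edges$from] + 1e-15))
    expect_true(all(fn$edges$doi <= nv[fn$edges$to] + 1e-15))
    ev <- fe$edges$doi
    nv2 <- stats::setNames(fe$nodes$doi, fe$nodes$id)
    expect_true(all(nv2[fe$edges$from] >= ev - 1e-15))
    expect_true(all(nv2[fe$edges$to] >= ev - 1e-15))
  }
})

test_that("thresholding commutes with the min/max extension", {
  for (s in 1:10) {
    net <- random_network(n = 20, density = 0.25, seed = 100 + s)
    theta <- stats::runif(1)
    # route 1: build field, threshold via combine
    f <- combine_continuous(net,
                            list(continuous_doi(net, "pval", "node", "one_minus")),
                            theta)
    # route 2: threshold native node values first, then extend by hand
    t_node <- 1 - net$nodes$pval
    t_node[is.na(t_node)] <- 0
    t_node[t_node < theta] <- 0
    names(t_node) <- net$nodes$id
    manual_edge <- pmin(t_node[net$edges$from], t_node[net$edges$to])
    expect_equal(f$nodes$doi, unname(t_node))
    expect_equal(f$edges$doi, unname(manual_edge))
  }
})

test_that("visible sets are nested as the threshold grows", {
  for (s in 1:5) {
    net <- random_network(n = 30, density = 0.2, seed = 200 + s)
    fields <- list(continuous_doi(net, "pval", "node", "one_minus"),
                   continuous_doi(net, "abs_correlation", "edge"))
    prev <- NULL
    for (theta in seq(0, 1, by = 0.25)) {
      f <- final_doi(net, cont = combine_continuous(net, fields,
                                                    c(theta, theta), "AND"))
      vis <- f$nodes$id[f$nodes$doi > 0]
      if (!is.null(prev)) expect_true(all(vis %in% prev))
      prev <- vis
    }
  }
})

test_that("every visible edge has two visible endpoints", {
  for (s in 1:20) {
    net <- random_network(n = 25, density = 0.25, seed = 300 + s)
    f <- final_doi(
      net,
      disc = discrete_doi(net, random_source(net, seed = s)),
      cont = combine_continuous(
        net, list(continuous_doi(net, "abs_correlation", "edge")), 0.3)
    )
    sub <- apply_filter(net, f)  # aborts internally on a closure violation
    expect_true(all(sub$edges$from %in% sub$nodes$id))
    expect_true(all(sub$edges$to %in% sub$nodes$id))
  }
})
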