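test_that("build_graph symmetrizes arcs, drops self-loops and keeps their nodes", {
  g <- build_graph(rbind(c("a", "b"), c("b", "a"), c("c", "c")), directed = TRUE)
  expect_equal(g$m, 1L)
  expect_setequal(g$nodes, c("a", "b", "c"))
  expect_length(graph_neighbors(g, "c"), 0)

  # regulatory-network style input: self-regulation arcs contribute no edges
  arcs <- rbind(c("x1", "x2"), c("x2", "x3"), c("x3", "x1"),
                cbind(paste0("s", 1:5), paste0("s", 1:5)))
  gr <- build_graph(arcs, directed = TRUE)
  expect_equal(gr$m, 3L)
  expect_equal(sum(node_degrees(gr) == 0), 5L)
})

test_that("build_graph is edge-order invariant and collapses parallel edges", {
  el <- rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 1), c(2, 3), c(3, 2))
  g1 <- build_graph(el)
  set.seed(11)
  g2 <- build_graph(el[sample(nrow(el)), c(2, 1)])
  expect_identical(g1, g2)
  expect_equal(g1$m, 4L)
  # degree sum identity
  expect_equal(sum(node_degrees(g1)), 2L * g1$m)
})

test_that("build_graph rejects malformed records and missing endpoints", {
  expect_error(build_graph(list(c("a", "b"), c("c"))), "malformed")
  expect_error(build_graph(matrix(letters[1:9], ncol = 3)), "malformed")
  expect_error(build_graph(rbind(c("a", NA))), "non-missing")
})

test_that("connected_components separates components and isolated nodes", {
  g <- build_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                         c("x", "y"), c("y", "z"), c("z", "x")),
                   nodes = "lone")
  cc <- connected_components(g)
  expect_length(cc$components, 2)
  expect_equal(sort(vapply(cc$components, length, 1L)), c(3L, 3L))
  expect_equal(cc$isolated, "lone")

  g2 <- karate_graph()
  cc2 <- connected_components(g2)
  expect_length(cc2$components, 1)
  expect_length(cc2$isolated, 0)
})

test_that("component decomposition matches an independent oracle on a 29+5 layout", {
  # 29 disjoint random connected subgraphs plus 5 degree-0 nodes, the
  # component/isolated structure reported for the E. coli regulatory network
  set.seed(4)
  edges <- NULL
  for (k in 1:29) {
    sz <- sample(2:8, 1)
    labs <- sprintf("c%02d_%d", k, seq_len(sz))
    edges <- rbind(edges, cbind(labs[-sz], labs[-1]))  # spanning path
    if (sz > 3) edges <- rbind(edges, cbind(labs[1], labs[sz]))
  }
  g <- build_graph(edges, nodes = paste0("iso", 1:5))
  cc <- connected_components(g)
  expect_length(cc$components, 29)
  expect_length(cc$isolated, 5)
  # oracle: igraph's component count on the same edge list
  ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
  expect_equal(igraph::components(ig)$no, 29)
  expect_equal(sort(unlist(cc$components)), sort(igraph::V(ig)$name))
})

test_that("shortest_path_length is BFS distance with Inf across components", {
  g <- build_graph(rbind(c("a", "b"), c("b", "c"), c("x", "y")))
  expect_equal(shortest_path_length(g, "a", "c"), 2)
  expect_equal(shortest_path_length(g, "b", "b"), 0)
  expect_equal(shortest_path_length(g, "a", "x"), Inf)
  expect_error(shortest_path_length(g, "a", "nope"), "unknown node")
})

test_that("BFS distances agree with igraph and satisfy the triangle inequality", {
  g <- random_graph(40, 0.12, seed = 7)
  ig <- igraph::graph_from_data_frame(
    do.call(rbind, lapply(seq_along(g$nodes), function(v) {
      nb <- g$adj[[v]]; nb <- nb[nb > v]
      if (length(nb)) data.frame(from = g$nodes[v], to = g$nodes[nb]) else NULL
    })), directed = FALSE, vertices = g$nodes)
  dmat <- igraph::distances(ig)
  set.seed(1)
  for (i in 1:30) {
    uvw <- sample(g$nodes, 3)
    duv <- shortest_path_length(g, uvw[1], uvw[2])
    expect_equal(duv, dmat[uvw[1], uvw[2]])
    dvw <- shortest_path_length(g, uvw[2], uvw[3])
    duw <- shortest_path_length(g, uvw[1], uvw[3])
    expect_true(duw <= duv + dvw)
  }
})

test_that("edge_counts matches brute force and the partition identity", {
  k4 <- rbind(clique_edges(paste0("k", 1:4)), c("k4", "p"))
  g <- build_graph(k4)
  expect_equal(edge_counts(g, paste0("k", 1:4)), c(internal = 6L, external = 1L))
  expect_equal(edge_counts(g, g$nodes), c(internal = g$m, external = 0L))
  expect_equal(edge_counts(g, character(0)), c(internal = 0L, external = 0L))

  g2 <- random_graph(30, 0.15, seed = 3)
  set.seed(5)
  for (i in 1:10) {
    S <- sample(g2$nodes, sample(1:25, 1))
    expect_equal(edge_counts(g2, S), brute_edge_counts(g2, S))
    # internal(S) + external(S) + internal(complement) = m
    comp <- setdiff(g2$nodes, S)
    ec <- edge_counts(g2, S)
    expect_equal(ec[["internal"]] + ec[["external"]] +
                   edge_counts(g2, comp)[["internal"]], g2$m)
  }
})

test_that("edges_between counts cross edges and rejects overlapping sets", {
  tri2 <- rbind(c("a1", "a2"), c("a2", "a3"), c("a3", "a1"),
                c("b1", "b2"), c("b2", "b3"), c("b3", "b1"),
                c("a1", "b1"), c("a2", "b2"))
  g <- build_graph(tri2)
  A <- paste0("a", 1:3); B <- paste0("b", 1:3)
  expect_equal(edges_between(g, A, B), 2L)
  expect_error(edges_between(g, A, c("a1", "b1")), "disjoint")

  gd <- build_graph(rbind(c("a", "b"), c("x", "y")))
  expect_equal(edges_between(gd, c("a", "b"), c("x", "y")), 0L)

  # conservation: summed cross edges over a partition equal external(S)
  g2 <- random_graph(24, 0.2, seed = 9)
  S <- g2$nodes[1:8]
  T1 <- g2$nodes[9:16]; T2 <- g2$nodes[17:24]
  expect_equal(edges_between(g2, S, T1) + edges_between(g2, S, T2),
               edge_counts(g2, S)[["external"]])
})
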