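test_that("seed_candidates caches closed neighbourhoods with exact counts", {
  tri <- build_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  cands <- seed_candidates(tri)
  expect_length(cands, 3)
  for (cd in cands) {
    expect_setequal(cd$members, tri$nodes)
    expect_equal(cd$internal, 3L)
    expect_equal(cd$external, 0L)
  }

  star <- build_graph(cbind("hub", paste0("leaf", 1:4)))
  cands <- seed_candidates(star)
  center <- Filter(function(c) c$anchor == "hub", cands)[[1]]
  expect_setequal(center$members, star$nodes)
  leaf <- Filter(function(c) c$anchor == "leaf1", cands)[[1]]
  expect_setequal(leaf$members, c("leaf1", "hub"))

  # cached counts equal the edge-count primitive on a random graph
  g <- random_graph(30, 0.15, seed = 21)
  for (cd in seed_candidates(g)[1:10]) {
    expect_equal(edge_counts(g, cd$members),
                 c(internal = cd$internal, external = cd$external))
  }
})

test_that("strong seeds are disjoint and recover separated cliques", {
  tri2 <- build_graph(rbind(clique_edges(paste0("a", 1:3)),
                            clique_edges(paste0("b", 1:3))))
  seeds <- extract_strong_seeds(tri2)
  expect_length(seeds, 2)
  expect_setequal(unlist(seeds), tri2$nodes)

  k5 <- build_graph(rbind(clique_edges(paste0("a", 1:5)),
                          clique_edges(paste0("b", 1:5)), c("a1", "b1")))
  seeds <- extract_strong_seeds(k5)
  expect_length(seeds, 2)
  expect_setequal(seeds[[1]], paste0("a", 1:5))
  expect_setequal(seeds[[2]], paste0("b", 1:5))
  expect_length(intersect(seeds[[1]], seeds[[2]]), 0)
  # seeds are strong-sense at extraction time (first seed in the full graph)
  expect_true(is_strong_sense(k5, seeds[[1]]))
})

test_that("cycles are seeded from merged adjacency lists", {
  # no single closed neighbourhood of a 6-cycle is strong (internal 2 =
  # external 2): a seed only exists after merging neighbourhoods
  g6 <- build_graph(cbind(paste0("n", 1:6), paste0("n", c(2:6, 1))))
  for (cd in seed_candidates(g6)) {
    expect_false(is_strong_sense(g6, cd$members))
  }
  seeds <- extract_strong_seeds(g6)
  expect_gte(length(seeds), 1)
  cov <- detect_communities(g6)
  expect_setequal(unlist(lapply(cov$communities, `[[`, "members")), g6$nodes)
})

test_that("growth attaches every remaining node to its best seed", {
  g <- build_graph(rbind(clique_edges(paste0("a", 1:4)),
                         clique_edges(paste0("b", 1:4)),
                         c("a1", "b1"), c("a2", "p")))
  cov <- grow_weak_communities(g, list(paste0("a", 1:4), paste0("b", 1:4)))
  expect_equal(unname(cov$membership[["p"]]),
               unname(cov$membership[["a1"]]))
  expect_length(cov$membership, 9)

  # chain with a single seed at one end: deferred sweeps claim everyone
  chain <- build_graph(cbind(paste0("c", 1:7), paste0("c", 2:8)))
  covc <- grow_weak_communities(chain, list(c("c1", "c2")))
  expect_length(covc$membership, 8)
  expect_equal(unique(unname(covc$membership)), 1L)

  expect_error(grow_weak_communities(g, list(paste0("a", 1:4), c("a1", "b1"))),
               "disjoint")
})

test_that("reassignment is a fixpoint on a correct cover and repairs bad moves", {
  g <- build_graph(rbind(clique_edges(paste0("a", 1:4)),
                         clique_edges(paste0("b", 1:4)), c("a1", "b1")))
  good <- make_cover(g, structure(rep(1:2, each = 4),
                                  names = c(paste0("a", 1:4), paste0("b", 1:4))))
  res <- reassign_to_convergence(g, good)
  expect_true(res$trace$converged)
  expect_equal(res$trace$passes, 1L)
  expect_equal(res$trace$moves_per_pass, 0L)
  expect_equal(res$cover$membership, good$membership)

  bad <- make_cover(g, structure(c(2L, rep(1L, 3), rep(2L, 4)),
                                 names = c(paste0("a", 1:4), paste0("b", 1:4))))
  res2 <- reassign_to_convergence(g, bad)
  expect_true(res2$trace$converged)
  expect_equal(unname(res2$cover$membership[paste0("a", 1:4)]), rep(1L, 4))
})

test_that("reassignment from a random cover satisfies the membership property", {
  g <- build_graph(rbind(clique_edges(paste0("a", 1:6)),
                         clique_edges(paste0("b", 1:6))))
  set.seed(31)
  lab <- structure(sample(1:4, 12, TRUE), names = g$nodes)
  res <- reassign_to_convergence(g, make_cover(g, lab))
  expect_true(res$trace$converged)
  # each clique ends uniformly labeled (exhaustive membership check)
  expect_length(unique(res$cover$membership[paste0("a", 1:6)]), 1)
  expect_length(unique(res$cover$membership[paste0("b", 1:6)]), 1)
  expect_membership_property(g, res$cover)
})

test_that("the karate club splits into the two known factions", {
  g <- karate_graph()
  cov <- detect_communities(g)
  expect_length(cov$communities, 2)
  expect_equal(nmi(cover_labels(cov), karate_truth()), 1)
  expect_true(cov$trace$converged)
})

test_that("disjoint cliques and lone nodes are fully recovered", {
  parts <- lapply(1:4, function(k) clique_edges(sprintf("q%d_%d", k, 1:4)))
  g <- build_graph(do.call(rbind, parts), nodes = c("iso1", "iso2", "iso3"))
  cov <- detect_communities(g)
  expect_length(cov$communities, 4)
  expect_setequal(cov$isolated, c("iso1", "iso2", "iso3"))
  sizes <- vapply(cov$communities, function(c) length(c$members), 1L)
  expect_equal(unname(sizes), rep(4L, 4))
  # no community spans two components
  cc <- connected_components(g)
  for (cm in cov$communities) {
    holders <- vapply(cc$components, function(comp) any(cm$members %in% comp), TRUE)
    expect_equal(sum(holders), 1L)
  }
})

test_that("two cliques sharing a node give two communities and a type-2 overlap", {
  g <- shared_cliques_graph(4)
  cov <- detect_communities(g)
  expect_length(cov$communities, 2)
  expect_equal(cov$overlaps$node, "v")
  expect_equal(cov$overlaps$type, 2L)
})

test_that("three-cluster pattern yields one strong and two weak communities", {
  g <- three_cluster_graph()
  cov <- detect_communities(g)
  expect_length(cov$communities, 3)
  strong <- vapply(cov$communities, `[[`, TRUE, "strong")
  weak <- vapply(cov$communities, `[[`, TRUE, "weak")
  expect_equal(sum(strong), 1L)
  expect_equal(sum(weak), 2L)
  strong_comm <- cov$communities[[which(strong)]]
  expect_setequal(strong_comm$members, paste0("a", 1:4))
})

test_that("detection output is invariant to edge-order permutation", {
  inst <- generate_lfr(lfr_params(), seed = 7)
  g <- inst$graph
  el <- do.call(rbind, lapply(seq_along(g$nodes), function(v) {
    nb <- g$adj[[v]]; nb <- nb[nb > v]
    if (length(nb)) cbind(g$nodes[v], g$nodes[nb]) else NULL
  }))
  c1 <- detect_communities(build_graph(el))
  set.seed(17)
  c2 <- detect_communities(build_graph(el[sample(nrow(el)), c(2, 1)]))
  expect_identical(c1$membership, c2$membership)
  expect_identical(c1$overlaps, c2$overlaps)
})

test_that("every converged cover satisfies the membership property", {
  for (s in c(2, 9)) {
    inst <- generate_lfr(lfr_params(), seed = s)
    cov <- detect_communities(inst$graph)
    expect_true(cov$trace$converged)
    expect_membership_property(inst$graph, cov)
  }
})

test_that("the empty graph yields an empty cover", {
  cov <- detect_communities(build_graph(NULL, nodes = c("x", "y")))
  expect_length(cov$communities, 0)
  expect_setequal(cov$isolated, c("x", "y"))
})
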