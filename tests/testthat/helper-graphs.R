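# Fixture builders shared across the suite. Everything is constructed in
# code; the only files read are the small plain-text karate fixtures.

karate_graph <- function() {
  read_graph_file(system.file("extdata", "karate_edges.tsv", package = "topocomm"))
}

karate_truth <- function() {
  read_membership(system.file("extdata", "karate_groups.tsv", package = "topocomm"))
}

clique_edges <- function(labels) {
  t(utils::combn(labels, 2))
}

# two k-cliques sharing the single node "v" (the canonical type-2 bridge)
shared_cliques_graph <- function(k = 4) {
  a <- c(paste0("a", seq_len(k - 1)), "v")
  b <- c(paste0("b", seq_len(k - 1)), "v")
  build_graph(rbind(clique_edges(a), clique_edges(b)))
}

# mirror-symmetric bridge: two K4s, the middle node "m" holds 2 edges into
# each and sits at distance 1 from both hub sets (the type-1 situation)
barbell_graph <- function() {
  a <- paste0("a", 1:4)
  b <- paste0("b", 1:4)
  build_graph(rbind(clique_edges(a), clique_edges(b),
                    cbind("m", c("a1", "a2", "b1", "b2"))))
}

# three-community graph patterned on the strong/weak illustration: one K4
# community (strong) and two triangles whose internal edge counts equal
# their external counts but exceed their edges to any single neighbour
# community (weak)
three_cluster_graph <- function() {
  a <- paste0("a", 1:4)
  edges <- rbind(
    clique_edges(a),
    c("b1", "b2"), c("b1", "b3"), c("b2", "b3"),
    c("c1", "c2"), c("c1", "c3"), c("c2", "c3"),
    c("b1", "a1"), c("b2", "a2"),      # yellow -> cyan
    c("b3", "c3"),                     # yellow -> orange
    c("c1", "a3"), c("c2", "a4"))      # orange -> cyan
  build_graph(edges)
}

# Erdos-Renyi-style random simple graph with canonical labels
random_graph <- function(n, p, seed) {
  generate_planted_partition(1, n, p_in = p, p_out = 0, seed = seed)$graph
}

# independent per-edge count of internal/external edges of a node set
brute_edge_counts <- function(g, S) {
  internal <- 0L; external <- 0L
  for (v in seq_along(g$nodes)) {
    for (w in g$adj[[v]]) {
      if (w <= v) next
      inS <- c(g$nodes[v] %in% S, g$nodes[w] %in% S)
      if (all(inS)) internal <- internal + 1L
      else if (any(inS)) external <- external + 1L
    }
  }
  c(internal = internal, external = external)
}

# per-edge modularity oracle: Q = (1/2m) sum_vw (A_vw - k_v k_w / 2m) delta
brute_modularity <- function(g, labels) {
  m2 <- 2 * g$m
  deg <- vapply(g$adj, length, 1L)
  q <- 0
  for (v in seq_along(g$nodes)) {
    for (w in seq_along(g$nodes)) {
      if (labels[[g$nodes[v]]] != labels[[g$nodes[w]]]) next
      a_vw <- as.integer(w %in% g$adj[[v]])
      q <- q + a_vw - deg[v] * deg[w] / m2
    }
  }
  q / m2
}

expect_membership_property <- function(g, cover) {
  ov <- cover$overlaps$node
  for (v in names(cover$membership)) {
    if (v %in% ov) next
    counts <- membership_counts(g, v, cover)
    expect_equal(counts[[as.character(cover$membership[[v]])]], max(counts),
                 info = paste("membership property violated at node", v))
  }
}
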