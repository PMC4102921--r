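## Node identifiers are canonicalized to character and ordered with a
## locale-independent radix sort, so graphs built from shuffled input are
## bit-identical. Internally nodes are 1-based indices into `nodes`.

new_tc_graph <- function(nodes, adj, m) {
  structure(list(nodes = nodes, adj = adj, m = m), class = "tc_graph")
}

canonical_sort <- function(x) sort(x, method = "radix")

node_index <- function(g, v) {
  i <- match(as.character(v), g$nodes)
  if (anyNA(i)) {
    stop("unknown node(s): ", paste(as.character(v)[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  i
}

#' Build an undirected simple graph from an edge list
#'
#' Constructs the graph representation used throughout the package: a
#' canonically ordered node vector plus adjacency lists. Self-loops are
#' dropped, parallel edges are collapsed, and directed input is symmetrized,
#' so the result is always a simple undirected graph. The constructor is
#' invariant under permutation of the input edges.
#'
#' @param edges A two-column matrix or data frame (one edge per row), or a
#'   list of length-2 vectors. May be `NULL` for an explicit empty graph.
#' @param directed Logical; if `TRUE` the input rows are arcs and each arc is
#'   symmetrized into an undirected edge.
#' @param nodes Optional additional node identifiers (e.g. isolated nodes
#'   that appear in no edge).
#' @return An object of class `tc_graph` with fields `nodes` (character,
#'   canonical order), `adj` (list of integer neighbour indices) and `m`
#'   (edge count).
#' @examples
#' g <- build_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
#' g$m  # 3
#' @export
build_graph <- function(edges, directed = FALSE, nodes = NULL) {
  if (is.null(edges) || (is.list(edges) && !is.data.frame(edges) && length(edges) == 0L)) {
    ends <- matrix(character(0), ncol = 2L)
  } else if (is.list(edges) && !is.data.frame(edges)) {
    bad <- which(vapply(edges, length, 1L) != 2L)
    if (length(bad)) {
      stop("malformed edge record at position ", bad[1L], ": expected 2 endpoints, got ",
           length(edges[[bad[1L]]]), call. = FALSE)
    }
    ends <- matrix(as.character(unlist(lapply(edges, as.character))),
                   ncol = 2L, byrow = TRUE)
  } else {
    edges <- as.matrix(edges)
    if (length(edges) && ncol(edges) != 2L) {
      stop("malformed edge table: expected 2 columns, got ", ncol(edges), call. = FALSE)
    }
    ends <- matrix(as.character(edges), ncol = 2L)
  }
  if (anyNA(ends) || any(ends == "")) stop("edge endpoints must be non-missing tokens", call. = FALSE)

  all_nodes <- canonical_sort(unique(c(ends, as.character(nodes))))
  keep <- ends[, 1L] != ends[, 2L]           # self-loops contribute no edges,
  ends <- ends[keep, , drop = FALSE]         # but their node still exists
  n <- length(all_nodes)

  if (nrow(ends)) {
    i <- match(ends[, 1L], all_nodes)
    j <- match(ends[, 2L], all_nodes)
    a <- pmin(i, j)
    b <- pmax(i, j)
    key <- unique((a - 1) * n + b)            # collapse parallel edges
    a <- as.integer((key - 1) %/% n) + 1L
    b <- as.integer((key - 1) %% n) + 1L
    adj <- vector("list", n)
    nb <- split(c(b, a), c(a, b))
    adj[as.integer(names(nb))] <- lapply(nb, function(x) sort.int(unique(x)))
    empty <- vapply(adj, is.null, TRUE)
    adj[empty] <- list(integer(0))
    m <- length(key)
  } else {
    adj <- rep(list(integer(0)), n)
    m <- 0L
  }
  new_tc_graph(all_nodes, adj, as.integer(m))
}

#' @export
print.tc_graph <- function(x, ...) {
  cat("tc_graph: ", length(x$nodes), " nodes, ", x$m, " edges\n", sep = "")
  invisible(x)
}

#' Number of nodes in a graph
#' @param g A `tc_graph`.
#' @return Integer node count.
#' @export
node_count <- function(g) length(g$nodes)

#' Node degrees
#' @param g A `tc_graph`.
#' @return Named integer vector of degrees in canonical node order.
#' @export
node_degrees <- function(g) {
  d <- vapply(g$adj, length, 1L)
  names(d) <- g$nodes
  d
}

#' Neighbours of a node
#' @param g A `tc_graph`.
#' @param v A node identifier.
#' @return Character vector of neighbour identifiers.
#' @export
graph_neighbors <- function(g, v) g$nodes[g$adj[[node_index(g, v)]]]

## BFS distances from a single source, over node indices; Inf when
## unreachable. The workhorse behind shortest_path_length and the hub
## distance used in overlap classification.
bfs_distances <- function(g, src) {
  n <- length(g$nodes)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- unique(unlist(g$adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Unweighted shortest-path distance between two nodes
#'
#' Breadth-first-search distance; `Inf` when the nodes lie in different
#' connected components.
#'
#' @param g A `tc_graph`.
#' @param u,v Node identifiers.
#' @return A non-negative integer distance, or `Inf`.
#' @export
shortest_path_length <- function(g, u, v) {
  iu <- node_index(g, u)
  iv <- node_index(g, v)
  if (iu == iv) return(0)
  bfs_distances(g, iu)[iv]
}

#' Connected components and isolated nodes
#'
#' Decomposes a graph into its connected components (size at least 2) and
#' the set of degree-0 nodes, which are reported separately rather than as
#' size-1 components. Components are ordered by decreasing size, ties broken
#' by their smallest member in canonical order, so the decomposition is
#' deterministic.
#'
#' @param g A `tc_graph`.
#' @return An object of class `tc_components`: a list with `components`
#'   (list of character vectors) and `isolated` (character vector).
#' @export
connected_components <- function(g) {
  n <- length(g$nodes)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L || length(g$adj[[s]]) == 0L) next
    cid <- cid + 1L
    comp[s] <- cid
    frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(g$adj[frontier], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  comps <- lapply(seq_len(cid), function(k) g$nodes[comp == k])
  if (cid > 0L) {
    sizes <- vapply(comps, length, 1L)
    first <- vapply(comps, function(x) x[1L], "")   # members already canonical
    comps <- comps[order(-sizes, first, method = "radix")]
  }
  isolated <- g$nodes[vapply(g$adj, length, 1L) == 0L]
  structure(list(components = comps, isolated = isolated), class = "tc_components")
}

#' @export
print.tc_components <- function(x, ...) {
  cat("tc_components: ", length(x$components), " components, ",
      length(x$isolated), " isolated nodes\n", sep = "")
  invisible(x)
}

## index-level edge counting core shared by the exported helpers
edge_counts_idx <- function(g, idx) {
  if (!length(idx)) return(c(internal = 0L, external = 0L))
  inS <- logical(length(g$nodes))
  inS[idx] <- TRUE
  twice_int <- 0L
  incident <- 0L
  for (v in idx) {
    nb <- g$adj[[v]]
    incident <- incident + length(nb)
    twice_int <- twice_int + sum(inS[nb])
  }
  internal <- twice_int %/% 2L
  c(internal = internal, external = incident - twice_int)
}

#' Internal and external edge counts of a node set
#'
#' The counts at the heart of the strong/weak community definitions:
#' internal edges have both endpoints in `S`, external edges exactly one.
#'
#' @param g A `tc_graph`.
#' @param S Character vector of node identifiers (may be empty).
#' @return Named integer vector `c(internal = , external = )`.
#' @export
edge_counts <- function(g, S) {
  if (!length(S)) return(c(internal = 0L, external = 0L))
  edge_counts_idx(g, node_index(g, unique(as.character(S))))
}

#' Number of edges between two disjoint node sets
#'
#' @param g A `tc_graph`.
#' @param S,T Disjoint character vectors of node identifiers.
#' @return Integer count of edges with one endpoint in each set.
#' @export
edges_between <- function(g, S, T) {
  S <- unique(as.character(S)); T <- unique(as.character(T))
  if (length(intersect(S, T))) {
    stop("S and T must be disjoint node sets", call. = FALSE)
  }
  iS <- node_index(g, S)
  iT <- node_index(g, T)
  inT <- logical(length(g$nodes))
  inT[iT] <- TRUE
  sum(vapply(iS, function(v) sum(inT[g$adj[[v]]]), 1L))
}
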