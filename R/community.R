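## Definitional layer: strong/weak-sense community tests, hub members,
## membership counts and the two overlap-node classifiers. A "cover" is the
## output container: a primary community per non-isolated node, community
## member lists (which may include overlap nodes in more than one
## community), overlap records and isolated nodes.

#' Strong-sense community test
#'
#' A node set is a strong-sense community when its internal edge count
#' strictly exceeds its external edge count.
#'
#' @param g A `tc_graph`.
#' @param S Non-empty character vector of node identifiers.
#' @return Logical flag.
#' @export
is_strong_sense <- function(g, S) {
  stopifnot(length(S) > 0L)
  ec <- edge_counts(g, S)
  ec[["internal"]] > ec[["external"]]
}

#' Weak-sense community test
#'
#' A node set is a weak-sense community when its internal edges do not
#' exceed its external edges overall, yet exceed its edges to every single
#' other community. Strong-sense sets are excluded by construction, so the
#' two predicates are mutually exclusive.
#'
#' @param g A `tc_graph`.
#' @param S Non-empty character vector of node identifiers.
#' @param others List of node sets (each disjoint from `S`).
#' @return Logical flag.
#' @export
is_weak_sense <- function(g, S, others) {
  stopifnot(length(S) > 0L)
  ec <- edge_counts(g, S)
  if (ec[["internal"]] > ec[["external"]]) return(FALSE)
  all(vapply(others, function(T) ec[["internal"]] > edges_between(g, S, T), TRUE))
}

#' Hub members of a community
#'
#' Hub members are the community members with the greatest number of
#' neighbours inside the community; all tied maximizers are returned.
#'
#' @param g A `tc_graph`.
#' @param S Non-empty character vector of node identifiers.
#' @return Character vector of hub node identifiers (canonical order).
#' @export
hub_members <- function(g, S) {
  stopifnot(length(S) > 0L)
  idx <- node_index(g, unique(as.character(S)))
  inS <- logical(length(g$nodes))
  inS[idx] <- TRUE
  deg_in <- vapply(idx, function(v) sum(inS[g$adj[[v]]]), 1L)
  canonical_sort(g$nodes[idx[deg_in == max(deg_in)]])
}

## ---- cover ----------------------------------------------------------------

new_cover <- function(membership, communities, overlaps, isolated, trace = NULL) {
  structure(list(membership = membership, communities = communities,
                 overlaps = overlaps, isolated = isolated, trace = trace),
            class = "tc_cover")
}

empty_overlaps <- function() {
  data.frame(node = character(0), type = integer(0),
             community_ids = character(0), stringsAsFactors = FALSE)
}

#' Construct a cover from a primary membership
#'
#' Builds a `tc_cover` from a node-to-community assignment: community member
#' lists, hub members and strong/weak labels (each community is tested
#' against the other communities of its connected component) are derived
#' from the graph. Overlap records start empty; [detect_communities()] fills
#' them after convergence.
#'
#' @param g A `tc_graph`.
#' @param membership Named integer vector mapping every non-isolated node to
#'   a community id.
#' @param trace Optional convergence trace to attach.
#' @return A `tc_cover`.
#' @export
make_cover <- function(g, membership, trace = NULL) {
  isolated <- g$nodes[vapply(g$adj, length, 1L) == 0L]
  need <- setdiff(g$nodes, isolated)
  if (!all(need %in% names(membership))) {
    stop("membership must label every non-isolated node", call. = FALSE)
  }
  membership <- membership[need]
  ids <- sort(unique(membership))
  comp <- connected_components(g)
  comp_of <- integer(0)
  for (k in seq_along(comp$components)) {
    comp_of[comp$components[[k]]] <- k
  }
  communities <- lapply(ids, function(id) {
    members <- canonical_sort(names(membership)[membership == id])
    list(id = id, members = members, hubs = hub_members(g, members),
         strong = NA, weak = NA, component = comp_of[[members[1L]]])
  })
  names(communities) <- as.character(ids)
  for (i in seq_along(communities)) {
    S <- communities[[i]]$members
    others <- lapply(communities[vapply(communities, function(x)
      x$component == communities[[i]]$component && x$id != communities[[i]]$id, TRUE)],
      function(x) x$members)
    communities[[i]]$strong <- is_strong_sense(g, S)
    communities[[i]]$weak <- if (communities[[i]]$strong) FALSE else is_weak_sense(g, S, others)
  }
  new_cover(membership, communities, empty_overlaps(), isolated, trace)
}

#' @export
print.tc_cover <- function(x, ...) {
  sizes <- vapply(x$communities, function(c) length(c$members), 1L)
  cat("tc_cover: ", length(x$communities), " communities (sizes ",
      paste(sizes, collapse = ", "), "), ", nrow(x$overlaps),
      " overlapping nodes, ", length(x$isolated), " isolated\n", sep = "")
  invisible(x)
}

#' Flatten a cover to partition labels
#'
#' Returns the primary community id per node. Isolated nodes are included
#' as fresh singleton communities (the convention used when comparing
#' covers with NMI); set `include_isolated = FALSE` to drop them (the
#' convention for modularity, where degree-0 nodes carry no edges).
#'
#' @param cover A `tc_cover`.
#' @param include_isolated Logical.
#' @return Named integer vector of community labels.
#' @export
cover_labels <- function(cover, include_isolated = TRUE) {
  lab <- cover$membership
  if (include_isolated && length(cover$isolated)) {
    extra <- seq_along(cover$isolated) + max(c(0L, lab))
    names(extra) <- cover$isolated
    lab <- c(lab, extra)
  }
  lab
}

community_members <- function(cover, id) {
  cover$communities[[as.character(id)]]$members
}

primary_members <- function(cover, id) {
  names(cover$membership)[cover$membership == id]
}

## ---- membership + overlap classification ----------------------------------

#' Neighbour counts per community
#'
#' Counts a node's neighbours by their primary community — the quantity the
#' membership property is stated in: a node should sit in the community
#' holding the maximum of these counts unless it is an overlapping node.
#'
#' @param g A `tc_graph`.
#' @param v A non-isolated node identifier.
#' @param cover A `tc_cover`.
#' @return Named integer vector (names are community ids, only communities
#'   with at least one neighbour appear); sums to `degree(v)`.
#' @export
membership_counts <- function(g, v, cover) {
  nb <- graph_neighbors(g, v)
  if (!length(nb)) stop("membership_counts is undefined for isolated nodes", call. = FALSE)
  tab <- table(cover$membership[nb])
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(as.integer(names(counts)))]
}

## minimum BFS distance from v to any hub of each community in `ids`
hub_distances <- function(g, v, cover, ids) {
  dist <- bfs_distances(g, node_index(g, v))
  vapply(ids, function(id) {
    hubs <- cover$communities[[as.character(id)]]$hubs
    min(dist[node_index(g, hubs)])
  }, numeric(1))
}

overlap_record <- function(node, type, ids) {
  list(node = node, type = type, community_ids = sort(as.integer(ids)))
}

#' Classify a node as a type-1 overlapping node
#'
#' A type-1 overlap requires two equalities: at least two communities tie
#' for the node's maximum neighbour count, and the node's shortest-path
#' distance to the hub members of every tied community (minimum over each
#' community's hub set) is identical. Nodes failing the distance equality —
#' like nodes 3 and 10 of the karate club, which tie in neighbour counts
#' but sit at different distances from the two hubs — are not overlapping.
#'
#' @param g A `tc_graph`.
#' @param v A non-isolated node identifier.
#' @param cover A `tc_cover`.
#' @return A record `list(node, type = 1, community_ids)` or `NULL`.
#' @export
classify_type1 <- function(g, v, cover) {
  counts <- membership_counts(g, v, cover)
  tied <- names(counts)[counts == max(counts)]
  if (length(tied) < 2L) return(NULL)
  d <- hub_distances(g, v, cover, tied)
  if (all(is.finite(d)) && length(unique(d)) == 1L) {
    overlap_record(v, 1L, tied)
  } else {
    NULL
  }
}

#' Classify a node as a type-2 overlapping node
#'
#' A type-2 overlap is a bridge: the node is tightly attached (at least 2
#' edges) to two communities that would share few direct edges without it —
#' operationalized as the residual edge count between the two communities
#' (node removed) being strictly below the node's smaller attachment count.
#' Community pairs are scanned in increasing id order and the first
#' qualifying pair is reported.
#'
#' @param g A `tc_graph`.
#' @param v A non-isolated node identifier.
#' @param cover A `tc_cover`.
#' @return A record `list(node, type = 2, community_ids)` or `NULL`.
#' @export
classify_type2 <- function(g, v, cover) {
  counts <- membership_counts(g, v, cover)
  cand <- names(counts)[counts >= 2L]
  if (length(cand) < 2L) return(NULL)
  cand <- cand[order(as.integer(cand))]
  for (i in seq_len(length(cand) - 1L)) {
    for (j in seq(i + 1L, length(cand))) {
      A <- setdiff(primary_members(cover, cand[i]), v)
      B <- setdiff(primary_members(cover, cand[j]), v)
      if (!length(A) || !length(B)) next
      between <- edges_between(g, A, B)
      if (between < min(counts[[cand[i]]], counts[[cand[j]]])) {
        return(overlap_record(v, 2L, c(cand[i], cand[j])))
      }
    }
  }
  NULL
}
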