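## Partition-comparison metrics: Shannon entropy of a labeling, normalized
## mutual information between two labelings, and Newman modularity from the
## community mixing matrix.

as_labels <- function(x) {
  if (inherits(x, "tc_cover")) x <- cover_labels(x)
  if (is.null(names(x)) || !length(x)) stop("labels must be a non-empty named vector", call. = FALSE)
  x
}

#' Entropy of a community labeling
#'
#' Shannon entropy (base 2) of the community-size distribution; 0 when all
#' nodes share one community.
#'
#' @param labels Named vector mapping nodes to community ids, or a `tc_cover`.
#' @return Entropy in bits.
#' @export
partition_entropy <- function(labels) {
  labels <- as_labels(labels)
  p <- as.numeric(table(labels)) / length(labels)
  -sum(p * log2(p))
}

#' Normalized mutual information between two labelings
#'
#' `NMI = 2 (H(X) + H(Y) - H(X,Y)) / (H(X) + H(Y))`, with entropies in bits
#' over the community-size distributions. Equals 1 for identical partitions
#' (up to relabeling), tends to 0 for independent ones, and is symmetric in
#' its arguments. When both labelings are a single community (zero entropy)
#' the convention is 1 if they are identical as partitions, else 0.
#'
#' @param X,Y Named vectors over the same node set (or `tc_cover`s; covers
#'   are flattened to primary labels with isolated nodes as singletons).
#' @return A value in `[0, 1]`.
#' @export
nmi <- function(X, Y) {
  X <- as_labels(X)
  Y <- as_labels(Y)
  if (length(X) != length(Y) || !setequal(names(X), names(Y))) {
    stop("labelings must cover the same node set", call. = FALSE)
  }
  Y <- Y[names(X)]
  n <- length(X)
  hx <- partition_entropy(X)
  hy <- partition_entropy(Y)
  joint <- as.numeric(table(paste(X, Y, sep = "\r"))) / n
  hxy <- -sum(joint * log2(joint))
  if (hx + hy == 0) {
    return(if (hxy == 0) 1 else 0)
  }
  i <- hx + hy - hxy
  val <- 2 * i / (hx + hy)
  min(max(val, 0), 1)
}

#' Community mixing matrix
#'
#' Fractions of edge endpoints between communities: diagonal entries are the
#' fraction of edges internal to each community, off-diagonal entries split
#' each between-community edge symmetrically, so the matrix sums to 1 and
#' its row sums `a_i` are the fractions of edge ends attached to each
#' community.
#'
#' @param g A `tc_graph`.
#' @param labels Named vector over all non-isolated nodes.
#' @return List with `e` (k x k symmetric matrix) and `a` (row sums).
#' @export
mixing_matrix <- function(g, labels) {
  labels <- as_labels(labels)
  need <- g$nodes[vapply(g$adj, length, 1L) > 0L]
  if (!all(need %in% names(labels))) {
    stop("every non-isolated node needs a community label", call. = FALSE)
  }
  ids <- sort(unique(as.vector(labels[need])))
  k <- length(ids)
  e <- matrix(0, k, k, dimnames = list(ids, ids))
  lab_of <- labels[g$nodes]
  for (v in seq_along(g$nodes)) {
    nb <- g$adj[[v]]
    nb <- nb[nb > v]            # each edge visited once
    if (!length(nb)) next
    cv <- as.character(lab_of[[v]])
    for (w in nb) {
      cw <- as.character(lab_of[[w]])
      if (cv == cw) {
        e[cv, cw] <- e[cv, cw] + 1
      } else {
        e[cv, cw] <- e[cv, cw] + 0.5
        e[cw, cv] <- e[cw, cv] + 0.5
      }
    }
  }
  e <- e / g$m
  list(e = e, a = rowSums(e))
}

#' Newman modularity of a partition
#'
#' `Q = sum_i (e_ii - a_i^2)` over the mixing matrix of the partition:
#' within-community edge fractions compared against the random expectation
#' from the community degree fractions. Isolated nodes carry no edges and
#' are excluded.
#'
#' @param g A `tc_graph` with at least one edge.
#' @param labels Named vector over all non-isolated nodes, or a `tc_cover`.
#' @return Modularity Q.
#' @export
modularity_q <- function(g, labels) {
  if (inherits(labels, "tc_cover")) labels <- cover_labels(labels, include_isolated = FALSE)
  if (g$m == 0L) stop("modularity is undefined for an edgeless graph", call. = FALSE)
  mm <- mixing_matrix(g, labels)
  sum(diag(mm$e) - mm$a^2)
}
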