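## The detection pipeline, run independently on every connected component:
##   1. initialize candidate seeds from the closed neighbourhood of each node,
##   2. extract disjoint strong-sense seeds by iterative peeling,
##   3. grow weak-sense communities by attaching the remaining nodes to the
##      seed community holding most of their neighbours,
##   4. reassign nodes asynchronously until the membership property holds.
## Overlap classification runs once, on the converged cover. Every step is
## deterministic: node order is canonical, all ties have explicit rules, and
## no randomness is used anywhere.

#' Seed candidates: closed neighbourhoods with cached edge counts
#'
#' One candidate per non-isolated node, in canonical node order: the node
#' (anchor) together with its neighbours, plus the internal/external edge
#' counts of that set.
#'
#' @param g A `tc_graph`.
#' @return List of records `list(anchor, members, internal, external)`.
#' @export
seed_candidates <- function(g) {
  out <- list()
  for (v in seq_along(g$nodes)) {
    if (!length(g$adj[[v]])) next
    idx <- c(v, g$adj[[v]])
    ec <- edge_counts_idx(g, idx)
    out[[length(out) + 1L]] <- list(anchor = g$nodes[v],
                                    members = g$nodes[sort.int(idx)],
                                    internal = ec[["internal"]],
                                    external = ec[["external"]])
  }
  out
}

## Candidate statistics restricted to the residual (unclaimed) subgraph.
## For each live anchor u: members = closed neighbourhood of u within U,
## internal/external counted in the subgraph induced by U.
residual_candidates <- function(g, U) {
  live <- which(U)
  cand <- vector("list", length(live))
  keep <- logical(length(live))
  for (k in seq_along(live)) {
    u <- live[k]
    nb <- g$adj[[u]]
    nb <- nb[U[nb]]
    if (!length(nb)) next
    S <- c(u, nb)
    inS <- logical(length(g$nodes))
    inS[S] <- TRUE
    twice_int <- 0L
    ext <- 0L
    for (v in S) {
      av <- g$adj[[v]]
      av <- av[U[av]]
      twice_int <- twice_int + sum(inS[av])
      ext <- ext + sum(!inS[av])
    }
    cand[[k]] <- list(anchor = u, members = sort.int(S),
                      internal = twice_int %/% 2L, external = ext)
    keep[k] <- TRUE
  }
  cand[keep]
}

## membership-property trim of a candidate seed: repeatedly drop members
## (never the anchor) with strictly more neighbours outside the set than
## inside, counted in the full graph; removal is synchronous per round so
## the result is order-free
trim_candidate <- function(g, S, anchor) {
  n <- length(g$nodes)
  repeat {
    inS <- logical(n)
    inS[S] <- TRUE
    drop <- S[vapply(S, function(v) {
      if (v == anchor) return(FALSE)
      nb <- g$adj[[v]]
      sum(inS[nb]) < sum(!inS[nb])
    }, TRUE)]
    if (!length(drop)) return(S)
    S <- setdiff(S, drop)
  }
}

## internal/external counts of S within the residual subgraph induced by U
residual_strength <- function(g, S, U) {
  inS <- logical(length(g$nodes))
  inS[S] <- TRUE
  twice_int <- 0L
  ext <- 0L
  for (v in S) {
    av <- g$adj[[v]]
    av <- av[U[av]]
    twice_int <- twice_int + sum(inS[av])
    ext <- ext + sum(!inS[av])
  }
  c(internal = twice_int %/% 2L, external = ext)
}

## greedy expansion of a candidate within the residual graph: while the set
## is not strong-sense, absorb the unclaimed node with the most neighbours
## inside it (ties: smallest index) — the merged-adjacency-list search that
## lets sparse communities, whose single closed neighbourhoods are never
## strong, still produce a strong seed
expand_to_strong <- function(g, S, U) {
  n <- length(g$nodes)
  inS <- logical(n)
  inS[S] <- TRUE
  repeat {
    rs <- residual_strength(g, S, U)
    if (rs[["internal"]] > rs[["external"]]) return(S)
    att <- integer(n)
    for (v in S) {
      nb <- g$adj[[v]]
      nb <- nb[U[nb] & !inS[nb]]
      att[nb] <- att[nb] + 1L
    }
    if (!any(att > 0L)) return(S)
    w <- which.max(att)
    S <- c(S, w)
    inS[w] <- TRUE
  }
}

## absorb the single best-attached unclaimed node, or NULL when none exists
expand_step <- function(g, S, U) {
  att <- integer(length(g$nodes))
  inS <- logical(length(g$nodes))
  inS[S] <- TRUE
  for (v in S) {
    nb <- g$adj[[v]]
    nb <- nb[U[nb] & !inS[nb]]
    att[nb] <- att[nb] + 1L
  }
  if (!any(att > 0L)) return(NULL)
  c(S, which.max(att))
}

## Iterative peeling with a minimality filter, greedy expansion and a
## membership trim (see vignette): per round, strong candidates that
## strictly contain another strong candidate are ineligible; candidates are
## ranked by (internal - external) desc, internal desc, anchor asc; the best
## one is expanded until strong on the residual graph, trimmed by the
## membership property (drop members with more neighbours outside than
## inside) and, if still strong with at least 2 members, peeled off; the
## round then repeats on the remaining nodes.
extract_seeds_idx <- function(g, comp_idx) {
  n <- length(g$nodes)
  U <- logical(n)
  U[comp_idx] <- TRUE
  seeds <- list()
  repeat {
    first_round <- length(seeds) == 0L
    cand <- residual_candidates(g, U)
    if (!length(cand)) break
    is_str <- vapply(cand, function(c) length(c$members) >= 2L && c$internal > c$external, TRUE)
    strong <- cand[is_str]
    rest <- cand[!is_str]
    if (!length(strong)) {
      ## no closed neighbourhood is strong on its own (sparse communities):
      ## every candidate goes through greedy expansion instead
      strong <- cand
      rest <- list()
    }
    anchors <- vapply(strong, `[[`, 1L, "anchor")
    sizes <- vapply(strong, function(c) length(c$members), 1L)
    is_strong_anchor <- logical(n)
    is_strong_anchor[anchors] <- TRUE
    size_of <- integer(n)
    size_of[anchors] <- sizes
    members_of <- vector("list", n)
    members_of[anchors] <- lapply(strong, `[[`, "members")
    eligible <- vapply(strong, function(c) {
      inS <- logical(n); inS[c$members] <- TRUE
      for (w in c$members) {
        if (w == c$anchor || !is_strong_anchor[w]) next
        if (size_of[w] < length(c$members) && all(inS[members_of[[w]]])) return(FALSE)
      }
      TRUE
    }, TRUE)
    sort_excess <- function(cs) {
      excess <- vapply(cs, function(c) c$internal - c$external, 1L)
      internal <- vapply(cs, `[[`, 1L, "internal")
      anchor <- vapply(cs, `[[`, 1L, "anchor")
      cs[order(-excess, -internal, anchor)]
    }
    ## candidates that must be grown before they can be strong are ranked
    ## by neighbourhood density: a bridge node's neighbourhood spans two
    ## communities that barely interlink, so it ranks below any anchor
    ## whose neighbourhood lies inside one community
    sort_density <- function(cs) {
      dens <- vapply(cs, function(c) {
        s <- length(c$members)
        c$internal / max(1, s * (s - 1) / 2)
      }, numeric(1))
      excess <- vapply(cs, function(c) c$internal - c$external, 1L)
      anchor <- vapply(cs, `[[`, 1L, "anchor")
      cs[order(-dens, -excess, anchor)]
    }
    ## first round: the component is intact and high-excess candidates are
    ## the global hubs' neighbourhoods - the most reliable seeds. In later
    ## rounds the residual frame inflates the excess of large mixed
    ## left-over sets, so neighbourhood density is the safer ranking.
    pool <- if (first_round) sort_excess(strong[eligible]) else sort_density(strong[eligible])
    ## strong candidates are tried first; if none yields a seed, the
    ## remaining candidates are tried through the expansion path
    if (length(rest)) pool <- c(pool, sort_density(rest))
    accepted <- FALSE
    for (cand_i in pool) {
      ## expand until strong, then trim; if the trimmed core is not itself a
      ## strong set, expand one node further and retry, so that sparse
      ## communities stabilize instead of being rejected outright
      S <- cand_i$members
      found <- NULL
      repeat {
        S <- expand_to_strong(g, S, U)
        rs <- residual_strength(g, S, U)
        if (rs[["internal"]] <= rs[["external"]]) break
        S2 <- trim_candidate(g, S, cand_i$anchor)
        if (length(S2) >= 2L) {
          rs2 <- residual_strength(g, S2, U)
          if (rs2[["internal"]] > rs2[["external"]]) { found <- S2; break }
        }
        S <- expand_step(g, S, U)
        if (is.null(S)) break
      }
      if (!is.null(found)) {
        seeds[[length(seeds) + 1L]] <- sort.int(found)
        U[found] <- FALSE
        accepted <- TRUE
        break
      }
    }
    if (!accepted || !any(U)) break
  }
  if (!length(seeds)) {
    ## component admits no strong seed (e.g. a cycle): fall back to the
    ## single best candidate under the same ordering
    cand <- residual_candidates(g, U)
    excess <- vapply(cand, function(c) c$internal - c$external, 1L)
    internal <- vapply(cand, `[[`, 1L, "internal")
    anchor <- vapply(cand, `[[`, 1L, "anchor")
    best <- cand[[order(-excess, -internal, anchor)[1L]]]
    seeds <- list(best$members)
    attr(seeds, "fallback") <- TRUE
  }
  seeds
}

#' Extract disjoint strong-sense seed communities
#'
#' Runs the peeling extraction per connected component over the anchors of
#' the supplied candidates. Each returned set is strong-sense at extraction
#' time, except the declared fallback seed taken when a component (such as a
#' cycle) admits no strong candidate at all.
#'
#' @param g A `tc_graph`.
#' @param candidates Candidate list from [seed_candidates()].
#' @return List of character vectors (pairwise disjoint node sets). The
#'   attribute `"fallback"` holds the indices of fallback seeds, if any.
#' @export
extract_strong_seeds <- function(g, candidates = seed_candidates(g)) {
  anchors <- node_index(g, vapply(candidates, `[[`, "", "anchor"))
  comp <- connected_components(g)
  seeds <- list()
  fallback <- integer(0)
  for (cc in comp$components) {
    idx <- node_index(g, cc)
    idx <- idx[idx %in% anchors]
    if (!length(idx)) next
    s <- extract_seeds_idx(g, idx)
    if (isTRUE(attr(s, "fallback"))) fallback <- c(fallback, length(seeds) + 1L)
    seeds <- c(seeds, lapply(s, function(i) g$nodes[i]))
  }
  attr(seeds, "fallback") <- fallback
  seeds
}

## ---- growth ---------------------------------------------------------------

## hubs (indices) of community `id` under an index-space membership vector
hubs_idx <- function(g, membership, id) {
  members <- which(membership == id)
  inS <- logical(length(g$nodes))
  inS[members] <- TRUE
  deg_in <- vapply(members, function(v) sum(inS[g$adj[[v]]]), 1L)
  members[deg_in == max(deg_in)]
}

## nearest-hub then smallest-id tie break among community ids `tied`
break_tie <- function(g, membership, v, tied) {
  if (length(tied) == 1L) return(tied)
  dist <- bfs_distances(g, v)
  hd <- vapply(tied, function(id) min(dist[hubs_idx(g, membership, id)]), numeric(1))
  tied[hd == min(hd)][1L]   # tied ids are in increasing order
}

grow_idx <- function(g, membership, comp_idx) {
  unassigned <- comp_idx[membership[comp_idx] == 0L]
  while (length(unassigned)) {
    progressed <- FALSE
    deferred <- integer(0)
    for (v in unassigned) {
      nbm <- membership[g$adj[[v]]]
      nbm <- nbm[nbm > 0L]
      if (!length(nbm)) { deferred <- c(deferred, v); next }
      counts <- tabulate(nbm)
      tied <- which(counts == max(counts))
      membership[v] <- break_tie(g, membership, v, tied)
      progressed <- TRUE
    }
    if (!progressed) stop("growth stalled: seeds do not reach every node of the component", call. = FALSE)
    unassigned <- deferred
  }
  membership
}

#' Grow weak-sense communities around strong seeds
#'
#' Every non-isolated node outside the seeds joins the seed community
#' holding the maximum number of its neighbours (ties: nearest hub, then
#' smallest community id). Nodes with no edge into any seeded community yet
#' are deferred and re-swept after their neighbours have been claimed, so
#' the cover always spans the seeded components.
#'
#' @param g A `tc_graph`.
#' @param seeds List of disjoint node sets, each within one component; every
#'   non-singleton component must contain at least one seed.
#' @return A `tc_cover` spanning all non-isolated nodes.
#' @export
grow_weak_communities <- function(g, seeds) {
  n <- length(g$nodes)
  membership <- integer(n)
  for (i in seq_along(seeds)) {
    idx <- node_index(g, seeds[[i]])
    if (any(membership[idx] != 0L)) stop("seeds must be pairwise disjoint", call. = FALSE)
    membership[idx] <- i
  }
  comp <- connected_components(g)
  for (cc in comp$components) {
    idx <- node_index(g, cc)
    if (!any(membership[idx] > 0L)) {
      stop("component containing node ", cc[1L], " has no seed", call. = FALSE)
    }
    membership <- grow_idx(g, membership, idx)
  }
  lab <- membership[membership > 0L]
  names(lab) <- g$nodes[membership > 0L]
  make_cover(g, lab)
}

## ---- iterative reassignment ----------------------------------------------

reassign_idx <- function(g, membership, comp_idx, max_passes = 100L) {
  moves_per_pass <- integer(0)
  converged <- FALSE
  for (pass in seq_len(max_passes)) {
    moves <- 0L
    for (v in comp_idx) {
      nbm <- membership[g$adj[[v]]]
      nbm <- nbm[nbm > 0L]
      if (!length(nbm)) next
      counts <- tabulate(nbm)
      tied <- which(counts == max(counts))
      winner <- break_tie(g, membership, v, tied)
      if (winner != membership[v]) {
        membership[v] <- winner
        moves <- moves + 1L
      }
    }
    moves_per_pass <- c(moves_per_pass, moves)
    if (moves == 0L) { converged <- TRUE; break }
  }
  list(membership = membership,
       trace = list(passes = length(moves_per_pass),
                    moves_per_pass = moves_per_pass, converged = converged))
}

#' Iteratively reassign nodes until the membership property holds
#'
#' Asynchronous sweeps in canonical node order: each node moves to the
#' community holding the maximum number of its neighbours (ties: nearest
#' hub, then smallest community id). Stops when a full pass makes no move,
#' or after 100 passes (flagged in the trace). Emptied communities are
#' deleted and ids compacted.
#'
#' @param g A `tc_graph`.
#' @param cover A `tc_cover` spanning all non-isolated nodes.
#' @param max_passes Pass cap (default 100).
#' @return List with elements `cover` (converged `tc_cover`) and `trace`
#'   (`passes`, `moves_per_pass`, `converged`).
#' @export
reassign_to_convergence <- function(g, cover, max_passes = 100L) {
  n <- length(g$nodes)
  membership <- integer(n)
  membership[node_index(g, names(cover$membership))] <- cover$membership
  comp <- connected_components(g)
  traces <- list()
  for (cc in comp$components) {
    res <- reassign_idx(g, membership, node_index(g, cc), max_passes)
    membership <- res$membership
    traces[[length(traces) + 1L]] <- res$trace
  }
  passes <- max(c(0L, vapply(traces, `[[`, 1L, "passes")))
  moves <- integer(passes)
  for (tr in traces) {
    mp <- tr$moves_per_pass
    if (length(mp)) moves[seq_along(mp)] <- moves[seq_along(mp)] + mp
  }
  trace <- list(passes = passes, moves_per_pass = moves,
                converged = all(vapply(traces, `[[`, TRUE, "converged")))
  ## delete emptied communities: compact ids in order of first appearance
  keep <- sort(unique(membership[membership > 0L]))
  membership[membership > 0L] <- match(membership[membership > 0L], keep)
  lab <- membership[membership > 0L]
  names(lab) <- g$nodes[membership > 0L]
  list(cover = make_cover(g, lab, trace = trace), trace = trace)
}

## ---- full pipeline --------------------------------------------------------

#' Detect communities from network topology
#'
#' The full deterministic pipeline: per connected component, strong-sense
#' seeds are extracted from node neighbourhoods, weak-sense communities are
#' grown around them, and nodes are iteratively reassigned until every
#' non-overlapping node satisfies the membership property. Overlapping
#' nodes are then classified (type 1 tested before type 2; a node carries at
#' most one record) and added to the member lists of the communities they
#' bridge. Isolated (degree-0) nodes are reported separately. Community ids
#' are assigned in order of (component, size descending, smallest member).
#'
#' @param g A `tc_graph`.
#' @return A `tc_cover` with communities, primary membership, overlap
#'   records, isolated nodes and a convergence trace.
#' @examples
#' g <- build_graph(rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6), c(6, 4)))
#' detect_communities(g)
#' @export
detect_communities <- function(g) {
  n <- length(g$nodes)
  comp <- connected_components(g)
  if (!length(comp$components)) {
    return(new_cover(structure(integer(0), names = character(0)),
                     structure(list(), names = character(0)),
                     empty_overlaps(), comp$isolated,
                     trace = list(passes = 0L, moves_per_pass = integer(0), converged = TRUE)))
  }
  membership <- integer(n)
  traces <- list()
  next_id <- 0L
  for (cc in comp$components) {
    idx <- node_index(g, cc)
    seeds <- extract_seeds_idx(g, idx)
    local <- integer(n)
    for (i in seq_along(seeds)) local[seeds[[i]]] <- i
    local <- grow_idx(g, local, idx)
    res <- reassign_idx(g, local, idx)
    local <- res$membership
    traces[[length(traces) + 1L]] <- res$trace
    ## component-local ids -> global ids ordered by (size desc, smallest member)
    ids <- sort(unique(local[idx]))
    sizes <- vapply(ids, function(id) sum(local[idx] == id), 1L)
    firsts <- vapply(ids, function(id) min(idx[local[idx] == id]), 1L)
    ids <- ids[order(-sizes, firsts)]
    for (i in seq_along(ids)) {
      membership[idx[local[idx] == ids[i]]] <- next_id + i
    }
    next_id <- next_id + length(ids)
  }
  passes <- max(vapply(traces, `[[`, 1L, "passes"))
  moves <- integer(passes)
  for (tr in traces) {
    mp <- tr$moves_per_pass
    if (length(mp)) moves[seq_along(mp)] <- moves[seq_along(mp)] + mp
  }
  trace <- list(passes = passes, moves_per_pass = moves,
                converged = all(vapply(traces, `[[`, TRUE, "converged")))
  lab <- membership[membership > 0L]
  names(lab) <- g$nodes[membership > 0L]
  cover <- make_cover(g, lab, trace = trace)

  ## overlap classification on the converged cover: type 1 first, one
  ## record per node; overlap nodes join the member lists of the
  ## communities they bridge
  records <- list()
  for (v in names(cover$membership)) {
    r <- classify_type1(g, v, cover)
    if (is.null(r)) r <- classify_type2(g, v, cover)
    if (!is.null(r)) records[[length(records) + 1L]] <- r
  }
  if (length(records)) {
    cover$overlaps <- data.frame(
      node = vapply(records, `[[`, "", "node"),
      type = vapply(records, `[[`, 1L, "type"),
      community_ids = vapply(records, function(r) paste(r$community_ids, collapse = ","), ""),
      stringsAsFactors = FALSE)
    for (r in records) {
      for (id in r$community_ids) {
        key <- as.character(id)
        cover$communities[[key]]$members <-
          canonical_sort(unique(c(cover$communities[[key]]$members, r$node)))
      }
    }
  }
  cover
}
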