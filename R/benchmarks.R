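## Synthetic benchmark generators with planted ground truth. All randomness
## flows from one explicit seed per call; the caller's RNG state is saved
## and restored, so generation never perturbs global state and identical
## (seed, params) yield bit-identical instances.

with_seed <- function(seed, f) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  f()
}

new_benchmark <- function(graph, membership, overlaps, params, seed) {
  structure(list(graph = graph,
                 truth = list(membership = membership, overlaps = overlaps),
                 params = params, seed = as.integer(seed)),
            class = "tc_benchmark")
}

#' @export
print.tc_benchmark <- function(x, ...) {
  cat("tc_benchmark: ", length(x$graph$nodes), " nodes, ", x$graph$m,
      " edges, ", length(unique(x$truth$membership)), " planted communities\n", sep = "")
  invisible(x)
}

#' Planted-partition benchmark graph
#'
#' `l` groups of `size` nodes each; every within-group node pair is linked
#' independently with probability `p_in`, every between-group pair with
#' `p_out`. The planted groups are the ground truth.
#'
#' @param l Number of groups.
#' @param size Nodes per group.
#' @param p_in,p_out Edge probabilities in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical instances.
#' @return A `tc_benchmark`: `graph`, `truth` (named membership vector plus
#'   an empty overlap table) and the generator `params`.
#' @export
generate_planted_partition <- function(l, size, p_in, p_out, seed) {
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stop("p_in and p_out must be probabilities in [0, 1]", call. = FALSE)
  }
  if (l * size < 2) stop("need at least 2 nodes", call. = FALSE)
  n <- l * size
  width <- nchar(as.character(n))
  nodes <- sprintf("n%0*d", width, seq_len(n))
  group <- rep(seq_len(l), each = size)
  with_seed(seed, function() {
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L) + i
    p <- ifelse(group[i] == group[j], p_in, p_out)
    keep <- stats::runif(length(p)) < p
    g <- build_graph(cbind(nodes[i[keep]], nodes[j[keep]]), nodes = nodes)
    membership <- group
    names(membership) <- nodes
    new_benchmark(g, membership, empty_overlaps(),
                  list(l = l, size = size, p_in = p_in, p_out = p_out), seed)
  })
}

#' LFR generator parameters
#'
#' Defaults reproduce the benchmark configuration analysed in the package's
#' acceptance suite: 128 nodes, average degree 9.328, maximum degree 30,
#' mixing parameter 0.1, community sizes between 10 and 30, and 10
#' overlapping nodes holding 2 memberships each. Degree and community-size
#' exponents default to the canonical values 2 and 1.
#'
#' @param n Number of nodes.
#' @param avg_k,max_k Average and maximum degree.
#' @param mu Mixing parameter in `[0, 1]`: the fraction of each node's edges
#'   that leave its planted community.
#' @param min_c,max_c Community-size bounds.
#' @param on Number of overlapping nodes.
#' @param om Memberships per overlapping node.
#' @param tau1,tau2 Power-law exponents of the degree and community-size
#'   distributions.
#' @return A list of validated parameters.
#' @export
lfr_params <- function(n = 128, avg_k = 9.328, max_k = 30, mu = 0.1,
                       min_c = 10, max_c = 30, on = 10, om = 2,
                       tau1 = 2, tau2 = 1) {
  stopifnot(min_c <= max_c, max_c <= n, avg_k <= max_k, on <= n,
            mu >= 0, mu <= 1, om >= 1, n >= 2)
  list(n = as.integer(n), avg_k = avg_k, max_k = as.integer(max_k), mu = mu,
       min_c = as.integer(min_c), max_c = as.integer(max_c),
       on = as.integer(on), om = as.integer(om), tau1 = tau1, tau2 = tau2)
}

## mean of a continuous power law with density ~ x^-tau on [a, b]
powerlaw_mean <- function(a, b, tau) {
  norm <- if (tau == 1) log(b / a) else (b^(1 - tau) - a^(1 - tau)) / (1 - tau)
  num <- if (tau == 2) log(b / a) else (b^(2 - tau) - a^(2 - tau)) / (2 - tau)
  num / norm
}

## inverse-CDF sampling of the same distribution
powerlaw_sample <- function(nsamp, a, b, tau) {
  u <- stats::runif(nsamp)
  if (tau == 1) {
    a * (b / a)^u
  } else {
    (a^(1 - tau) + u * (b^(1 - tau) - a^(1 - tau)))^(1 / (1 - tau))
  }
}

## power-law degree sequence with exact total round(n * avg_k) (made even),
## corrected by adjusting highest-degree nodes
lfr_degrees <- function(p) {
  kmin <- if (powerlaw_mean(1, p$max_k, p$tau1) >= p$avg_k) 1 else {
    stats::uniroot(function(a) powerlaw_mean(a, p$max_k, p$tau1) - p$avg_k,
                   lower = 1, upper = p$max_k - 1e-9, tol = 1e-10)$root
  }
  k <- round(powerlaw_sample(p$n, kmin, p$max_k, p$tau1))
  k <- pmin(pmax(k, 1L), p$max_k)
  target <- round(p$n * p$avg_k)
  if (target %% 2 == 1) target <- target + 1
  ## correct the total one unit per node, sweeping the highest-degree nodes,
  ## so no single node is dragged to the cap
  while (sum(k) != target) {
    if (sum(k) < target) {
      cand <- order(-k)
      cand <- cand[k[cand] < p$max_k]
      take <- min(length(cand), target - sum(k))
      k[cand[seq_len(take)]] <- k[cand[seq_len(take)]] + 1L
    } else {
      cand <- order(-k)
      cand <- cand[k[cand] > 1L]
      take <- min(length(cand), sum(k) - target)
      k[cand[seq_len(take)]] <- k[cand[seq_len(take)]] - 1L
    }
  }
  as.integer(k)
}

## power-law community sizes fitted to sum exactly to `total`. The number
## of communities is derived from the parameterization (total memberships
## over the expected community size under the truncated power law), so a
## fixed parameter set always plants the same community count - the
## composition the benchmark description states - while sizes themselves
## stay random: sampled from the power law, then nudged by random unit
## steps within [min_c, max_c] until they sum to the target.
lfr_community_sizes <- function(p, total) {
  support <- p$min_c:p$max_c
  prob <- support^(-p$tau2)
  mean_size <- sum(support * prob) / sum(prob)
  k <- max(p$om, round(total / mean_size))
  if (k * p$min_c > total || k * p$max_c < total) {
    k <- max(p$om, min(total %/% p$min_c, max(1L, ceiling(total / p$max_c))))
  }
  if (k * p$min_c > total || k * p$max_c < total) {
    stop("generation error: cannot fit community sizes to ", total, call. = FALSE)
  }
  sizes <- sample(support, k, replace = TRUE, prob = prob)
  guard <- 0L
  while (sum(sizes) != total) {
    guard <- guard + 1L
    if (guard > 10000L) stop("generation error: cannot fit community sizes to ", total, call. = FALSE)
    if (sum(sizes) < total) {
      cand <- which(sizes < p$max_c)
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      sizes[j] <- sizes[j] + 1L
    } else {
      cand <- which(sizes > p$min_c)
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      sizes[j] <- sizes[j] - 1L
    }
  }
  sizes
}

## seat nodes in communities subject to capacity and internal-degree
## feasibility; returns a list of membership vectors (community ids), the
## first entry of an overlapping node's vector is its planted primary
lfr_assign_memberships <- function(p, k, overlap, max_restarts = 100L) {
  d_int <- as.integer(pmin(round((1 - p$mu) * k), k))
  memb_of <- function(v) if (overlap[v]) p$om else 1L
  demand <- ceiling(d_int / ifelse(overlap, p$om, 1L))
  for (attempt in seq_len(max_restarts)) {
    sizes <- lfr_community_sizes(p, p$n + sum(overlap) * (p$om - 1L))
    if (length(sizes) < p$om) next
    ## feasibility repair: at least one community must be able to host the
    ## largest internal degree (slots shifted from other communities)
    need <- max(demand) + 1L
    if (need > p$max_c) stop("generation error: max internal degree ", max(demand),
                             " cannot fit any community of size <= ", p$max_c, call. = FALSE)
    j <- which.max(sizes)
    while (sizes[j] < need) {
      cand <- setdiff(which(sizes > p$min_c), j)
      if (!length(cand)) break
      d <- cand[which.max(sizes[cand])]
      sizes[d] <- sizes[d] - 1L
      sizes[j] <- sizes[j] + 1L
    }
    if (sizes[j] < need) next
    free <- sizes
    memberships <- vector("list", p$n)
    ok <- TRUE
    for (v in order(-demand)) {
      eligible <- which(free > 0L & (sizes - 1L) >= demand[v])
      if (length(eligible) < memb_of(v)) { ok <- FALSE; break }
      pick <- if (length(eligible) == 1L) eligible else sample(eligible, memb_of(v))
      memberships[[v]] <- pick
      free[pick] <- free[pick] - 1L
    }
    if (ok) return(list(memberships = memberships, sizes = sizes, d_int = d_int))
  }
  stop("generation error: cannot seat nodes in communities after ", max_restarts,
       " attempts (degree/community-size constraints too tight)", call. = FALSE)
}

## random stub matching with rewiring: pairs `stubs` (node indices), avoiding
## self-loops, duplicates (also against `existing` keys) and, when
## `share_comm` is given, pairs of nodes sharing a community
pair_stubs <- function(stubs, n, existing = integer(0), share_comm = NULL,
                       max_sweeps = 300L) {
  if (length(stubs) < 2L) return(matrix(integer(0), ncol = 2L))
  if (length(stubs) %% 2L == 1L) stubs <- stubs[-length(stubs)]
  stubs <- sample(stubs)
  np <- length(stubs) %/% 2L
  u <- stubs[seq_len(np) * 2L - 1L]
  v <- stubs[seq_len(np) * 2L]
  for (sweep in seq_len(max_sweeps)) {
    a <- pmin(u, v); b <- pmax(u, v)
    key <- (a - 1) * n + b
    bad <- (u == v) | duplicated(key) | (key %in% existing)
    if (!is.null(share_comm)) bad <- bad | share_comm(u, v)
    if (!any(bad)) break
    ## reshuffle the stubs of bad pairs together with as many good pairs
    idx_bad <- which(bad)
    idx_good <- which(!bad)
    take <- idx_good[sample.int(length(idx_good), min(length(idx_good), length(idx_bad)))]
    pool_idx <- c(idx_bad, take)
    pool <- sample(c(u[pool_idx], v[pool_idx]))
    u[pool_idx] <- pool[seq_along(pool_idx)]
    v[pool_idx] <- pool[seq_along(pool_idx) + length(pool_idx)]
  }
  a <- pmin(u, v); b <- pmax(u, v)
  key <- (a - 1) * n + b
  bad <- (u == v) | duplicated(key) | (key %in% existing)
  if (!is.null(share_comm)) bad <- bad | share_comm(u, v)
  cbind(a[!bad], b[!bad])
}

## realize an intra-community degree sequence as a simple graph:
## Havel-Hakimi construction (drops unseatable stubs of non-graphical
## sequences), then randomization by double-edge swaps that respect
## simplicity and previously created edges
wire_community <- function(ids, d, n, existing) {
  if (sum(d) %% 2L == 1L) {
    j <- which.max(d)
    d[j] <- d[j] - 1L
  }
  u <- integer(0); v <- integer(0)
  dd <- d
  repeat {
    ord <- order(-dd, ids)
    if (dd[ord[1L]] == 0L) break
    s <- ord[1L]
    need <- dd[s]
    targets <- ord[-1L]
    targets <- targets[dd[targets] > 0L][seq_len(min(need, sum(dd[targets] > 0L)))]
    if (!length(targets)) { dd[s] <- 0L; next }
    u <- c(u, rep(ids[s], length(targets)))
    v <- c(v, ids[targets])
    dd[targets] <- dd[targets] - 1L
    dd[s] <- dd[s] - length(targets)   # 0 if graphical, drops the rest
    if (dd[s] > 0L) dd[s] <- 0L
  }
  ne <- length(u)
  if (ne < 2L) {
    a <- pmin(u, v); b <- pmax(u, v)
    return(cbind(a, b)[!( (a - 1) * n + b ) %in% existing, , drop = FALSE])
  }
  a <- pmin(u, v); b <- pmax(u, v)
  key <- (a - 1) * n + b
  have <- c(existing, key)
  for (t in seq_len(5L * ne)) {
    ij <- sample.int(ne, 2L)
    i <- ij[1L]; j <- ij[2L]
    if (stats::runif(1) < 0.5) {
      n1 <- c(a[i], b[j]); n2 <- c(a[j], b[i])
    } else {
      n1 <- c(a[i], a[j]); n2 <- c(b[i], b[j])
    }
    if (n1[1L] == n1[2L] || n2[1L] == n2[2L]) next
    k1 <- (min(n1) - 1) * n + max(n1)
    k2 <- (min(n2) - 1) * n + max(n2)
    if (k1 == k2 || k1 %in% have || k2 %in% have) next
    have <- setdiff(have, c(key[i], key[j]))
    a[i] <- min(n1); b[i] <- max(n1); key[i] <- k1
    a[j] <- min(n2); b[j] <- max(n2); key[j] <- k2
    have <- c(have, k1, k2)
  }
  keep <- !(key %in% existing) & !duplicated(key)
  cbind(a, b)[keep, , drop = FALSE]
}

## wire a community and report per-node unrealized internal stubs, so the
## generator can reroute them through the external pool instead of losing
## them (keeps realized edge totals at the stub count)
wire_community_with_deficit <- function(ids, d, n, existing) {
  em <- wire_community(ids, d, n, existing)
  realized <- integer(length(ids))
  names(realized) <- as.character(ids)
  if (nrow(em)) {
    tab <- table(c(em[, 1L], em[, 2L]))
    realized[names(tab)[names(tab) %in% names(realized)]] <-
      as.integer(tab[names(tab) %in% names(realized)])
  }
  list(edges = em, deficit = pmax(d - realized, 0L))
}

#' LFR-style benchmark graph with planted overlapping nodes
#'
#' Generates a graph with a truncated power-law degree sequence, power-law
#' community sizes, a planted cover with `on` overlapping nodes holding `om`
#' memberships each, and a mixing parameter `mu`: each node routes a
#' fraction `1 - mu` of its edge stubs inside its own community (split
#' evenly across an overlapping node's communities) and `mu` outside. Stubs
#' are wired by configuration-model matching with rewiring to avoid
#' self-loops, parallel edges and spurious intra-community external edges.
#'
#' @param params Parameter list from [lfr_params()].
#' @param seed Integer seed.
#' @return A `tc_benchmark`; `truth$membership` holds the planted primary
#'   community per node and `truth$overlaps` lists each overlapping node
#'   with all its planted communities.
#' @export
generate_lfr <- function(params = lfr_params(), seed) {
  p <- params
  with_seed(seed, function() {
    k <- lfr_degrees(p)
    overlap <- logical(p$n)
    if (p$on > 0L) overlap[sample.int(p$n, p$on)] <- TRUE
    seat <- lfr_assign_memberships(p, k, overlap)
    memberships <- seat$memberships
    ncomm <- length(seat$sizes)
    d_int <- seat$d_int

    ## per-(node, community) internal stubs: split evenly for overlap nodes,
    ## the remainder going to randomly chosen memberships
    int_stubs <- vector("list", p$n)
    for (v in seq_len(p$n)) {
      cs <- memberships[[v]]
      base <- d_int[v] %/% length(cs)
      alloc <- rep(base, length(cs))
      rem <- d_int[v] - base * length(cs)
      if (rem > 0L) {
        extra <- if (length(cs) == 1L) 1L else sample.int(length(cs), rem)
        alloc[extra] <- alloc[extra] + 1L
      }
      alloc <- pmin(alloc, seat$sizes[cs] - 1L)
      int_stubs[[v]] <- structure(alloc, names = as.character(cs))
    }

    comm_sets <- lapply(seq_len(ncomm), function(c)
      which(vapply(memberships, function(m) c %in% m, TRUE)))

    ## wire each community internally
    edges <- matrix(integer(0), ncol = 2L)
    keys <- numeric(0)
    deficit <- integer(p$n)
    for (c in seq_len(ncomm)) {
      members <- comm_sets[[c]]
      degs <- vapply(members, function(v) int_stubs[[v]][[as.character(c)]], 1L)
      wc <- wire_community_with_deficit(members, degs, p$n, existing = keys)
      em <- wc$edges
      deficit[members] <- deficit[members] + wc$deficit
      if (nrow(em)) {
        edges <- rbind(edges, em)
        keys <- c(keys, (em[, 1L] - 1) * p$n + em[, 2L])
      }
    }

    ## wire the external stubs globally, avoiding intra-community pairs;
    ## unrealized internal stubs rejoin the pool here
    used <- vapply(seq_len(p$n), function(v) as.integer(sum(int_stubs[[v]])), 1L)
    ext <- pmax(k - used, 0L) + deficit
    if (p$mu == 0) ext[] <- 0L   # no external stubs at zero mixing
    share_comm <- function(u, v) {
      mapply(function(a, b) length(intersect(memberships[[a]], memberships[[b]])) > 0L, u, v)
    }
    stubs_e <- rep(seq_len(p$n), ext)
    em <- pair_stubs(stubs_e, p$n, existing = keys, share_comm = share_comm)
    if (nrow(em)) edges <- rbind(edges, em)

    width <- nchar(as.character(p$n))
    nodes <- sprintf("v%0*d", width, seq_len(p$n))
    g <- build_graph(cbind(nodes[edges[, 1L]], nodes[edges[, 2L]]), nodes = nodes)

    membership <- vapply(memberships, `[[`, 1L, 1L)   # planted primary
    names(membership) <- nodes
    overlaps <- if (any(overlap)) {
      data.frame(node = nodes[overlap],
                 type = NA_integer_,
                 community_ids = vapply(memberships[overlap],
                                        function(m) paste(sort(m), collapse = ","), ""),
                 stringsAsFactors = FALSE)
    } else empty_overlaps()
    new_benchmark(g, membership, overlaps, p, seed)
  })
}
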