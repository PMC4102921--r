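## Readers and writers: whitespace/TSV edge lists (with `#` comments), GML
## and Pajek .net via igraph, plus the cover serialization (membership TSV,
## overlaps TSV, JSON summary) with stable ordering so outputs are diffable.

to_igraph <- function(g) {
  el <- do.call(rbind, lapply(seq_along(g$nodes), function(v) {
    nb <- g$adj[[v]]
    nb <- nb[nb > v]
    if (length(nb)) cbind(g$nodes[v], g$nodes[nb]) else NULL
  }))
  d <- if (is.null(el)) data.frame(from = character(0), to = character(0)) else
    data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(d, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  if (!length(keep)) stop("empty edge list: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad)) {
    stop("malformed edge at line ", keep[bad[1L]], " of ", path,
         ": expected 2 fields, got ", length(parts[[bad[1L]]]), call. = FALSE)
  }
  matrix(unlist(parts), ncol = 2L, byrow = TRUE)
}

igraph_labels <- function(ig) {
  va <- igraph::vertex_attr(ig)
  for (key in c("name", "label", "id")) {
    if (!is.null(va[[key]])) return(as.character(va[[key]]))
  }
  as.character(seq_len(igraph::vcount(ig)))
}

#' Read a graph file
#'
#' Supported dialects: whitespace/tab-separated edge lists (one edge per
#' line, `#` comments ignored), GML and Pajek `.net` (parsed by igraph,
#' vertex labels preserved). The result is always a simple undirected
#' `tc_graph`; directed input is symmetrized.
#'
#' @param path File path.
#' @param format One of `"edgelist"`, `"gml"`, `"pajek"`.
#' @param directed Declare the input as directed (arcs are symmetrized
#'   either way; the flag only documents intent).
#' @return A `tc_graph`.
#' @export
read_graph_file <- function(path, format = c("edgelist", "gml", "pajek"),
                            directed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edgelist") {
    return(build_graph(read_edgelist(path), directed = directed))
  }
  ig <- igraph::read_graph(path, format = format)
  labels <- igraph_labels(ig)
  el <- igraph::as_edgelist(ig, names = FALSE)
  build_graph(cbind(labels[el[, 1L]], labels[el[, 2L]]),
              directed = directed, nodes = labels)
}

#' Write a graph file
#'
#' @param g A `tc_graph`.
#' @param path Output path.
#' @param format One of `"edgelist"`, `"gml"`, `"pajek"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("edgelist", "gml", "pajek")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    el <- do.call(rbind, lapply(seq_along(g$nodes), function(v) {
      nb <- g$adj[[v]]
      nb <- nb[nb > v]
      if (length(nb)) cbind(g$nodes[v], g$nodes[nb]) else NULL
    }))
    lines <- if (is.null(el)) character(0) else paste(el[, 1L], el[, 2L], sep = "\t")
    writeLines(lines, path)
  } else if (format == "pajek") {
    ## written directly so vertex labels survive the round trip
    lines <- c(paste("*Vertices", length(g$nodes)),
               sprintf('%d "%s"', seq_along(g$nodes), g$nodes),
               "*Edges")
    for (v in seq_along(g$nodes)) {
      nb <- g$adj[[v]]
      nb <- nb[nb > v]
      if (length(nb)) lines <- c(lines, paste(v, nb))
    }
    writeLines(lines, path)
  } else {
    igraph::write_graph(to_igraph(g), path, format = format)
  }
  invisible(path)
}

#' Write a cover to disk
#'
#' Produces three files under `prefix`: `<prefix>_membership.tsv` (node,
#' primary community), `<prefix>_overlaps.tsv` (node, type, comma-joined
#' community ids) and `<prefix>_summary.json` (community count, sizes,
#' strong/weak flags, hubs, overlap and isolated counts, convergence
#' trace). Rows are ordered canonically so re-running never changes files.
#'
#' @param cover A `tc_cover`.
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
write_cover <- function(cover, prefix) {
  nodes <- canonical_sort(names(cover$membership))
  mem_path <- paste0(prefix, "_membership.tsv")
  ov_path <- paste0(prefix, "_overlaps.tsv")
  js_path <- paste0(prefix, "_summary.json")
  writeLines(c("node\tcommunity",
               paste(nodes, cover$membership[nodes], sep = "\t")), mem_path)
  ov <- cover$overlaps[order(cover$overlaps$node, method = "radix"), , drop = FALSE]
  writeLines(c("node\ttype\tcommunity_ids",
               if (nrow(ov)) paste(ov$node, ov$type, ov$community_ids, sep = "\t")),
             ov_path)
  summary <- list(
    n_communities = length(cover$communities),
    communities = lapply(unname(cover$communities), function(c) list(
      id = c$id, size = length(c$members),
      strong = isTRUE(c$strong), weak = isTRUE(c$weak), hubs = c$hubs)),
    n_overlapping = nrow(cover$overlaps),
    n_isolated = length(cover$isolated),
    isolated = cover$isolated,
    trace = cover$trace)
  jsonlite::write_json(summary, js_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(mem_path, ov_path, js_path))
}

#' Read a node-to-community membership TSV
#'
#' @param path TSV with columns node, community (a header line is detected
#'   and skipped).
#' @return Named integer-ish vector mapping node to community label.
#' @export
read_membership <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  if (length(parts) && identical(tolower(parts[[1L]][1L]), "node")) parts <- parts[-1L]
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad)) stop("malformed membership row ", bad[1L], " in ", path, call. = FALSE)
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  labels <- m[, 2L]
  names(labels) <- m[, 1L]
  labels
}

#' Rebuild a cover from files written by [write_cover()]
#'
#' @param g The `tc_graph` the cover refers to.
#' @param prefix The prefix passed to [write_cover()].
#' @return A `tc_cover`.
#' @export
read_cover <- function(g, prefix) {
  labels <- read_membership(paste0(prefix, "_membership.tsv"))
  membership <- as.integer(labels)
  names(membership) <- names(labels)
  cover <- make_cover(g, membership)
  ov_path <- paste0(prefix, "_overlaps.tsv")
  if (file.exists(ov_path)) {
    lines <- readLines(ov_path, warn = FALSE)
    lines <- lines[trimws(lines) != ""]
    if (length(lines) > 1L) {
      parts <- strsplit(lines[-1L], "\t")
      cover$overlaps <- data.frame(
        node = vapply(parts, `[[`, "", 1L),
        type = as.integer(vapply(parts, `[[`, "", 2L)),
        community_ids = vapply(parts, `[[`, "", 3L),
        stringsAsFactors = FALSE)
      for (i in seq_len(nrow(cover$overlaps))) {
        for (id in strsplit(cover$overlaps$community_ids[i], ",")[[1L]]) {
          cover$communities[[id]]$members <- canonical_sort(
            unique(c(cover$communities[[id]]$members, cover$overlaps$node[i])))
        }
      }
    }
  }
  cover
}
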