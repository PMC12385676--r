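#' Construct a scored protein-protein interaction network
#'
#' An undirected graph whose nodes are gene symbols (uppercased on entry)
#' and whose edges carry a confidence in \[0,1\]. Self-loops are dropped and
#' duplicate unordered pairs are collapsed to a single edge keeping the
#' maximum confidence.
#'
#' @param edges Data.frame with columns `from`, `to`, `confidence`.
#' @param nodes Optional character vector of extra (possibly isolated)
#'   node symbols to include.
#' @param provenance Free-text label recorded on the network.
#' @return An object of class `scored_network` wrapping an igraph graph.
#' @export
#' @examples
#' net <- scored_network(data.frame(from = "a", to = "b", confidence = 0.9))
#' network_nodes(net)
scored_network <- function(edges, nodes = character(), provenance = "") {
  stopifnot(all(c("from", "to", "confidence") %in% names(edges)))
  edges$from <- toupper(as.character(edges$from))
  edges$to <- toupper(as.character(edges$to))
  if (nrow(edges)) {
    if (any(!is.finite(edges$confidence) | edges$confidence < 0 |
              edges$confidence > 1)) {
      stop("edge confidence out of [0, 1]")
    }
    edges <- edges[edges$from != edges$to, , drop = FALSE]  # no self-loops
    # collapse duplicate unordered pairs, keep max confidence
    a <- pmin(edges$from, edges$to)
    b <- pmax(edges$from, edges$to)
    key <- paste(a, b, sep = "\r")
    conf <- tapply(edges$confidence, key, max)
    keys <- names(conf)
    parts <- strsplit(keys, "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(parts, `[`, "", 1),
                        to = vapply(parts, `[`, "", 2),
                        confidence = as.numeric(conf),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  all_nodes <- sort(unique(c(edges$from, edges$to, toupper(nodes))))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = all_nodes)
  structure(list(graph = g, provenance = provenance),
            class = "scored_network")
}

#' @export
print.scored_network <- function(x, ...) {
  cat("<scored_network>", x$provenance, "-",
      igraph::vcount(x$graph), "nodes,", igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' Node symbols of a scored network
#' @param net A [scored_network()].
#' @return Sorted character vector of node symbols.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "scored_network"))
  sort(igraph::V(net$graph)$name)
}

#' Edge table of a scored network
#' @param net A [scored_network()].
#' @return Data.frame with `from`, `to`, `confidence`, each pair ordered
#'   `from < to` and rows sorted, so the table is a canonical form.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "scored_network"))
  el <- igraph::as_edgelist(net$graph)
  if (!nrow(el)) {
    return(data.frame(from = character(), to = character(),
                      confidence = numeric(), stringsAsFactors = FALSE))
  }
  df <- data.frame(from = pmin(el[, 1], el[, 2]),
                   to = pmax(el[, 1], el[, 2]),
                   confidence = igraph::E(net$graph)$confidence,
                   stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a scored edge list from disk
#'
#' Supported dialects:
#' * `simple_tsv` — three tab-separated columns: symbol A, symbol B,
#'   confidence.
#' * `hippie` — the HIPPIE tab layout: UniProt name A, Entrez A, UniProt
#'   name B, Entrez B, confidence, annotation. Symbols are the UniProt
#'   names with a trailing `_HUMAN` stripped.
#' * `sif` — `node relation node`; SIF carries no score, so confidence 1.
#'
#' Duplicate unordered pairs keep the maximum confidence; symbols are
#' uppercased. A confidence outside \[0,1\] or an unparseable row raises an
#' error naming the line; an empty file yields an empty network with a
#' warning.
#'
#' @param path Path to the edge-list file.
#' @param dialect One of `"simple_tsv"`, `"hippie"`, `"sif"`.
#' @return A [scored_network()].
#' @export
read_edge_list <- function(path, dialect = c("simple_tsv", "hippie", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty edge-list file: ", path)
    return(scored_network(data.frame(from = character(), to = character(),
                                     confidence = numeric()),
                          provenance = basename(path)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  parse_row <- function(p, i) {
    if (dialect == "simple_tsv") {
      if (length(p) < 3) stop("unparseable row at line ", i, ": need 3 columns")
      conf <- suppressWarnings(as.numeric(p[3]))
      c(p[1], p[2], conf)
    } else if (dialect == "hippie") {
      if (length(p) < 5) stop("unparseable row at line ", i, ": need 5 columns")
      conf <- suppressWarnings(as.numeric(p[5]))
      c(sub("_HUMAN$", "", p[1]), sub("_HUMAN$", "", p[3]), conf)
    } else {
      if (length(p) < 3) stop("unparseable row at line ", i, ": need 3 columns")
      c(p[1], p[3], 1)
    }
  }
  rows <- lapply(seq_along(parts), function(i) parse_row(parts[[i]], i))
  conf <- as.numeric(vapply(rows, `[`, "", 3))
  bad <- which(!is.finite(conf) | conf < 0 | conf > 1)
  if (length(bad)) {
    stop("confidence out of range or not numeric at line ", bad[1])
  }
  scored_network(data.frame(from = vapply(rows, `[`, "", 1),
                            to = vapply(rows, `[`, "", 2),
                            confidence = conf, stringsAsFactors = FALSE),
                 provenance = basename(path))
}

#' Filter a network by edge confidence
#'
#' Retains exactly the edges with confidence greater than or equal to the
#' threshold (0.63 is the HIPPIE medium-confidence cutoff used to build the
#' base interactome). Nodes left with no edges are dropped: isolated nodes
#' are not counted in a filtered interactome.
#'
#' @param net A [scored_network()].
#' @param threshold Confidence threshold in \[0,1\].
#' @return The filtered [scored_network()].
#' @export
filter_confidence <- function(net, threshold) {
  stopifnot(inherits(net, "scored_network"))
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  ed <- network_edges(net)
  ed <- ed[ed$confidence >= threshold, , drop = FALSE]
  scored_network(ed, provenance = net$provenance)
}

#' Extract the first-neighbor subnetwork of a query gene list
#'
#' The node set is the query genes present in the network together with all
#' of their direct neighbors; the edge set is by default the *induced*
#' subgraph on that node set (neighbor-neighbor edges included). Query
#' symbols absent from the network are returned as a side list, not an
#' error.
#'
#' @param net A [scored_network()].
#' @param query Character vector of query gene symbols.
#' @param edges `"induced"` (default) or `"incident"` (only edges touching a
#'   query gene).
#' @return A [scored_network()] with an extra element `missing_query`
#'   listing query symbols absent from `net`.
#' @export
first_neighbor_subnetwork <- function(net, query,
                                      edges = c("induced", "incident")) {
  stopifnot(inherits(net, "scored_network"))
  edges <- match.arg(edges)
  query <- unique(toupper(as.character(query)))
  present <- intersect(query, igraph::V(net$graph)$name)
  missing <- setdiff(query, present)
  if (!length(present)) {
    out <- scored_network(data.frame(from = character(), to = character(),
                                     confidence = numeric()),
                          provenance = net$provenance)
    out$missing_query <- missing
    return(out)
  }
  nb <- unique(unlist(igraph::adjacent_vertices(net$graph, present)))
  keep <- union(present, igraph::V(net$graph)$name[nb])
  ed <- network_edges(net)
  ed <- if (edges == "induced") {
    ed[ed$from %in% keep & ed$to %in% keep, , drop = FALSE]
  } else {
    ed[ed$from %in% present | ed$to %in% present, , drop = FALSE]
  }
  out <- scored_network(ed, nodes = keep, provenance = net$provenance)
  out$missing_query <- missing
  out
}

#' Merge two scored networks
#'
#' Node union and edge union; duplicate unordered pairs collapse to the
#' maximum confidence. Commutative and associative on node/edge sets.
#'
#' @param a,b [scored_network()]s.
#' @return The merged [scored_network()].
#' @export
merge_networks <- function(a, b) {
  stopifnot(inherits(a, "scored_network"), inherits(b, "scored_network"))
  prov <- paste(unique(c(a$provenance, b$provenance)), collapse = "+")
  scored_network(rbind(network_edges(a), network_edges(b)),
                 nodes = c(network_nodes(a), network_nodes(b)),
                 provenance = prov)
}

#' Degree-class report for query genes within a network
#'
#' Classifies each query gene by its degree in the network: singletons
#' (degree 0, including genes absent from the network), single-interaction
#' genes (degree 1), degree 2, and degree >= 3.
#'
#' @param net A [scored_network()].
#' @param query Character vector of query gene symbols.
#' @return Data.frame with `symbol`, `degree`, `degree_class` (one of
#'   `"0"`, `"1"`, `"2"`, `">=3"`).
#' @export
component_report <- function(net, query) {
  stopifnot(inherits(net, "scored_network"))
  query <- unique(toupper(as.character(query)))
  deg <- setNames(rep(0L, length(query)), query)
  present <- intersect(query, igraph::V(net$graph)$name)
  if (length(present)) {
    deg[present] <- igraph::degree(net$graph, v = present)
  }
  cls <- ifelse(deg >= 3, ">=3", as.character(deg))
  data.frame(symbol = query, degree = as.integer(deg), degree_class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}
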