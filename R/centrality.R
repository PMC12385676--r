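#' Per-node centrality profiles
#'
#' Computes, on the unweighted topology:
#' * `degree` — incident edge count;
#' * `betweenness` — exact unnormalized shortest-path betweenness (Brandes
#'   accumulation; each unordered pair counted once);
#' * `closeness` — number of reachable nodes divided by the sum of
#'   shortest-path distances to them, a within-component "proximity";
#' * `aspl` — the node's mean shortest-path distance (hops) to reachable
#'   nodes.
#'
#' Closeness and aspl are only defined within a node's connected component;
#' singleton nodes carry `NA` (never 0) for both.
#'
#' @param net A [scored_network()].
#' @param normalize If `TRUE`, betweenness is divided by `(n-1)(n-2)/2`
#'   (the number of node pairs excluding the focal node), for cross-network
#'   comparison plots.
#' @return Data.frame with `node`, `degree`, `betweenness`, `closeness`,
#'   `aspl`, one row per node, sorted by node.
#' @export
#' @examples
#' star <- scored_network(data.frame(from = "hub", to = c("a", "b", "c", "d"),
#'                                   confidence = 1))
#' compute_centralities(star)
compute_centralities <- function(net, normalize = FALSE) {
  stopifnot(inherits(net, "scored_network"))
  g <- net$graph
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  if (n == 0) {
    return(data.frame(node = character(), degree = integer(),
                      betweenness = numeric(), closeness = numeric(),
                      aspl = numeric(), stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE,
                             weights = NA)
  if (normalize && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  d <- igraph::distances(g, weights = NA)
  clo <- aspl <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    if (length(reach)) {
      aspl[i] <- mean(reach)
      clo[i] <- length(reach) / sum(reach)
    }
  }
  out <- data.frame(node = nodes, degree = as.integer(deg),
                    betweenness = as.numeric(btw), closeness = clo,
                    aspl = aspl, stringsAsFactors = FALSE)
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Network-level centrality summary
#'
#' Degree and betweenness are summarized by their mean, closeness and
#' average shortest path length by their median (nodes with undefined
#' closeness/aspl are excluded from the medians). These summaries are the
#' classification thresholds of [classify_roles()]. Set
#' `median_for_all = TRUE` to use medians for all four measures.
#'
#' @param profiles Output of [compute_centralities()].
#' @param median_for_all Use the median for degree and betweenness too.
#' @return An object of class `network_summary`: list with `mean_degree`,
#'   `mean_betweenness`, `median_closeness`, `median_aspl`.
#' @export
summarize_centralities <- function(profiles, median_for_all = FALSE) {
  if (!nrow(profiles)) stop("cannot summarize an empty profile table")
  ctr <- if (median_for_all) stats::median else mean
  structure(list(
    mean_degree = ctr(profiles$degree),
    mean_betweenness = ctr(profiles$betweenness),
    median_closeness = stats::median(profiles$closeness, na.rm = TRUE),
    median_aspl = stats::median(profiles$aspl, na.rm = TRUE)
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0("<network_summary> mean degree %.3f | mean betweenness ",
                     "%.3f | median closeness %.4f | median aspl %.3f\n"),
              x$mean_degree, x$mean_betweenness, x$median_closeness,
              x$median_aspl))
  invisible(x)
}

#' Classify genes into topological roles
#'
#' Two independent axes, thresholded at the network summary values with
#' "high" meaning at-or-above the threshold:
#'
#' *Hub axis* (degree vs betweenness):
#' * `hub` — degree and betweenness both high: central regulators;
#' * `provincial_hub` — high degree, low betweenness: locally interactive;
#' * `connector_bottleneck` — low degree, high betweenness: few connections
#'   but essential for cross-network communication;
#' * `peripheral` — both low.
#'
#' *Integration axis* (closeness vs aspl):
#' * `integrated` — closeness at/above the median and aspl at/below it;
#' * `vulnerable` — closeness below the median and aspl above it;
#' * `intermediate` — otherwise, including nodes with undefined
#'   closeness/aspl (these are flagged).
#'
#' Labels are invariant to rescaling all betweenness values by a positive
#' constant, since the threshold rescales with them.
#'
#' @param profiles Output of [compute_centralities()].
#' @param summary Output of [summarize_centralities()] on the same profiles.
#' @return Data.frame with `node`, `hub_axis`, `integration_axis`,
#'   `undefined_integration` (logical flag).
#' @export
classify_roles <- function(profiles, summary) {
  stopifnot(inherits(summary, "network_summary"))
  hi_deg <- profiles$degree >= summary$mean_degree
  hi_btw <- profiles$betweenness >= summary$mean_betweenness
  hub_axis <- ifelse(hi_deg & hi_btw, "hub",
              ifelse(hi_deg & !hi_btw, "provincial_hub",
              ifelse(!hi_deg & hi_btw, "connector_bottleneck", "peripheral")))
  undef <- is.na(profiles$closeness) | is.na(profiles$aspl)
  hi_clo <- profiles$closeness >= summary$median_closeness
  lo_aspl <- profiles$aspl <= summary$median_aspl
  integration <- ifelse(undef, "intermediate",
                 ifelse(hi_clo & lo_aspl, "integrated",
                 ifelse(!hi_clo & !lo_aspl, "vulnerable", "intermediate")))
  data.frame(node = profiles$node, hub_axis = hub_axis,
             integration_axis = integration, undefined_integration = undef,
             row.names = NULL, stringsAsFactors = FALSE)
}
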