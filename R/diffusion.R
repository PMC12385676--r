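#' Configuration for heat-kernel network propagation
#'
#' @param time_t Positive diffusion time. The default 0.1 matches the
#'   default of the widely used network-diffusion app on whose behavior the
#'   propagation step is modelled.
#' @param selection_mode `"output_size"` (select a fixed number of top-heat
#'   nodes) or `"rank_cutoff"` (select all nodes with 0-based rank up to the
#'   cutoff, so cutoff 99 selects 100 nodes).
#' @param selection_value Non-negative integer for the chosen mode.
#' @param include_query In `output_size` mode, whether seed nodes are always
#'   retained in addition to the `selection_value` top-heat non-seed nodes.
#' @param weighted If `TRUE`, diffuse on the confidence-weighted Laplacian
#'   instead of the default unweighted topology.
#' @return An object of class `diffusion_config`.
#' @export
diffusion_config <- function(time_t = 0.1,
                             selection_mode = c("rank_cutoff", "output_size"),
                             selection_value = 99L,
                             include_query = TRUE,
                             weighted = FALSE) {
  selection_mode <- match.arg(selection_mode)
  if (!is.numeric(time_t) || time_t <= 0) stop("time_t must be > 0")
  if (selection_value < 0) stop("selection_value must be >= 0")
  structure(list(time_t = time_t, selection_mode = selection_mode,
                 selection_value = as.integer(selection_value),
                 include_query = isTRUE(include_query),
                 weighted = isTRUE(weighted)),
            class = "diffusion_config")
}

# exp(-tL) %*% h0 by uniformization: with mu >= max degree, P = I - L/mu is
# a nonnegative matrix with unit row sums, and
#   exp(-tL) h0 = sum_k exp(-t mu) (t mu)^k / k!  P^k h0.
# All terms are nonnegative, so truncating when the remaining Poisson tail
# mass drops below tol bounds the L1 error by tol * ||h0||_1.
.heat_kernel_apply <- function(L, h0, time_t, tol = 1e-10) {
  mu <- max(Matrix::diag(L))
  if (mu == 0) return(h0)  # edgeless graph: nothing diffuses
  n <- length(h0)
  P <- Matrix::Diagonal(n) - L / mu
  # split t into segments with Poisson rate <= 20 so exp(-lam) never
  # underflows; exp(-tL) = (exp(-(t/s)L))^s
  s <- max(1L, ceiling(time_t * mu / 20))
  lam <- time_t * mu / s
  # terminate when the remaining Poisson tail mass, relative to the total
  # initial heat, drops below tol: bounds the relative conservation error
  seg_tol <- tol / s
  h <- h0
  for (seg in seq_len(s)) {
    w <- exp(-lam)
    acc <- w * h
    v <- h
    cum <- w
    k <- 0L
    max_iter <- 1000L
    while (1 - cum > seg_tol && k < max_iter) {
      k <- k + 1L
      v <- as.numeric(P %*% v)
      w <- w * lam / k
      acc <- acc + w * v
      cum <- cum + w
    }
    if (1 - cum > seg_tol) {
      # tail mass must be exhausted for the stated tolerance to hold
      stop("heat-kernel series did not converge; increase max iterations")
    }
    h <- acc
  }
  h
}

#' Propagate heat from seed genes over a network
#'
#' Computes `h = exp(-t L) h0` where `L = D - A` is the graph Laplacian of
#' the (by default unweighted) network topology and `h0` places unit heat on
#' each seed gene. The kernel is evaluated by a uniformization series
#' truncated when the remaining Poisson tail mass falls below 1e-10 of the
#' initial heat, so results agree with a dense matrix exponential to well
#' within 1e-8 and total heat is conserved (`sum(h) = number of seeds`).
#'
#' @param net A [scored_network()].
#' @param seeds Character vector of seed gene symbols; at least one must be
#'   present in the network.
#' @param cfg A [diffusion_config()].
#' @return A `heat_vector`: data.frame with `node`, `heat`, and 0-based
#'   `rank` by descending heat (ties broken by node name, so ranks are a
#'   permutation). Attributes: `seeds` (matched seeds) and `missing_seeds`.
#' @export
#' @examples
#' net <- scored_network(data.frame(from = c("a", "b"), to = c("b", "c"),
#'                                  confidence = 1))
#' heat_diffuse(net, "a", diffusion_config(time_t = 0.1))
heat_diffuse <- function(net, seeds, cfg = diffusion_config()) {
  stopifnot(inherits(net, "scored_network"), inherits(cfg, "diffusion_config"))
  seeds <- unique(toupper(as.character(seeds)))
  nodes <- igraph::V(net$graph)$name
  present <- intersect(seeds, nodes)
  if (!length(present)) {
    stop("no seed overlaps the network; missing seeds: ",
         paste(seeds, collapse = ", "))
  }
  A <- igraph::as_adjacency_matrix(
    net$graph, sparse = TRUE,
    attr = if (cfg$weighted) "confidence" else NULL
  )
  A <- methods::as(A, "dMatrix")
  L <- Matrix::Diagonal(x = Matrix::rowSums(A)) - A
  h0 <- as.numeric(nodes %in% present)
  h <- .heat_kernel_apply(L, h0, cfg$time_t)
  ord <- order(-h, nodes)
  rank <- integer(length(h))
  rank[ord] <- seq_along(h) - 1L
  out <- data.frame(node = nodes, heat = h, rank = rank,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seeds") <- present
  attr(out, "missing_seeds") <- setdiff(seeds, present)
  class(out) <- c("heat_vector", "data.frame")
  out
}

#' Select a propagated subnetwork from a heat vector
#'
#' In `rank_cutoff` mode, selects every node with rank up to
#' `selection_value` (cutoff 99 yields 100 nodes on a network of at least
#' 100 nodes). In `output_size` mode, selects the `selection_value` top-heat
#' nodes; with `include_query = TRUE` the seed nodes are retained in
#' addition, and `selection_value` counts non-seed nodes. Heat ties at the
#' selection boundary are broken by node name and reported in the
#' `tie_at_boundary` element.
#'
#' @param net The [scored_network()] on which `heat` was computed.
#' @param heat A `heat_vector` from [heat_diffuse()].
#' @param cfg The [diffusion_config()].
#' @return A list with `network` (induced [scored_network()] on the selected
#'   nodes), `genes` (sorted selected symbols) and `tie_at_boundary`
#'   (logical).
#' @export
select_subnetwork <- function(net, heat, cfg) {
  stopifnot(inherits(net, "scored_network"), inherits(heat, "heat_vector"),
            inherits(cfg, "diffusion_config"))
  if (!setequal(heat$node, igraph::V(net$graph)$name)) {
    stop("heat vector was not computed on this network")
  }
  h <- heat[order(heat$rank), , drop = FALSE]
  n <- nrow(h)
  if (cfg$selection_mode == "rank_cutoff") {
    k <- cfg$selection_value + 1L
    if (k > n) {
      warning("rank cutoff exceeds node count; selecting all nodes")
      k <- n
    }
    sel <- h$node[seq_len(k)]
  } else {
    seeds <- attr(heat, "seeds")
    if (cfg$include_query) {
      nonseed <- h$node[!h$node %in% seeds]
      k <- cfg$selection_value
      if (k > length(nonseed)) {
        warning("selection_value exceeds non-seed count; selecting all")
        k <- length(nonseed)
      }
      sel <- c(seeds, nonseed[seq_len(k)])
    } else {
      k <- cfg$selection_value
      if (k > n) {
        warning("selection_value exceeds node count; selecting all nodes")
        k <- n
      }
      sel <- h$node[seq_len(k)]
    }
  }
  # a tie straddles the boundary if the last selected node's heat recurs
  # just outside the selection
  tie <- FALSE
  if (length(sel) && length(sel) < n) {
    cut_heat <- min(h$heat[h$node %in% sel])
    outside <- h$heat[!h$node %in% sel]
    tie <- any(abs(outside - cut_heat) <= 1e-12)
  }
  ed <- network_edges(net)
  ed <- ed[ed$from %in% sel & ed$to %in% sel, , drop = FALSE]
  sub <- scored_network(ed, nodes = sel, provenance = net$provenance)
  list(network = sub, genes = sort(unique(sel)), tie_at_boundary = tie)
}
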