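# Independent brute-force oracles. These deliberately avoid the package's
# internals and its dependencies' set/graph algorithms: interval truth comes
# from per-base boolean arrays, betweenness from exhaustive simple-path
# enumeration, neighborhoods from direct adjacency scans.

# ---- per-base interval oracle (BED 0-based half-open) ----

oracle_masks <- function(bed, chrom_lengths) {
  masks <- lapply(chrom_lengths, function(len) logical(len))
  for (i in seq_len(nrow(bed))) {
    ch <- bed$chrom[i]
    masks[[ch]][(bed$start[i] + 1):bed$end[i]] <- TRUE
  }
  masks
}

oracle_bed <- function(masks) {
  out <- do.call(rbind, lapply(names(masks), function(ch) {
    r <- rle(masks[[ch]])
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    if (!any(r$values)) return(NULL)
    data.frame(chrom = ch, start = s[r$values], end = e[r$values],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_merge <- function(bed, chrom_lengths) {
  oracle_bed(oracle_masks(bed, chrom_lengths))
}

oracle_combine <- function(a, b, op, chrom_lengths) {
  ma <- oracle_masks(a, chrom_lengths)
  mb <- oracle_masks(b, chrom_lengths)
  oracle_bed(Map(op, ma, mb))
}

random_bed <- function(n, chrom_lengths, max_width = NULL) {
  chroms <- names(chrom_lengths)
  ch <- sample(chroms, n, replace = TRUE)
  len <- unname(chrom_lengths[ch])
  if (is.null(max_width)) max_width <- pmax(2, floor(len / 4))
  w <- pmax(1, floor(runif(n) * max_width))
  s <- floor(runif(n) * (len - w))
  data.frame(chrom = ch, start = s, end = s + w, stringsAsFactors = FALSE)
}

bed_equal <- function(a, b) {
  a <- as.data.frame(a)[, c("chrom", "start", "end")]
  b <- as.data.frame(b)[, c("chrom", "start", "end")]
  isTRUE(all.equal(a[order(a$chrom, a$start), ],
                   b[order(b$chrom, b$start), ],
                   check.attributes = FALSE))
}

# ---- exhaustive betweenness oracle ----

# adj: list of integer neighbor vectors, 1..n
oracle_betweenness <- function(adj) {
  n <- length(adj)
  btw <- numeric(n)
  all_paths <- function(s, t) {
    res <- list()
    rec <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1L]] <<- path
        return(invisible())
      }
      for (w in adj[[v]]) if (!(w %in% path)) rec(c(path, w))
    }
    rec(s)
    res
  }
  if (n < 2) return(btw)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, 1L)
      sp <- paths[lens == min(lens)]
      counts <- numeric(n)
      for (p in sp) {
        inner <- p[-c(1, length(p))]
        counts[inner] <- counts[inner] + 1
      }
      btw <- btw + counts / length(sp)
    }
  }
  btw
}

# ---- random scored networks ----

random_edges <- function(n, p, symbols = NULL) {
  if (is.null(symbols)) symbols <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(from = symbols[pairs[keep, 1]],
             to = symbols[pairs[keep, 2]],
             confidence = round(runif(sum(keep)), 3),
             stringsAsFactors = FALSE)
}

edges_to_adj <- function(edges, symbols) {
  n <- length(symbols)
  adj <- rep(list(integer()), n)
  for (i in seq_len(nrow(edges))) {
    a <- match(edges$from[i], symbols)
    b <- match(edges$to[i], symbols)
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

# dense Laplacian of a scored_network, unweighted, in node-name order
dense_laplacian <- function(net) {
  nodes <- igraph::V(net$graph)$name
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  ed <- network_edges(net)
  for (i in seq_len(nrow(ed))) {
    A[ed$from[i], ed$to[i]] <- 1
    A[ed$to[i], ed$from[i]] <- 1
  }
  diag(rowSums(A)) - A
}

star_network <- function(n_leaves = 4) {
  scored_network(data.frame(from = "HUB",
                            to = sprintf("L%d", seq_len(n_leaves)),
                            confidence = 1))
}
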