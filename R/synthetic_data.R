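#' Configuration for the synthetic CNV/network study generator
#'
#' Bundles every knob of the synthetic world in one validated object. The
#' defaults describe a small NDD-style cohort: 30 tested samples, a genome of
#' two 100-kb chromosomes tiled with 200 genes, three loss and three gain
#' calls per sample with a quarter of the gain calls planted on top of loss
#' intervals, and a 160-node scale-free-like interactome with two planted
#' hubs, two provincial hubs and two bottleneck nodes.
#'
#' @param seed Integer master seed. Each generator component (gene models,
#'   calls, network, scores, panel) derives its own fixed substream from it,
#'   so adding one component never perturbs another's output.
#' @param n_samples Number of samples in the CNV call set.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#'   Kept small (<= 5 Mb enforced) so the per-base ground-truth oracle in
#'   [gen_cnv_callset()] stays exact and cheap.
#' @param n_genes Number of gene models to tile over the chromosomes.
#' @param calls_per_sample Number of CNV calls *per type* (loss and gain)
#'   emitted for each sample.
#' @param loss_gain_overlap_frac Fraction in \[0,1\] of gain calls planted as
#'   exact copies of loss intervals, controlling the size of the shared
#'   (both-loss-and-gain) region set.
#' @param network_n_nodes Number of nodes in the synthetic interactome; must
#'   not exceed `n_genes` (node names are gene symbols).
#' @param network_attach_m Preferential-attachment edges per new node.
#' @param n_planted_hubs,n_planted_provincial,n_planted_bottlenecks Counts of
#'   planted topological roles (see [gen_network()]).
#' @param confidence_beta_params Length-2 positive vector of Beta shape
#'   parameters for edge confidences. The default Beta(4,2) puts roughly a
#'   third of edges below the 0.63 medium-confidence cutoff, so the filter
#'   removes a nontrivial minority.
#'
#' @return An object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' cfg$n_samples
synthetic_config <- function(seed = 1L,
                             n_samples = 30L,
                             chrom_lengths = c(chrA = 100000, chrB = 100000),
                             n_genes = 200L,
                             calls_per_sample = 3L,
                             loss_gain_overlap_frac = 0.25,
                             network_n_nodes = 160L,
                             network_attach_m = 2L,
                             n_planted_hubs = 2L,
                             n_planted_provincial = 2L,
                             n_planted_bottlenecks = 2L,
                             confidence_beta_params = c(4, 2)) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  counts <- c(n_samples = n_samples, n_genes = n_genes,
              calls_per_sample = calls_per_sample,
              network_n_nodes = network_n_nodes,
              network_attach_m = network_attach_m,
              n_planted_hubs = n_planted_hubs,
              n_planted_provincial = n_planted_provincial,
              n_planted_bottlenecks = n_planted_bottlenecks)
  if (any(counts < 0)) {
    stop("all counts must be >= 0; offending: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  if (loss_gain_overlap_frac < 0 || loss_gain_overlap_frac > 1) {
    stop("loss_gain_overlap_frac must lie in [0, 1]")
  }
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector")
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (any(chrom_lengths > 5e6)) {
    stop("chromosome lengths must be <= 5e6 bp so the per-base ",
         "ground-truth oracle stays exact")
  }
  if (length(confidence_beta_params) != 2L || any(confidence_beta_params <= 0)) {
    stop("confidence_beta_params must be two positive shape parameters")
  }
  structure(list(
    seed = as.integer(seed),
    n_samples = as.integer(n_samples),
    chrom_lengths = chrom_lengths,
    n_genes = as.integer(n_genes),
    calls_per_sample = as.integer(calls_per_sample),
    loss_gain_overlap_frac = loss_gain_overlap_frac,
    network_n_nodes = as.integer(network_n_nodes),
    network_attach_m = as.integer(network_attach_m),
    n_planted_hubs = as.integer(n_planted_hubs),
    n_planted_provincial = as.integer(n_planted_provincial),
    n_planted_bottlenecks = as.integer(n_planted_bottlenecks),
    confidence_beta_params = confidence_beta_params
  ), class = "synthetic_config")
}

# fixed per-component substreams derived from the master seed
.substream <- function(seed, component) {
  offsets <- c(genes = 101L, calls = 211L, network = 307L,
               scores = 401L, panel = 503L)
  if (!component %in% names(offsets)) stop("unknown substream: ", component)
  (as.integer(seed) + offsets[[component]]) %% .Machine$integer.max
}

#' Generate non-overlapping synthetic gene models
#'
#' Tiles `cfg$n_genes` disjoint gene intervals over the configured
#' chromosomes. Each chromosome receives a share of genes proportional to its
#' length; each gene occupies a random sub-interval of its own slot, which
#' guarantees disjointness by construction. Coordinates are 0-based half-open
#' (BED convention).
#'
#' @param cfg A [synthetic_config()].
#' @return A data.frame with columns `chrom`, `start`, `end`, `symbol`,
#'   `gene_type` (`protein_coding` or `lncRNA`), sorted by position.
#' @export
#' @examples
#' gm <- gen_gene_models(synthetic_config(seed = 1, n_genes = 10))
#' nrow(gm)
gen_gene_models <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      symbol = character(), gene_type = character(),
                      stringsAsFactors = FALSE)
  if (cfg$n_genes == 0L) return(empty)
  set.seed(.substream(cfg$seed, "genes"))
  lens <- cfg$chrom_lengths
  # proportional allocation, remainders to the longest chromosomes
  share <- lens / sum(lens) * cfg$n_genes
  n_per <- floor(share)
  rem <- cfg$n_genes - sum(n_per)
  if (rem > 0) {
    idx <- order(share - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[idx] <- n_per[idx] + 1
  }
  out <- lapply(seq_along(lens), function(i) {
    n_c <- n_per[i]
    if (n_c == 0) return(NULL)
    slot <- floor(lens[i] / n_c)
    if (slot < 200) {
      stop("chromosome ", names(lens)[i], " too short to host ", n_c,
           " genes (need >= 200 bp per gene slot)")
    }
    # gene occupies a random window inside its slot, leaving >= 1 bp margin
    width <- pmax(100, floor(runif(n_c, 0.2, 0.8) * (slot - 2)))
    offset <- floor(runif(n_c, 0, 1) * (slot - width - 1))
    start <- (seq_len(n_c) - 1) * slot + offset
    data.frame(chrom = names(lens)[i], start = start, end = start + width,
               stringsAsFactors = FALSE)
  })
  gm <- do.call(rbind, out)
  gm <- gm[order(gm$chrom, gm$start), , drop = FALSE]
  gm$symbol <- sprintf("G%04d", seq_len(nrow(gm)))
  gm$gene_type <- sample(c("protein_coding", "lncRNA"), nrow(gm),
                         replace = TRUE, prob = c(0.8, 0.2))
  rownames(gm) <- NULL
  gm
}

# per-base membership oracle: logical vector per chromosome, then run-length
# extraction back to 0-based half-open intervals. Independent of the
# GenomicRanges-backed interval algebra in cnv_intervals.R.
.per_base_mask <- function(df, chrom_lengths) {
  masks <- lapply(chrom_lengths, function(len) logical(len))
  if (nrow(df)) {
    for (i in seq_len(nrow(df))) {
      ch <- df$chrom[i]
      s <- df$start[i] + 1L  # 1-based index into the mask
      e <- df$end[i]
      masks[[ch]][s:e] <- TRUE
    }
  }
  masks
}

.mask_to_bed <- function(masks) {
  out <- lapply(names(masks), function(ch) {
    r <- rle(masks[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Generate a synthetic CNV call set with per-base ground truth
#'
#' Each sample emits `calls_per_sample` loss calls and the same number of
#' gain calls. Loss calls are drawn in the first 45% of each chromosome and
#' non-planted gain calls in the last 45%, so with
#' `loss_gain_overlap_frac = 0` the shared (both-type) region set is empty by
#' construction. A fraction `loss_gain_overlap_frac` of gain calls are exact
#' copies of distinct loss intervals, so at fraction 1 the unique loss and
#' unique gain sets are both empty.
#'
#' The returned ground truth (`unique_loss`, `unique_gain`, `shared`) is
#' computed here by an independent per-base boolean oracle over the whole
#' chromosome, not by the interval algebra of [merge_same_type()] and
#' friends, so downstream set operations can be validated against it.
#'
#' @param cfg A [synthetic_config()] with `calls_per_sample >= 1`.
#' @return A list with `calls` (data.frame: `chrom`, `start`, `end`,
#'   `cnv_type`, `sample_id`) and `truth` (list of three BED-style
#'   data.frames: `unique_loss`, `unique_gain`, `shared`).
#' @export
#' @examples
#' sim <- gen_cnv_callset(synthetic_config(seed = 7, n_samples = 2))
#' head(sim$calls)
gen_cnv_callset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$calls_per_sample < 1L) stop("calls_per_sample must be >= 1")
  set.seed(.substream(cfg$seed, "calls"))
  lens <- cfg$chrom_lengths
  chroms <- names(lens)
  n_each <- cfg$n_samples * cfg$calls_per_sample

  draw_interval <- function(lo_frac, hi_frac) {
    ch <- sample(chroms, 1L, prob = lens)
    len <- lens[[ch]]
    lo <- floor(len * lo_frac)
    hi <- floor(len * hi_frac)
    w <- max(50L, floor(runif(1, 0.002, 0.05) * (hi - lo)))
    s <- lo + floor(runif(1) * (hi - lo - w))
    c(chrom = ch, start = s, end = s + w)
  }

  mk <- function(n, lo, hi) {
    rows <- t(vapply(seq_len(n), function(i) draw_interval(lo, hi),
                     c(chrom = "", start = "", end = "")))
    data.frame(chrom = rows[, "chrom"],
               start = as.numeric(rows[, "start"]),
               end = as.numeric(rows[, "end"]),
               stringsAsFactors = FALSE)
  }

  loss <- mk(n_each, 0.00, 0.45)
  n_planted <- round(cfg$loss_gain_overlap_frac * n_each)
  planted_idx <- if (n_planted > 0) sample(n_each, n_planted) else integer()
  gain_free <- if (n_each - n_planted > 0) {
    mk(n_each - n_planted, 0.55, 1.00)
  } else loss[0, ]
  gain <- rbind(loss[planted_idx, , drop = FALSE], gain_free)
  gain <- gain[sample(nrow(gain)), , drop = FALSE]

  sample_ids <- sprintf("S%03d", rep(seq_len(cfg$n_samples),
                                     each = cfg$calls_per_sample))
  calls <- rbind(
    cbind(loss, cnv_type = "loss", sample_id = sample_ids),
    cbind(gain, cnv_type = "gain", sample_id = sample_ids)
  )
  rownames(calls) <- NULL

  loss_mask <- .per_base_mask(calls[calls$cnv_type == "loss", ], lens)
  gain_mask <- .per_base_mask(calls[calls$cnv_type == "gain", ], lens)
  and_mask <- Map(`&`, loss_mask, gain_mask)
  truth <- list(
    unique_loss = .mask_to_bed(Map(function(l, g) l & !g, loss_mask, gain_mask)),
    unique_gain = .mask_to_bed(Map(function(l, g) g & !l, loss_mask, gain_mask)),
    shared = .mask_to_bed(and_mask)
  )
  list(calls = calls, truth = truth)
}

#' Generate a scored network with planted topological roles
#'
#' Builds two preferential-attachment communities over the non-bottleneck
#' nodes, joined only through the planted bottleneck nodes. Each bottleneck
#' attaches by two edges per community, preferentially to the
#' highest-degree community cores, so inter-community traffic funnels
#' through it while its own degree stays low. Planted hubs then receive
#' extra edges to ~8% of nodes across the whole graph; planted provincial
#' hubs receive extra edges to ~30% of their own community only. Edge
#' confidences are drawn from the configured Beta distribution; node names
#' are gene symbols from [gen_gene_models()].
#'
#' When hubs are planted their long-range edges may also join the two
#' communities; the removing-a-bottleneck-disconnects property holds for
#' configurations with a single bottleneck and no planted hubs.
#'
#' @param cfg A [synthetic_config()] with
#'   `network_n_nodes > network_attach_m >= 1` and
#'   `network_n_nodes <= n_genes`.
#' @return A list with `network` (a [scored_network()]) and `roles`
#'   (data.frame: `node`, `role` in hub / provincial_hub / bottleneck /
#'   backbone).
#' @export
#' @examples
#' net <- gen_network(synthetic_config(seed = 1))
#' table(net$roles$role)
gen_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$network_n_nodes
  m <- cfg$network_attach_m
  if (!(n > m && m >= 1)) stop("need network_n_nodes > network_attach_m >= 1")
  n_roles <- cfg$n_planted_hubs + cfg$n_planted_provincial +
    cfg$n_planted_bottlenecks
  if (n_roles > n) stop("more planted roles (", n_roles,
                        ") than nodes (", n, ")")
  if (n > cfg$n_genes) stop("network_n_nodes exceeds n_genes; node names ",
                            "are drawn from the gene models")
  n_back <- n - cfg$n_planted_bottlenecks
  n1 <- ceiling(n_back / 2)
  n2 <- n_back - n1
  if (min(n1, n2) <= m && cfg$n_planted_bottlenecks > 0) {
    stop("communities too small for attach m; increase network_n_nodes")
  }
  symbols <- gen_gene_models(cfg)$symbol
  set.seed(.substream(cfg$seed, "network"))
  nodes <- sample(symbols, n)

  pa_edges <- function(nn, offset) {
    g <- igraph::sample_pa(nn, m = m, directed = FALSE)
    e <- igraph::as_edgelist(g, names = FALSE)
    e + offset
  }
  e1 <- pa_edges(n1, 0L)
  e2 <- pa_edges(n2, n1)
  edges <- rbind(e1, e2)

  comm <- c(rep(1L, n1), rep(2L, n2))
  back_deg <- tabulate(c(edges), nbins = n)
  bneck <- if (cfg$n_planted_bottlenecks > 0) {
    n_back + seq_len(cfg$n_planted_bottlenecks)
  } else integer()
  for (b in bneck) {
    for (cm in 1:2) {
      own <- which(comm == cm)
      # attach to the community cores: funnels cross-community shortest
      # paths through the bottleneck while keeping its degree low
      k <- min(2L, length(own))
      targets <- own[order(-back_deg[own])][seq_len(k)]
      edges <- rbind(edges, cbind(b, targets))
    }
  }
  # hubs and provincial hubs drawn from community nodes, disjointly
  pool <- sample(seq_len(n_back))
  hubs <- head(pool, cfg$n_planted_hubs)
  prov <- head(setdiff(pool, hubs), cfg$n_planted_provincial)
  for (h in hubs) {
    k <- max(1L, round(0.08 * n))
    targets <- sample(setdiff(seq_len(n_back), h), min(k, n_back - 1L))
    edges <- rbind(edges, cbind(h, targets))
  }
  for (p in prov) {
    own <- which(comm == comm[p])
    k <- max(1L, round(0.30 * length(own)))
    targets <- sample(setdiff(own, p), min(k, length(own) - 1L))
    edges <- rbind(edges, cbind(p, targets))
  }

  df <- data.frame(from = nodes[edges[, 1]], to = nodes[edges[, 2]],
                   confidence = rbeta(nrow(edges),
                                      cfg$confidence_beta_params[1],
                                      cfg$confidence_beta_params[2]),
                   stringsAsFactors = FALSE)
  net <- scored_network(df, provenance = "synthetic")
  role <- rep("backbone", n)
  role[hubs] <- "hub"
  role[prov] <- "provincial_hub"
  role[bneck] <- "bottleneck"
  roles <- data.frame(node = nodes, role = role, stringsAsFactors = FALSE)
  roles <- roles[order(roles$node), , drop = FALSE]
  rownames(roles) <- NULL
  list(network = net, roles = roles)
}

#' Generate a synthetic per-gene dosage-score table
#'
#' One row per gene with the five constraint/dosage scores used for
#' candidate flagging: pLI, LOEUF, sHet, pHaplo and pTriplo. Probabilities
#' (pLI, pHaplo, pTriplo) are Beta draws, inherently in \[0,1\]; LOEUF and
#' sHet are positive log-normal draws on their conventional scales.
#'
#' @param genes Character vector of gene symbols.
#' @param seed Integer seed.
#' @return A data.frame with columns `symbol`, `pLI`, `LOEUF`, `sHet`,
#'   `pHaplo`, `pTriplo`.
#' @export
#' @examples
#' gen_dosage_table(c("G0001", "G0002"), seed = 1)
gen_dosage_table <- function(genes, seed = 1L) {
  genes <- as.character(genes)
  set.seed(.substream(seed, "scores"))
  n <- length(genes)
  data.frame(
    symbol = genes,
    pLI = rbeta(n, 0.4, 0.6),
    LOEUF = rlnorm(n, meanlog = log(0.8), sdlog = 0.5),
    sHet = rlnorm(n, meanlog = log(0.05), sdlog = 1),
    pHaplo = rbeta(n, 1.2, 1.2),
    pTriplo = rbeta(n, 1.2, 1.2),
    stringsAsFactors = FALSE
  )
}

#' Sample a synthetic NDD panel gene list
#'
#' Draws `n_panel` symbols from the supplied gene universe, emulating a
#' curated disease-gene panel used to steer diffusion seeds and candidate
#' overlap counts.
#'
#' @param genes Character vector of available gene symbols.
#' @param n_panel Panel size (capped at `length(genes)`).
#' @param seed Integer seed.
#' @return Sorted character vector of panel symbols.
#' @export
gen_ndd_panel <- function(genes, n_panel = 40L, seed = 1L) {
  set.seed(.substream(seed, "panel"))
  sort(sample(as.character(genes), min(n_panel, length(genes))))
}

#' Write a synthetic data set to plain-text files
#'
#' Writes the CNV calls and gene models as BED, the network as a three-column
#' TSV edge list, the dosage table as TSV, the NDD panel as one symbol per
#' line, and the interval ground truth as JSON.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_dataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- gen_cnv_callset(cfg)
  gm <- gen_gene_models(cfg)
  net <- gen_network(cfg)
  dosage <- gen_dosage_table(gm$symbol, seed = cfg$seed)
  panel <- gen_ndd_panel(gm$symbol, seed = cfg$seed)

  paths <- c(
    calls = file.path(dir, "cnv_calls.bed"),
    genes = file.path(dir, "gene_models.bed"),
    edges = file.path(dir, "network_edges.tsv"),
    dosage = file.path(dir, "dosage_scores.tsv"),
    panel = file.path(dir, "ndd_panel.txt"),
    truth = file.path(dir, "interval_truth.json"),
    roles = file.path(dir, "planted_roles.tsv")
  )
  write.table(sim$calls[, c("chrom", "start", "end", "cnv_type", "sample_id")],
              paths[["calls"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(gm[, c("chrom", "start", "end", "symbol", "gene_type")],
              paths[["genes"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(network_edges(net$network), paths[["edges"]], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(dosage, paths[["dosage"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(panel, paths[["panel"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], digits = NA,
                       dataframe = "columns")
  write.table(net$roles, paths[["roles"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
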