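test_that("network construction dedups, drops self-loops, normalizes case", {
  net <- scored_network(data.frame(
    from = c("a", "B", "A", "c", "c"),
    to = c("b", "a", "B", "c", "d"),
    confidence = c(0.5, 0.9, 0.7, 1, 0.2)
  ))
  ed <- network_edges(net)
  expect_equal(nrow(ed), 2)  # A-B collapsed, C-C dropped
  expect_equal(ed$confidence[ed$from == "A" & ed$to == "B"], 0.9)
  expect_setequal(network_nodes(net), c("A", "B", "C", "D"))
  expect_error(scored_network(data.frame(from = "A", to = "B",
                                         confidence = 1.2)),
               "\\[0, 1\\]")
})

test_that("edge-list reader handles dialects, duplicates and bad rows", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "simple.tsv")
  writeLines(c("A\tB\t0.5", "B\tA\t0.9", "B\tC\t0.7"), p)
  net <- read_edge_list(p, "simple_tsv")
  ed <- network_edges(net)
  expect_equal(nrow(ed), 2)
  expect_equal(ed$confidence[ed$from == "A"], 0.9)

  writeLines(c("A\tB\t1.2"), p)
  expect_error(read_edge_list(p, "simple_tsv"), "line 1")
  writeLines(c("A\tB\t0.5", "AB"), p)
  expect_error(read_edge_list(p, "simple_tsv"), "line 2")
  writeLines(character(), p)
  expect_warning(empty <- read_edge_list(p, "simple_tsv"), "empty")
  expect_length(network_nodes(empty), 0)

  ph <- file.path(dir, "hippie.tsv")
  writeLines(c("AL1A1_HUMAN\t216\tAL1A1_HUMAN\t216\t0.76\tsrc",
               "ITA7_HUMAN\t3679\tACHA_HUMAN\t1134\t0.73\tsrc",
               "NEB1_HUMAN\t55607\tACTG_HUMAN\t71\t0.65\tsrc"), ph)
  hip <- read_edge_list(ph, "hippie")
  expect_setequal(network_nodes(hip), c("ITA7", "ACHA", "NEB1", "ACTG"))
  expect_equal(igraph::ecount(hip$graph), 2)  # self-loop dropped

  ps <- file.path(dir, "net.sif")
  writeLines(c("A\tpp\tB", "B\tpp\tC"), ps)
  sif <- read_edge_list(ps, "sif")
  expect_equal(network_edges(sif)$confidence, c(1, 1))
})

test_that("confidence filter keeps >= threshold and drops isolated nodes", {
  net <- scored_network(data.frame(from = c("A", "B", "C"),
                                   to = c("B", "C", "D"),
                                   confidence = c(0.9, 0.63, 0.3)))
  f <- filter_confidence(net, 0.63)
  expect_setequal(network_nodes(f), c("A", "B", "C"))  # D isolated, dropped
  expect_equal(nrow(network_edges(f)), 2)  # boundary 0.63 retained

  expect_equal(network_edges(filter_confidence(net, 0)),
               network_edges(net))
  expect_length(network_nodes(filter_confidence(net, 1)), 0)
  expect_error(filter_confidence(net, 1.5), "\\[0, 1\\]")
})

test_that("raising the confidence threshold is monotone", {
  set.seed(8)
  net <- scored_network(random_edges(20, 0.3))
  prev_nodes <- network_nodes(net)
  prev_edges <- nrow(network_edges(net))
  for (th in c(0.2, 0.4, 0.6, 0.8)) {
    f <- filter_confidence(net, th)
    expect_true(all(network_nodes(f) %in% prev_nodes))
    expect_lte(nrow(network_edges(f)), prev_edges)
    prev_nodes <- network_nodes(f)
    prev_edges <- nrow(network_edges(f))
  }
})

test_that("first-neighbor extraction returns the induced neighborhood", {
  star <- star_network(4)
  whole <- first_neighbor_subnetwork(star, "HUB")
  expect_setequal(network_nodes(whole), network_nodes(star))
  expect_equal(nrow(network_edges(whole)), 4)

  leaf <- first_neighbor_subnetwork(star, "L1")
  expect_setequal(network_nodes(leaf), c("L1", "HUB"))
  expect_equal(nrow(network_edges(leaf)), 1)

  miss <- first_neighbor_subnetwork(star, c("L1", "NOPE"))
  expect_equal(miss$missing_query, "NOPE")
})

test_that("first-neighbor node set equals a brute-force adjacency union", {
  set.seed(13)
  edges <- random_edges(50, 0.08)
  net <- scored_network(edges)
  query <- sample(network_nodes(net), 5)
  sub <- first_neighbor_subnetwork(net, query)
  brute_nodes <- sort(unique(c(
    query,
    edges$from[edges$to %in% query], edges$to[edges$from %in% query]
  )))
  expect_equal(network_nodes(sub), brute_nodes)
  # induced edges: all-pairs membership scan over the original edge table
  keep <- edges$from %in% brute_nodes & edges$to %in% brute_nodes
  expect_equal(nrow(network_edges(sub)), sum(keep))
  # incident mode only keeps query-touching edges
  inc <- first_neighbor_subnetwork(net, query, edges = "incident")
  expect_equal(nrow(network_edges(inc)),
               sum(edges$from %in% query | edges$to %in% query))
  # repeated with a query covering the whole ball: identity
  again <- first_neighbor_subnetwork(sub, network_nodes(sub))
  expect_equal(network_edges(again), network_edges(sub))
})

test_that("network merge follows inclusion-exclusion and is idempotent", {
  a <- scored_network(data.frame(from = c("A", "B"), to = c("B", "C"),
                                 confidence = 0.8))
  b <- scored_network(data.frame(from = c("X", "Y"), to = c("Y", "Z"),
                                 confidence = 0.9), nodes = "W")
  expect_length(network_nodes(merge_networks(a, b)), 7)
  expect_equal(network_edges(merge_networks(a, a)), network_edges(a))

  set.seed(31)
  n1 <- scored_network(random_edges(30, 0.15))
  n2 <- scored_network(random_edges(30, 0.15,
                                    symbols = sprintf("N%02d", 16:45)))
  m <- merge_networks(n1, n2)
  expect_length(network_nodes(m),
                length(union(network_nodes(n1), network_nodes(n2))))
  # commutative on node and edge sets; duplicate pair keeps max confidence
  m2 <- merge_networks(n2, n1)
  expect_equal(network_edges(m), network_edges(m2))
  shared_pairs <- merge(network_edges(n1), network_edges(n2),
                        by = c("from", "to"))
  if (nrow(shared_pairs)) {
    got <- merge(network_edges(m), shared_pairs, by = c("from", "to"))
    expect_equal(got$confidence,
                 pmax(shared_pairs$confidence.x, shared_pairs$confidence.y))
  }
})

test_that("degree-class report matches direct adjacency counts", {
  empty <- scored_network(data.frame(from = character(), to = character(),
                                     confidence = numeric()))
  rep0 <- component_report(empty, c("A", "B"))
  expect_true(all(rep0$degree == 0))
  expect_true(all(rep0$degree_class == "0"))

  star <- star_network(6)
  expect_equal(component_report(star, "HUB")$degree, 6)
  expect_equal(component_report(star, "HUB")$degree_class, ">=3")

  set.seed(17)
  edges <- random_edges(25, 0.1)
  net <- scored_network(edges)
  query <- network_nodes(net)
  rep <- component_report(net, query)
  brute <- vapply(query, function(q) {
    sum(edges$from == q) + sum(edges$to == q)
  }, numeric(1))
  expect_equal(setNames(rep$degree, rep$symbol), setNames(as.integer(brute), query))
})
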