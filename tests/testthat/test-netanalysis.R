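test_that("betweenness matches hand counts on canonical small graphs", {
  p <- centrality_profile(network_from_edges(path_graph()), normalized = FALSE)
  expect_equal(p$betweenness[p$node == "B"], 1)
  expect_equal(p$betweenness[p$node %in% c("A", "C")], c(0, 0))
  expect_equal(p$closeness[p$node == "B"], 1)

  star <- centrality_profile(network_from_edges(star_graph(5)))
  expect_equal(star$betweenness[star$node == "hub"], 10)  # C(5,2)
  expect_equal(star$betweenness_norm[star$node == "hub"], 1)
  expect_true(all(star$betweenness[star$node != "hub"] == 0))

  tri <- centrality_profile(network_from_edges(complete_graph(c("a", "b", "c"))))
  expect_equal(tri$betweenness, c(0, 0, 0))

  k4 <- centrality_profile(network_from_edges(complete_graph(letters[1:4])))
  expect_equal(k4$closeness, rep(1, 4))

  iso <- centrality_profile(network_from_edges(path_graph(), nodes = "zzz"))
  expect_equal(iso$closeness[iso$node == "zzz"], 0)
  expect_equal(iso$degree[iso$node == "zzz"], 0)
})

test_that("betweenness equals Floyd-Warshall path-counting on random graphs", {
  # 100 unit-distance + 100 random-positive-distance seeded graphs, n <= 12
  mism_unit <- 0
  mism_wt <- 0
  for (i in 1:100) {
    n <- 4 + (i %% 9)
    ed <- random_graph(n, p = 0.45, seed = 1000 + i, weights = "unit")
    if (nrow(ed) == 0) next
    net <- network_from_edges(ed)
    got <- centrality_profile(net, normalized = FALSE)
    want <- oracle_betweenness(got$node, ed)
    if (!isTRUE(all.equal(got$betweenness, unname(want[got$node]),
                          tolerance = 1e-12))) {
      mism_unit <- mism_unit + 1
    }
  }
  for (i in 1:100) {
    n <- 4 + (i %% 9)
    ed <- random_graph(n, p = 0.45, seed = 2000 + i, weights = "random")
    if (nrow(ed) == 0) next
    net <- network_from_edges(ed)
    got <- centrality_profile(net, normalized = FALSE)
    want <- oracle_betweenness(got$node, ed)
    if (max(abs(got$betweenness - unname(want[got$node]))) > 1e-9) {
      mism_wt <- mism_wt + 1
    }
  }
  expect_equal(mism_unit, 0)
  expect_equal(mism_wt, 0)
})

test_that("betweenness agrees with an independent library implementation", {
  ed <- random_graph(10, p = 0.5, seed = 77, weights = "random")
  got <- centrality_profile(network_from_edges(ed), normalized = FALSE)
  ig <- igraph::graph_from_data_frame(ed, directed = FALSE)
  ref <- igraph::betweenness(ig, weights = igraph::E(ig)$distance,
                             normalized = FALSE)
  expect_equal(got$betweenness[match(names(ref), got$node)], unname(ref),
               tolerance = 1e-9)
})

test_that("hub detection uses the collapsed-degree threshold", {
  h <- hubs(network_from_edges(star_graph(5)), min_degree = 4)
  expect_equal(h$node, "hub")
  cyc <- tibble::tibble(u = letters[1:6], v = letters[c(2:6, 1)])
  expect_equal(nrow(hubs(network_from_edges(cyc), min_degree = 4)), 0)
  dd <- attr(h, "degree_distribution")
  expect_equal(sum(dd$count), 6)
  # hub set is invariant under node relabeling
  s <- make_toy_protein(18, 3, seed = 6)
  net <- build_rin(s)
  h1 <- hubs(net)
  perm <- withr::with_seed(1, sample(nrow(net$nodes)))
  relab <- setNames(sprintf("x%02d", order(perm)), net$nodes$id)
  net2 <- net
  net2$nodes$id <- unname(relab[net2$nodes$id])
  net2$edges$u <- unname(relab[net2$edges$u])
  net2$edges$v <- unname(relab[net2$edges$v])
  net2$distances <- NULL
  h2 <- hubs(net2)
  expect_setequal(unname(relab[h1$node]), h2$node)
})

test_that("k-clique enumeration matches exhaustive subset search", {
  tri <- network_from_edges(complete_graph(c("a", "b", "c")))
  expect_length(enumerate_k_cliques(tri, 3), 1)
  k4 <- network_from_edges(complete_graph(letters[1:4]))
  expect_length(enumerate_k_cliques(k4, 3), 4)
  expect_length(enumerate_k_cliques(k4, 4), 1)
  tree <- network_from_edges(path_graph(letters[1:6]))
  expect_length(enumerate_k_cliques(tree, 3), 0)
  for (i in 1:30) {
    n <- 6 + (i %% 7)
    ed <- random_graph(n, p = 0.5, seed = 300 + i)
    if (nrow(ed) == 0) next
    net <- network_from_edges(ed)
    nodes <- net$nodes$id
    for (k in 3:5) {
      expect_identical(enumerate_k_cliques(net, k),
                       oracle_k_cliques(nodes, ed, k))
    }
  }
  expect_error(enumerate_k_cliques(k4, 2), "k must be")
})

test_that("clique-percolation communities match brute force", {
  # two triangles sharing an edge -> one community of 4 nodes
  ed <- tibble::tibble(u = c("a", "a", "b", "b", "c"),
                       v = c("b", "c", "c", "d", "d"))
  cs <- cpm_communities(network_from_edges(ed), 3)
  expect_length(cs$communities, 1)
  expect_equal(cs$communities[[1]], c("a", "b", "c", "d"))
  # two disjoint triangles -> two communities
  ed2 <- dplyr::bind_rows(complete_graph(c("a", "b", "c")),
                          complete_graph(c("x", "y", "z")))
  expect_length(cpm_communities(network_from_edges(ed2), 3)$communities, 2)
  # K5 at k=5 -> a single 5-node community
  k5 <- cpm_communities(network_from_edges(complete_graph(letters[1:5])), 5)
  expect_length(k5$communities, 1)
  expect_equal(k5$communities[[1]], letters[1:5])
  # no k-cliques -> empty set
  expect_length(cpm_communities(network_from_edges(path_graph()), 3)$communities, 0)
})

test_that("clique-percolation equals brute force on 100 random graphs up to n = 15", {
  mismatches <- 0
  for (i in 1:100) {
    n <- 6 + (i %% 10)
    ed <- random_graph(n, p = 0.5, seed = 400 + i)
    if (nrow(ed) == 0) next
    net <- network_from_edges(ed)
    nodes <- net$nodes$id
    for (k in 3:5) {
      got <- cpm_communities(net, k)$communities
      want <- oracle_cpm(nodes, ed, k)
      if (!identical(got, want)) mismatches <- mismatches + 1
    }
  }
  expect_equal(mismatches, 0)
})

test_that("MCODE stages reproduce hand-run results deterministically", {
  # K5 plus a pendant node: the pendant scores below threshold and the
  # haircut leaves the K5 intact
  k5p <- dplyr::bind_rows(complete_graph(letters[1:5]),
                          tibble::tibble(u = "a", v = "p", distance = 1))
  cl <- mcode_clusters(network_from_edges(k5p))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$nodes[[1]], letters[1:5])
  # edgeless graph: nothing to cluster
  empty <- network_from_edges(tibble::tibble(u = character(0),
                                             v = character(0)),
                              nodes = letters[1:4])
  expect_equal(nrow(mcode_clusters(empty)), 0)
  # two disjoint K4s -> two clusters
  two_k4 <- dplyr::bind_rows(complete_graph(c("a", "b", "c", "d")),
                             complete_graph(c("w", "x", "y", "z")))
  cl2 <- mcode_clusters(network_from_edges(two_k4))
  expect_equal(nrow(cl2), 2)
  expect_equal(sort(unlist(cl2$nodes)), sort(c(letters[1:4], c("w", "x", "y", "z"))))
  # two K4s joined by one edge: every node scores 3 (core number x core
  # density of its closed neighbourhood), so expansion crosses the bridge
  # and a hand-run of the stages yields ONE cluster of all 8 nodes
  bridged <- dplyr::bind_rows(two_k4,
                              tibble::tibble(u = "d", v = "w", distance = 1))
  cl3 <- mcode_clusters(network_from_edges(bridged))
  expect_equal(nrow(cl3), 1)
  expect_equal(cl3$n_nodes, 8)
  # determinism
  expect_identical(cl3, mcode_clusters(network_from_edges(bridged)))
})

test_that("betweenness histograms conserve counts and normalize correctly", {
  prof <- centrality_profile(network_from_edges(star_graph(5)))
  h <- betweenness_histogram(prof, bin_width = 0.01)
  expect_equal(sum(h$count), 6)
  # the center's normalized value 1.0 lands in the last bin
  expect_equal(h$count[nrow(h)], 1)
  expect_equal(h$count[1], 5)
  zero <- centrality_profile(
    network_from_edges(complete_graph(c("a", "b", "c"))))
  hz <- betweenness_histogram(zero, bin_width = 0.01)
  expect_equal(hz$count[1], 3)
  expect_equal(sum(hz$count), 3)
  ed <- random_graph(10, 0.4, seed = 5)
  hp <- betweenness_histogram(centrality_profile(network_from_edges(ed)))
  expect_equal(sum(hp$count), 10)
})

test_that("self-comparison gives zero deltas and constructed deltas register", {
  s <- make_toy_protein(16, 3, seed = 9)
  net <- build_rin(s)
  self <- compare_networks(net, net)
  expect_true(all(self$delta_betweenness$delta == 0))
  expect_equal(
    self$clique_totals$total[self$clique_totals$network == "a"],
    self$clique_totals$total[self$clique_totals$network == "b"])

  # netB = netA plus one disjoint triangle: +1 clique at k = 3
  edges_b <- dplyr::bind_rows(
    net$edges,
    tibble::tibble(u = c("T:1", "T:1", "T:2"), v = c("T:2", "T:3", "T:3"),
                   etype = "cnt", subtype = "all-all", weight = 1))
  net_b <- network_from_edges(edges_b, nodes = c(net$nodes$id,
                                                 paste0("T:", 1:3)))
  diff <- compare_networks(net, net_b)
  c3 <- tidyr::pivot_wider(diff$clique_counts, names_from = "network",
                           values_from = "count")
  expect_equal(c3$b[c3$k == 3] - c3$a[c3$k == 3], 1)
})

test_that("differential reports round-trip through JSON", {
  s1 <- make_toy_protein(14, 3, seed = 1)
  s2 <- make_toy_protein(14, 3, seed = 2)
  d <- compare_networks(build_rin(s1), build_rin(s2))
  f <- withr::local_tempfile(fileext = ".json")
  write_diff_report(d, f)
  d2 <- read_diff_report(f)
  expect_equal(as.data.frame(d2$delta_betweenness),
               as.data.frame(d$delta_betweenness))
  expect_equal(as.data.frame(d2$clique_counts),
               as.data.frame(d$clique_counts))
  expect_equal(as.data.frame(d2$communities),
               as.data.frame(d$communities))
})

test_that("graph statistics are invariant under node relabeling", {
  ed <- random_graph(10, 0.5, seed = 12, weights = "random")
  net <- network_from_edges(ed)
  prof <- centrality_profile(net, normalized = FALSE)
  relab <- setNames(sprintf("m%02d", seq_len(10)), sort(net$nodes$id))
  ed2 <- tibble::tibble(u = unname(relab[ed$u]), v = unname(relab[ed$v]),
                        distance = ed$distance)
  prof2 <- centrality_profile(network_from_edges(ed2), normalized = FALSE)
  expect_equal(prof2$betweenness[match(unname(relab[prof$node]), prof2$node)],
               prof$betweenness, tolerance = 1e-12)
  cs <- cpm_communities(net, 3)$communities
  cs2 <- cpm_communities(network_from_edges(ed2), 3)$communities
  relabelled <- lapply(cs, function(cm) sort(unname(relab[cm])))
  relabelled <- relabelled[order(vapply(relabelled, paste, character(1),
                                        collapse = "|"))]
  expect_identical(cs2, relabelled)
})
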