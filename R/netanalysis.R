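#' Build a network directly from an edge table
#'
#' Convenience constructor for graph-statistics functions: takes a collapsed
#' simple edge list (columns `u`, `v`, optional `weight`, optional
#' `distance`) and an optional node list (to carry isolated nodes).
#'
#' @param edges Data frame with columns `u`, `v` and optionally `weight`,
#'   `distance`.
#' @param nodes Optional character vector of node ids.
#' @return A `mutnet_rin`.
#' @export
network_from_edges <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (!"etype" %in% names(edges)) edges$etype <- "cnt"
  if (!"subtype" %in% names(edges)) edges$subtype <- "all-all"
  ids <- unique(c(nodes, edges$u, edges$v))
  node_tbl <- tibble(id = ids, chain = NA_character_, resid = NA_integer_,
                     resname = NA_character_, is_ligand = FALSE)
  net <- new_rin(node_tbl, edges[, c("u", "v", "etype", "subtype", "weight")])
  if ("distance" %in% names(edges)) {
    net$distances <- edges |>
      group_by(.data$u, .data$v) |>
      summarise(weight = mean(.data$weight),
                distance = mean(.data$distance), .groups = "drop")
  }
  net
}

# Collapse a network to the simple weighted graph the statistics run on:
# node vector, adjacency/index lists and per-edge distances.
as_netgraph <- function(network, weighted = TRUE) {
  if (!inherits(network, "mutnet_rin")) {
    network <- network_from_edges(network)
  }
  if (is.null(network$distances)) {
    network <- edge_weights_to_distances(network)
  }
  nodes <- network$nodes$id
  ed <- network$distances
  ui <- match(ed$u, nodes)
  vi <- match(ed$v, nodes)
  dists <- if (weighted) ed$distance else rep(1, nrow(ed))
  n <- length(nodes)
  adj <- vector("list", n)
  wts <- vector("list", n)
  for (k in seq_along(ui)) {
    adj[[ui[k]]] <- c(adj[[ui[k]]], vi[k])
    wts[[ui[k]]] <- c(wts[[ui[k]]], dists[k])
    adj[[vi[k]]] <- c(adj[[vi[k]]], ui[k])
    wts[[vi[k]]] <- c(wts[[vi[k]]], dists[k])
  }
  list(nodes = nodes, n = n, adj = adj, wts = wts,
       edges = tibble(ui = ui, vi = vi, dist = dists))
}

netgraph_igraph <- function(g) {
  igraph::graph_from_data_frame(
    data.frame(from = g$nodes[g$edges$ui], to = g$nodes[g$edges$vi],
               weight = g$edges$dist),
    directed = FALSE, vertices = data.frame(name = g$nodes))
}

# Brandes' accumulation for weighted betweenness: one Dijkstra per source
# with shortest-path counting, then dependency back-propagation. Shortest
# paths are compared with a small relative tolerance so fractional distance
# scores (averaged multi-edge weights) tie correctly.
brandes_centrality <- function(g) {
  n <- g$n
  cb <- numeric(n)
  closeness <- numeric(n)
  tol <- 1e-10
  for (s in seq_len(n)) {
    d <- rep(Inf, n)
    sigma <- numeric(n)
    d[s] <- 0
    sigma[s] <- 1
    pred <- vector("list", n)
    done <- logical(n)
    order_out <- integer(0)
    repeat {
      cand <- which(!done & is.finite(d))
      if (length(cand) == 0) break
      u <- cand[which.min(d[cand])]
      done[u] <- TRUE
      order_out <- c(order_out, u)
      nb <- g$adj[[u]]
      for (k in seq_along(nb)) {
        v <- nb[k]
        alt <- d[u] + g$wts[[u]][k]
        if (!is.finite(d[v]) || alt < d[v] - tol * max(1, abs(alt))) {
          d[v] <- alt
          sigma[v] <- sigma[u]
          pred[[v]] <- u
        } else if (abs(alt - d[v]) <= tol * max(1, abs(alt))) {
          sigma[v] <- sigma[v] + sigma[u]
          pred[[v]] <- c(pred[[v]], u)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_out)) {
      for (p in pred[[w]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
    reach <- is.finite(d) & seq_len(n) != s
    closeness[s] <- if (any(reach)) (n - 1) / sum(d[reach]) else 0
  }
  list(betweenness = cb / 2, closeness = closeness)
}

#' Weighted centrality profile of a residue network
#'
#' Betweenness follows the shortest-path counting definition
#' `C_B(i) = sum_{j<k} P_jk(i)/P_jk` with `P_jk` the number of shortest paths
#' between j and k under the distance scores (unnormalized raw pair counts);
#' disconnected pairs contribute 0. Closeness is `(n-1)/sum_j d(i,j)` over
#' reachable j (0 for isolated nodes); degree is counted on the collapsed
#' simple graph.
#'
#' @param network A `mutnet_rin` (distance scores are derived on the fly via
#'   [edge_weights_to_distances()] when absent) or an edge data frame.
#' @param weighted Use distance scores (`TRUE`, default) or unit distances.
#' @param normalized Also report betweenness divided by `(n-1)(n-2)/2`.
#' @return A tibble (`node`, `degree`, `closeness`, `betweenness`,
#'   and `betweenness_norm` if requested).
#' @export
centrality_profile <- function(network, weighted = TRUE, normalized = TRUE) {
  g <- as_netgraph(network, weighted = weighted)
  bc <- brandes_centrality(g)
  out <- tibble(node = g$nodes,
                degree = vapply(g$adj, length, integer(1)),
                closeness = bc$closeness,
                betweenness = bc$betweenness)
  if (normalized) {
    n <- g$n
    denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
    out$betweenness_norm <- out$betweenness / denom
  }
  out
}

#' @rdname centrality_profile
#' @export
net_betweenness <- function(network, weighted = TRUE) {
  centrality_profile(network, weighted = weighted,
                     normalized = FALSE)[, c("node", "betweenness")]
}

#' @rdname centrality_profile
#' @export
net_closeness <- function(network, weighted = TRUE) {
  centrality_profile(network, weighted = weighted,
                     normalized = FALSE)[, c("node", "closeness")]
}

#' Hub nodes and the degree distribution
#'
#' Hubs are nodes with at least `min_degree` edges on the collapsed simple
#' graph (default 4).
#'
#' @param network A `mutnet_rin` or edge data frame.
#' @param min_degree Degree threshold.
#' @return A tibble (`node`, `degree`) of hubs, sorted by decreasing degree;
#'   the full degree distribution is attached as attribute
#'   `degree_distribution` (see [degree_distribution()]).
#' @export
hubs <- function(network, min_degree = 4) {
  g <- as_netgraph(network)
  deg <- vapply(g$adj, length, integer(1))
  out <- tibble(node = g$nodes, degree = deg) |>
    filter(.data$degree >= min_degree) |>
    arrange(dplyr::desc(.data$degree), .data$node)
  attr(out, "degree_distribution") <-
    tibble(degree = deg) |> count(.data$degree, name = "count")
  out
}

#' @rdname hubs
#' @export
degree_distribution <- function(network) {
  g <- as_netgraph(network)
  tibble(degree = vapply(g$adj, length, integer(1))) |>
    count(.data$degree, name = "count")
}

#' Enumerate all k-cliques
#'
#' All complete subgraphs of exactly `k` nodes (not only maximal ones), each
#' reported once with nodes sorted.
#'
#' @param network A `mutnet_rin` or edge data frame.
#' @param k Clique size, >= 3.
#' @return List of character vectors (sorted node ids), in canonical order.
#' @export
enumerate_k_cliques <- function(network, k) {
  if (k < 3) abort("k must be >= 3")
  g <- as_netgraph(network)
  ig <- netgraph_igraph(g)
  cl <- igraph::cliques(ig, min = k, max = k)
  out <- lapply(cl, function(vs) sort(igraph::V(ig)$name[as.integer(vs)]))
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}

#' Clique-percolation communities
#'
#' Two k-cliques are adjacent when they share k-1 nodes; a community is the
#' node union of a connected component of that clique-overlap graph.
#' Communities at fixed k are node-wise maximal by construction.
#'
#' @param network A `mutnet_rin` or edge data frame.
#' @param k Clique size (3, 4 or 5 typical).
#' @return A `community_set`: list with `k`, `communities` (list of sorted
#'   node-id vectors) and `cliques` plus `membership` (community index per
#'   clique).
#' @export
cpm_communities <- function(network, k) {
  cl <- enumerate_k_cliques(network, k)
  if (length(cl) == 0) {
    return(structure(list(k = k, communities = list(), cliques = list(),
                          membership = integer(0)),
                     class = "community_set"))
  }
  ids <- sort(unique(unlist(cl)))
  memb <- matrix(FALSE, length(cl), length(ids))
  for (i in seq_along(cl)) memb[i, match(cl[[i]], ids)] <- TRUE
  overlap <- tcrossprod(memb * 1)
  adj_pairs <- which(overlap == k - 1 & upper.tri(overlap), arr.ind = TRUE)
  cg <- igraph::graph_from_edgelist(cbind(adj_pairs[, 1], adj_pairs[, 2]),
                                    directed = FALSE)
  cg <- igraph::add_vertices(cg, max(0, length(cl) - igraph::vcount(cg)))
  comp <- igraph::components(cg)$membership
  communities <- lapply(sort(unique(comp)), function(cmp) {
    sort(unique(unlist(cl[comp == cmp])))
  })
  ord <- order(vapply(communities, paste, character(1), collapse = "|"))
  remap <- match(comp, sort(unique(comp))[ord])
  structure(list(k = k, communities = communities[ord], cliques = cl,
                 membership = remap),
            class = "community_set")
}

#' @export
print.community_set <- function(x, ...) {
  cat("<community_set> k =", x$k, "--", length(x$communities),
      "communities from", length(x$cliques), "cliques\n")
  invisible(x)
}

#' Binned betweenness frequency distribution
#'
#' Betweenness values are first normalized by `(n-1)(n-2)/2` (so bins such
#' as 0.01--0.02 are meaningful) and then binned with width `bin_width`; the
#' counts sum to the node count. Values equal to the upper limit fall in the
#' last bin.
#'
#' @param profile A centrality tibble from [centrality_profile()].
#' @param bin_width Bin width on the normalized scale (default 0.01).
#' @return A tibble (`bin_lo`, `bin_hi`, `count`).
#' @export
betweenness_histogram <- function(profile, bin_width = 0.01) {
  if (bin_width <= 0) abort("bin_width must be > 0")
  n <- nrow(profile)
  vals <- if ("betweenness_norm" %in% names(profile)) {
    profile$betweenness_norm
  } else {
    denom <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
    profile$betweenness / denom
  }
  top <- max(1, max(vals))
  n_bins <- ceiling(top / bin_width - 1e-12)
  idx <- pmin(floor(vals / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  tibble(bin_lo = (seq_len(n_bins) - 1) * bin_width,
         bin_hi = seq_len(n_bins) * bin_width,
         count = counts)
}

count_all_cliques <- function(network, k_min = 3) {
  g <- as_netgraph(network)
  ig <- netgraph_igraph(g)
  cl <- igraph::cliques(ig, min = k_min)
  if (length(cl) == 0) {
    return(tibble(k = integer(0), count = integer(0)))
  }
  sizes <- vapply(cl, length, integer(1))
  tibble(k = sizes) |> count(.data$k, name = "count") |> arrange(.data$k)
}

count_maximal_cliques <- function(network, k_min = 3) {
  g <- as_netgraph(network)
  ig <- netgraph_igraph(g)
  cl <- igraph::max_cliques(ig, min = k_min)
  if (length(cl) == 0) {
    return(tibble(k = integer(0), count = integer(0)))
  }
  tibble(k = vapply(cl, length, integer(1))) |>
    count(.data$k, name = "count") |> arrange(.data$k)
}

#' Differential network report
#'
#' Compares two residue networks built with identical parameters: total
#' clique counts (all k-cliques summed over k >= 3 by default; maximal-clique
#' counting selectable), community counts and nodes-per-community at
#' k = 3, 4, 5, hub degree distributions, normalized-betweenness histograms,
#' and per-shared-residue betweenness differences.
#'
#' @param net_a,net_b `mutnet_rin` networks (e.g. wild-type and mutant).
#' @param k_values Community clique sizes to report (default `3:5`).
#' @param min_degree Hub threshold (default 4).
#' @param bin_width Histogram bin width on the normalized scale.
#' @param clique_convention `"all"` (every k-clique, summed over k >= 3) or
#'   `"maximal"` (maximal cliques only).
#' @return A `mutnet_diff` object (tibbles: `clique_counts`, `communities`,
#'   `community_nodes`, `hubs`, `degree_distributions`, `histograms`,
#'   `delta_betweenness`).
#' @export
compare_networks <- function(net_a, net_b, k_values = 3:5, min_degree = 4,
                             bin_width = 0.01,
                             clique_convention = c("all", "maximal")) {
  clique_convention <- match.arg(clique_convention)
  nets <- list(a = net_a, b = net_b)
  counter <- if (clique_convention == "all") count_all_cliques else
    count_maximal_cliques
  clique_counts <- bind_rows(lapply(names(nets), function(nm) {
    mutate(counter(nets[[nm]]), network = nm)
  }))
  communities <- list()
  community_nodes <- list()
  for (nm in names(nets)) {
    for (k in k_values) {
      cs <- cpm_communities(nets[[nm]], k)
      communities[[length(communities) + 1]] <-
        tibble(network = nm, k = k, n_communities = length(cs$communities))
      if (length(cs$communities) > 0) {
        community_nodes[[length(community_nodes) + 1]] <-
          tibble(network = nm, k = k,
                 community = seq_along(cs$communities),
                 n_nodes = vapply(cs$communities, length, integer(1)))
      }
    }
  }
  hub_tbl <- bind_rows(lapply(names(nets), function(nm) {
    h <- hubs(nets[[nm]], min_degree)
    if (nrow(h) == 0) tibble(network = character(0), node = character(0),
                             degree = integer(0))
    else mutate(h, network = nm)[, c("network", "node", "degree")]
  }))
  degree_tbl <- bind_rows(lapply(names(nets), function(nm) {
    mutate(degree_distribution(nets[[nm]]), network = nm)
  }))
  profiles <- lapply(nets, centrality_profile)
  hist_tbl <- bind_rows(lapply(names(nets), function(nm) {
    mutate(betweenness_histogram(profiles[[nm]], bin_width), network = nm)
  }))
  shared <- intersect(profiles$a$node, profiles$b$node)
  if (length(shared) == 0) {
    warn("networks share no nodes; delta betweenness is empty")
    delta <- tibble(node = character(0), betweenness_a = numeric(0),
                    betweenness_b = numeric(0), delta = numeric(0))
  } else {
    pa <- profiles$a[match(shared, profiles$a$node), ]
    pb <- profiles$b[match(shared, profiles$b$node), ]
    delta <- tibble(node = shared, betweenness_a = pa$betweenness,
                    betweenness_b = pb$betweenness,
                    delta = pb$betweenness - pa$betweenness)
  }
  structure(list(
    clique_counts = clique_counts,
    clique_totals = clique_counts |> group_by(.data$network) |>
      summarise(total = sum(.data$count), .groups = "drop"),
    communities = bind_rows(communities),
    community_nodes = if (length(community_nodes)) bind_rows(community_nodes)
      else tibble(network = character(0), k = integer(0),
                  community = integer(0), n_nodes = integer(0)),
    hubs = hub_tbl,
    degree_distributions = degree_tbl,
    histograms = hist_tbl,
    delta_betweenness = delta,
    params = list(k_values = k_values, min_degree = min_degree,
                  bin_width = bin_width,
                  clique_convention = clique_convention)),
    class = "mutnet_diff")
}

#' @export
print.mutnet_diff <- function(x, ...) {
  cat("<mutnet_diff>\n  clique totals: ")
  cat(paste(x$clique_totals$network, x$clique_totals$total, sep = "="),
      sep = "  ")
  cat("\n  communities:", nrow(x$communities), "rows;",
      "delta betweenness over", nrow(x$delta_betweenness), "shared nodes\n")
  invisible(x)
}

#' Write / read a differential report as JSON
#'
#' @param diff A `mutnet_diff`.
#' @param path File path.
#' @return `path` (writer) or a `mutnet_diff` (reader).
#' @export
write_diff_report <- function(diff, path) {
  payload <- diff[setdiff(names(diff), "params")]
  payload <- lapply(payload, function(tb) as.data.frame(tb))
  payload$params <- diff$params
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_diff_report
#' @export
read_diff_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw[setdiff(names(raw), "params")], as_tibble)
  out$params <- raw$params
  class(out) <- "mutnet_diff"
  out
}
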