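#' MCODE-style graph clustering
#'
#' The three classical stages of the MCODE algorithm on the collapsed simple
#' graph:
#'
#' 1. *Node weighting*: each node is scored by its core-clustering
#'    coefficient -- the density of the highest k-core of its closed
#'    neighbourhood `N[v]` -- multiplied by that core's k-core number.
#' 2. *Cluster prediction*: nodes are visited in decreasing score order
#'    (ties broken by node id); an unvisited seed starts a cluster that
#'    greedily absorbs neighbouring nodes whose score is at least
#'    `(1 - node_score_cutoff)` times the seed score.
#' 3. *Post-processing*: with `haircut` on, members connected to the cluster
#'    by a single edge are removed (one pass).
#'
#' Only positive-score nodes seed, and clusters need at least three nodes,
#' so an edgeless graph yields no clusters. Clusters are ranked by
#' score = density x size. Fully deterministic.
#'
#' @param network A `mutnet_rin` or edge data frame.
#' @param node_score_cutoff Expansion threshold as a fraction of the seed
#'   score (Cytoscape default 0.2).
#' @param haircut Remove degree-1 cluster members (default `TRUE`).
#' @return A tibble (`cluster`, `score`, `n_nodes`, `nodes` list-column),
#'   ranked by decreasing cluster score.
#' @export
mcode_clusters <- function(network, node_score_cutoff = 0.2, haircut = TRUE) {
  g <- as_netgraph(network)
  n <- g$n
  empty <- tibble(cluster = integer(0), score = numeric(0),
                  n_nodes = integer(0), nodes = list())
  if (n == 0 || nrow(g$edges) == 0) return(empty)
  adj_sets <- lapply(g$adj, unique)
  density_of <- function(members) {
    m <- sum(g$edges$ui %in% members & g$edges$vi %in% members)
    k <- length(members)
    if (k < 2) 0 else 2 * m / (k * (k - 1))
  }
  # node score: k-core number of N[v] times the density of that k-core
  ig <- netgraph_igraph(g)
  score <- numeric(n)
  for (v in seq_len(n)) {
    nb <- c(v, adj_sets[[v]])
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(ig, g$nodes[nb])
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_nodes <- which(core == kmax | core > kmax)  # highest k-core members
    core_sub <- igraph::induced_subgraph(sub, core_nodes)
    nn <- igraph::vcount(core_sub)
    dens <- if (nn < 2) 0 else
      2 * igraph::ecount(core_sub) / (nn * (nn - 1))
    score[v] <- kmax * dens
  }
  visited <- logical(n)
  clusters <- list()
  ord <- order(-score, g$nodes)
  for (seed in ord) {
    if (visited[seed] || score[seed] <= 0) next
    thresh <- (1 - node_score_cutoff) * score[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (w in adj_sets[[u]]) {
          if (!visited[w] && score[w] >= thresh) {
            visited[w] <- TRUE
            members <- c(members, w)
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    if (haircut && length(members) > 1) {
      deg_in <- vapply(members, function(u) {
        sum(adj_sets[[u]] %in% members)
      }, integer(1))
      members <- members[deg_in >= 2]
    }
    if (length(members) >= 3) {
      clusters[[length(clusters) + 1]] <-
        list(members = sort(g$nodes[members]),
             score = density_of(members) * length(members))
    }
  }
  if (length(clusters) == 0) return(empty)
  out <- tibble(
    score = vapply(clusters, `[[`, numeric(1), "score"),
    n_nodes = vapply(clusters, function(cl) length(cl$members), integer(1)),
    nodes = lapply(clusters, `[[`, "members"))
  out <- arrange(out, dplyr::desc(.data$score),
                 vapply(out$nodes, paste, character(1), collapse = "|"))
  mutate(out, cluster = dplyr::row_number())[, c("cluster", "score",
                                                 "n_nodes", "nodes")]
}
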