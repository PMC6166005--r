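# Independent oracles used to validate the graph statistics. These
# deliberately use different algorithms from the package implementation:
# Floyd-Warshall all-pairs shortest-path counting for betweenness, and
# exhaustive subset enumeration plus union-find for cliques/communities.

# Floyd-Warshall distances and shortest-path counts, then the pair-fraction
# betweenness sum computed directly from its definition.
oracle_betweenness <- function(nodes, edges, tol = 1e-9) {
  n <- length(nodes)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  P <- matrix(0, n, n)
  ui <- match(edges$u, nodes)
  vi <- match(edges$v, nodes)
  for (e in seq_along(ui)) {
    D[ui[e], vi[e]] <- D[vi[e], ui[e]] <- edges$distance[e]
    P[ui[e], vi[e]] <- P[vi[e], ui[e]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i == k || !is.finite(D[i, k])) next
      for (j in seq_len(n)) {
        if (j == k || j == i || !is.finite(D[k, j])) next
        alt <- D[i, k] + D[k, j]
        if (alt < D[i, j] - tol * max(1, abs(alt))) {
          D[i, j] <- alt
          P[i, j] <- P[i, k] * P[k, j]
        } else if (abs(alt - D[i, j]) <= tol * max(1, abs(alt))) {
          P[i, j] <- P[i, j] + P[i, k] * P[k, j]
        }
      }
    }
  }
  cb <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n - 1)) {
      for (k in seq((j + 1), n)) {
        if (j == i || k == i || P[j, k] == 0) next
        on_path <- abs(D[j, i] + D[i, k] - D[j, k]) <=
          tol * max(1, abs(D[j, k]))
        if (on_path) cb[i] <- cb[i] + (P[j, i] * P[i, k]) / P[j, k]
      }
    }
  }
  stats::setNames(cb, nodes)
}

# every k-subset checked for completeness
oracle_k_cliques <- function(nodes, edges, k) {
  n <- length(nodes)
  if (n < k) return(list())
  A <- matrix(FALSE, n, n)
  ui <- match(edges$u, nodes)
  vi <- match(edges$v, nodes)
  A[cbind(ui, vi)] <- TRUE
  A[cbind(vi, ui)] <- TRUE
  out <- list()
  combos <- utils::combn(n, k)
  for (c_i in seq_len(ncol(combos))) {
    sub <- combos[, c_i]
    prs <- utils::combn(sub, 2)
    if (all(A[cbind(prs[1, ], prs[2, ])])) {
      out[[length(out) + 1]] <- sort(nodes[sub])
    }
  }
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}

# union-find over cliques sharing k-1 nodes
oracle_cpm <- function(nodes, edges, k) {
  cl <- oracle_k_cliques(nodes, edges, k)
  if (length(cl) == 0) return(list())
  parent <- seq_along(cl)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_along(cl)) {
    for (j in seq_along(cl)) {
      if (j <= i) next
      if (length(intersect(cl[[i]], cl[[j]])) == k - 1) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(cl), find, integer(1))
  comms <- lapply(unique(roots), function(r) {
    sort(unique(unlist(cl[roots == r])))
  })
  comms[order(vapply(comms, paste, character(1), collapse = "|"))]
}

# seeded Erdos-Renyi edge table on named nodes, optionally with random
# positive distance scores
random_graph <- function(n, p, seed, weights = c("unit", "random")) {
  weights <- match.arg(weights)
  nodes <- sprintf("n%02d", seq_len(n))
  prs <- utils::combn(n, 2)
  withr::with_seed(seed, {
    keep <- stats::runif(ncol(prs)) < p
    d <- if (weights == "unit") rep(1, sum(keep)) else
      stats::runif(sum(keep), 0.5, 3)
    tibble::tibble(u = nodes[prs[1, keep]], v = nodes[prs[2, keep]],
                   distance = d)
  })
}

path_graph <- function(ids = c("A", "B", "C")) {
  tibble::tibble(u = ids[-length(ids)], v = ids[-1], distance = 1)
}

star_graph <- function(n_leaves = 5) {
  tibble::tibble(u = "hub", v = sprintf("leaf%d", seq_len(n_leaves)),
                 distance = 1)
}

complete_graph <- function(ids) {
  prs <- utils::combn(ids, 2)
  tibble::tibble(u = prs[1, ], v = prs[2, ], distance = 1)
}

# trajectory where the two-residue O..N pair is inside the 3.5 A cutoff in
# `frames_on` of `n` frames and far outside otherwise
onoff_trajectory <- function(frames_on, n) {
  top <- two_residue_structure(gap = 3.0, ligand = TRUE)
  ref <- as.matrix(top[, c("x", "y", "z")])
  frames <- lapply(seq_len(n), function(i) {
    f <- ref
    if (!(i %in% frames_on)) f[3:4, 1] <- f[3:4, 1] + 20
    f
  })
  mutnet::new_trajectory(top, frames)
}

# minimal two-residue structure whose inter-residue O..N distance is `gap`
# (residues two apart in sequence so the chain-adjacency rule is inert)
two_residue_structure <- function(gap, ligand = FALSE) {
  tibble::tibble(
    chain = c("A", "A", if (ligand) c("L", "L") else c("A", "A")),
    resid = c(1L, 1L, if (ligand) c(1L, 1L) else c(3L, 3L)),
    resname = c("SER", "SER",
                if (ligand) c("FRU", "FRU") else c("THR", "THR")),
    is_ligand = c(FALSE, FALSE, ligand, ligand),
    atom = c("CA", "OG", "CA", "N"),
    element = c("C", "O", "C", "N"),
    x = c(0, 0, gap + 1, gap), y = 0, z = 0)
}
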