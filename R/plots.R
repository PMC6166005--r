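#' Tidy and summarize analysis results
#'
#' broom-style accessors: `tidy()` returns the result's main table as a
#' tibble, `glance()` a one-row summary.
#'
#' @param x An `asmd_result`, `pmf_profile`, `mutnet_rin`, `fel_result`,
#'   `community_set` or `mutnet_diff`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.asmd_result <- function(x, ...) as_tibble(x$profile)

#' @rdname tidiers
#' @export
glance.asmd_result <- function(x, ...) {
  tibble(endpoint_pmf = x$profile$pmf[nrow(x$profile)],
         n_stages = x$params$n_stages, n_traj = x$params$n_traj,
         span_start = x$params$span[1], span_end = x$params$span[2],
         temperature = x$params$langevin$temperature)
}

#' @rdname tidiers
#' @export
tidy.mutnet_rin <- function(x, ...) as_tibble(x$edges)

#' @rdname tidiers
#' @export
glance.mutnet_rin <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_ligand_nodes = sum(x$nodes$is_ligand),
         has_distances = !is.null(x$distances))
}

#' @rdname tidiers
#' @export
tidy.community_set <- function(x, ...) {
  if (length(x$communities) == 0) {
    return(tibble(community = integer(0), node = character(0),
                  k = integer(0)))
  }
  bind_rows(lapply(seq_along(x$communities), function(i) {
    tibble(community = i, node = x$communities[[i]], k = x$k)
  }))
}

#' @rdname tidiers
#' @export
glance.community_set <- function(x, ...) {
  tibble(k = x$k, n_communities = length(x$communities),
         n_cliques = length(x$cliques))
}

#' @rdname tidiers
#' @export
tidy.fel_result <- function(x, ...) as_tibble(x$grid)

#' @rdname tidiers
#' @export
tidy.mutnet_diff <- function(x, ...) as_tibble(x$delta_betweenness)

#' Plot a PMF profile
#'
#' @param object An `asmd_result` or `pmf_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.asmd_result <- function(object, ...) {
  autoplot.pmf_profile(object$profile, ...)
}

#' @rdname autoplot.asmd_result
#' @export
autoplot.pmf_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$rc, y = .data$pmf)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Reaction coordinate (Å)",
                  y = "PMF (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot a PCA free-energy landscape
#'
#' Occupied bins are coloured by free energy; empty bins are blank.
#'
#' @param object A `fel_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fel_result <- function(object, ...) {
  grid <- filter(as_tibble(object$grid), is.finite(.data$free_energy))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$pc1, y = .data$pc2,
                                     fill = .data$free_energy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "ΔG (kcal/mol)") +
    ggplot2::labs(x = "PC1", y = "PC2") +
    ggplot2::theme_minimal()
}

#' Plot a betweenness frequency distribution
#'
#' @param histogram A tibble from [betweenness_histogram()].
#' @return A ggplot.
#' @export
plot_betweenness_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = (histogram$bin_hi - histogram$bin_lo)[1],
                      fill = "steelblue") +
    ggplot2::labs(x = "Normalized betweenness", y = "Node count") +
    ggplot2::theme_minimal()
}

#' Plot per-residue betweenness differences between two networks
#'
#' @param diff A `mutnet_diff` from [compare_networks()].
#' @return A ggplot.
#' @export
plot_delta_betweenness <- function(diff) {
  d <- as_tibble(diff$delta_betweenness)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$node, y = .data$delta)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = "Δ betweenness (B - A)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
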