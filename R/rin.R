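# Fixed van der Waals radii (Angstrom) so overlap edges are deterministic
# across platforms; elements not listed fall back to 1.7.
VDW_RADII <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

MAINCHAIN_ATOMS <- c("N", "CA", "C", "O", "OXT")

atom_class <- function(structure) {
  ifelse(structure$is_ligand, "ligand",
         ifelse(structure$atom %in% MAINCHAIN_ATOMS, "mc", "sc"))
}

# All inter-residue heavy-atom pairs within `cutoff`, with residue/atom
# metadata. The workhorse behind contact, overlap and H-bond detection.
atom_pairs_within <- function(structure, cutoff, atoms_keep = NULL) {
  s <- as_tibble(structure)
  s$row <- seq_len(nrow(s))
  if (!is.null(atoms_keep)) s <- s[atoms_keep, , drop = FALSE]
  if (nrow(s) < 2) {
    return(tibble(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  d <- as.matrix(dist(as.matrix(s[, c("x", "y", "z")])))
  hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble(i = integer(0), j = integer(0), dist = numeric(0)))
  }
  out <- tibble(i = s$row[hit[, 1]], j = s$row[hit[, 2]],
                dist = d[hit])
  out[order(out$i, out$j), ]
}

pair_meta <- function(structure, pairs) {
  s <- as_tibble(structure)
  id <- node_ids(s)
  cls <- atom_class(s)
  same_res <- id[pairs$i] == id[pairs$j]
  pairs <- pairs[!same_res, , drop = FALSE]
  mutate(pairs,
         u = id[.data$i], v = id[.data$j],
         atom_u = s$atom[.data$i], atom_v = s$atom[.data$j],
         el_u = s$element[.data$i], el_v = s$element[.data$j],
         class_u = cls[.data$i], class_v = cls[.data$j],
         chain_u = s$chain[.data$i], chain_v = s$chain[.data$j],
         resid_u = s$resid[.data$i], resid_v = s$resid[.data$j],
         lig_u = s$is_ligand[.data$i], lig_v = s$is_ligand[.data$j])
}

# Covalent chain neighbours are not noncovalent interactions: drop pairs of
# sequence-adjacent protein residues on the same chain.
drop_chain_adjacent <- function(pm) {
  adj <- !pm$lig_u & !pm$lig_v & pm$chain_u == pm$chain_v &
    abs(pm$resid_u - pm$resid_v) == 1
  pm[!adj, , drop = FALSE]
}

canonical_uv <- function(pm) {
  swap <- order_key(pm$u, pm$resid_u, pm$chain_u) >
    order_key(pm$v, pm$resid_v, pm$chain_v)
  tmp_u <- pm$u
  pm$u[swap] <- pm$v[swap]
  pm$v[swap] <- tmp_u[swap]
  tmp <- pm$class_u
  pm$class_u[swap] <- pm$class_v[swap]
  pm$class_v[swap] <- tmp[swap]
  pm
}

order_key <- function(id, resid, chain) {
  paste(chain, sprintf("%08d", resid), id)
}

subtype_label <- function(class_u, class_v) {
  lab <- vapply(seq_along(class_u), function(k) {
    cls <- c(class_u[k], class_v[k])
    if ("ligand" %in% cls) {
      other <- setdiff(cls, "ligand")
      if (length(other) == 0) "ligand-ligand"
      else paste0(other[1], "-ligand")
    } else if (all(cls == "mc")) "mc-mc"
    else if (all(cls == "sc")) "sc-sc"
    else "all-all"
  }, character(1))
  lab
}

# Per-edge subtype: the most frequent atom-pair label; mixed labels that tie
# collapse to all-all (ligand edges keep the majority mc-/sc-ligand label).
aggregate_subtype <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) == 1) names(tab)[1]
  else if (tab[1] > tab[2]) names(tab)[1]
  else "all-all"
}

#' Detect interatomic contact edges
#'
#' One `cnt` edge per residue pair having at least one heavy-atom pair within
#' `cutoff`, excluding sequence-adjacent residues on the same chain; the edge
#' weight is the number of qualifying atom pairs (the interaction count used
#' as edge weight throughout the network analysis).
#'
#' @param structure A `mutnet_structure`.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.5).
#' @return An edge tibble (`u`, `v`, `etype`, `subtype`, `weight`).
#' @export
detect_contacts <- function(structure, cutoff = 4.5) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  structure <- as_structure(structure)
  heavy <- which(structure$element != "H")
  pm <- pair_meta(structure, atom_pairs_within(structure, cutoff, heavy))
  pm <- drop_chain_adjacent(pm)
  edge_rollup(pm, "cnt")
}

edge_rollup <- function(pm, etype) {
  if (nrow(pm) == 0) {
    return(tibble(u = character(0), v = character(0), etype = character(0),
                  subtype = character(0), weight = integer(0)))
  }
  pm <- canonical_uv(pm)
  pm$lab <- subtype_label(pm$class_u, pm$class_v)
  pm |>
    group_by(.data$u, .data$v) |>
    summarise(etype = etype, subtype = aggregate_subtype(.data$lab),
              weight = dplyr::n(), .groups = "drop") |>
    select("u", "v", "etype", "subtype", "weight")
}

# Donor/acceptor heavy-atom pairs qualifying as hydrogen bonds in one frame.
# Hydrogen-free structures (all synthetic fixtures) use the distance-only
# criterion on an N/O whitelist; when hydrogens are present the
# donor-H-acceptor angle must also pass `angle_cut`.
hbond_atom_pairs <- function(structure, d_cut = 3.5, angle_cut = 120) {
  structure <- as_structure(structure)
  polar <- which(structure$element %in% c("N", "O"))
  pm <- pair_meta(structure, atom_pairs_within(structure, d_cut, polar))
  pm <- drop_chain_adjacent(pm)
  if (nrow(pm) == 0) return(pm)
  hyd <- which(structure$element == "H")
  if (length(hyd) > 0) {
    coords <- coord_matrix(structure)
    keep <- vapply(seq_len(nrow(pm)), function(k) {
      ok <- FALSE
      for (ends in list(c(pm$i[k], pm$j[k]), c(pm$j[k], pm$i[k]))) {
        don <- ends[1]; acc <- ends[2]
        # hydrogens covalently attached to the donor (same residue, <1.25 A)
        same_res <- node_ids(structure)[hyd] == node_ids(structure)[don]
        hs <- hyd[same_res]
        if (length(hs) == 0) next
        dh <- sqrt(rowSums(sweep(coords[hs, , drop = FALSE], 2,
                                 coords[don, ])^2))
        hs <- hs[dh < 1.25]
        for (h in hs) {
          v1 <- coords[don, ] - coords[h, ]
          v2 <- coords[acc, ] - coords[h, ]
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang >= angle_cut) { ok <- TRUE; break }
        }
        if (ok) break
      }
      ok
    }, logical(1))
    pm <- pm[keep, , drop = FALSE]
  }
  pm
}

#' Detect hydrogen-bond edges
#'
#' Donor-acceptor heavy-atom (N/O) pairs within `d_cut` Angstrom form `hbond`
#' edges; the weight is the number of qualifying donor-acceptor pairs between
#' the two residues. With hydrogens present the donor-H-acceptor angle must
#' be at least `angle_cut` degrees; hydrogen-free structures use the
#' distance-only criterion.
#'
#' @param structure A `mutnet_structure` (e.g. one trajectory frame).
#' @param d_cut Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut Donor-H-acceptor angle cutoff, degrees (default 120).
#' @return An edge tibble (`u`, `v`, `etype`, `subtype`, `weight`).
#' @export
detect_hbonds <- function(structure, d_cut = 3.5, angle_cut = 120) {
  edge_rollup(hbond_atom_pairs(structure, d_cut, angle_cut), "hbond")
}

detect_overlaps <- function(structure, tolerance = 0.4) {
  structure <- as_structure(structure)
  heavy <- which(structure$element != "H")
  max_r <- 2 * max(vdw_radius(unique(structure$element)))
  pm <- pair_meta(structure, atom_pairs_within(structure, max_r, heavy))
  pm <- drop_chain_adjacent(pm)
  if (nrow(pm) > 0) {
    lim <- vdw_radius(pm$el_u) + vdw_radius(pm$el_v) - tolerance
    pm <- pm[pm$dist < lim, , drop = FALSE]
  }
  edge_rollup(pm, "ovl")
}

#' Build a residue interaction network
#'
#' Nodes are residues (plus the ligand); edges are typed noncovalent
#' interactions weighted by interaction count:
#' * `cnt` -- heavy-atom contact within `contact_cutoff` ([detect_contacts()]),
#' * `hbond` -- hydrogen bonds ([detect_hbonds()]),
#' * `ovl` -- van der Waals overlap (any heavy-atom pair closer than the sum
#'   of vdW radii minus 0.4 Angstrom),
#' * `combi` -- added for every residue pair carrying at least two distinct
#'   edge types, with weight equal to the sum of the member weights.
#'
#' @param structure A `mutnet_structure`.
#' @param contact_cutoff Contact cutoff, Angstrom.
#' @param hbond_d_cut,hbond_angle_cut Hydrogen-bond criteria.
#' @return A `mutnet_rin` object: `nodes` tibble (`id`, `chain`, `resid`,
#'   `resname`, `is_ligand`) and `edges` tibble.
#' @examples
#' s <- make_toy_protein(20, 4, seed = 1)
#' net <- build_rin(s)
#' net
#' @export
build_rin <- function(structure, contact_cutoff = 4.5, hbond_d_cut = 3.5,
                      hbond_angle_cut = 120) {
  structure <- as_structure(structure)
  nodes <- residues(structure) |>
    mutate(id = paste(.data$chain, .data$resid, sep = ":")) |>
    select("id", "chain", "resid", "resname", "is_ligand")
  edges <- bind_rows(
    detect_contacts(structure, contact_cutoff),
    detect_hbonds(structure, hbond_d_cut, hbond_angle_cut),
    detect_overlaps(structure))
  combi <- edges |>
    group_by(.data$u, .data$v) |>
    summarise(n_types = dplyr::n_distinct(.data$etype),
              weight = sum(.data$weight), .groups = "drop") |>
    filter(.data$n_types >= 2) |>
    mutate(etype = "combi", subtype = "all-all") |>
    select("u", "v", "etype", "subtype", "weight")
  edges <- bind_rows(edges, combi) |>
    arrange(.data$u, .data$v, .data$etype)
  new_rin(nodes, edges)
}

new_rin <- function(nodes, edges, distances = NULL) {
  bad <- setdiff(unique(c(edges$u, edges$v)), nodes$id)
  if (length(bad) > 0) {
    abort(paste0("edge endpoint(s) not in node set: ",
                 paste(bad, collapse = ", ")))
  }
  if (any(edges$u == edges$v)) abort("self-loops are not allowed")
  structure(list(nodes = nodes, edges = edges, distances = distances),
            class = "mutnet_rin")
}

#' @export
print.mutnet_rin <- function(x, ...) {
  cat("<mutnet_rin> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " typed edges", if (!is.null(x$distances)) " (+distance scores)",
      "\n", sep = "")
  if (nrow(x$edges) > 0) {
    tab <- table(x$edges$etype)
    cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Induced subnetwork around a ligand
#'
#' The ligand node plus its direct neighbours, with all edges among them
#' (all edge types retained).
#'
#' @param network A `mutnet_rin`.
#' @param ligand_id Node id of the ligand (default: the unique ligand node).
#' @return A `mutnet_rin` restricted to the ligand neighbourhood.
#' @export
ligand_subnetwork <- function(network, ligand_id = NULL) {
  if (is.null(ligand_id)) {
    lig <- network$nodes$id[network$nodes$is_ligand]
    if (length(lig) != 1) abort("specify ligand_id: ligand node not unique")
    ligand_id <- lig
  }
  if (!ligand_id %in% network$nodes$id) {
    abort(paste0("unknown ligand id: ", ligand_id))
  }
  nb <- unique(c(network$edges$v[network$edges$u == ligand_id],
                 network$edges$u[network$edges$v == ligand_id]))
  keep <- c(ligand_id, nb)
  edges <- filter(network$edges, .data$u %in% keep & .data$v %in% keep)
  nodes <- filter(network$nodes, .data$id %in% keep)
  new_rin(nodes, edges)
}

#' Convert interaction weights to distance scores
#'
#' Parallel edges between a residue pair are first collapsed to their average
#' weight (negative weights dropped beforehand); the distance score is then
#' `d = (w_max + 1) - w_bar`, where `w_max` is the network-wide maximum
#' collapsed weight, so the strongest interaction has distance 1 and every
#' distance is >= 1 (the max-value conversion). A `reciprocal` scheme
#' (`d = w_max / w_bar`) is available behind a flag.
#'
#' @param network A `mutnet_rin`.
#' @param method `"max"` (default) or `"reciprocal"`.
#' @return The network with a `distances` tibble (`u`, `v`, `weight`
#'   = collapsed average, `distance`).
#' @export
edge_weights_to_distances <- function(network, method = c("max", "reciprocal")) {
  method <- match.arg(method)
  edges <- filter(network$edges, .data$weight >= 0)
  if (nrow(edges) == 0) {
    network$distances <- tibble(u = character(0), v = character(0),
                                weight = numeric(0), distance = numeric(0))
    return(network)
  }
  collapsed <- edges |>
    group_by(.data$u, .data$v) |>
    summarise(weight = mean(.data$weight), .groups = "drop")
  w_max <- max(collapsed$weight)
  collapsed$distance <- switch(method,
    max = (w_max + 1) - collapsed$weight,
    reciprocal = w_max / collapsed$weight)
  network$distances <- collapsed
  network
}

#' Serialize a residue network as an edge-list TSV
#'
#' Columns `u`, `v`, `etype`, `subtype`, `weight` and (when distance scores
#' have been computed) a collapsed `distance` table appended with
#' `etype = "dist"`. Node metadata rides along in a `# node` comment header
#' so the round trip is lossless.
#'
#' @param network A `mutnet_rin`.
#' @param path File path.
#' @return `path` (writer) or a `mutnet_rin` (reader).
#' @export
write_rin <- function(network, path) {
  hdr <- sprintf("# node\t%s\t%s\t%d\t%s\t%d", network$nodes$id,
                 network$nodes$chain, network$nodes$resid,
                 network$nodes$resname, as.integer(network$nodes$is_ligand))
  body <- sprintf("%s\t%s\t%s\t%s\t%g", network$edges$u, network$edges$v,
                  network$edges$etype, network$edges$subtype,
                  network$edges$weight)
  writeLines(c(hdr, "u\tv\tetype\tsubtype\tweight", body), path)
  invisible(path)
}

#' @rdname write_rin
#' @export
read_rin <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nl <- grep("^# node\t", lines, value = TRUE)
  parts <- strsplit(sub("^# node\t", "", nl), "\t", fixed = TRUE)
  nodes <- tibble(
    id = vapply(parts, `[`, character(1), 1),
    chain = vapply(parts, `[`, character(1), 2),
    resid = as.integer(vapply(parts, `[`, character(1), 3)),
    resname = vapply(parts, `[`, character(1), 4),
    is_ligand = vapply(parts, `[`, character(1), 5) == "1")
  edges <- readr::read_tsv(I(lines[!grepl("^# node\t", lines)]),
                           show_col_types = FALSE)
  new_rin(nodes, as_tibble(edges))
}
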