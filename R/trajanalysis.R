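#' Hydrogen-bond occupancy table over a trajectory
#'
#' For every specific donor-acceptor heavy-atom pair, the occupancy is the
#' percentage of frames in which the pair satisfies the geometric
#' hydrogen-bond criterion of [detect_hbonds()]. Pairs are reported as
#' `RESNAME resid: atom` labels, sorted by decreasing occupancy, and rows
#' below `threshold` percent are dropped (default 5%, a typical reporting
#' floor for occupancy tables).
#'
#' @param traj A `mutnet_trajectory`.
#' @param d_cut,angle_cut Hydrogen-bond criteria (see [detect_hbonds()]).
#' @param threshold Reporting threshold in percent (default 5).
#' @param ligand_only Keep only protein-ligand pairs (default `FALSE`).
#' @return A tibble (`donor`, `acceptor`, `occupancy`), sorted by
#'   decreasing occupancy.
#' @export
hbond_occupancy <- function(traj, d_cut = 3.5, angle_cut = 120,
                            threshold = 5, ligand_only = FALSE) {
  nf <- n_frames(traj)
  if (nf < 1) abort("trajectory has no frames")
  top <- as_tibble(traj$topology)
  label <- paste0(top$resname, top$resid, ":", top$atom)
  per_frame <- lapply(seq_len(nf), function(i) {
    pm <- hbond_atom_pairs(trajectory_frame(traj, i), d_cut, angle_cut)
    if (ligand_only && nrow(pm) > 0) pm <- pm[xor(pm$lig_u, pm$lig_v), ]
    if (nrow(pm) == 0) return(character(0))
    a <- pmin(pm$i, pm$j)
    b <- pmax(pm$i, pm$j)
    paste(label[a], label[b], sep = "\r")
  })
  counts <- table(unlist(per_frame))
  if (length(counts) == 0) {
    return(tibble(donor = character(0), acceptor = character(0),
                  occupancy = numeric(0)))
  }
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- tibble(donor = vapply(parts, `[`, character(1), 1),
                acceptor = vapply(parts, `[`, character(1), 2),
                occupancy = 100 * as.numeric(counts) / nf)
  out |>
    filter(.data$occupancy >= threshold) |>
    arrange(dplyr::desc(.data$occupancy), .data$donor, .data$acceptor)
}

#' Mean protein-ligand hydrogen-bond count along the reaction coordinate
#'
#' Each frame's count of ligand-protein hydrogen bonds is averaged within
#' bins of the per-frame reaction coordinate.
#'
#' @param traj A `mutnet_trajectory` carrying a per-frame reaction
#'   coordinate (`traj$rc`).
#' @param bin_width Reaction-coordinate bin width, Angstrom (default 1).
#' @param d_cut,angle_cut Hydrogen-bond criteria.
#' @return A tibble (`rc_lo`, `rc_hi`, `rc_mid`, `mean_count`, `n_frames`).
#' @export
hbond_count_vs_rc <- function(traj, bin_width = 1, d_cut = 3.5,
                              angle_cut = 120) {
  if (is.null(traj$rc) || any(is.na(traj$rc))) {
    abort("trajectory has no per-frame reaction coordinate")
  }
  counts <- vapply(seq_len(n_frames(traj)), function(i) {
    pm <- hbond_atom_pairs(trajectory_frame(traj, i), d_cut, angle_cut)
    if (nrow(pm) == 0) return(0L)
    sum(xor(pm$lig_u, pm$lig_v))
  }, integer(1))
  bin <- floor(traj$rc / bin_width)
  tibble(bin = bin, count = counts) |>
    group_by(.data$bin) |>
    summarise(mean_count = mean(.data$count), n_frames = dplyr::n(),
              .groups = "drop") |>
    mutate(rc_lo = .data$bin * bin_width,
           rc_hi = (.data$bin + 1) * bin_width,
           rc_mid = .data$rc_lo + bin_width / 2) |>
    arrange(.data$rc_lo) |>
    select("rc_lo", "rc_hi", "rc_mid", "mean_count", "n_frames")
}

resolve_atoms <- function(topology, atoms) {
  if (is.numeric(atoms)) return(as.integer(atoms))
  lab <- paste(node_ids(topology), topology$atom, sep = ":")
  idx <- match(atoms, lab)
  if (any(is.na(idx))) {
    abort(paste0("unknown atom id(s): ",
                 paste(atoms[is.na(idx)], collapse = ", "),
                 " (use 'chain:resid:ATOM' or row indices)"))
  }
  idx
}

dihedral_one <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  b2u <- b2 / sqrt(sum(b2^2))
  m1 <- c(b2u[2] * n1[3] - b2u[3] * n1[2],
          b2u[3] * n1[1] - b2u[1] * n1[3],
          b2u[1] * n1[2] - b2u[2] * n1[1])
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Signed dihedral-angle time series
#'
#' The torsion about the 2-3 bond of four atoms, by the standard IUPAC sign
#' convention: cis = 0, trans = 180, range (-180, 180]. Passing the atoms in
#' reverse order negates the angle. A frame with a colinear atom triple has
#' no defined torsion and raises an error naming the frame.
#'
#' @param traj A `mutnet_trajectory`.
#' @param atoms Four distinct atoms, as row indices into the topology or as
#'   `"chain:resid:ATOM"` labels.
#' @return A tibble (`frame`, `dihedral`) in degrees.
#' @export
dihedral_series <- function(traj, atoms) {
  idx <- resolve_atoms(traj$topology, atoms)
  if (length(idx) != 4 || anyDuplicated(idx)) {
    abort("dihedral_series needs four distinct atoms")
  }
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    f <- traj$frames[[i]]
    d <- dihedral_one(f[idx[1], ], f[idx[2], ], f[idx[3], ], f[idx[4], ])
    if (is.na(d)) {
      abort(paste0("undefined dihedral (colinear atoms) in frame ", i))
    }
    d
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)), dihedral = vals)
}

#' Distance between two atom-set centroids, per frame
#'
#' Unweighted centroids (e.g. of two aromatic rings).
#'
#' @param traj A `mutnet_trajectory`.
#' @param set_a,set_b Atom selections (indices or `"chain:resid:ATOM"`
#'   labels), non-empty.
#' @return A tibble (`frame`, `distance`) in Angstrom.
#' @export
centroid_distance <- function(traj, set_a, set_b) {
  ia <- resolve_atoms(traj$topology, set_a)
  ib <- resolve_atoms(traj$topology, set_b)
  if (length(ia) == 0 || length(ib) == 0) {
    abort("both atom sets must be non-empty")
  }
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    f <- traj$frames[[i]]
    ca <- colMeans(f[ia, , drop = FALSE])
    cb <- colMeans(f[ib, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  tibble(frame = seq_len(n_frames(traj)), distance = vals)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fits the mobile coordinates onto the reference over the
#' selected atoms (singular-value decomposition with reflection guard) and
#' reports the post-fit RMSD over the selection.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices or structures.
#' @param selection Optional atom indices to fit on (default: all).
#' @return List with `coords` (transformed mobile, all atoms), `rmsd`,
#'   `rotation`, `translation`.
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  mm <- if (is.data.frame(mobile)) coord_matrix(as_structure(mobile)) else
    as.matrix(mobile)
  rr <- if (is.data.frame(reference)) coord_matrix(as_structure(reference)) else
    as.matrix(reference)
  if (nrow(mm) != nrow(rr)) abort("mobile and reference atom counts differ")
  sel <- if (is.null(selection)) seq_len(nrow(mm)) else as.integer(selection)
  if (length(sel) < 3) abort("superposition needs at least 3 atoms")
  a <- mm[sel, , drop = FALSE]
  b <- rr[sel, , drop = FALSE]
  if (qr(sweep(a, 2, colMeans(a)))$rank < 2) {
    abort("selected atoms are colinear; superposition is ill-defined")
  }
  ca <- colMeans(a)
  cb <- colMeans(b)
  h <- crossprod(sweep(a, 2, ca), sweep(b, 2, cb))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  out <- sweep(mm, 2, ca) %*% t(rot)
  out <- sweep(out, 2, cb, "+")
  rmsd <- sqrt(mean(rowSums((out[sel, , drop = FALSE] - b)^2)))
  list(coords = out, rmsd = rmsd, rotation = rot, translation = cb - ca)
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' @param traj A `mutnet_trajectory`.
#' @param ref_frame Reference frame index (default 1).
#' @param selection Optional atom indices to fit on.
#' @return The trajectory with fitted frames; per-frame RMSDs in attribute
#'   `"rmsd"`.
#' @export
superpose_trajectory <- function(traj, ref_frame = 1, selection = NULL) {
  ref <- traj$frames[[ref_frame]]
  rmsd <- numeric(n_frames(traj))
  frames <- vector("list", n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    fit <- superpose(traj$frames[[i]], ref, selection)
    frames[[i]] <- fit$coords
    rmsd[i] <- fit$rmsd
  }
  out <- new_trajectory(traj$topology, frames, rc = traj$rc)
  attr(out, "rmsd") <- rmsd
  out
}

#' PCA free-energy landscape of a trajectory
#'
#' Frames are rigid-body superposed onto the first frame, flattened to a
#' `frames x 3N` matrix, and decomposed by principal component analysis
#' (unweighted -- the pseudo-atoms carry no masses). The projections onto
#' PC1/PC2 are histogrammed on a `bins x bins` grid and converted to a free
#' energy via `FEL = -kB T ln(P / P_max)`: the most occupied bin is 0 and
#' empty bins are `Inf` (never zero).
#'
#' @param traj A `mutnet_trajectory` with at least 2 frames.
#' @param temperature Kelvin (default 333).
#' @param bins Bins per principal-component axis (default 32).
#' @param superpose Superpose frames first (default `TRUE`).
#' @return A `fel_result`: list with `projections` (tibble `frame`, `PC1`,
#'   `PC2`), `grid` (tibble `pc1`, `pc2`, `probability`, `free_energy`),
#'   `variance_explained`, `temperature`.
#' @export
pca_fel <- function(traj, temperature = 333, bins = 32, superpose = TRUE) {
  nf <- n_frames(traj)
  if (nf < 2) abort("PCA needs at least 2 frames (degenerate covariance)")
  if (superpose) traj <- superpose_trajectory(traj)
  flat <- t(vapply(traj$frames, function(f) as.numeric(f),
                   numeric(3 * n_atoms(traj$topology))))
  pc <- prcomp(flat, center = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  proj <- tibble(frame = seq_len(nf), PC1 = pc$x[, 1],
                 PC2 = if (ncol(pc$x) >= 2) pc$x[, 2] else rep(0, nf))
  brk <- function(z) {
    r <- range(z)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = bins + 1)
  }
  b1 <- brk(proj$PC1)
  b2 <- brk(proj$PC2)
  i1 <- pmin(findInterval(proj$PC1, b1, rightmost.closed = TRUE), bins)
  i2 <- pmin(findInterval(proj$PC2, b2, rightmost.closed = TRUE), bins)
  counts <- matrix(0, bins, bins)
  for (k in seq_len(nf)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1
  p <- counts / nf
  fel <- -KB_KCAL * temperature * log(p / max(p))
  fel[p == 0] <- Inf
  mid <- function(b) (b[-1] + b[-length(b)]) / 2
  grid <- tibble(pc1 = rep(mid(b1), times = bins),
                 pc2 = rep(mid(b2), each = bins),
                 probability = as.numeric(p),
                 free_energy = as.numeric(fel))
  structure(list(projections = proj, grid = grid,
                 variance_explained = ve, temperature = temperature,
                 breaks = list(pc1 = b1, pc2 = b2)),
            class = "fel_result")
}

#' @export
print.fel_result <- function(x, ...) {
  cat("<fel_result> ", nrow(x$projections), " frames; PC1/PC2 explain ",
      round(100 * sum(x$variance_explained[1:2]), 1), "% variance\n",
      sep = "")
  invisible(x)
}
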