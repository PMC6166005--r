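#' Generate a compact toy protein with a pocket-bound ligand
#'
#' Builds a pseudo-atom polymer on a compact space-filling (boustrophedon
#' grid) curve, so the contact graph has cliques and communities like a
#' folded domain, and places a small ligand residue in a pocket near the
#' fold's centre. Each protein residue carries five pseudo-atoms (N, CA, C,
#' O, CB); the ligand (`FRU`, chain `L`) carries C1, O1, O2 so hydrogen-bond
#' donors/acceptors exist on both sides. Purely geometric -- no physics;
#' only the contact topology matters downstream.
#'
#' The construction is deterministic under `seed` (a small seeded jitter
#' decorrelates structures built with different seeds). After placement the
#' pocket contract -- ligand centroid within 4 Angstrom of the nearest atom
#' of at least `pocket_size` residues -- is verified, and the generator
#' errors rather than return a structure that violates it (geometrically
#' unattainable for large `pocket_size`).
#'
#' @param n_res Number of protein residues, >= 8.
#' @param pocket_size Number of pocket residues the ligand must touch,
#'   in `[3, n_res)`.
#' @param seed Integer seed.
#' @return A `mutnet_structure` tibble (protein residues plus one ligand).
#' @export
make_toy_protein <- function(n_res, pocket_size, seed) {
  if (n_res < 8) abort("n_res must be >= 8")
  if (pocket_size < 3 || pocket_size >= n_res) {
    abort("pocket_size must satisfy 3 <= pocket_size < n_res")
  }
  spacing <- 4.0
  m <- ceiling(n_res^(1 / 3))
  # boustrophedon walk over an m^3 grid: consecutive residues stay adjacent
  pos <- matrix(0, n_res, 3)
  i <- 0
  for (iz in seq_len(m)) {
    ys <- if (iz %% 2 == 1) seq_len(m) else rev(seq_len(m))
    for (iy in ys) {
      fwd <- (iz + iy) %% 2 == 0
      xs <- if (fwd) seq_len(m) else rev(seq_len(m))
      for (ix in xs) {
        i <- i + 1
        if (i > n_res) break
        pos[i, ] <- spacing * c(ix, iy, iz)
      }
      if (i > n_res) break
    }
    if (i > n_res) break
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pos <- pos + matrix(rnorm(3 * n_res, 0, 0.15), n_res, 3)
  centre <- colMeans(pos)
  unitv <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-9) c(1, 0, 0) else v / n
  }
  resnames <- sample(c("ALA", "SER", "THR", "VAL", "LEU", "ASP", "ASN", "GLY"),
                     n_res, replace = TRUE)
  rows <- vector("list", n_res + 1)
  for (r in seq_len(n_res)) {
    ca <- pos[r, ]
    nxt <- if (r < n_res) pos[r + 1, ] else pos[r - 1, ]
    prv <- if (r > 1) pos[r - 1, ] else pos[r + 1, ]
    u_chain <- unitv(nxt - prv)
    u_in <- unitv(centre - ca)
    at_n <- ca - 1.2 * u_chain
    at_c <- ca + 1.2 * u_chain
    at_o <- at_c + 1.2 * unitv(u_in + c(0.3, 0, 0))
    at_cb <- ca + 1.5 * u_in
    xyz <- unname(rbind(at_n, ca, at_c, at_o, at_cb))
    rows[[r]] <- tibble(
      chain = "A", resid = r, resname = resnames[r], is_ligand = FALSE,
      atom = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  cb_mat <- t(vapply(rows[seq_len(n_res)],
                     function(d) c(d$x[5], d$y[5], d$z[5]), numeric(3)))
  d_centre <- sqrt(rowSums(sweep(cb_mat, 2, centre)^2))
  pocket <- order(d_centre)[seq_len(pocket_size)]
  lig_centre <- colMeans(cb_mat[pocket, , drop = FALSE])
  lig_off <- rbind(c(0, 0, 0), c(0.7, 0, 0), c(-0.35, 0.6, 0))
  lig_xyz <- sweep(lig_off, 2, lig_centre - colMeans(lig_off), "+")
  rows[[n_res + 1]] <- tibble(
    chain = "L", resid = 1L, resname = "FRU", is_ligand = TRUE,
    atom = c("C1", "O1", "O2"), element = c("C", "O", "O"),
    x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3])
  s <- as_structure(bind_rows(rows))
  # verify the pocket contract instead of silently violating it
  lig_cen <- colMeans(lig_xyz)
  near <- vapply(pocket, function(r) {
    d <- rows[[r]]
    min(sqrt((d$x - lig_cen[1])^2 + (d$y - lig_cen[2])^2 +
               (d$z - lig_cen[3])^2))
  }, numeric(1))
  if (sum(near <= 4) < pocket_size) {
    abort(paste0("could not place a ligand within 4 Angstrom of ",
                 pocket_size, " pocket residues; reduce pocket_size"))
  }
  s
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Thermally perturb a structure into a multi-frame trajectory
#'
#' Frame i equals the reference coordinates plus i.i.d. Gaussian noise of
#' standard deviation `noise_sd` on every coordinate -- an idealized stand-in
#' for equilibrated-ensemble snapshots in which persistent contacts stay
#' within their geometric cutoffs and marginal ones flicker.
#'
#' @param structure Reference `mutnet_structure`.
#' @param n_frames Number of frames, >= 1.
#' @param noise_sd Per-coordinate noise SD in Angstrom, >= 0.
#' @param seed Integer seed.
#' @return A `mutnet_trajectory`.
#' @export
perturb_trajectory <- function(structure, n_frames, noise_sd, seed) {
  structure <- as_structure(structure)
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  ref <- coord_matrix(structure)
  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(i) {
      ref + matrix(rnorm(length(ref), 0, noise_sd), nrow(ref), 3)
    })
  })
  new_trajectory(structure, frames)
}

#' Steered overdamped Langevin dynamics on a toy potential
#'
#' A particle on potential `U` is dragged by a harmonic guide of stiffness
#' `k_spring` whose anchor moves at constant velocity `v` from `span[1]` to
#' `span[2]`. The overdamped update is
#' `x <- x + (dt/friction) * (-U'(x) + k_spring (lambda - x)) +
#' sqrt(2 kB T dt / friction) * xi`, and the external work accumulates as
#' `dW = k_spring (lambda - x) * v dt` (the work done by the moving guide;
#' it can be negative). `W(0) = 0` and the trace ends when the guide reaches
#' `span[2]`.
#'
#' @param potential A [toy_potential()].
#' @param k_spring Guide stiffness, kcal/(mol A^2). Default 40.
#' @param v Pulling speed, Angstrom/ns. Default 10.
#' @param span Numeric `(start, end)` of the guide position, Angstrom.
#' @param params A [langevin_params()] (seed mandatory).
#' @param x0 Initial particle position; defaults to `span[1]`.
#' @param store_every Store every `store_every`-th step (plus start and end).
#' @return A `work_trajectory` tibble with columns `time` (ps), `lambda`,
#'   `position` (Angstrom) and `work` (kcal/mol).
#' @export
steered_langevin <- function(potential, k_spring = 40, v = 10, span,
                             params, x0 = span[1], store_every = 1L) {
  res <- steer_swarm(potential, k_spring, v, span, params$temperature,
                     params$friction, params$dt, seeds = params$seed,
                     x0 = x0, store_every = store_every)
  out <- tibble(time = res$time, lambda = res$lambda,
                position = res$position[, 1], work = res$work[, 1])
  class(out) <- unique(c("work_trajectory", class(out)))
  attr(out, "meta") <- list(k_spring = k_spring, v = v, span = span,
                            temperature = params$temperature,
                            friction = params$friction, dt = params$dt,
                            seed = params$seed)
  out
}

# Vectorized engine: one time loop, columns are independent trajectories
# (each with its own noise stream seeded from seeds[j]).
steer_swarm <- function(potential, k_spring, v, span, temperature, friction,
                        dt, seeds, x0, store_every = 1L) {
  if (span[2] == span[1]) abort("span end must differ from span start")
  dirn <- sign(span[2] - span[1])  # descending spans = reverse pulls
  check_domain(potential, sort(span))
  n_traj <- length(seeds)
  v_ps <- v / 1000  # Angstrom/ns -> Angstrom/ps
  if (v_ps > 0) {
    n_steps <- ceiling(abs(span[2] - span[1]) / (v_ps * dt) - 1e-9)
  } else {
    n_steps <- 0L
  }
  noise_amp <- sqrt(2 * KB_KCAL * temperature * dt / friction)
  noise <- matrix(0, max(n_steps, 1), n_traj)
  for (j in seq_len(n_traj)) {
    noise[, j] <- with_seed(seeds[j], rnorm(max(n_steps, 1)))
  }
  if (dt * k_spring / friction > 1.5) {
    warn("dt * k_spring / friction > 1.5: overdamped update may be unstable")
  }
  x <- rep(x0, length.out = n_traj)
  w <- numeric(n_traj)
  keep <- unique(c(0, seq(0, n_steps, by = max(1L, as.integer(store_every))),
                   n_steps))
  keep <- sort(keep)
  X <- matrix(NA_real_, length(keep), n_traj)
  W <- matrix(NA_real_, length(keep), n_traj)
  clamp <- function(z) if (dirn > 0) pmin(z, span[2]) else pmax(z, span[2])
  lam_keep <- clamp(span[1] + dirn * v_ps * dt * keep)
  slot <- 1
  X[1, ] <- x
  W[1, ] <- 0
  if (n_steps > 0) {
    for (step in seq_len(n_steps)) {
      lam <- clamp(span[1] + dirn * v_ps * dt * (step - 1))
      pull <- k_spring * (lam - x)
      w <- w + pull * dirn * v_ps * dt
      x <- x + (dt / friction) * (-potential$dU(x) + pull) +
        noise_amp * noise[step, ]
      if (keep[slot + 1] == step) {
        slot <- slot + 1
        X[slot, ] <- x
        W[slot, ] <- w
      }
    }
  }
  list(time = keep * dt, lambda = lam_keep, position = X, work = W,
       x_final = x, w_final = w)
}

#' Mean energy-term specification
#'
#' @param E_vdW,E_ele,G_GB,G_SA,minus_T_dS Component means, kcal/mol.
#'   `minus_T_dS` is the entropic term kept in its -T*dS sign convention so
#'   binding free energy is a plain sum.
#' @return A one-row tibble of components.
#' @export
energy_components <- function(E_vdW, E_ele, G_GB, G_SA, minus_T_dS = 0) {
  tibble(E_vdW = E_vdW, E_ele = E_ele, G_GB = G_GB, G_SA = G_SA,
         minus_T_dS = minus_T_dS)
}

#' Simulate a per-frame energy-component table
#'
#' Each term is drawn i.i.d. Gaussian around its specified mean with a
#' common (or per-term) SD, emulating the per-snapshot samples behind an
#' end-state MM-GB/SA average.
#'
#' @param mean_components One-row data frame of term means (see
#'   [energy_components()]).
#' @param sd Common SD (kcal/mol) or a named vector per term.
#' @param n_frames Number of rows, >= 2.
#' @param seed Integer seed.
#' @return A tibble with `n_frames` rows and one column per term.
#' @export
make_energy_table <- function(mean_components, sd, n_frames, seed) {
  if (n_frames < 2) abort("n_frames must be >= 2")
  mc <- as_tibble(mean_components)
  if (nrow(mc) != 1) abort("mean_components must have exactly one row")
  terms <- names(mc)
  sds <- if (length(sd) == 1) setNames(rep(sd, length(terms)), terms) else sd
  with_seed(seed, {
    as_tibble(lapply(setNames(terms, terms), function(tm) {
      rnorm(n_frames, mean = mc[[tm]], sd = sds[[tm]])
    }))
  })
}

#' Write / read steered-work traces as 4-column delimited text
#'
#' Columns: `time` (ps), `lambda`, `position` (Angstrom), `work` (kcal/mol).
#'
#' @param trace A `work_trajectory` tibble.
#' @param path File path.
#' @return `path` (writer) or a `work_trajectory` tibble (reader).
#' @export
write_work_trace <- function(trace, path) {
  readr::write_tsv(as_tibble(trace)[, c("time", "lambda", "position", "work")],
                   path)
  invisible(path)
}

#' @rdname write_work_trace
#' @export
read_work_trace <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("time", "lambda", "position", "work")
  if (!all(need %in% names(out))) {
    abort(paste0("work trace must have columns ", paste(need, collapse = ", ")))
  }
  class(out) <- unique(c("work_trajectory", class(out)))
  out
}
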