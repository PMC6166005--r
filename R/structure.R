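#' Atom-level structure tables
#'
#' A structure is an ordinary tibble with one row per atom and columns
#' `chain`, `resid`, `resname`, `is_ligand`, `atom`, `element`, `x`, `y`, `z`
#' (coordinates in Angstrom). `as_structure()` validates a data frame and
#' stamps the `mutnet_structure` class so downstream functions can assume the
#' invariants: finite coordinates, non-empty atom names, atom names unique
#' within a residue, and atoms of a residue contiguous.
#'
#' @param x A data frame with the columns listed above (`element` and
#'   `is_ligand` are filled in when absent).
#' @return A `mutnet_structure` tibble.
#' @examples
#' s <- make_toy_protein(n_res = 10, pocket_size = 3, seed = 1)
#' n_atoms(s)
#' residues(s)
#' @export
as_structure <- function(x) {
  x <- as_tibble(x)
  needed <- c("chain", "resid", "resname", "atom", "x", "y", "z")
  miss <- setdiff(needed, names(x))
  if (length(miss) > 0) {
    abort(paste0("structure is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) abort("structure must contain at least one atom")
  if (!"is_ligand" %in% names(x)) x$is_ligand <- FALSE
  if (!"element" %in% names(x)) x$element <- guess_element(x$atom)
  x$resid <- as.integer(x$resid)
  coords <- as.matrix(x[, c("x", "y", "z")])
  if (!all(is.finite(coords))) abort("structure coordinates must be finite")
  if (any(!nzchar(x$atom))) abort("atom names must be non-empty")
  key <- paste(x$chain, x$resid, sep = ":")
  dup <- duplicated(paste(key, x$atom))
  if (any(dup)) {
    abort(paste0("duplicate atom name within residue: ",
                 paste(unique(paste(key, x$atom)[dup]), collapse = ", ")))
  }
  # residues must be contiguous blocks so frame coordinates map unambiguously
  blocks <- rle(key)$values
  if (anyDuplicated(blocks)) abort("atoms of each (chain, resid) must be contiguous")
  class(x) <- unique(c("mutnet_structure", setdiff(class(x), "mutnet_structure")))
  x
}

guess_element <- function(atom_name) {
  el <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", atom_name)), 1, 1))
  el[!nzchar(el)] <- "C"
  el
}

#' @rdname as_structure
#' @export
n_atoms <- function(x) nrow(x)

#' @rdname as_structure
#' @export
residues <- function(x) {
  distinct(as_tibble(x), .data$chain, .data$resid, .data$resname, .data$is_ligand)
}

#' Residue node identifiers
#'
#' Network node ids are `"chain:resid"` strings, e.g. `"A:114"`.
#'
#' @param x A structure tibble or a data frame with `chain`/`resid` columns.
#' @return Character vector of node ids (one per row of `x`).
#' @export
node_ids <- function(x) paste(x$chain, x$resid, sep = ":")

coord_matrix <- function(structure) {
  m <- as.matrix(structure[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

set_coords <- function(structure, coords) {
  structure$x <- coords[, 1]
  structure$y <- coords[, 2]
  structure$z <- coords[, 3]
  structure
}

#' Read a PDB file into a structure table
#'
#' Parses the fixed-column `ATOM`/`HETATM` subset of the PDB format. `HETATM`
#' residues are flagged as ligand. Alternate locations are resolved by keeping
#' the highest-occupancy record (first on ties); insertion codes are rejected
#' with an error since residue identity is keyed on `(chain, resid)` alone.
#'
#' @param path Path to a PDB file.
#' @return A `mutnet_structure` tibble.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read PDB file: ", path))
  lines <- readLines(path, warn = FALSE)
  parse_pdb_atoms(lines, path)
}

parse_pdb_atoms <- function(lines, path = "<text>") {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) abort(paste0("no ATOM/HETATM records in ", path))
  idx <- which(is_atom)
  ln <- lines[idx]
  fx <- function(from, to) trimws(substr(ln, from, to))
  icode <- fx(27, 27)
  if (any(nzchar(icode))) {
    abort(paste0("insertion codes are not supported (line ",
                 idx[which(nzchar(icode))[1]], " of ", path, ")"))
  }
  num <- function(s, what) {
    out <- suppressWarnings(as.numeric(s))
    bad <- which(!is.finite(out) | !nzchar(s))
    if (length(bad) > 0) {
      abort(paste0("unparsable ", what, " field at line ", idx[bad[1]],
                   " of ", path, ": '", ln[bad[1]], "'"))
    }
    out
  }
  occ_raw <- fx(55, 60)
  occ <- suppressWarnings(as.numeric(occ_raw))
  occ[!is.finite(occ)] <- 1
  el <- fx(77, 78)
  atom_name <- fx(13, 16)
  el[!nzchar(el)] <- guess_element(atom_name[!nzchar(el)])
  dat <- tibble(
    record = substr(ln, 1, 6),
    atom = atom_name,
    altloc = fx(17, 17),
    resname = fx(18, 20),
    chain = fx(22, 22),
    resid = as.integer(num(fx(23, 26), "residue number")),
    x = num(fx(31, 38), "x coordinate"),
    y = num(fx(39, 46), "y coordinate"),
    z = num(fx(47, 54), "z coordinate"),
    occupancy = occ,
    element = toupper(el)
  )
  dat$chain[!nzchar(dat$chain)] <- "A"
  # alternate locations: highest occupancy wins, first record on ties
  dat <- dat |>
    mutate(.ord = seq_len(dplyr::n())) |>
    group_by(.data$chain, .data$resid, .data$atom) |>
    filter(.data$.ord == .data$.ord[order(-.data$occupancy, .data$.ord)][1]) |>
    ungroup() |>
    arrange(.data$.ord)
  dat |>
    mutate(is_ligand = .data$record == "HETATM") |>
    group_by(.data$chain, .data$resid) |>
    mutate(is_ligand = any(.data$is_ligand)) |>
    ungroup() |>
    select("chain", "resid", "resname", "is_ligand", "atom", "element",
           "x", "y", "z") |>
    as_structure()
}

format_pdb_atoms <- function(structure, serial_start = 1L) {
  name4 <- ifelse(nchar(structure$atom) < 4,
                  sprintf(" %-3s", structure$atom),
                  substr(structure$atom, 1, 4))
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(structure$is_ligand, "HETATM", "ATOM"),
          serial_start - 1L + seq_len(nrow(structure)),
          name4, structure$resname, structure$chain, structure$resid,
          structure$x, structure$y, structure$z, 1, 0,
          substr(structure$element, 1, 2))
}

#' Write a structure as a PDB file
#'
#' Coordinates are written in the standard 8.3 fixed columns (three decimals);
#' ligand residues become `HETATM` records. Output is bit-stable for a fixed
#' input and re-readable by [read_pdb()].
#'
#' @param structure A `mutnet_structure` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  structure <- as_structure(structure)
  out <- c(format_pdb_atoms(structure), "END")
  tryCatch(writeLines(out, path),
           error = function(e) abort(paste0("cannot write PDB file: ", path)))
  invisible(path)
}

#' Trajectories
#'
#' A trajectory couples a topology (a structure table) with an ordered list of
#' coordinate frames (each an `n_atoms x 3` matrix, Angstrom) and an optional
#' per-frame reaction-coordinate value.
#'
#' @param topology A `mutnet_structure` tibble.
#' @param frames List of `n_atoms x 3` coordinate matrices.
#' @param rc Optional numeric vector, one reaction-coordinate value per frame.
#' @return A `mutnet_trajectory` object.
#' @export
new_trajectory <- function(topology, frames, rc = NULL) {
  topology <- as_structure(topology)
  if (length(frames) < 1) abort("a trajectory needs at least one frame")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    if (nrow(frames[[i]]) != na || ncol(frames[[i]]) != 3) {
      abort(paste0("frame ", i, " has ", nrow(frames[[i]]),
                   " atoms; topology has ", na))
    }
  }
  if (!is.null(rc) && length(rc) != length(frames)) {
    abort("rc must have one value per frame")
  }
  structure(list(topology = topology, frames = frames, rc = rc),
            class = "mutnet_trajectory")
}

#' @export
print.mutnet_trajectory <- function(x, ...) {
  cat("<mutnet_trajectory> ", length(x$frames), " frames, ",
      n_atoms(x$topology), " atoms",
      if (!is.null(x$rc)) " (+reaction coordinate)", "\n", sep = "")
  invisible(x)
}

#' @rdname new_trajectory
#' @param traj A `mutnet_trajectory`.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory as a structure
#'
#' @param traj A `mutnet_trajectory`.
#' @param i Frame index.
#' @return A `mutnet_structure` tibble with the frame's coordinates.
#' @export
trajectory_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) abort(paste0("no frame ", i))
  set_coords(traj$topology, traj$frames[[i]])
}

#' Read a trajectory from multi-model PDB or per-frame XYZ text
#'
#' Multi-model PDB (`MODEL`/`ENDMDL`) is the canonical dialect; a plain
#' whitespace-delimited XYZ-per-frame reader (three numbers per atom line,
#' frames of `n_atoms` lines, optional `# rc <value>` line before a frame) is
#' provided for synthetic fixtures. A per-frame reaction coordinate is
#' preserved when present (PDB dialect: `REMARK   6 RC <value>` inside a
#' model).
#'
#' @param path Path to the trajectory file.
#' @param topology A `mutnet_structure` giving the atom order.
#' @return A `mutnet_trajectory`.
#' @export
read_trajectory <- function(path, topology) {
  topology <- as_structure(topology)
  if (!file.exists(path)) abort(paste0("cannot read trajectory file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^(ATOM  |HETATM|MODEL)", lines))) {
    read_trajectory_pdb(lines, topology, path)
  } else {
    read_trajectory_xyz(lines, topology, path)
  }
}

read_trajectory_pdb <- function(lines, topology, path) {
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    s <- parse_pdb_atoms(lines, path)
    check_frame_atoms(n_atoms(s), n_atoms(topology), 1)
    return(new_trajectory(topology, list(coord_matrix(s))))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    abort(paste0("unbalanced MODEL/ENDMDL records in ", path))
  }
  frames <- vector("list", length(model_starts))
  rc <- rep(NA_real_, length(model_starts))
  for (i in seq_along(model_starts)) {
    chunk <- lines[model_starts[i]:model_ends[i]]
    rc_line <- grep("^REMARK +6 +RC ", chunk, value = TRUE)
    if (length(rc_line) > 0) {
      rc[i] <- as.numeric(sub("^REMARK +6 +RC +", "", rc_line[1]))
    }
    s <- parse_pdb_atoms(chunk, path)
    check_frame_atoms(n_atoms(s), n_atoms(topology), i)
    frames[[i]] <- coord_matrix(s)
  }
  new_trajectory(topology, frames, rc = if (all(is.na(rc))) NULL else rc)
}

read_trajectory_xyz <- function(lines, topology, path) {
  lines <- lines[nzchar(trimws(lines))]
  na <- n_atoms(topology)
  frames <- list()
  rc <- numeric(0)
  i <- 1
  frame_no <- 0
  while (i <= length(lines)) {
    frame_no <- frame_no + 1
    this_rc <- NA_real_
    if (grepl("^#", lines[i])) {
      if (grepl("^# *rc ", lines[i], ignore.case = TRUE)) {
        this_rc <- as.numeric(sub("^# *rc +", "", lines[i], ignore.case = TRUE))
      }
      i <- i + 1
    }
    stop_at <- i
    while (stop_at <= length(lines) && !grepl("^#", lines[stop_at])) {
      stop_at <- stop_at + 1
    }
    avail <- stop_at - i
    take <- min(avail, na)
    if (take < na) {
      abort(paste0("frame ", frame_no, " of ", path, " has ", take,
                   " atom line(s); topology has ", na))
    }
    block <- lines[i:(i + na - 1)]
    vals <- suppressWarnings(
      matrix(as.numeric(unlist(strsplit(trimws(block), "[[:space:]]+"))),
             ncol = 3, byrow = TRUE))
    if (nrow(vals) != na || !all(is.finite(vals))) {
      abort(paste0("frame ", frame_no, " of ", path,
                   " is not 3-column numeric XYZ"))
    }
    frames[[frame_no]] <- vals
    rc[frame_no] <- this_rc
    i <- i + na
    if (avail > na && avail %% na != 0) {
      abort(paste0("frame ", frame_no + 1, " of ", path,
                   " has ", avail - na, " atom line(s); topology has ", na))
    }
  }
  if (length(frames) == 0) abort(paste0("no frames in ", path))
  new_trajectory(topology, frames, rc = if (all(is.na(rc))) NULL else rc)
}

check_frame_atoms <- function(got, want, frame) {
  if (got != want) {
    abort(paste0("frame ", frame, " has ", got, " atoms; topology has ", want))
  }
}

#' Write a trajectory
#'
#' @param traj A `mutnet_trajectory`.
#' @param path Output path.
#' @param format `"pdb"` (multi-model, canonical) or `"xyz"` (plain text).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  out <- character(0)
  for (i in seq_len(n_frames(traj))) {
    s <- trajectory_frame(traj, i)
    rc_i <- if (!is.null(traj$rc)) traj$rc[i] else NA_real_
    if (format == "pdb") {
      out <- c(out, sprintf("MODEL %8d", i),
               if (!is.na(rc_i)) sprintf("REMARK   6 RC %.6f", rc_i),
               format_pdb_atoms(s), "ENDMDL")
    } else {
      out <- c(out,
               if (!is.na(rc_i)) sprintf("# rc %.6f", rc_i) else "# frame",
               sprintf("%.6f %.6f %.6f", s$x, s$y, s$z))
    }
  }
  if (format == "pdb") out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
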