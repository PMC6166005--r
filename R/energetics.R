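ENERGY_TERMS <- c("E_vdW", "E_ele", "G_GB", "G_SA", "minus_T_dS")

#' Nonpolar solvation energy from a surface-area change
#'
#' The linear surface-area model `G_SA = 0.0072 * dSASA` (kcal/mol per
#' Angstrom^2). Only the linear map is provided; computing the surface area
#' itself is out of scope.
#'
#' @param dSASA Change in solvent-accessible surface area, Angstrom^2.
#' @return Nonpolar solvation free energy, kcal/mol.
#' @examples
#' gsa_from_sasa(1000)  # 7.2
#' @export
gsa_from_sasa <- function(dSASA) {
  if (any(!is.finite(dSASA))) abort("dSASA must be finite")
  0.0072 * dSASA
}

#' Combine MM-GB/SA components into derived binding energies
#'
#' For each input row:
#' `G_polar = E_ele + G_GB`, `G_nonpolar = E_vdW + G_SA`,
#' `G_mmgbsa = E_ele + G_GB + E_vdW + G_SA`,
#' `G_bind = G_mmgbsa + minus_T_dS` (the entropic term is consumed as a
#' number in its -T*dS convention, so binding free energy is a plain sum).
#' All arithmetic is full precision; use [format_energies()] for the
#' conventional 2-decimal presentation.
#'
#' @param components A data frame with columns `E_vdW`, `E_ele`, `G_GB`,
#'   `G_SA` and optionally `minus_T_dS` (a named vector also works). If a
#'   `dSASA` column is present, `G_SA` must agree with
#'   [gsa_from_sasa()] within 0.005 kcal/mol.
#' @return The input tibble with `G_polar`, `G_nonpolar`, `G_mmgbsa`,
#'   `G_bind` columns appended.
#' @examples
#' mmgbsa_combine(energy_components(
#'   E_vdW = -15.61, E_ele = -72.82, G_GB = 59.62, G_SA = -3.88,
#'   minus_T_dS = 19.46))
#' @export
mmgbsa_combine <- function(components) {
  if (is.numeric(components) && !is.null(names(components))) {
    components <- as_tibble(as.list(components))
  }
  components <- as_tibble(components)
  for (term in c("E_vdW", "E_ele", "G_GB", "G_SA")) {
    if (!term %in% names(components)) {
      abort(paste0("missing energy term: ", term))
    }
    if (any(!is.finite(components[[term]]))) {
      abort(paste0("energy term ", term, " must be finite"))
    }
  }
  if (!"minus_T_dS" %in% names(components)) components$minus_T_dS <- 0
  if ("dSASA" %in% names(components)) {
    implied <- gsa_from_sasa(components$dSASA)
    if (any(abs(implied - components$G_SA) > 0.005)) {
      abort("G_SA is inconsistent with 0.0072 * dSASA (tolerance 0.005)")
    }
  }
  mutate(components,
         G_polar = .data$E_ele + .data$G_GB,
         G_nonpolar = .data$E_vdW + .data$G_SA,
         G_mmgbsa = .data$E_ele + .data$G_GB + .data$E_vdW + .data$G_SA,
         G_bind = .data$G_mmgbsa + .data$minus_T_dS)
}

#' @rdname mmgbsa_combine
#' @param x A tibble of energies.
#' @param digits Presentation rounding (default 2, the conventional table
#'   format).
#' @export
format_energies <- function(x, digits = 2) {
  mutate(x, across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

#' Average a per-frame energy-component table
#'
#' @param table A data frame of per-frame samples with one column per energy
#'   term (at least 2 rows).
#' @return A one-row tibble of per-term means plus `<term>_sd` sample
#'   standard deviations.
#' @export
aggregate_frames <- function(table) {
  table <- as_tibble(table)
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  if (length(num) == 0) abort("no numeric energy-term columns found")
  if (nrow(table) < 2) {
    abort("aggregate_frames needs at least 2 frames")
  }
  means <- as_tibble(lapply(table[num], mean))
  sds <- as_tibble(setNames(lapply(table[num], sd), paste0(num, "_sd")))
  dplyr::bind_cols(means, sds)
}

#' Check a per-residue energy decomposition against the total
#'
#' @param per_residue Named numeric vector or data frame (`residue`,
#'   `energy`) of per-residue contributions.
#' @param total The total the contributions should sum to, kcal/mol.
#' @param tol Acceptance tolerance, > 0.
#' @return A one-row tibble (`pass`, `residual`, `decomposed_sum`, `total`).
#' @export
decomposition_check <- function(per_residue, total, tol = 0.05) {
  if (tol <= 0) abort("tol must be > 0")
  vals <- if (is.data.frame(per_residue)) per_residue$energy else
    as.numeric(per_residue)
  if (length(vals) == 0) abort("per-residue decomposition is empty")
  s <- sum(vals)
  residual <- abs(s - total)
  tibble(pass = residual <= tol, residual = residual,
         decomposed_sum = s, total = total)
}

#' Read / write energy-component tables as delimited text
#'
#' Header column names follow the term names of [energy_components()].
#'
#' @param path File path.
#' @param table A data frame of per-frame components.
#' @return A tibble (reader) or `path` (writer).
#' @export
read_energy_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_energy_table
#' @export
write_energy_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}
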