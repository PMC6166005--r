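#' Toy one-dimensional potentials
#'
#' A small library of analytically differentiable potentials used as
#' stand-ins for the protein--ligand interaction along a dissociation
#' coordinate when exercising the steered-dynamics machinery. Energies are
#' kcal/mol, coordinates Angstrom.
#'
#' * `flat`: U(x) = 0.
#' * `harmonic`: U(x) = c/2 (x - x0)^2, parameters `c` (kcal/(mol A^2)) and `x0`.
#' * `double_well`: U(x) = h (((x - c)/w)^2 - 1)^2, minima at `c - w` and
#'   `c + w`, barrier height `h` at `x = c`.
#' * `tabulated`: natural cubic spline through points (`x`, `y`); evaluable
#'   only inside `range(x)`.
#'
#' @param kind Potential family, one of `"flat"`, `"harmonic"`,
#'   `"double_well"`, `"tabulated"`.
#' @param ... Parameters of the family (see above).
#' @return A `toy_potential` object with `U(x)` and `dU(x)` evaluators.
#' @examples
#' pot <- toy_potential("harmonic", c = 0.2, x0 = 4)
#' potential_energy(pot, c(4, 30))
#' @export
toy_potential <- function(kind = c("flat", "harmonic", "double_well", "tabulated"),
                          ...) {
  kind <- match.arg(kind)
  p <- list(...)
  pot <- switch(kind,
    flat = list(U = function(x) rep(0, length(x)),
                dU = function(x) rep(0, length(x)),
                domain = c(-Inf, Inf)),
    harmonic = {
      cc <- p$c %||% 1
      x0 <- p$x0 %||% 0
      list(U = function(x) 0.5 * cc * (x - x0)^2,
           dU = function(x) cc * (x - x0),
           domain = c(-Inf, Inf))
    },
    double_well = {
      h <- p$h %||% 2
      cen <- p$c %||% 0
      w <- p$w %||% 1
      list(U = function(x) h * (((x - cen) / w)^2 - 1)^2,
           dU = function(x) 4 * h * (((x - cen) / w)^2 - 1) * (x - cen) / w^2,
           domain = c(-Inf, Inf))
    },
    tabulated = {
      xs <- p$x
      ys <- p$y
      if (is.null(xs) || is.null(ys) || length(xs) != length(ys) || length(xs) < 4) {
        abort("tabulated potential needs x and y vectors of equal length >= 4")
      }
      f <- stats::splinefun(xs, ys, method = "natural")
      list(U = function(x) f(x), dU = function(x) f(x, deriv = 1),
           domain = range(xs))
    })
  structure(c(pot, list(kind = kind, params = p)), class = "toy_potential")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname toy_potential
#' @param pot A `toy_potential`.
#' @param x Coordinates (Angstrom) at which to evaluate.
#' @export
potential_energy <- function(pot, x) {
  check_domain(pot, x)
  pot$U(x)
}

#' @rdname toy_potential
#' @export
potential_force <- function(pot, x) {
  check_domain(pot, x)
  -pot$dU(x)
}

check_domain <- function(pot, x) {
  if (any(x < pot$domain[1] | x > pot$domain[2])) {
    abort(paste0("potential '", pot$kind, "' is not evaluable outside [",
                 pot$domain[1], ", ", pot$domain[2], "]"))
  }
  invisible(TRUE)
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("<toy_potential> kind =", x$kind, "\n")
  invisible(x)
}

#' Parameters for overdamped steered Langevin dynamics
#'
#' `friction` is the effective (mass-scaled) friction coefficient of the
#' overdamped update, in kcal ps/(mol A^2); together with the thermal noise
#' amplitude sqrt(2 kB T dt / friction) it sets the diffusion constant
#' D = kB T / friction. The default temperature of 333 K matches the
#' production conditions the synthetic traces emulate.
#'
#' @param temperature Kelvin, > 0.
#' @param friction Effective friction, > 0.
#' @param dt Time step in ps, > 0.
#' @param seed Integer seed; mandatory for any stochastic run.
#' @return A `langevin_params` list.
#' @export
langevin_params <- function(temperature = 333, friction = 1, dt = 0.01,
                            seed = NULL) {
  if (is.null(seed)) abort("langevin_params requires an explicit seed")
  if (temperature <= 0) abort("temperature must be > 0")
  if (friction <= 0) abort("friction must be > 0")
  if (dt <= 0) abort("dt must be > 0")
  structure(list(temperature = temperature, friction = friction, dt = dt,
                 seed = as.integer(seed)),
            class = "langevin_params")
}
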