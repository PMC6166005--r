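#' Jarzynski free-energy estimate from nonequilibrium work samples
#'
#' The Jarzynski equality `exp(-beta dF) = <exp(-beta W)>` turns work values
#' from repeated finite-speed pulls into a free-energy difference:
#' `dF = -(1/beta) ln mean(exp(-beta W))`. Computed in shifted
#' (log-sum-exp) form for numerical stability; mathematically identical to
#' the direct expression. By Jensen's inequality `dF <= mean(W)`, with
#' equality when all works coincide.
#'
#' @param works Numeric vector of accumulated works, kcal/mol (length >= 1).
#' @param temperature Kelvin.
#' @param kB Boltzmann constant; default kcal/(mol K). Pass `kB = 1`,
#'   `temperature = 1` for natural units where `beta = 1`.
#' @return Free-energy estimate, kcal/mol.
#' @examples
#' jarzynski_free_energy(c(1, 2), temperature = 1, kB = 1)
#' # -log((exp(-1) + exp(-2))/2)
#' @export
jarzynski_free_energy <- function(works, temperature = 333,
                                  kB = 0.0019872041) {
  if (length(works) < 1) abort("works must contain at least one value")
  if (temperature <= 0) abort("temperature must be > 0")
  beta <- 1 / (kB * temperature)
  w_min <- min(works)
  w_min - log(mean(exp(-beta * (works - w_min)))) / beta
}

#' A stage swarm of steered work trajectories
#'
#' @param trajectories List of `work_trajectory` tibbles sharing an identical
#'   guide grid.
#' @param span Numeric `(start, end)` of the stage's guide positions.
#' @param stage Optional stage index.
#' @return A `stage_swarm` object.
#' @export
stage_swarm <- function(trajectories, span, stage = NA_integer_) {
  if (length(trajectories) < 1) abort("a stage swarm needs >= 1 trajectory")
  lam <- trajectories[[1]]$lambda
  for (tr in trajectories) {
    if (length(tr$lambda) != length(lam) ||
        max(abs(tr$lambda - lam)) > 1e-9) {
      abort("all swarm trajectories must share an identical guide grid")
    }
    if (abs(tr$work[1]) > 1e-12) abort("work must start at 0")
  }
  structure(list(trajectories = trajectories, span = span,
                 stage = stage, lambda = lam),
            class = "stage_swarm")
}

swarm_work_matrix <- function(swarm) {
  vapply(swarm$trajectories, function(tr) tr$work,
         numeric(length(swarm$lambda)))
}

final_works <- function(swarm) {
  vapply(swarm$trajectories, function(tr) tr$work[length(tr$work)],
         numeric(1))
}

#' Select the trajectory closest to the Jarzynski average
#'
#' The stage's representative trajectory is the one whose final accumulated
#' work lies closest to the swarm's Jarzynski average; ties go to the lowest
#' index. Its end state seeds the next stage.
#'
#' @param swarm A [stage_swarm()].
#' @param temperature Kelvin.
#' @param kB Boltzmann constant (see [jarzynski_free_energy()]).
#' @return 1-based index of the selected trajectory.
#' @export
select_ja_trajectory <- function(swarm, temperature = 333,
                                 kB = 0.0019872041) {
  wf <- final_works(swarm)
  ja <- jarzynski_free_energy(wf, temperature, kB)
  which.min(abs(wf - ja))
}

#' Assemble a staged PMF profile by per-stage Jarzynski averaging
#'
#' Within each stage the PMF at guide position lambda is the stage's work
#' offset plus the Jarzynski average of the member trajectories' works
#' accumulated to lambda; the next stage's offset is the previous stage's
#' endpoint value, so the profile is continuous across boundaries and
#' anchored at zero at the first coordinate.
#'
#' @param stages List of [stage_swarm()]s, contiguous in the guide
#'   coordinate (each span starts where the previous ended).
#' @param temperature Kelvin.
#' @param kB Boltzmann constant.
#' @return A `pmf_profile` tibble (`rc` Angstrom, `pmf` kcal/mol) with the
#'   per-stage diagnostics attached as attribute `"diagnostics"`.
#' @export
assemble_pmf <- function(stages, temperature = 333, kB = 0.0019872041) {
  if (length(stages) == 0) abort("no stages supplied")
  for (i in seq_along(stages)[-1]) {
    gap <- stages[[i]]$span[1] - stages[[i - 1]]$span[2]
    if (abs(gap) > 1e-6) {
      abort(paste0("stages ", i - 1, " and ", i,
                   " are not contiguous: gap of ", signif(gap, 3),
                   " Angstrom"))
    }
  }
  offset <- 0
  rc <- numeric(0)
  pmf <- numeric(0)
  diags <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    sw <- stages[[i]]
    W <- swarm_work_matrix(sw)
    ja_curve <- apply(W, 1, jarzynski_free_energy, temperature = temperature,
                      kB = kB)
    vals <- offset + ja_curve
    keep <- if (i == 1) seq_along(sw$lambda) else seq_along(sw$lambda)[-1]
    rc <- c(rc, sw$lambda[keep])
    pmf <- c(pmf, vals[keep])
    wf <- final_works(sw)
    sel <- select_ja_trajectory(sw, temperature, kB)
    diags[[i]] <- tibble(stage = i, span_start = sw$span[1],
                         span_end = sw$span[2],
                         ja = ja_curve[length(ja_curve)],
                         mean_work = mean(wf),
                         sd_work = if (length(wf) > 1) sd(wf) else 0,
                         n_traj = length(wf), selected = sel)
    offset <- vals[length(vals)]
  }
  out <- tibble(rc = rc, pmf = pmf)
  class(out) <- unique(c("pmf_profile", class(out)))
  attr(out, "diagnostics") <- bind_rows(diags)
  attr(out, "temperature") <- temperature
  out
}

#' Staged adaptive steered dynamics on a toy potential
#'
#' The pulling coordinate `span` is divided into `n_stages` equal stages; in
#' each stage a swarm of `n_traj` steered overdamped-Langevin trajectories
#' ([steered_langevin()]) is launched from the previous stage's selected
#' end state (the trajectory whose final work is closest to the stage's
#' Jarzynski average), and the per-stage Jarzynski averages are concatenated
#' into a PMF profile. Per-trajectory sub-seeds are derived once from the
#' master seed in `params`, so a fixed master seed gives a bit-identical
#' result.
#'
#' @param potential A [toy_potential()].
#' @param n_stages Number of stages (default 14).
#' @param n_traj Trajectories per stage (default 24).
#' @param span Guide coordinate range, Angstrom (default `c(4, 30)`).
#' @param k_spring Guide stiffness, kcal/(mol A^2) (default 40).
#' @param v Pulling speed, Angstrom/ns (default 10).
#' @param params A [langevin_params()]; `params$seed` is the master seed.
#' @param store_every Work-grid stride in integrator steps (default: about
#'   150 stored points per stage).
#' @return An `asmd_result`: list with `profile` (a `pmf_profile` tibble),
#'   `stages` (list of [stage_swarm()]s), `diagnostics` (per-stage tibble)
#'   and `params`.
#' @export
run_asmd <- function(potential, n_stages = 14, n_traj = 24, span = c(4, 30),
                     k_spring = 40, v = 10, params, store_every = NULL) {
  if (n_stages < 1 || n_traj < 1) abort("n_stages and n_traj must be >= 1")
  bounds <- seq(span[1], span[2], length.out = n_stages + 1)
  sub_seeds <- with_seed(params$seed, {
    matrix(sample.int(.Machine$integer.max, n_stages * n_traj),
           n_stages, n_traj)
  })
  v_ps <- v / 1000
  if (is.null(store_every)) {
    steps_per_stage <- (bounds[2] - bounds[1]) / (v_ps * params$dt)
    store_every <- max(1L, floor(steps_per_stage / 150))
  }
  x0 <- span[1]
  stages <- vector("list", n_stages)
  for (s in seq_len(n_stages)) {
    res <- steer_swarm(potential, k_spring, v, c(bounds[s], bounds[s + 1]),
                       params$temperature, params$friction, params$dt,
                       seeds = sub_seeds[s, ], x0 = x0,
                       store_every = store_every)
    trajs <- lapply(seq_len(n_traj), function(j) {
      tr <- tibble(time = res$time, lambda = res$lambda,
                   position = res$position[, j], work = res$work[, j])
      class(tr) <- unique(c("work_trajectory", class(tr)))
      tr
    })
    stages[[s]] <- stage_swarm(trajs, span = c(bounds[s], bounds[s + 1]),
                               stage = s)
    sel <- select_ja_trajectory(stages[[s]], params$temperature)
    x0 <- res$x_final[sel]
  }
  profile <- assemble_pmf(stages, temperature = params$temperature)
  structure(list(profile = profile,
                 stages = stages,
                 diagnostics = attr(profile, "diagnostics"),
                 params = list(n_stages = n_stages, n_traj = n_traj,
                               span = span, k_spring = k_spring, v = v,
                               langevin = params)),
            class = "asmd_result")
}

#' @export
print.asmd_result <- function(x, ...) {
  cat("<asmd_result> ", x$params$n_stages, " stages x ", x$params$n_traj,
      " trajectories, span ", x$params$span[1], "-", x$params$span[2],
      " Angstrom\n  PMF endpoint: ",
      round(x$profile$pmf[nrow(x$profile)], 3), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Bootstrap standard error of the PMF endpoint
#'
#' Resamples trajectories with replacement within every stage and
#' recomputes the sum of per-stage Jarzynski averages.
#'
#' @param result An `asmd_result` (or list of [stage_swarm()]s).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param temperature Kelvin; defaults to the run's temperature.
#' @return Bootstrap SE of the endpoint PMF value, kcal/mol.
#' @export
pmf_endpoint_se <- function(result, n_boot = 200, seed = 1,
                            temperature = NULL) {
  stages <- if (inherits(result, "asmd_result")) result$stages else result
  if (is.null(temperature)) {
    temperature <- if (inherits(result, "asmd_result")) {
      result$params$langevin$temperature
    } else 333
  }
  wf <- lapply(stages, final_works)
  with_seed(seed, {
    boots <- vapply(seq_len(n_boot), function(b) {
      sum(vapply(wf, function(w) {
        jarzynski_free_energy(sample(w, length(w), replace = TRUE),
                              temperature)
      }, numeric(1)))
    }, numeric(1))
    sd(boots)
  })
}

#' Write / read a PMF profile as 2-column CSV
#'
#' @param profile A `pmf_profile` tibble.
#' @param path File path.
#' @return `path` (writer) or a `pmf_profile` tibble (reader).
#' @export
write_pmf <- function(profile, path) {
  readr::write_csv(as_tibble(profile)[, c("rc", "pmf")], path)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- unique(c("pmf_profile", class(out)))
  out
}
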