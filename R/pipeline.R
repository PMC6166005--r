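# FNV-1a 32-bit hash, implemented with 16-bit split multiplication so the
# arithmetic stays exact in doubles; used to fingerprint resolved configs.
fnv1a32 <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  prime <- 16777619
  two32 <- 2^32
  for (b in bytes) {
    h <- xor32(h, b)
    hi <- floor(h / 65536)
    lo <- h - hi * 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% two32
  }
  sprintf("%04x%04x", floor(h / 65536), h %% 65536)
}

xor32 <- function(a, b) {
  hi_a <- floor(a / 2^16); lo_a <- a - hi_a * 2^16
  hi_b <- floor(b / 2^16); lo_b <- b - hi_b * 2^16
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 2^16 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

#' Generate the full synthetic demo input set
#'
#' Writes everything [run_pipeline()] needs into `outdir`: two toy
#' structures (an "a" and a "b" variant built from different seeds), two
#' perturbed trajectories, two per-frame energy-component tables, and a
#' `config.yaml` wiring them together with a steered-dynamics block sized to
#' run the whole pipeline in a few minutes on one CPU. Fully deterministic
#' under `seed`.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Master integer seed.
#' @return The config file path, invisibly.
#' @export
make_demo_inputs <- function(outdir, seed = 42) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(paste0("cannot create directory: ", outdir))
  sa <- make_toy_protein(24, 4, seed = seed)
  sb <- make_toy_protein(24, 4, seed = seed + 1)
  write_pdb(sa, file.path(outdir, "structure_a.pdb"))
  write_pdb(sb, file.path(outdir, "structure_b.pdb"))
  ta <- perturb_trajectory(sa, n_frames = 40, noise_sd = 0.3,
                           seed = seed + 2)
  tb <- perturb_trajectory(sb, n_frames = 40, noise_sd = 0.3,
                           seed = seed + 3)
  write_trajectory(ta, file.path(outdir, "traj_a.pdb"))
  write_trajectory(tb, file.path(outdir, "traj_b.pdb"))
  # per-frame component samples around end-state means of the two variants
  mean_a <- energy_components(E_vdW = -16.67, E_ele = -59.39, G_GB = 57.42,
                              G_SA = -3.81)
  mean_b <- energy_components(E_vdW = -15.61, E_ele = -72.82, G_GB = 59.62,
                              G_SA = -3.88)
  write_energy_table(make_energy_table(mean_a, sd = 3, n_frames = 500,
                                       seed = seed + 4),
                     file.path(outdir, "energy_a.tsv"))
  write_energy_table(make_energy_table(mean_b, sd = 3, n_frames = 500,
                                       seed = seed + 5),
                     file.path(outdir, "energy_b.tsv"))
  config <- list(
    seed = seed,
    output_dir = file.path(outdir, "run"),
    structures = list(a = file.path(outdir, "structure_a.pdb"),
                      b = file.path(outdir, "structure_b.pdb")),
    trajectories = list(a = file.path(outdir, "traj_a.pdb"),
                        b = file.path(outdir, "traj_b.pdb")),
    energy_tables = list(a = file.path(outdir, "energy_a.tsv"),
                         b = file.path(outdir, "energy_b.tsv")),
    entropy = list(a = 19.95, b = 19.46),
    network = list(contact_cutoff = 4.5, hbond_d_cut = 3.5,
                   hbond_angle_cut = 120, k_values = c(3, 4, 5),
                   min_degree = 4, bin_width = 0.01),
    hbond_threshold = 5,
    asmd = list(potential = "harmonic", c = 0.2, x0 = 4,
                n_stages = 4, n_traj = 8, span = c(4, 12),
                k_spring = 40, v = 10, temperature = 333,
                friction = 1, dt = 0.01),
    stages = c("network", "energetics", "pmf", "traj"))
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  invisible(file.path(outdir, "config.yaml"))
}

resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) abort("config must set a seed")
  for (grp in c("structures", "trajectories", "energy_tables")) {
    for (p in unlist(config[[grp]])) {
      if (!file.exists(p)) {
        abort(paste0("config references missing file: ", p, " (", grp, ")"))
      }
    }
  }
  if (is.null(config$output_dir)) abort("config must set output_dir")
  config
}

config_potential <- function(a) {
  switch(a$potential %||% "harmonic",
         harmonic = toy_potential("harmonic", c = a$c %||% 0.2,
                                  x0 = a$x0 %||% a$span[[1]]),
         flat = toy_potential("flat"),
         double_well = toy_potential("double_well", h = a$h %||% 2,
                                     c = a$c %||% 0, w = a$w %||% 1),
         abort(paste0("unknown potential kind: ", a$potential)))
}

#' Run the end-to-end comparative pipeline
#'
#' Executes the requested stages on the two input systems and writes
#' per-stage artifacts plus a combined `report.json` under the configured
#' output directory (`networks/`, `energetics/`, `pmf/`, `traj/`). Stages
#' are independently skippable through the config's `stages` list. All
#' randomness is seeded from the config seed, and the report carries a
#' provenance block (config hash, seed, package version), so identical
#' config plus seed gives a byte-identical report. A stage failure aborts
#' with the stage name; artifacts already written are retained next to a
#' `FAILED` marker file.
#'
#' @param config Path to a YAML config (see [make_demo_inputs()] for the
#'   schema) or an equivalent named list.
#' @param quiet Suppress progress messages.
#' @return The report as a named list (also written as JSON), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- resolve_config(config)
  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[mutnet] ", ...)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  report <- list(provenance = list(
    config_hash = fnv1a32(as.character(cfg_json)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("mutnet"))))
  stages <- config$stages %||% c("network", "energetics", "pmf", "traj")
  run_stage <- function(name, fn) {
    if (!name %in% stages) return(NULL)
    say("stage '", name, "' ...")
    tryCatch(fn(), error = function(e) {
      writeLines(paste0("FAILED at stage ", name, ": ",
                        conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      abort(paste0("pipeline failed at stage '", name, "': ",
                   conditionMessage(e)))
    })
  }
  structs <- lapply(config$structures, read_pdb)

  report$network <- run_stage("network", function() {
    dir.create(file.path(outdir, "networks"), showWarnings = FALSE)
    np <- config$network %||% list()
    nets <- lapply(structs, function(s) {
      build_rin(s, contact_cutoff = np$contact_cutoff %||% 4.5,
                hbond_d_cut = np$hbond_d_cut %||% 3.5,
                hbond_angle_cut = np$hbond_angle_cut %||% 120)
    })
    for (nm in names(nets)) {
      write_rin(nets[[nm]], file.path(outdir, "networks",
                                      paste0("rin_", nm, ".tsv")))
    }
    diff <- compare_networks(nets$a, nets$b,
                             k_values = unlist(np$k_values %||% 3:5),
                             min_degree = np$min_degree %||% 4,
                             bin_width = np$bin_width %||% 0.01)
    write_diff_report(diff, file.path(outdir, "networks", "diff.json"))
    list(clique_totals = as.data.frame(diff$clique_totals),
         n_communities = as.data.frame(diff$communities),
         n_hubs = as.data.frame(count(diff$hubs, .data$network)),
         n_shared_nodes = nrow(diff$delta_betweenness))
  })

  report$energetics <- run_stage("energetics", function() {
    dir.create(file.path(outdir, "energetics"), showWarnings = FALSE)
    out <- lapply(names(config$energy_tables), function(nm) {
      tab <- read_energy_table(config$energy_tables[[nm]])
      agg <- aggregate_frames(tab)
      agg$minus_T_dS <- config$entropy[[nm]] %||% 0
      derived <- mmgbsa_combine(agg[c(ENERGY_TERMS)])
      jsonlite::write_json(
        list(full_precision = as.list(derived),
             rounded = as.list(format_energies(derived))),
        file.path(outdir, "energetics", paste0("derived_", nm, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      as.data.frame(format_energies(derived))
    })
    setNames(out, names(config$energy_tables))
  })

  report$pmf <- run_stage("pmf", function() {
    dir.create(file.path(outdir, "pmf"), showWarnings = FALSE)
    a <- config$asmd %||% list()
    pot <- config_potential(a)
    span <- unlist(a$span %||% c(4, 30))
    out <- list()
    for (nm in names(config$structures)) {
      lp <- langevin_params(temperature = a$temperature %||% 333,
                            friction = a$friction %||% 1,
                            dt = a$dt %||% 0.01,
                            seed = config$seed + match(nm, names(config$structures)))
      res <- run_asmd(pot, n_stages = a$n_stages %||% 14,
                      n_traj = a$n_traj %||% 24, span = span,
                      k_spring = a$k_spring %||% 40, v = a$v %||% 10,
                      params = lp)
      write_pmf(res$profile, file.path(outdir, "pmf",
                                       paste0("pmf_", nm, ".csv")))
      out[[nm]] <- list(endpoint = res$profile$pmf[nrow(res$profile)],
                        n_stages = res$params$n_stages,
                        n_traj = res$params$n_traj)
    }
    out
  })

  report$traj <- run_stage("traj", function() {
    dir.create(file.path(outdir, "traj"), showWarnings = FALSE)
    out <- list()
    for (nm in names(config$trajectories)) {
      tr <- read_trajectory(config$trajectories[[nm]], structs[[nm]])
      occ <- hbond_occupancy(tr, threshold = config$hbond_threshold %||% 5)
      readr::write_tsv(occ, file.path(outdir, "traj",
                                      paste0("occupancy_", nm, ".tsv")))
      out[[nm]] <- list(n_pairs = nrow(occ),
                        top_occupancy = if (nrow(occ)) occ$occupancy[1]
                        else NA)
    }
    out
  })

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("report written to ", file.path(outdir, "report.json"))
  invisible(report)
}
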