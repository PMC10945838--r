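# Langevin dynamics drivers.

run_engine <- function(state, template, ff, cfg, n_steps, snapshot_every,
                       seed, thermostat = TRUE, limit_disp = -1) {
  check_state_template(state, template)
  .cf_run(state$positions, state$velocities, state$box_length,
          template$n_beads, template$charges,
          ff$eps_H, ff$eps_E, ff$screening_length, ff$r_cut,
          ff$exclusion_depth,
          template$bond_r0, template$bond_k,
          template$angle_theta0, template$angle_k,
          cfg$timestep, cfg$langevin_damping, cfg$temperature,
          as.integer(n_steps), as.integer(snapshot_every),
          as.integer(seed), thermostat, limit_disp)
}

#' Advance the system by Langevin dynamics steps
#'
#' Inertial Langevin dynamics (BAOAB splitting of velocity Verlet with
#' friction and seeded Gaussian noise satisfying fluctuation-dissipation at
#' the configured temperature; bead mass 1, damping time
#' `cfg$langevin_damping`).  With `thermostat = FALSE` the friction and
#' noise are dropped and the integrator reduces to plain velocity Verlet
#' (NVE).
#'
#' @param state a [system_state()].
#' @param template a [molecule_template()].
#' @param ff a [force_field()].
#' @param cfg a [sim_config()]; supplies timestep, damping, temperature.
#' @param n_steps number of steps to take (default 1).
#' @param seed RNG seed for the noise stream (default `cfg$seed`).
#' @param thermostat logical; `FALSE` gives NVE velocity Verlet.
#' @return the advanced [system_state()].
#' @export
step_langevin <- function(state, template, ff, cfg, n_steps = 1L,
                          seed = cfg$seed, thermostat = TRUE) {
  out <- run_engine(state, template, ff, cfg, n_steps, snapshot_every = 0L,
                    seed = seed, thermostat = thermostat)
  system_state(out$final_positions, out$final_velocities, state$box_length,
               state$n_beads, time = state$time + n_steps * cfg$timestep)
}

#' Run a self-assembly simulation
#'
#' Initialises the system (unless `state` is supplied), integrates
#' `cfg$n_steps` steps of Langevin dynamics at constant N and V, and stores
#' snapshots every `cfg$snapshot_interval` steps.  Fully reproducible given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param template a [molecule_template()].
#' @param ff a [force_field()].
#' @param state optional starting [system_state()]; defaults to
#'   [init_system()].
#' @return object of class `"cg_trajectory"`: snapshot times (tau0), bead
#'   coordinate matrices, potential/kinetic energies at snapshots, the final
#'   state, and all parameters and the seed as metadata.
#' @export
#' @examples
#' tr <- run_simulation(sim_config(n_molecules = 4, box_length = 22,
#'                                 n_steps = 200, seed = 7),
#'                      molecule_template(), force_field())
#' tr
run_simulation <- function(cfg, template, ff, state = NULL) {
  if (is.null(state)) state <- init_system(cfg, template)
  out <- run_engine(state, template, ff, cfg, cfg$n_steps,
                    snapshot_every = cfg$snapshot_interval, seed = cfg$seed)
  final <- system_state(out$final_positions, out$final_velocities,
                        state$box_length, state$n_beads,
                        time = state$time + cfg$n_steps * cfg$timestep)
  structure(
    list(times = out$times, snapshots = out$snapshots,
         potential = out$potential, kinetic = out$kinetic,
         final_state = final,
         config = cfg, force_field = ff, template = template,
         box_length = state$box_length, n_beads = state$n_beads,
         n_molecules = state$n_molecules, seed = cfg$seed),
    class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("Coarse-grained trajectory: %d molecules x %d beads, %d snapshots\n",
              x$n_molecules, x$n_beads, length(x$times)))
  cat(sprintf("  t = %g .. %g tau0; eps_H = %g kT, eps_E = %g kT; seed %d\n",
              min(x$times), max(x$times), x$force_field$eps_H,
              x$force_field$eps_E, x$seed))
  invisible(x)
}

#' Snapshot of a trajectory as a system state
#'
#' @param traj a `cg_trajectory`.
#' @param i snapshot index (default: last).
#' @return a [system_state()] (velocities only available for the final
#'   snapshot).
#' @export
trajectory_state <- function(traj, i = length(traj$times)) {
  system_state(traj$snapshots[[i]], NULL, traj$box_length, traj$n_beads,
               time = traj$times[i])
}

#' Write a trajectory as XYZ-style text plus a JSON sidecar
#'
#' One record per bead and snapshot: molecule id, bead index, charge sign,
#' x, y, z.  Parameters and seed go to `<basename>.json`.
#'
#' @param traj a `cg_trajectory`.
#' @param dir output directory (created if needed).
#' @param basename file stem (default `"trajectory"`).
#' @return invisibly, the paths written.
#' @export
write_trajectory <- function(traj, dir, basename = "trajectory") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dat <- file.path(dir, paste0(basename, ".xyz.tsv"))
  meta <- file.path(dir, paste0(basename, ".json"))
  nb <- traj$n_beads
  tab <- do.call(rbind, lapply(seq_along(traj$times), function(i) {
    p <- traj$snapshots[[i]]
    data.frame(snapshot = i, time = traj$times[i],
               molecule = rep(seq_len(traj$n_molecules), each = nb),
               bead = rep(seq_len(nb), traj$n_molecules),
               charge = rep(traj$template$charges, traj$n_molecules),
               x = p[, 1], y = p[, 2], z = p[, 3])
  }))
  write.table(tab, dat, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_molecules = traj$n_molecules, n_beads = nb,
         box_length = traj$box_length, seed = traj$seed,
         times = traj$times,
         config = unclass(traj$config), force_field = unclass(traj$force_field),
         template = unclass(traj$template),
         potential = traj$potential, kinetic = traj$kinetic),
    meta, auto_unbox = TRUE, digits = NA)
  invisible(c(dat, meta))
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param dir directory containing the files.
#' @param basename file stem used when writing.
#' @return a `cg_trajectory` (without velocities).
#' @export
read_trajectory <- function(dir, basename = "trajectory") {
  tab <- read.table(file.path(dir, paste0(basename, ".xyz.tsv")),
                    header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(file.path(dir, paste0(basename, ".json")),
                              simplifyVector = TRUE)
  times <- meta$times
  snaps <- lapply(seq_along(times), function(i) {
    s <- tab[tab$snapshot == i, c("x", "y", "z")]
    unname(as.matrix(s))
  })
  tpl <- do.call(molecule_template, meta$template[
    c("n_beads", "bead_diameter", "bond_r0", "bond_k",
      "angle_theta0", "angle_k", "charges")])
  ff <- do.call(force_field, meta$force_field[
    c("eps_H", "eps_E", "screening_length", "r_cut", "exclusion_depth")])
  cfg <- do.call(sim_config, meta$config[
    c("n_molecules", "box_length", "timestep", "langevin_damping",
      "temperature", "n_steps", "seed", "snapshot_interval")])
  final <- system_state(snaps[[length(snaps)]], NULL, meta$box_length,
                        meta$n_beads, time = times[length(times)])
  structure(
    list(times = times, snapshots = snaps,
         potential = meta$potential, kinetic = meta$kinetic,
         final_state = final, config = cfg, force_field = ff, template = tpl,
         box_length = meta$box_length, n_beads = meta$n_beads,
         n_molecules = meta$n_molecules, seed = meta$seed),
    class = "cg_trajectory")
}
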