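#' Simulation configuration
#'
#' Parameters of one NVT Langevin run.  The reference system randomises
#' N = 2500 molecules in a cubic box of side L = 171 sigma, a number
#' concentration of `2500 / 171^3 = 0.0005` molecules per sigma^3; smaller,
#' denser systems are used for desk-scale work.  Integration uses a timestep
#' of 0.001 tau0 and a Langevin damping time of 1 tau0 by default.
#'
#' @param n_molecules number of molecules.
#' @param box_length cubic box side in sigma; must exceed the template
#'   length so a molecule fits without self-image contact.
#' @param timestep integration timestep in tau0.
#' @param langevin_damping thermostat damping time in tau0.
#' @param temperature temperature in kT.
#' @param n_steps number of integration steps.
#' @param seed integer RNG seed (controls initialisation and noise).
#' @param snapshot_interval steps between stored snapshots.
#' @return object of class `"sim_config"`; `$concentration` holds
#'   `n_molecules / box_length^3` in sigma^-3.
#' @export
#' @examples
#' cfg <- sim_config(n_molecules = 2500, box_length = 171, n_steps = 0)
#' signif(cfg$concentration, 1)  # 0.0005 sigma^-3
sim_config <- function(n_molecules = 2500L, box_length = 171,
                       timestep = 0.001, langevin_damping = 1,
                       temperature = 1, n_steps = 1000L, seed = 1L,
                       snapshot_interval = max(1L, n_steps %/% 50L)) {
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  if (box_length <= 0) stop("box_length must be positive")
  if (timestep <= 0) stop("timestep must be positive")
  if (langevin_damping <= 0) stop("langevin_damping must be positive")
  structure(
    list(n_molecules = n_molecules, box_length = box_length,
         timestep = timestep, langevin_damping = langevin_damping,
         temperature = temperature, n_steps = as.integer(n_steps),
         seed = as.integer(seed),
         snapshot_interval = as.integer(snapshot_interval),
         concentration = n_molecules / box_length^3),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (reduced units)\n")
  cat(sprintf("  N = %d molecules, L = %g sigma (c = %.3g sigma^-3)\n",
              x$n_molecules, x$box_length, x$concentration))
  cat(sprintf("  dt = %g tau0, damping = %g tau0, T = %g kT\n",
              x$timestep, x$langevin_damping, x$temperature))
  cat(sprintf("  steps = %d, snapshot every %d, seed = %d\n",
              x$n_steps, x$snapshot_interval, x$seed))
  invisible(x)
}

#' Read a simulation configuration from JSON
#'
#' The JSON document maps directly onto the fields of [sim_config()],
#' [force_field()] and [molecule_template()], grouped under keys
#' `"config"`, `"force_field"` and `"template"` (missing groups take the
#' defaults).
#'
#' @param path JSON file path.
#' @return list with elements `config`, `force_field`, `template`.
#' @export
read_sim_json <- function(path) {
  if (!is.character(path) || length(path) != 1 || !nzchar(path) ||
      !file.exists(path))
    stop("config file not found: '", path, "'")
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(sim_config, as.list(doc$config %||% list()))
  ff <- do.call(force_field, as.list(doc$force_field %||% list()))
  tpl <- do.call(molecule_template, as.list(doc$template %||% list()))
  list(config = cfg, force_field = ff, template = tpl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
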