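# System state container and initialisation.
#
# Positions and velocities are stored as (n_molecules * n_beads) x 3 matrices,
# beads of molecule m occupying rows ((m-1)*n_beads + 1) : (m*n_beads).
# Molecules are kept spatially whole; the molecule centroid is wrapped into
# the periodic box, and all pair interactions use minimum-image distances.

#' Construct a system state
#'
#' @param positions numeric matrix, `(n_molecules * n_beads) x 3`, in sigma.
#' @param velocities numeric matrix of the same shape, in sigma/tau0.
#' @param box_length cubic box side in sigma.
#' @param n_beads beads per molecule.
#' @param time simulation time in tau0.
#' @return object of class `"system_state"`.
#' @export
system_state <- function(positions, velocities, box_length, n_beads, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (nrow(positions) %% n_beads != 0)
    stop("row count is not a multiple of n_beads")
  if (missing(velocities) || is.null(velocities))
    velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  if (!identical(dim(velocities), dim(positions)))
    stop("velocities must match the shape of positions")
  structure(
    list(positions = positions, velocities = velocities,
         box_length = box_length, n_beads = as.integer(n_beads),
         n_molecules = nrow(positions) %/% as.integer(n_beads),
         time = time),
    class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("System state: %d molecules x %d beads, box %g sigma, t = %g tau0\n",
              x$n_molecules, x$n_beads, x$box_length, x$time))
  invisible(x)
}

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Initialise a system of randomly placed rods
#'
#' Places `n_molecules` straight rods with uniformly random centres and
#' orientations in the periodic cubic box, removes hard overlaps with a
#' bounded soft-core push-off relaxation (purely repulsive cores, capped
#' displacement steepest descent), and draws velocities from the
#' Maxwell-Boltzmann distribution at the configured temperature.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param template a [molecule_template()].
#' @param relax_iter iterations of the push-off relaxation.
#' @return a [system_state()].
#' @export
#' @examples
#' st <- init_system(sim_config(n_molecules = 5, box_length = 25, seed = 1),
#'                   molecule_template())
init_system <- function(cfg, template, relax_iter = 500L) {
  L <- cfg$box_length
  if (L <= template_length(template))
    stop("initialization error: box_length must exceed the template length (",
         round(template_length(template), 3), " sigma)")
  # overlapping beads in a rod: occupied volume is closer to a spherocylinder
  rod_vol <- pi / 4 * template$bead_diameter^2 * template_length(template)
  if (cfg$n_molecules * rod_vol > 0.45 * L^3)
    stop("initialization error: packing fraction infeasible")
  nb <- template$n_beads
  with_seed(cfg$seed, {
    centers <- matrix(runif(cfg$n_molecules * 3, 0, L), ncol = 3)
    # uniform random axes
    u <- matrix(rnorm(cfg$n_molecules * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    s <- (seq_len(nb) - (nb + 1) / 2) * template$bond_r0
    pos <- matrix(0, cfg$n_molecules * nb, 3)
    for (m in seq_len(cfg$n_molecules)) {
      rows <- (m - 1L) * nb + seq_len(nb)
      pos[rows, ] <- rep(centers[m, ], each = nb) + outer(s, u[m, ])
    }
    pos <- .cf_relax(pos, L, nb, template$charges,
                     2^(1 / 6), 5L, template$bond_r0, template$bond_k,
                     template$angle_theta0, template$angle_k,
                     as.integer(relax_iter), 0.05)
    # displacement-capped athermal warm-up with purely repulsive cores to
    # defuse any residual overlap the push-off left behind
    warm <- .cf_run(pos, matrix(0, nrow(pos), 3), L, nb, template$charges,
                    1, 0, 1, 2^(1 / 6), 5L,
                    template$bond_r0, template$bond_k,
                    template$angle_theta0, template$angle_k,
                    1e-3, 0.2, 0,
                    2000L, 0L, cfg$seed + 7L, TRUE, 0.02)
    # Maxwell-Boltzmann velocities at the configured temperature
    vel <- matrix(rnorm(length(pos), sd = sqrt(cfg$temperature)), ncol = 3)
    system_state(warm$final_positions, vel, L, nb, time = 0)
  })
}

#' Bonded energy of a state
#'
#' Sum of harmonic bond terms `k_bond (r - r0)^2` and harmonic angle terms
#' `k_angle (theta - theta0)^2` over all molecules.
#'
#' @param state a [system_state()].
#' @param template a [molecule_template()].
#' @return list with `total` and `per_molecule` energies in kT.
#' @export
bonded_energy <- function(state, template) {
  check_state_template(state, template)
  r <- .cf_energy_forces(state$positions, state$box_length, template$n_beads,
                         template$charges, 0, 0, 1, 2, 5L,
                         template$bond_r0, template$bond_k,
                         template$angle_theta0, template$angle_k)
  list(total = r$bonded, per_molecule = r$bonded_per_molecule)
}

#' Total potential energy and forces
#'
#' Bonded plus nonbonded energy of a state under minimum-image periodic
#' boundaries, with intra-molecular 1-2 through 1-5 pairs excluded from the
#' nonbonded terms, and the per-bead forces (negative energy gradient).
#'
#' @param state a [system_state()].
#' @param template a [molecule_template()].
#' @param ff a [force_field()].
#' @return list with `energy`, `nonbonded`, `bonded` (kT) and `forces`
#'   (`n x 3` matrix, kT/sigma).
#' @export
total_energy_forces <- function(state, template, ff) {
  check_state_template(state, template)
  r <- .cf_energy_forces(state$positions, state$box_length, template$n_beads,
                         template$charges, ff$eps_H, ff$eps_E,
                         ff$screening_length, ff$r_cut, ff$exclusion_depth,
                         template$bond_r0, template$bond_k,
                         template$angle_theta0, template$angle_k)
  r[c("energy", "nonbonded", "bonded", "forces")]
}

check_state_template <- function(state, template) {
  if (state$n_beads != template$n_beads)
    stop("shape error: state and template disagree on n_beads")
  if (nrow(state$positions) != state$n_molecules * template$n_beads)
    stop("shape error: positions inconsistent with template")
  invisible(TRUE)
}
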