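# Cluster decomposition and assembled-mass accounting.

#' Detect molecular clusters by bead contact
#'
#' Two molecules are connected iff any inter-molecular bead pair is closer
#' than `contact_cutoff` under minimum-image periodic boundaries; clusters
#' are the connected components of that contact graph.
#'
#' @param state a [system_state()].
#' @param contact_cutoff contact distance in sigma (default 1.5, between
#'   bead-surface contact at 1.12 and the interaction cutoff at 2).
#' @param min_fibril_size smallest cluster counted as a fibril (molecules).
#' @return object of class `"cluster_set"`: `assignment` (molecule ->
#'   cluster id), `sizes` (molecules per cluster), `shifts` (per-molecule
#'   periodic image shifts, in box lengths, making each cluster whole),
#'   plus the parameters.
#' @export
detect_clusters <- function(state, contact_cutoff = 1.5, min_fibril_size = 5L) {
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive")
  r <- .cf_clusters(state$positions, state$box_length, state$n_beads,
                    contact_cutoff)
  sizes <- tabulate(r$assignment)
  structure(
    list(assignment = r$assignment, sizes = sizes, shifts = r$shifts,
         n_molecules = state$n_molecules,
         contact_cutoff = contact_cutoff,
         min_fibril_size = as.integer(min_fibril_size)),
    class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d molecules in %d clusters (largest %d)\n",
              x$n_molecules, length(x$sizes), max(x$sizes)))
  cat(sprintf("  contact cutoff %g sigma, fibril threshold %d molecules\n",
              x$contact_cutoff, x$min_fibril_size))
  invisible(x)
}

#' Assembled-mass fraction
#'
#' Fraction of molecules belonging to clusters of at least
#' `min_fibril_size` molecules (the normalised fibril mass).
#'
#' @param clusters a `cluster_set` from [detect_clusters()].
#' @param min_fibril_size override of the threshold stored in `clusters`.
#' @return fraction in `[0, 1]`.
#' @export
assembled_mass_fraction <- function(clusters,
                                    min_fibril_size = clusters$min_fibril_size) {
  if (min_fibril_size < 2) stop("min_fibril_size must be >= 2")
  big <- which(clusters$sizes >= min_fibril_size)
  sum(clusters$sizes[big]) / clusters$n_molecules
}

#' Time at which a fraction series first reaches a target
#'
#' First crossing time of `target`, linearly interpolated between the
#' bracketing snapshots; `NA` ("not reached") if the series never attains
#' the target.  Used for t80, the time at which the assembled mass reaches
#' 80% of the total monomer mass.
#'
#' @param times snapshot times (strictly increasing).
#' @param phi assembled-mass fractions at those times.
#' @param target fraction in (0, 1); default 0.8.
#' @return crossing time, or `NA_real_` when never reached.
#' @export
#' @examples
#' time_to_fraction(0:10, (0:10) / 10, 0.8)  # 8
time_to_fraction <- function(times, phi, target = 0.8) {
  if (length(times) != length(phi)) stop("times and phi lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (target <= 0 || target >= 1) stop("target must be in (0, 1)")
  idx <- which(phi >= target)
  if (length(idx) == 0) return(NA_real_)
  i <- idx[1]
  if (i == 1L) return(times[1])
  t0 <- times[i - 1]; t1 <- times[i]
  p0 <- phi[i - 1]; p1 <- phi[i]
  t0 + (target - p0) / (p1 - p0) * (t1 - t0)
}

#' Assembled-mass fraction time series of a trajectory
#'
#' @param traj a `cg_trajectory`.
#' @param contact_cutoff,min_fibril_size see [detect_clusters()].
#' @return data frame with columns `time` and `phi`.
#' @export
assembly_curve <- function(traj, contact_cutoff = 1.5, min_fibril_size = 5L) {
  phi <- vapply(seq_along(traj$times), function(i) {
    cs <- detect_clusters(trajectory_state(traj, i), contact_cutoff,
                          min_fibril_size)
    assembled_mass_fraction(cs)
  }, numeric(1))
  data.frame(time = traj$times, phi = phi)
}
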