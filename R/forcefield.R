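#' Nonbonded force field of the coarse-grained model
#'
#' Two cut-and-shifted pair potentials act between beads: a generic
#' hydrophobic attraction modelled as a Lennard-Jones potential
#' `E_LJ = 4 eps_H ((sigma/r)^12 - (sigma/r)^6) + E_shift` for `r < r_cut`,
#' and a screened electrostatic (DLVO / Debye-Hueckel) potential
#' `E_DLVO = eps_E qi qj exp(-kappa r) / r + qi qj E_shift` for `r < r_cut`,
#' with `kappa = 1/screening_length`.  Both shift constants are derived from
#' `r_cut` at construction time so that each potential is exactly zero at and
#' beyond the cutoff.  Nonbonded interactions between beads of the same
#' molecule separated by 1-2 up to 1-5 bonds are excluded.
#'
#' @param eps_H hydrophobic (LJ) strength in kT.
#' @param eps_E electrostatic strength in kT.
#' @param screening_length Debye screening length in sigma (1 sigma = 1 nm,
#'   physiological conditions).
#' @param r_cut cutoff in sigma.
#' @param exclusion_depth bonded-neighbour span excluded from nonbonded
#'   terms; 5 means 1-2 through 1-5 pairs are excluded.
#' @return object of class `"force_field"` with the derived shift constants
#'   `lj_shift` and `dlvo_shift_unit` (per unit `qi*qj`).
#' @export
#' @examples
#' ff <- force_field(eps_H = 0.05, eps_E = 5)
#' lj_pair_energy(2, ff$eps_H, ff$r_cut)     # 0 at the cutoff
force_field <- function(eps_H = 0.05, eps_E = 5, screening_length = 1,
                        r_cut = 2, exclusion_depth = 5L) {
  if (r_cut <= 0) stop("r_cut must be positive")
  if (screening_length <= 0) stop("screening_length must be positive")
  structure(
    list(eps_H = eps_H, eps_E = eps_E, screening_length = screening_length,
         r_cut = r_cut, exclusion_depth = as.integer(exclusion_depth),
         lj_shift = -4 * eps_H * (r_cut^-12 - r_cut^-6),
         dlvo_shift_unit = -eps_E * exp(-r_cut / screening_length) / r_cut),
    class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat("Coarse-grained nonbonded force field (cut-and-shifted)\n")
  cat(sprintf("  eps_H = %g kT, eps_E = %g kT\n", x$eps_H, x$eps_E))
  cat(sprintf("  screening length = %g sigma, r_cut = %g sigma\n",
              x$screening_length, x$r_cut))
  cat(sprintf("  exclusions: 1-2 .. 1-%d within a molecule\n", x$exclusion_depth))
  invisible(x)
}

#' Cut-and-shifted Lennard-Jones pair energy
#'
#' `4 eps_H (r^-12 - r^-6) + E_shift` for `r < r_cut`, zero otherwise, with
#' the shift chosen so the potential is continuous (zero) at `r_cut`.
#' Vectorised over `r`.
#'
#' @param r pair distance(s) in sigma, > 0.
#' @param eps_H LJ strength in kT.
#' @param r_cut cutoff in sigma.
#' @return energy in kT.
#' @export
lj_pair_energy <- function(r, eps_H, r_cut = 2) {
  if (any(r <= 0)) stop("pair distance must be positive")
  shift <- -4 * eps_H * (r_cut^-12 - r_cut^-6)
  e <- 4 * eps_H * (r^-12 - r^-6) + shift
  e[r >= r_cut] <- 0
  e
}

#' Cut-and-shifted screened electrostatic (DLVO) pair energy
#'
#' `eps_E qi qj exp(-r/lambda) / r + qi qj E_shift` for `r < r_cut`, zero
#' otherwise; `lambda` is the Debye screening length.  Vectorised over `r`.
#'
#' @param r pair distance(s) in sigma, > 0.
#' @param qi,qj charge signs in `{-1, 0, 1}`.
#' @param eps_E electrostatic strength in kT.
#' @param screening_length Debye length in sigma.
#' @param r_cut cutoff in sigma.
#' @return energy in kT.
#' @export
dlvo_pair_energy <- function(r, qi, qj, eps_E, screening_length = 1, r_cut = 2) {
  if (any(r <= 0)) stop("pair distance must be positive")
  if (!all(c(qi, qj) %in% c(-1, 0, 1))) stop("charges must be -1, 0 or +1")
  qq <- qi * qj
  shift <- -eps_E * exp(-r_cut / screening_length) / r_cut
  e <- qq * (eps_E * exp(-r / screening_length) / r + shift)
  e[r >= r_cut] <- 0
  e
}
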