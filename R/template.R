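#' Default charge pattern of the collagen-mimetic rod
#'
#' Sign sequence (+1/0/-1) of the 36-bead rod.  The default places four
#' positive charges in the first third of the chain and four negative charges
#' in the last third, every third bead, mirroring the blocky
#' cationic/neutral/anionic charge motif of D-periodic collagen-mimetic
#' 36-mer peptides (arginines near the N terminus, glutamates near the C
#' terminus).  Any pattern of the right length may be supplied to
#' [molecule_template()] instead.
#'
#' @param n_beads number of beads (default 36).
#' @return integer vector of length `n_beads` with values in `{-1, 0, 1}`.
#' @export
#' @examples
#' table(default_charge_pattern())
default_charge_pattern <- function(n_beads = 36L) {
  q <- integer(n_beads)
  pos <- seq(2L, length.out = 4L, by = 3L)          # beads 2, 5, 8, 11
  neg <- seq(n_beads - 11L, length.out = 4L, by = 3L)  # beads 25, 28, 31, 34
  q[pos[pos <= n_beads]] <- 1L
  q[neg[neg >= 1L & neg <= n_beads]] <- -1L
  q
}

#' Collagen-mimetic molecule template
#'
#' Geometry and bonded parameters of the 36-bead elastic rod used by the
#' coarse-grained simulator: beads of diameter 1.12 sigma connected by
#' harmonic bonds `E = k_bond (r - r0)^2` with `r0 = 0.255` sigma and
#' straightened by harmonic angles `E = k_angle (theta - pi)^2`.  With the
#' defaults the end-to-end template length is
#' `(n_beads - 1) * r0 + bead_diameter = 10.045` sigma, i.e. a 10 nm rod.
#'
#' @param n_beads number of beads (>= 3).
#' @param bead_diameter bead diameter in sigma.
#' @param bond_r0 equilibrium bond length in sigma.
#' @param bond_k bond strength in kT/sigma^2.
#' @param angle_theta0 equilibrium angle in radians.
#' @param angle_k angular stiffness in kT.
#' @param charges per-bead charge signs in `{-1, 0, 1}`, length `n_beads`.
#' @return object of class `"molecule_template"`.
#' @export
#' @examples
#' tpl <- molecule_template()
#' template_length(tpl)  # ~10 sigma
molecule_template <- function(n_beads = 36L, bead_diameter = 1.12,
                              bond_r0 = 0.255, bond_k = 500,
                              angle_theta0 = pi, angle_k = 50,
                              charges = default_charge_pattern(n_beads)) {
  n_beads <- as.integer(n_beads)
  if (n_beads < 3L) stop("n_beads must be >= 3")
  if (bond_r0 <= 0) stop("bond_r0 must be positive")
  charges <- as.integer(charges)
  if (length(charges) != n_beads)
    stop("charges must have length n_beads (", n_beads, ")")
  if (!all(charges %in% c(-1L, 0L, 1L)))
    stop("charges must be -1, 0 or +1")
  structure(
    list(n_beads = n_beads, bead_diameter = bead_diameter,
         bond_r0 = bond_r0, bond_k = bond_k,
         angle_theta0 = angle_theta0, angle_k = angle_k,
         charges = charges),
    class = "molecule_template")
}

#' End-to-end template length
#'
#' `(n_beads - 1) * bond_r0 + bead_diameter`, in sigma.
#'
#' @param template a [molecule_template()].
#' @return length in sigma.
#' @export
template_length <- function(template) {
  (template$n_beads - 1) * template$bond_r0 + template$bead_diameter
}

#' @export
print.molecule_template <- function(x, ...) {
  cat("Coarse-grained rod template\n")
  cat(sprintf("  beads: %d (diameter %.3f sigma)\n", x$n_beads, x$bead_diameter))
  cat(sprintf("  bonds: r0 = %.3f sigma, k = %g kT/sigma^2\n", x$bond_r0, x$bond_k))
  cat(sprintf("  angles: theta0 = %.3f rad, k = %g kT\n", x$angle_theta0, x$angle_k))
  cat(sprintf("  end-to-end length: %.3f sigma\n", template_length(x)))
  cat(sprintf("  charges: %d+, %d-, %d neutral\n",
              sum(x$charges == 1), sum(x$charges == -1), sum(x$charges == 0)))
  invisible(x)
}
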