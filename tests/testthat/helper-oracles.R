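# Independent oracles used across the suite: plain double-loop energies with
# minimum-image distances, written without reference to the engine code.

# all-pairs nonbonded energy (LJ + screened electrostatics, cut and shifted)
brute_nonbonded <- function(state, template, ff) {
  P <- state$positions
  L <- state$box_length
  nb <- state$n_beads
  n <- nrow(P)
  q <- rep(template$charges, state$n_molecules)
  mol <- rep(seq_len(state$n_molecules), each = nb)
  bead <- rep(seq_len(nb), state$n_molecules)
  lj_shift <- -4 * ff$eps_H * (ff$r_cut^-12 - ff$r_cut^-6)
  dlvo_shift <- -ff$eps_E * exp(-ff$r_cut / ff$screening_length) / ff$r_cut
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (mol[i] == mol[j] && abs(bead[i] - bead[j]) <= ff$exclusion_depth - 1)
        next
      d <- P[i, ] - P[j, ]
      d <- d - L * round(d / L)
      r2 <- sum(d^2)
      if (r2 >= ff$r_cut^2) next
      r <- sqrt(r2)
      e <- e + 4 * ff$eps_H * (r^-12 - r^-6) + lj_shift
      qq <- q[i] * q[j]
      if (qq != 0)
        e <- e + ff$eps_E * qq * exp(-r / ff$screening_length) / r +
          qq * dlvo_shift
    }
  }
  e
}

# brute-force connected components of the molecular contact graph
brute_clusters <- function(state, cutoff) {
  n <- state$n_molecules
  nb <- state$n_beads
  L <- state$box_length
  parent <- seq_len(n)
  findp <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (mi in seq_len(n - 1)) {
    Pi <- state$positions[(mi - 1) * nb + seq_len(nb), , drop = FALSE]
    for (mj in (mi + 1):n) {
      Pj <- state$positions[(mj - 1) * nb + seq_len(nb), , drop = FALSE]
      touching <- FALSE
      for (a in seq_len(nb)) {
        d <- sweep(Pj, 2, Pi[a, ])
        d <- d - L * round(d / L)
        if (any(rowSums(d^2) < cutoff^2)) { touching <- TRUE; break }
      }
      if (touching) {
        ra <- findp(mi); rb <- findp(mj)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  vapply(seq_len(n), findp, integer(1))
}

# canonical form of a partition label vector (order-independent comparison)
canon_partition <- function(lab) as.integer(factor(lab, levels = unique(lab)))

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

# small random system used by several energy tests
random_system <- function(n_molecules, box_length, seed,
                          template = molecule_template()) {
  init_system(sim_config(n_molecules = n_molecules, box_length = box_length,
                         n_steps = 0L, seed = seed), template)
}
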