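# Fibril diameter estimation.

#' Diameter of one fibril
#'
#' The fibril axis is taken as the principal axis of the bead cloud (first
#' principal component through the centroid); the diameter is twice the
#' 95th-percentile radial bead-centre distance from that axis plus one bead
#' diameter.  A single straight molecule therefore measures exactly one
#' bead diameter.  The percentile (rather than the maximum) makes the
#' estimate robust to dangling molecules.
#'
#' @param coords `n x 3` matrix of bead coordinates of one cluster, already
#'   unwrapped (spatially whole).
#' @param bead_diameter bead diameter in sigma.
#' @param percentile radial percentile used (default 0.95).
#' @return diameter in sigma.
#' @export
#' @examples
#' rod <- cbind(seq(0, 10, by = 0.25), 0, 0)
#' fibril_diameter(rod)  # 1.12
fibril_diameter <- function(coords, bead_diameter = 1.12, percentile = 0.95) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("cluster must contain at least one bead")
  ctr <- colMeans(coords)
  xc <- sweep(coords, 2, ctr)
  if (nrow(coords) == 1) return(bead_diameter)
  ax <- svd(xc, nu = 0, nv = 1)$v[, 1]
  along <- drop(xc %*% ax)
  radial <- sqrt(pmax(rowSums(xc^2) - along^2, 0))
  2 * unname(quantile(radial, percentile, type = 7)) + bead_diameter
}

#' Fibril diameters in one snapshot
#'
#' @param state a [system_state()].
#' @param clusters optional precomputed [detect_clusters()] result.
#' @param contact_cutoff,min_fibril_size see [detect_clusters()].
#' @param bead_diameter bead diameter in sigma.
#' @return data frame with columns `cluster`, `n_molecules`, `diameter`.
#' @export
snapshot_diameters <- function(state, clusters = NULL, contact_cutoff = 1.5,
                               min_fibril_size = 5L, bead_diameter = 1.12) {
  if (is.null(clusters))
    clusters <- detect_clusters(state, contact_cutoff, min_fibril_size)
  ids <- which(clusters$sizes >= clusters$min_fibril_size)
  if (length(ids) == 0)
    return(data.frame(cluster = integer(), n_molecules = integer(),
                      diameter = numeric()))
  nb <- state$n_beads
  # unwrap: add the per-molecule periodic image shifts
  mol_shift <- clusters$shifts * state$box_length
  d <- vapply(ids, function(cid) {
    mols <- which(clusters$assignment == cid)
    rows <- as.vector(outer(seq_len(nb), (mols - 1L) * nb, `+`))
    coords <- state$positions[rows, , drop = FALSE] +
      mol_shift[rep(mols, each = nb), , drop = FALSE]
    fibril_diameter(coords, bead_diameter)
  }, numeric(1))
  data.frame(cluster = ids, n_molecules = clusters$sizes[ids], diameter = d)
}

#' Pooled fibril diameter distribution over a trajectory tail
#'
#' Per-fibril diameters are pooled over the equilibrated tail of the
#' trajectory (the final `tail_fraction` of snapshots); `D0` is the pooled
#' minimum and the normalised diameters are `D / D0 >= 1`.
#'
#' @param traj a `cg_trajectory`.
#' @param contact_cutoff,min_fibril_size see [detect_clusters()].
#' @param tail_fraction fraction of trailing snapshots analysed.
#' @param breaks histogram bin specification passed to [graphics::hist()].
#' @return object of class `"diameter_distribution"`: `diameters` (data
#'   frame with snapshot, cluster, D, D_norm), `D0`, and `histogram`
#'   (counts over `D/D0`); or an empty-result sentinel with `D0 = NA` when
#'   no fibrils are present.
#' @export
diameter_distribution <- function(traj, contact_cutoff = 1.5,
                                  min_fibril_size = 5L, tail_fraction = 0.2,
                                  breaks = "Sturges") {
  ns <- length(traj$times)
  first <- max(1L, ns - max(1L, ceiling(tail_fraction * ns)) + 1L)
  rows <- lapply(first:ns, function(i) {
    st <- trajectory_state(traj, i)
    d <- snapshot_diameters(st, contact_cutoff = contact_cutoff,
                            min_fibril_size = min_fibril_size,
                            bead_diameter = traj$template$bead_diameter)
    if (nrow(d)) cbind(snapshot = i, d) else NULL
  })
  all <- do.call(rbind, rows)
  if (is.null(all) || nrow(all) == 0) {
    return(structure(list(diameters = data.frame(), D0 = NA_real_,
                          histogram = NULL),
                     class = "diameter_distribution"))
  }
  D0 <- min(all$diameter)
  all$D_norm <- all$diameter / D0
  h <- graphics::hist(all$D_norm, breaks = breaks, plot = FALSE)
  structure(list(diameters = all, D0 = D0, histogram = h),
            class = "diameter_distribution")
}

#' @export
print.diameter_distribution <- function(x, ...) {
  if (is.na(x$D0)) {
    cat("Diameter distribution: no fibrils in the analysed snapshots\n")
  } else {
    cat(sprintf("Diameter distribution: %d fibril measurements, D0 = %.3f sigma\n",
                nrow(x$diameters), x$D0))
    q <- quantile(x$diameters$D_norm, c(0.25, 0.5, 0.75))
    cat(sprintf("  D/D0 quartiles: %.2f / %.2f / %.2f\n", q[1], q[2], q[3]))
  }
  invisible(x)
}
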