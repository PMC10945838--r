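# Seeded synthetic-data generators.  Every generator is deterministic under
# its seed and returns the ground-truth parameters alongside the data (and
# can write them to a JSON sidecar) so downstream stages can be validated by
# round-trip recovery.

write_sidecar <- function(truth, path) {
  if (!is.null(path))
    jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate a synthetic sigmoidal turbidity trace
#'
#' Logistic turbidity kinetics
#' `tau(t) = delta_tau / (1 + exp(-k (t - t_half)))` with i.i.d. Gaussian
#' noise (sd = `noise * delta_tau`), expressed as absorbance
#' `A313 = tau / ln(10) + baseline` so that [absorbance_to_turbidity()]
#' recovers the turbidity.
#'
#' @param delta_tau plateau turbidity amplitude.
#' @param k logistic rate in 1/s.
#' @param t_half midpoint time in s.
#' @param noise relative noise level (fraction of `delta_tau`).
#' @param sampling_dt sampling interval in s.
#' @param t_max trace duration in s (default `2 * t_half`).
#' @param baseline absorbance baseline added to the trace.
#' @param seed integer seed.
#' @param sidecar optional path for a JSON ground-truth sidecar.
#' @return data frame with columns `time`, `A313`; the ground truth
#'   (including the tangent-construction descriptors `t_lag`, `k_g`,
#'   `t_plateau`) is attached as attribute `"truth"`.
#' @export
gen_turbidity_trace <- function(delta_tau = 0.5, k = 0.02, t_half = 500,
                                noise = 0.05, sampling_dt = 5,
                                t_max = 2 * t_half, baseline = 0.05,
                                seed = 1L, sidecar = NULL) {
  if (k <= 0) stop("k must be positive")
  time <- seq(0, t_max, by = sampling_dt)
  if (t_half <= min(time) || t_half >= max(time))
    stop("generator error: transition outside the sampled window")
  tau <- logistic_curve(time, delta_tau, k, t_half)
  with_seed(seed, tau <- tau + rnorm(length(time), sd = noise * delta_tau))
  truth <- list(delta_tau = delta_tau, k = k, t_half = t_half,
                noise = noise, baseline = baseline, seed = seed,
                t_lag = t_half - 2 / k, t_plateau = t_half + 2 / k,
                k_g = k * delta_tau / 4)
  write_sidecar(truth, sidecar)
  structure(data.frame(time = time, A313 = tau / log(10) + baseline),
            truth = truth)
}

#' Generate a synthetic 2D-IR bleach with known pump-probe correlation
#'
#' Negative-going bivariate-Gaussian lobe centred at `center` on both axes
#' with per-axis standard deviation `sqrt(sigma_inhom^2 + sigma_hom^2)` and
#' pump-probe frequency correlation `rho`, plus i.i.d. Gaussian noise
#' (sd = `noise * amplitude`).  By construction [compute_cls()] applied to
#' the noiseless lobe returns `rho`.
#'
#' @param center band centre in cm^-1.
#' @param sigma_inhom inhomogeneous width in cm^-1.
#' @param sigma_hom homogeneous width in cm^-1.
#' @param rho pump-probe correlation in `[0, 1]`; default
#'   `sigma_inhom^2 / (sigma_inhom^2 + sigma_hom^2)`.
#' @param amplitude bleach depth (positive; the lobe is `-amplitude` deep).
#' @param nu_pump,nu_probe frequency grids; default `center +- 3` total
#'   widths at 1 cm^-1 spacing.
#' @param noise relative noise level.
#' @param seed integer seed.
#' @param sidecar optional JSON sidecar path.
#' @return list with `nu_pump`, `nu_probe`, `delta_A` and attribute
#'   `"truth"`.
#' @export
gen_2dir_bleach <- function(center = 1635, sigma_inhom = 8, sigma_hom = 4,
                            rho = sigma_inhom^2 / (sigma_inhom^2 + sigma_hom^2),
                            amplitude = 1,
                            nu_pump = NULL, nu_probe = NULL,
                            noise = 0, seed = 1L, sidecar = NULL) {
  s <- sqrt(sigma_inhom^2 + sigma_hom^2)
  if (s <= 0) stop("generator error: degenerate widths")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (is.null(nu_pump)) nu_pump <- seq(center - 3 * s, center + 3 * s, by = 1)
  if (is.null(nu_probe)) nu_probe <- seq(center - 3 * s, center + 3 * s, by = 1)
  zp <- (nu_pump - center) / s
  zr <- (nu_probe - center) / s
  om <- 1 - rho^2
  if (om < 1e-12) {
    # fully correlated limit: a ridge along the diagonal
    q <- outer(zp, zr, function(a, b) (a - b)^2) / 1e-6 +
      outer(zp^2, rep(1, length(zr)))
    dA <- -amplitude * exp(-0.5 * q)
  } else {
    q <- outer(zp^2, rep(1, length(zr))) -
      2 * rho * outer(zp, zr) +
      outer(rep(1, length(zp)), zr^2)
    dA <- -amplitude * exp(-0.5 * q / om)
  }
  if (noise > 0)
    with_seed(seed, dA <- dA + matrix(rnorm(length(dA), sd = noise * amplitude),
                                      nrow = nrow(dA)))
  truth <- list(center = center, sigma_inhom = sigma_inhom,
                sigma_hom = sigma_hom, rho = rho, amplitude = amplitude,
                noise = noise, seed = seed)
  write_sidecar(truth, sidecar)
  structure(list(nu_pump = nu_pump, nu_probe = nu_probe, delta_A = dA),
            truth = truth)
}

#' Generate a synthetic amide-I spectrum (Gaussian mixture)
#'
#' `y = b0 + b1 (x - mean(x)) + sum_i A_i exp(-(x - c_i)^2/(2 w_i^2))` plus
#' i.i.d. Gaussian noise (sd = `noise * max amplitude`).
#'
#' @param centers peak centres in cm^-1 (default 1635, 1660).
#' @param widths peak standard deviations in cm^-1.
#' @param areas peak areas (amplitude `A_i = area_i / (w_i sqrt(2 pi))`).
#' @param baseline `c(b0, b1)` linear baseline coefficients.
#' @param x wavenumber grid.
#' @param noise relative noise level.
#' @param seed integer seed.
#' @param sidecar optional JSON sidecar path.
#' @return data frame with columns `x`, `y` and attribute `"truth"`.
#' @export
gen_amide_spectrum <- function(centers = c(1635, 1660), widths = c(10, 8),
                               areas = c(1, 1), baseline = c(0.02, 0),
                               x = seq(1580, 1720, by = 0.5),
                               noise = 0.01, seed = 1L, sidecar = NULL) {
  if (any(centers < 1600) || any(centers > 1700))
    stop("component centres must lie within 1600-1700 cm^-1")
  if (length(widths) != length(centers) || length(areas) != length(centers))
    stop("centers, widths, areas must have equal length")
  if (any(widths <= 0) || any(areas < 0)) stop("invalid widths or areas")
  amps <- areas / (widths * sqrt(2 * pi))
  y <- baseline[1] + baseline[2] * (x - mean(x))
  for (i in seq_along(centers))
    y <- y + amps[i] * exp(-(x - centers[i])^2 / (2 * widths[i]^2))
  if (noise > 0)
    with_seed(seed, y <- y + rnorm(length(x), sd = noise * max(amps)))
  truth <- list(centers = centers, widths = widths, areas = areas,
                baseline = baseline, noise = noise, seed = seed,
                area_ratio_low_high = if (length(areas) >= 2)
                  areas[which.min(abs(centers - 1635))] /
                  areas[which.min(abs(centers - 1660))] else NA)
  write_sidecar(truth, sidecar)
  structure(data.frame(x = x, y = y), truth = truth)
}

#' Generate a synthetic two-state CD melting curve
#'
#' `y(T) = (bf + mf T) f + (bu + mu T)(1 - f)` with folded fraction
#' `f = 1 / (1 + exp((T - t_m) / width))`, plus i.i.d. Gaussian noise
#' (sd = `noise * |amplitude|`).
#'
#' @param t_m melting temperature in C.
#' @param width transition width in C (width -> 0 gives a step).
#' @param folded_baseline,unfolded_baseline `c(intercept, slope)` pairs.
#' @param temperature scanned temperatures in C (must bracket `t_m`).
#' @param noise relative noise level.
#' @param seed integer seed.
#' @param sidecar optional JSON sidecar path.
#' @return data frame with columns `temperature`, `signal` and attribute
#'   `"truth"`.
#' @export
gen_cd_melt <- function(t_m = 43, width = 1.5,
                        folded_baseline = c(1, 0),
                        unfolded_baseline = c(0, 0),
                        temperature = seq(25, 60, by = 1),
                        noise = 0.02, seed = 1L, sidecar = NULL) {
  if (t_m <= min(temperature) || t_m >= max(temperature))
    stop("generator error: t_m outside the scanned range")
  f <- if (width <= 0) as.numeric(temperature < t_m)
       else 1 / (1 + exp((temperature - t_m) / width))
  y <- (folded_baseline[1] + folded_baseline[2] * temperature) * f +
    (unfolded_baseline[1] + unfolded_baseline[2] * temperature) * (1 - f)
  amp <- abs(folded_baseline[1] + folded_baseline[2] * t_m -
             unfolded_baseline[1] - unfolded_baseline[2] * t_m)
  if (noise > 0)
    with_seed(seed, y <- y + rnorm(length(y), sd = noise * amp))
  truth <- list(t_m = t_m, width = width,
                folded_baseline = folded_baseline,
                unfolded_baseline = unfolded_baseline,
                noise = noise, seed = seed)
  write_sidecar(truth, sidecar)
  structure(data.frame(temperature = temperature, signal = y), truth = truth)
}

#' Generate an idealised fibril bundle of parallel rods
#'
#' Straight rods on a hexagonal lattice (filled shell by shell around a
#' central rod), all parallel to a common axis, as a fixture of known
#' diameter for the fibril-diameter estimator.  The ground-truth diameter
#' is `2 * r_outer + bead_diameter` where `r_outer` is the outermost
#' occupied lattice radius.
#'
#' @param n_rods number of rods (1, or up to a filled shell count 7, 19, ...).
#' @param spacing centre-to-centre lattice spacing in sigma (>=
#'   `bead_diameter`).
#' @param template a [molecule_template()] providing bead geometry.
#' @param axis unit 3-vector for the bundle axis (default z).
#' @param origin 3-vector offset.
#' @return a [system_state()] in a large box, with attribute `"truth"`
#'   holding the lattice diameter.
#' @export
#' @examples
#' b <- gen_fibril_bundle(7, spacing = 1.5)
#' attr(b, "truth")$diameter  # 2 * 1.5 + 1.12
gen_fibril_bundle <- function(n_rods = 7L, spacing = 1.5,
                              template = molecule_template(),
                              axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  if (spacing < template$bead_diameter)
    stop("generator error: spacing smaller than the bead diameter")
  axis <- axis / sqrt(sum(axis^2))
  # hexagonal lattice sites sorted by radius
  k <- 6L
  pts <- expand.grid(i = -k:k, j = -k:k)
  xy <- cbind(pts$i + pts$j / 2, pts$j * sqrt(3) / 2) * spacing
  r <- sqrt(rowSums(xy^2))
  ord <- order(r, atan2(xy[, 2], xy[, 1]))
  if (n_rods > nrow(xy)) stop("n_rods too large")
  sites <- xy[ord[seq_len(n_rods)], , drop = FALSE]
  r_outer <- max(sqrt(rowSums(sites^2)))
  # orthonormal frame around the axis
  tmp <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- tmp - sum(tmp * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  nb <- template$n_beads
  s <- (seq_len(nb) - (nb + 1) / 2) * template$bond_r0
  pos <- do.call(rbind, lapply(seq_len(n_rods), function(m) {
    ctr <- origin + sites[m, 1] * e1 + sites[m, 2] * e2
    t(vapply(s, function(z) ctr + z * axis, numeric(3)))
  }))
  box <- 4 * (template_length(template) + r_outer + spacing) + 10
  st <- system_state(pos + box / 2, NULL, box, nb)
  attr(st, "truth") <- list(n_rods = n_rods, spacing = spacing,
                            r_outer = r_outer,
                            diameter = 2 * r_outer + template$bead_diameter)
  st
}
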