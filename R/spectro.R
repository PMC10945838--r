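# Spectroscopy analyses: amide-I band decomposition, 2D-IR central line
# slope, CD helicity ratio and thermal melting.

#' Fit Gaussian amide-I bands to a 1D IR spectrum
#'
#' Least-squares decomposition of the amide-I region into `n_components`
#' Gaussian peaks on a linear baseline,
#' `y = b0 + b1 x + sum_i A_i exp(-(x - c_i)^2 / (2 w_i^2))`.
#' Triple-helical collagen shows two main bands near 1635 cm^-1
#' (solvent-exposed carbonyls) and 1660 cm^-1 (buried carbonyls); the ratio
#' of their areas tracks the solvation state.
#'
#' @param x wavenumber in cm^-1 (strictly monotone).
#' @param y absorbance.
#' @param n_components number of Gaussian components (default 2).
#' @param init_centers initial peak centres in cm^-1 (default 1635, 1660).
#' @param window fit window in cm^-1 (default `c(1600, 1700)`).
#' @return object of class `"amide_fit"`: `components` data frame (center,
#'   width, amplitude, area), `area_ratio_low_high` (area of the component
#'   nearest 1635 over the one nearest 1660), `baseline` coefficients,
#'   `residual_rms`, `converged`.
#' @export
fit_amide_bands <- function(x, y, n_components = 2L,
                            init_centers = c(1635, 1660),
                            window = c(1600, 1700)) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(diff(x) == 0) || (any(diff(x) > 0) && any(diff(x) < 0)))
    stop("x must be strictly monotone")
  keep <- x >= window[1] & x <= window[2]
  if (sum(keep) < 3 * n_components + 2)
    stop("spectrum must cover the amide-I window ", window[1], "-", window[2])
  xs <- x[keep]; ys <- y[keep]
  n_components <- as.integer(n_components)
  if (length(init_centers) != n_components)
    init_centers <- seq(window[1] + 10, window[2] - 10,
                        length.out = n_components)

  base0 <- min(ys)
  amp0 <- vapply(init_centers, function(cc)
    max(ys[which.min(abs(xs - cc))] - base0, 1e-4 * (max(ys) - base0 + 1e-12)),
    numeric(1))
  start <- c(as.list(setNames(init_centers, paste0("c", seq_len(n_components)))),
             as.list(setNames(rep(8, n_components), paste0("w", seq_len(n_components)))),
             as.list(setNames(amp0, paste0("A", seq_len(n_components)))),
             list(b0 = base0, b1 = 0))
  gmix <- function(p) {
    yy <- p[["b0"]] + p[["b1"]] * (xs - mean(xs))
    for (i in seq_len(n_components))
      yy <- yy + p[[paste0("A", i)]] *
        exp(-(xs - p[[paste0("c", i)]])^2 / (2 * p[[paste0("w", i)]]^2))
    yy
  }
  resid_fun <- function(par) ys - gmix(as.list(par))
  lower <- c(rep(window[1], n_components), rep(1, n_components),
             rep(0, n_components), -Inf, -Inf)
  upper <- c(rep(window[2], n_components), rep(60, n_components),
             rep(Inf, n_components), Inf, Inf)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = unlist(start), fn = resid_fun,
                       lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4
  p <- if (is.null(fit)) unlist(start) else fit$par
  pl <- as.list(p)
  comp <- data.frame(
    center = unlist(pl[paste0("c", seq_len(n_components))]),
    width = abs(unlist(pl[paste0("w", seq_len(n_components))])),
    amplitude = unlist(pl[paste0("A", seq_len(n_components))]))
  comp$area <- comp$amplitude * comp$width * sqrt(2 * pi)
  rownames(comp) <- NULL
  ratio <- NA_real_
  if (n_components >= 2) {
    lo <- which.min(abs(comp$center - 1635))
    hi <- which.min(abs(comp$center - 1660))
    if (lo != hi && comp$area[hi] > 0) ratio <- comp$area[lo] / comp$area[hi]
  }
  structure(
    list(components = comp, area_ratio_low_high = ratio,
         baseline = c(b0 = pl$b0, b1 = pl$b1),
         residual_rms = sqrt(mean((ys - gmix(pl))^2)),
         converged = converged, x = xs, y = ys,
         fitted = gmix(pl)),
    class = "amide_fit")
}

#' @export
print.amide_fit <- function(x, ...) {
  cat("Amide-I Gaussian band fit",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(transform(x$components,
                  center = round(center, 1), width = round(width, 2),
                  amplitude = signif(amplitude, 4), area = signif(area, 4)))
  cat(sprintf("  low/high area ratio = %.4g, residual RMS = %.3g\n",
              x$area_ratio_low_high, x$residual_rms))
  invisible(x)
}

#' @export
plot.amide_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, cex = 0.4,
                 xlab = "wavenumber (cm^-1)", ylab = "absorbance", ...)
  graphics::lines(x$x, x$fitted, col = 2, lwd = 2)
  invisible(x)
}

#' Central line slope (CLS) of a 2D-IR bleach
#'
#' Quantifies the inhomogeneous broadening of a vibrational band from a
#' 2D-IR spectrum.  Within the band window, each probe-frequency slice is
#' scanned for the pump frequency with the most negative delta-A (the
#' bleach), refined by parabolic sub-grid interpolation; a line is fitted
#' through the (probe, pump-minimum) locus.  The central line drawn in the
#' conventional pump-on-x orientation has slope `d(probe)/d(pump) >= 1` for
#' a correlated band, and the CLS is its inverse,
#' `d(pump)/d(probe)` of the fitted locus, clipped to `[0, 1]`.  CLS -> 0
#' for a homogeneous (untilted) band and -> 1 for fully inhomogeneous
#' (diagonally elongated) lineshapes; for a bivariate-Gaussian bleach the
#' CLS equals the pump-probe frequency correlation.
#'
#' @param nu_pump pump-frequency grid (rows of `delta_A`), cm^-1.
#' @param nu_probe probe-frequency grid (columns of `delta_A`), cm^-1.
#' @param delta_A matrix of absorption changes, `length(nu_pump) x
#'   length(nu_probe)`; bleaches are negative.
#' @param band_window `c(lo, hi)` in cm^-1 defining the band on both axes.
#' @param min_slices minimum number of usable probe slices (default 5).
#' @return object of class `"cls_fit"`: `cls`, `center_line` (data frame
#'   probe, pump), `slope` (raw d pump / d probe), `band_window`.
#' @export
compute_cls <- function(nu_pump, nu_probe, delta_A, band_window,
                        min_slices = 5L) {
  if (!is.matrix(delta_A) || nrow(delta_A) != length(nu_pump) ||
      ncol(delta_A) != length(nu_probe))
    stop("delta_A must be a length(nu_pump) x length(nu_probe) matrix")
  if (any(diff(nu_pump) <= 0) || any(diff(nu_probe) <= 0))
    stop("frequency grids must be strictly increasing")
  pr <- which(nu_probe >= band_window[1] & nu_probe <= band_window[2])
  pu <- which(nu_pump >= band_window[1] & nu_pump <= band_window[2])
  if (length(pr) < min_slices || length(pu) < 3)
    stop("band window too narrow: fewer than ", min_slices, " usable slices")
  sub <- delta_A[pu, pr, drop = FALSE]
  if (min(sub) >= 0) stop("no bleach (delta_A < 0) in the band window")
  depth <- -apply(sub, 2, min)
  # only slices with an appreciable bleach contribute
  usable <- which(depth >= 0.1 * max(depth))
  if (length(usable) < min_slices)
    stop("fewer than ", min_slices, " usable slices in the band window")
  pump_min <- vapply(usable, function(jc) {
    col <- sub[, jc]
    j <- which.min(col)
    if (j == 1L || j == length(col)) return(nu_pump[pu][j])
    # parabolic refinement through the three points around the minimum
    y1 <- col[j - 1]; y2 <- col[j]; y3 <- col[j + 1]
    denom <- (y1 - 2 * y2 + y3)
    off <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y1 - y3) / denom
    x0 <- nu_pump[pu][j]
    h <- (nu_pump[pu][j + 1] - nu_pump[pu][j - 1]) / 2
    x0 + off * h
  }, numeric(1))
  probe_at <- nu_probe[pr][usable]
  line <- lm(pump_min ~ probe_at)
  slope <- unname(coef(line)[2])
  structure(
    list(cls = min(max(slope, 0), 1),
         slope = slope,
         center_line = data.frame(probe = probe_at, pump = pump_min),
         band_window = band_window),
    class = "cls_fit")
}

#' @export
print.cls_fit <- function(x, ...) {
  cat(sprintf("2D-IR central line slope: CLS = %.3f (raw slope %.3f)\n",
              x$cls, x$slope))
  cat(sprintf("  band window %g-%g cm^-1, %d slices\n",
              x$band_window[1], x$band_window[2], nrow(x$center_line)))
  invisible(x)
}

#' CD helicity ratio Rpn
#'
#' Ratio of the positive CD maximum (near 220 nm) to the absolute value of
#' the negative minimum (near 198 nm), an empirical criterion for collagen
#' triple-helicity.  `Rpn = max(y in positive window) / |min(y in negative
#' window)|`; scale-invariant.
#'
#' @param wavelength wavelength in nm.
#' @param ellipticity CD signal (instrument units).
#' @param negative_window search window for the minimum (default 190-205 nm).
#' @param positive_window search window for the maximum (default 210-230 nm).
#' @return the ratio Rpn.
#' @export
cd_rpn <- function(wavelength, ellipticity,
                   negative_window = c(190, 205),
                   positive_window = c(210, 230)) {
  if (length(wavelength) != length(ellipticity))
    stop("wavelength and ellipticity lengths differ")
  inn <- wavelength >= negative_window[1] & wavelength <= negative_window[2]
  inp <- wavelength >= positive_window[1] & wavelength <= positive_window[2]
  if (!any(inn) || !any(inp))
    stop("spectrum must span both extremum search windows")
  mn <- min(ellipticity[inn])
  mx <- max(ellipticity[inp])
  if (mn >= 0 || mx <= 0)
    stop("not a triple-helical signature: need a negative minimum near 198 nm and a positive maximum near 220 nm")
  mx / abs(mn)
}

#' Fit a two-state thermal melting curve
#'
#' Fits the temperature dependence of a CD signal with a two-state model
#' with linear folded and unfolded baselines:
#' `y(T) = (bf + mf T) f(T) + (bu + mu T) (1 - f(T))` with the folded
#' fraction `f(T) = 1 / (1 + exp((T - Tm) / width))`.  `Tm` is the midpoint
#' temperature at which half the molecules are unfolded.
#'
#' @param temperature temperatures in degrees C (>= 6 points).
#' @param signal ellipticity at a fixed wavelength.
#' @return object of class `"cd_melt"`: `t_m`, `width`, baselines,
#'   `converged`, `fibrillation`-style flag `transition` and diagnostics.
#' @export
#' @examples
#' T <- seq(25, 60, by = 2)
#' y <- 1 / (1 + exp((T - 43) / 1.5))
#' fit_melting_curve(T, y)$t_m  # 43
fit_melting_curve <- function(temperature, signal) {
  if (length(temperature) != length(signal))
    stop("temperature and signal lengths differ")
  if (length(temperature) < 6)
    stop("need at least 6 temperature points spanning the transition")
  o <- order(temperature)
  T <- temperature[o]; y <- signal[o]
  n <- length(T)
  nb <- max(2L, n %/% 5L)
  # baseline guesses from the end segments
  yf <- mean(y[seq_len(nb)]); yu <- mean(y[(n - nb + 1):n])
  empty <- function() structure(
    list(t_m = NA_real_, width = NA_real_,
         baselines = c(bf = yf, mf = 0, bu = yu, mu = 0),
         converged = FALSE, transition = FALSE,
         residual_rms = sd(y), temperature = T, signal = y),
    class = "cd_melt")
  if (abs(yf - yu) < 5 * sd(c(y[seq_len(nb)] - yf, y[(n - nb + 1):n] - yu)) ||
      abs(yf - yu) < 1e-12) {
    # amplitude indistinguishable from baseline scatter
    return(empty())
  }
  tm0 <- T[which.min(abs(y - (yf + yu) / 2))]
  w0 <- max(diff(range(T)) / 20, 1e-3)
  dat <- data.frame(T = T, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (bf + mf * T) / (1 + exp((T - tm) / w)) +
        (bu + mu * T) * (1 - 1 / (1 + exp((T - tm) / w))),
      data = dat,
      start = list(bf = yf, mf = 0, bu = yu, mu = 0, tm = tm0, w = w0),
      lower = c(-Inf, -Inf, -Inf, -Inf, min(T), 1e-4),
      upper = c(Inf, Inf, Inf, Inf, max(T), diff(range(T))),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(empty())
  p <- coef(fit)
  structure(
    list(t_m = unname(p["tm"]), width = unname(p["w"]),
         baselines = p[c("bf", "mf", "bu", "mu")],
         converged = TRUE, transition = TRUE,
         residual_rms = sqrt(mean(residuals(fit)^2)),
         temperature = T, signal = y, fitted = predict(fit)),
    class = "cd_melt")
}

#' @export
print.cd_melt <- function(x, ...) {
  if (!x$transition) {
    cat("CD melting fit: no sigmoidal transition detected\n")
  } else {
    cat(sprintf("CD melting fit: Tm = %.2f C (width %.2f C), residual RMS %.3g\n",
                x$t_m, x$width, x$residual_rms))
  }
  invisible(x)
}

#' Read a two-column spectrum (x, y) with a header
#'
#' @param path delimited text file.
#' @param sep field separator.
#' @return data frame with columns `x` and `y`.
#' @export
read_spectrum <- function(path, sep = "") {
  d <- read.table(path, header = TRUE, sep = sep)
  names(d)[1:2] <- c("x", "y")
  d[, 1:2]
}

#' Read a 2D-IR matrix: pump grid as first column, probe grid as first row
#'
#' @param path delimited text file (no header line; cell (1,1) ignored).
#' @param sep field separator.
#' @return list with `nu_pump`, `nu_probe`, `delta_A`.
#' @export
read_spectrum2d <- function(path, sep = "") {
  m <- as.matrix(read.table(path, header = FALSE, sep = sep))
  list(nu_pump = unname(m[-1, 1]), nu_probe = unname(m[1, -1]),
       delta_A = unname(m[-1, -1, drop = FALSE]))
}

#' Write a 2D-IR matrix in the layout read by [read_spectrum2d()]
#'
#' @param nu_pump,nu_probe,delta_A grids and matrix.
#' @param path output file.
#' @export
write_spectrum2d <- function(nu_pump, nu_probe, delta_A, path) {
  m <- rbind(c(NA, nu_probe), cbind(nu_pump, delta_A))
  write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              na = "0")
}
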