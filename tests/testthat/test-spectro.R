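test_that("two-Gaussian amide-I spectra are recovered within tight tolerances", {
  sp <- gen_amide_spectrum(centers = c(1635, 1660), widths = c(10, 8),
                           areas = c(1.2, 0.9), noise = 0.01, seed = 4)
  f <- fit_amide_bands(sp$x, sp$y)
  expect_true(f$converged)
  cen <- sort(f$components$center)
  expect_lt(abs(cen[1] - 1635), 1)
  expect_lt(abs(cen[2] - 1660), 1)
  lo <- which.min(abs(f$components$center - 1635))
  hi <- which.min(abs(f$components$center - 1660))
  expect_lt(rel_err(f$components$area[lo], 1.2), 0.05)
  expect_lt(rel_err(f$components$area[hi], 0.9), 0.05)
  expect_lt(rel_err(f$area_ratio_low_high, 1.2 / 0.9), 0.05)
})

test_that("a single-band spectrum fitted with two components leaves one empty", {
  sp <- gen_amide_spectrum(centers = 1640, widths = 9, areas = 1,
                           noise = 0, seed = 1)
  f <- fit_amide_bands(sp$x, sp$y, n_components = 2,
                       init_centers = c(1635, 1660))
  minor <- min(f$components$area)
  expect_lt(minor / sum(f$components$area), 0.02)
  expect_lt(f$residual_rms, 1e-4)
})

test_that("a 30% reduction of the low band reduces the fitted area ratio by 30%", {
  full <- gen_amide_spectrum(areas = c(1, 1), noise = 0.005, seed = 6)
  less <- gen_amide_spectrum(areas = c(0.7, 1), noise = 0.005, seed = 7)
  r_full <- fit_amide_bands(full$x, full$y)$area_ratio_low_high
  r_less <- fit_amide_bands(less$x, less$y)$area_ratio_low_high
  expect_lt(abs(r_less / r_full - 0.7), 0.05)
})

test_that("band areas scale with the spectrum and the area ratio is scale-invariant", {
  sp <- gen_amide_spectrum(areas = c(1, 0.8), noise = 0.002, seed = 9)
  f1 <- fit_amide_bands(sp$x, sp$y)
  f3 <- fit_amide_bands(sp$x, 3 * sp$y)
  expect_lt(rel_err(sum(f3$components$area), 3 * sum(f1$components$area)), 0.01)
  expect_lt(rel_err(f3$area_ratio_low_high, f1$area_ratio_low_high), 0.01)
})

test_that("amide fit rejects spectra that do not cover the band window", {
  expect_error(fit_amide_bands(seq(1700, 1750, 2), rnorm(26)), "window")
})

test_that("CLS recovers the constructed pump-probe correlation", {
  for (rho in c(0, 0.3, 0.5, 0.7, 0.9)) {
    sp <- gen_2dir_bleach(rho = rho, noise = 0.005, seed = 31)
    cls <- compute_cls(sp$nu_pump, sp$nu_probe, sp$delta_A,
                       band_window = c(1615, 1655))
    expect_lt(abs(cls$cls - rho), 0.05)
  }
})

test_that("CLS limits: homogeneous band ~ 0, diagonal ridge ~ 1", {
  hom <- gen_2dir_bleach(rho = 0, noise = 0, seed = 1)
  expect_lte(compute_cls(hom$nu_pump, hom$nu_probe, hom$delta_A,
                         c(1615, 1655))$cls, 0.05)
  ridge <- gen_2dir_bleach(rho = 1, sigma_hom = 0.01, noise = 0, seed = 1)
  expect_gte(compute_cls(ridge$nu_pump, ridge$nu_probe, ridge$delta_A,
                         c(1615, 1655))$cls, 0.95)
})

test_that("CLS input validation: bleach and slice count", {
  sp <- gen_2dir_bleach(rho = 0.5, noise = 0, seed = 2)
  expect_error(compute_cls(sp$nu_pump, sp$nu_probe, -sp$delta_A,
                           c(1615, 1655)), "bleach")
  expect_error(compute_cls(sp$nu_pump, sp$nu_probe, sp$delta_A,
                           c(1634, 1636)), "slices")
})

test_that("2D spectrum text round trip preserves grids and matrix", {
  sp <- gen_2dir_bleach(rho = 0.6, noise = 0.01, seed = 3)
  d <- withr::local_tempdir()
  p <- file.path(d, "bleach.tsv")
  write_spectrum2d(sp$nu_pump, sp$nu_probe, sp$delta_A, p)
  back <- read_spectrum2d(p, sep = "\t")
  expect_equal(back$nu_pump, sp$nu_pump)
  expect_equal(back$nu_probe, sp$nu_probe)
  expect_equal(back$delta_A, sp$delta_A, tolerance = 1e-9)
  cls1 <- compute_cls(sp$nu_pump, sp$nu_probe, sp$delta_A, c(1615, 1655))$cls
  cls2 <- compute_cls(back$nu_pump, back$nu_probe, back$delta_A,
                      c(1615, 1655))$cls
  expect_equal(cls1, cls2, tolerance = 1e-9)
})

test_that("Rpn is the forced max/|min| arithmetic and is scale-invariant", {
  wl <- seq(185, 240, 0.5)
  y <- -0.1 * exp(-(wl - 198)^2 / 18) + 0.019 * exp(-(wl - 220)^2 / 40)
  expect_equal(cd_rpn(wl, y), 0.19, tolerance = 1e-4)
  expect_equal(cd_rpn(wl, 250 * y), cd_rpn(wl, y), tolerance = 1e-12)
  expect_error(cd_rpn(wl, abs(y) + 0.01), "triple-helical")
  expect_error(cd_rpn(seq(210, 240), rnorm(31)), "windows")
})

test_that("noiseless two-state melting curves are recovered to 0.1 C", {
  for (tm in c(40, 43)) {
    cm <- gen_cd_melt(t_m = tm, width = 1.5, noise = 0, seed = 1)
    f <- fit_melting_curve(cm$temperature, cm$signal)
    expect_true(f$transition)
    expect_lt(abs(f$t_m - tm), 0.1)
  }
})

test_that("for a symmetric sigmoid t_m coincides with the inflection of the signal", {
  cm <- gen_cd_melt(t_m = 42, width = 2, noise = 0, seed = 1,
                    temperature = seq(20, 65, 0.25))
  f <- fit_melting_curve(cm$temperature, cm$signal)
  dy <- diff(cm$signal) / diff(cm$temperature)
  t_inflect <- cm$temperature[which.min(dy)] + 0.125
  expect_lt(abs(f$t_m - t_inflect), 0.3)
})

test_that("melting temperature is recovered within 1 C median at 2% noise", {
  tms <- sapply(1:20, function(s) {
    cm <- gen_cd_melt(t_m = 43, width = 1.5, noise = 0.02, seed = s)
    fit_melting_curve(cm$temperature, cm$signal)$t_m
  })
  expect_lt(median(abs(tms - 43)), 1)
})

test_that("melting fit is invariant under scaling and temperature-independent offsets", {
  cm <- gen_cd_melt(t_m = 41, width = 1.2, noise = 0.01, seed = 5)
  f0 <- fit_melting_curve(cm$temperature, cm$signal)
  fs <- fit_melting_curve(cm$temperature, 7 * cm$signal)
  fo <- fit_melting_curve(cm$temperature, cm$signal + 3)
  expect_lt(abs(fs$t_m - f0$t_m), 1e-6)
  expect_lt(abs(fo$t_m - f0$t_m), 1e-6)
})

test_that("flat melting signals yield a flagged no-transition result", {
  f <- fit_melting_curve(seq(25, 60, 2), rep(0.5, 18))
  expect_false(f$transition)
  expect_true(is.na(f$t_m))
})

test_that("sloped baselines with small steps do not fool the melting fit", {
  cm <- gen_cd_melt(t_m = 44, width = 1, folded_baseline = c(1, -0.004),
                    unfolded_baseline = c(0.1, -0.001), noise = 0, seed = 2)
  f <- fit_melting_curve(cm$temperature, cm$signal)
  expect_lt(abs(f$t_m - 44), 0.1)
})
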