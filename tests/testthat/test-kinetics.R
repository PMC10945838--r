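test_that("absorbance-to-turbidity conversion applies ln(10) and baseline subtraction", {
  t <- 0:99
  # all-zero absorbance stays zero
  expect_true(all(absorbance_to_turbidity(t, rep(0, 100))$tau == 0))
  # constant absorbance is annihilated by its own baseline
  expect_equal(absorbance_to_turbidity(t, rep(0.7, 100))$tau, rep(0, 100))
  # A = 1 over a zero baseline gives ln(10)
  A <- c(rep(0, 10), rep(1, 90))
  tr <- absorbance_to_turbidity(t, A, baseline_window = 1:10)
  expect_equal(tr$tau[100], log(10), tolerance = 1e-12)
  expect_error(absorbance_to_turbidity(t, A, baseline_window = integer(0)),
               "baseline")
  expect_error(absorbance_to_turbidity(c(0, 0, 1), c(1, 2, 3)), "increasing")
})

test_that("turbidity conversion is linear in the absorbance", {
  t <- 0:200
  A <- 0.1 + 0.5 / (1 + exp(-0.05 * (t - 100)))
  tau1 <- absorbance_to_turbidity(t, A)$tau
  tau3 <- absorbance_to_turbidity(t, 3 * A)$tau
  expect_equal(tau3, 3 * tau1, tolerance = 1e-12)
})

test_that("pH* correction is the exact affine transform", {
  expect_equal(ph_star_to_ph(0), 0.4)
  expect_equal(ph_star_to_ph(7.4), 7.2746)
  x <- seq(2, 12, 0.5)
  expect_true(all(diff(ph_star_to_ph(x)) > 0))
  expect_error(ph_star_to_ph(NA), "finite")
})

test_that("noiseless logistic input is recovered exactly with the tangent descriptors", {
  t <- seq(0, 1000, by = 2)
  tau <- 0.5 / (1 + exp(-0.02 * (t - 500)))
  f <- fit_fibrillation_kinetics(t, tau)
  expect_true(f$fibrillation)
  expect_lt(rel_err(f$t_lag, 400), 1e-6)
  expect_lt(rel_err(f$t_plateau, 600), 1e-6)
  expect_lt(rel_err(f$k_g, 0.0025), 1e-6)
  expect_lt(rel_err(f$delta_tau, 0.5), 1e-6)
  # tangent identity t_plateau - t_lag = 4/k
  expect_lt(rel_err(f$t_plateau - f$t_lag, 4 / f$k), 1e-6)
})

test_that("flat traces yield a flagged no-fibrillation result, not an error", {
  t <- seq(0, 1000, by = 5)
  f <- fit_fibrillation_kinetics(t, rep(0.001, length(t)))
  expect_false(f$fibrillation)
  expect_true(is.na(f$t_lag))
  expect_equal(f$delta_tau, 0)
  f2 <- fit_fibrillation_kinetics(gen_turbidity_trace(delta_tau = 0, seed = 3)$time,
                                  rep(0, 201))
  expect_false(f2$fibrillation)
})

test_that("descriptors are recovered within 10% median relative error at 5% noise", {
  errs <- sapply(1:50, function(s) {
    truth <- list(delta_tau = runif(1, 0.1, 1) * 0 + 0.5, k = 0.02, t_half = 500)
    tr <- gen_turbidity_trace(delta_tau = 0.5, k = 0.02, t_half = 500,
                              noise = 0.05, seed = s)
    tb <- absorbance_to_turbidity(tr$time, tr$A313)
    f <- fit_fibrillation_kinetics(tb$time, tb$tau)
    tt <- attr(tr, "truth")
    c(rel_err(f$t_lag, tt$t_lag), rel_err(f$k_g, tt$k_g),
      rel_err(f$t_plateau, tt$t_plateau), rel_err(f$delta_tau, tt$delta_tau))
  })
  expect_lt(median(errs[1, ]), 0.1)
  expect_lt(median(errs[2, ]), 0.1)
  expect_lt(median(errs[3, ]), 0.1)
  expect_lt(median(errs[4, ]), 0.1)
})

test_that("recovery holds across the descriptor grid", {
  set.seed(77)
  cases <- expand.grid(delta_tau = c(0.1, 0.5, 1), k = c(0.005, 0.03, 0.1))
  errs <- apply(cases, 1, function(cs) {
    th <- 3 / cs["k"]
    tr <- gen_turbidity_trace(delta_tau = cs["delta_tau"], k = cs["k"],
                              t_half = th, noise = 0.05,
                              sampling_dt = th / 150, seed = 91)
    tb <- absorbance_to_turbidity(tr$time, tr$A313)
    f <- fit_fibrillation_kinetics(tb$time, tb$tau)
    tt <- attr(tr, "truth")
    max(rel_err(coef(f)[c("t_lag", "k_g", "t_plateau", "delta_tau")],
                unlist(tt[c("t_lag", "k_g", "t_plateau", "delta_tau")])))
  })
  expect_lt(median(errs), 0.1)
})

test_that("the Gompertz option fits asymmetric sigmoids with its tangent descriptors", {
  t <- seq(0, 1500, by = 3)
  tau <- 0.4 * exp(-exp(-0.01 * (t - 400)))
  f <- fit_fibrillation_kinetics(t, tau, model = "gompertz")
  expect_lt(rel_err(f$delta_tau, 0.4), 1e-5)
  expect_lt(rel_err(f$t_lag, 400 - 1 / 0.01), 1e-5)
  expect_lt(rel_err(f$t_plateau, 400 + (exp(1) - 1) / 0.01), 1e-5)
  expect_lt(rel_err(f$k_g, 0.01 * 0.4 / exp(1)), 1e-5)
})

test_that("descriptor ordering survives 2x time-axis subsampling", {
  tr <- gen_turbidity_trace(delta_tau = 0.5, k = 0.02, t_half = 500,
                            noise = 0.05, seed = 13)
  tb <- absorbance_to_turbidity(tr$time, tr$A313)
  f1 <- fit_fibrillation_kinetics(tb$time, tb$tau)
  keep <- seq(1, nrow(tb), by = 2)
  f2 <- fit_fibrillation_kinetics(tb$time[keep], tb$tau[keep])
  expect_true(f2$t_lag < f2$t_half && f2$t_half < f2$t_plateau)
  expect_lt(rel_err(f2$t_lag, f1$t_lag), 0.1)
  expect_lt(rel_err(f2$delta_tau, f1$delta_tau), 0.1)
})

test_that("fibkin methods expose the fit", {
  t <- seq(0, 1000, by = 5)
  tau <- 0.5 / (1 + exp(-0.02 * (t - 500)))
  f <- fit_fibrillation_kinetics(t, tau)
  expect_named(coef(f), c("t_lag", "k_g", "t_plateau", "delta_tau",
                          "t_half", "k"))
  expect_equal(predict(f, newdata = list(time = 500)), 0.25, tolerance = 1e-6)
  expect_output(print(f), "t_lag")
})

test_that("turbidity trace files round-trip through the reader", {
  d <- withr::local_tempdir()
  tr <- gen_turbidity_trace(seed = 5)
  p <- file.path(d, "trace.tsv")
  write.table(data.frame(time_s = tr$time, A313 = tr$A313), p,
              sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_turbidity_trace(p, sep = "\t")
  expect_equal(back$time, tr$time)
  expect_equal(back$A313, tr$A313, tolerance = 1e-9)
})
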