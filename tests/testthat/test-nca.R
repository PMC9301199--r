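test_that("linear trapezoid AUC: triangles, constants, interpolation, errors", {
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 2, 2), 0, 2), 3)
  expect_equal(auc_trapezoid(c(0, 5, 9), c(4, 4, 4), 0, 9), 36)
  # interpolated bounds: exact for a piecewise-linear profile
  expect_equal(auc_trapezoid(c(0, 1, 2), c(0, 2, 2), 0.5, 1.5), 1.75,
               tolerance = 1e-12)
  expect_error(auc_trapezoid(c(0, 1, 2), c(1, 1, 1), 2, 1), "exceed")
  expect_error(auc_trapezoid(c(0, 1, 2), c(1, 1, 1), 0, 3), "within")
})

test_that("AUC is exactly additive over abutting intervals", {
  set.seed(9)
  for (i in 1:10) {
    tt <- sort(runif(12, 0, 48))
    cc <- runif(12, 0, 10)
    a <- tt[1]; c_ <- tt[12]
    b <- runif(1, a, c_)
    expect_equal(
      auc_trapezoid(tt, cc, a, b) + auc_trapezoid(tt, cc, b, c_),
      auc_trapezoid(tt, cc, a, c_), tolerance = 1e-13)
  }
})

test_that("terminal slope: exact exponential, degenerate and biexponential", {
  tt <- c(4, 6, 8, 12, 24)
  lz <- lambda_z(tt, 10 * exp(-0.1 * tt))
  expect_equal(lz$lambda_z, 0.1, tolerance = 1e-10)
  expect_equal(log(2) / lz$lambda_z, 6.931, tolerance = 1e-3)

  expect_error(lambda_z(c(0, 1, 2, 3, 4), rep(5, 5)), "negative")
  expect_error(lambda_z(c(0, 1, 2), c(1, 0.5, 0.2)), "at least 3")

  # biexponential with terminal phase k = 0.05 dominating after ~24 h
  tt2 <- c(0.5, 1, 2, 4, 8, 12, 24, 36, 48, 72, 96)
  cc2 <- 5 * exp(-0.3 * tt2) + 2 * exp(-0.05 * tt2)
  lz2 <- lambda_z(tt2, cc2)
  expect_equal(lz2$lambda_z, 0.05, tolerance = 0.02)
  expect_true(lz2$n_points >= 3 && lz2$n_points <= 6)
})

test_that("single-dose NCA obeys its internal identities", {
  # one-compartment bolus, D/V = 100 ng/mL, k = 0.1/h on the default grid
  tt <- c(0.08, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48, 72)
  k <- 0.1; V <- 5000; dose <- 100 * V
  res <- nca_single_dose(tt, 100 * exp(-k * tt), dose)
  expect_equal(res$CL_F, k * V, tolerance = 0.02)
  expect_equal(res$T_half, log(2) / k, tolerance = 1e-6)
  expect_equal(res$CL_F * res$AUCinf, dose, tolerance = 1e-12)  # by construction
  expect_equal(res$V_F, res$CL_F / res$lambda_z, tolerance = 1e-12)
  expect_gte(res$AUCinf, res$AUClast)
  expect_equal(res$AUC_pct_extrap,
               100 * (res$AUCinf - res$AUClast) / res$AUCinf)

  expect_error(nca_single_dose(c(1, 2, 3), c(0, 0, 0), 100), "positive")
})

test_that("Cmax and Tmax are read off the grid without interpolation", {
  sim <- pbpk_simulate(default_phys, us_sys, default_frac,
                       single_dose_regimen(0.12, "intranasal"))
  res <- nca(sim, "plasma")
  expect_true(res$Tmax %in% sim$time)
  expect_equal(res$Cmax, max(sim$conc$C_plasma))
  # repeat runs are bit-for-bit identical (deterministic pipeline)
  sim2 <- pbpk_simulate(default_phys, us_sys, default_frac,
                        single_dose_regimen(0.12, "intranasal"))
  expect_identical(unclass(nca(sim2, "plasma")), unclass(res))
})

test_that("multidose NCA reproduces the superposition accumulation oracle", {
  # first-order-absorption train (continuous at dose times, like the model)
  k <- 0.045; tau <- 12; ka <- 2
  reg <- bid_regimen(0.06, "intranasal", days = 7, tau = tau)
  dose_times <- vapply(reg$events, `[[`, 0, "time")
  tt <- sort(unique(c(sampling_grid(reg), seq(0, 216, 0.25))))
  cc <- bateman_train(tt, 1e5, 1, ka, 1e4, 0.045 * 1e4, dose_times)
  res <- nca_multidose(tt, cc, reg, 0.06e6)
  # final interval collects the 13 shifted copies of one dose's [m*tau,
  # (m+1)*tau] slices, i.e. the dose's full AUC fraction up to 13*tau
  r_expected <- bateman_auc_frac(13 * tau, ka, k) /
    bateman_auc_frac(tau, ka, k)
  expect_equal(res$R_AUC, r_expected, tolerance = 0.01)
  expect_equal(r_expected, 2.474, tolerance = 1e-3)
  expect_equal(res$lambda_z, k, tolerance = 0.01)

  # fast elimination: the day-7 interval is a copy of day 1, no accumulation
  tt1 <- seq(0, 24, by = 0.1)
  cc1 <- bateman_train(tt1, 1e5, 1, 2, 1e4, 0.5 * 1e4, c(0, 12))
  two <- regimen(list(dose_event(0, "intranasal", 0.06e6),
                      dose_event(12, "intranasal", 0.06e6)))
  res1 <- nca_multidose(tt1, cc1, two, 0.06e6)
  expect_equal(res1$R_Cmax, 1, tolerance = 5e-3)
  expect_equal(res1$R_AUC, 1, tolerance = 5e-3)

  expect_error(nca_multidose(tt[tt <= 100], cc[tt <= 100], reg, 0.06e6),
               "cover")
})

test_that("time to steady state follows the trough-fraction oracle", {
  # troughs of a first-order absorption train: with absorption complete
  # within each interval, trough(day d)/trough(ss) = the partial geometric
  # sums, giving day 4 at the 0.95 criterion for k = 0.045/h
  k <- 0.045; tau <- 12
  reg <- bid_regimen(0.06, "intranasal", days = 7, tau = tau)
  dose_times <- vapply(reg$events, `[[`, 0, "time")
  tt <- sort(unique(c(sampling_grid(reg), seq(0, 216, 0.5))))
  cc <- bateman_train(tt, 1e5, 1, 2, 1e4, k * 1e4, dose_times)
  # trough fraction after n doses is 1 - exp(-n k tau): first morning
  # pre-dose trough at >= 0.95 of the final trough is day 4 (6 doses)
  expect_identical(time_to_steady_state(tt, cc, reg, 0.95), 4L)
  expect_identical(time_to_steady_state(tt, cc, reg, 0), 1L)
  # a more permissive criterion qualifies a day earlier (day-3 fraction 0.886)
  expect_identical(time_to_steady_state(tt, cc, reg, 0.85), 3L)
  expect_error(time_to_steady_state(tt, cc, single_dose_regimen(0.06),
                                    0.95), "2 dosing days")
})
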