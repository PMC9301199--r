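test_that("objective: exactness, arithmetic, scale invariance, BLQ handling", {
  expect_identical(pk_objective(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(pk_objective(c(1, 2), c(0, 0), weighting = "uniform"), 5)
  # 1/y^2 weighting is scale-invariant
  o <- c(0.2, 1.5, 4); p <- c(0.25, 1.2, 4.4)
  expect_equal(pk_objective(10 * o, 10 * p), pk_objective(o, p),
               tolerance = 1e-12)
  # censored (zero) observations are excluded
  expect_identical(pk_objective(c(0, 1), c(7, 1), weighting = "uniform"), 0)
  expect_error(pk_objective(c(0, 0), c(1, 1)), "LLOQ")
})

test_that("systemic parameters are recovered from a noise-free oral profile", {
  suite <- generate_fit_suite(seed = 101, noise = noise_free(101))
  init <- systemic_params(tlag = 0.2, ka = 0.5, Vc = 100, CL = 20)
  fit <- fit_systemic(suite$us_oral, default_phys, init = init,
                      restarts = 3, seed = 1)
  est <- coef(fit)
  truth <- c(tlag = 0.371, ka = 1.036, Vc = 194352, CL = 10001)
  for (p in names(truth))
    expect_equal(est[[p]], truth[[p]], tolerance = 0.01)
  expect_true(fit$converged)
  # minimizer contract: optimum no worse than the starting point
  obj_init <- pk_objective(
    suite$us_oral$conc_ng_ml,
    predict(structure(list(estimates = c(tlag = 0.2, ka = 0.5,
                                         Vc = 1e5, CL = 2e4),
                           kind = "systemic", obs = suite$us_oral,
                           phys = default_phys, engine = "compiled"),
                      class = "pbpk_fit")))
  expect_lte(fit$objective, obj_init)
  # accepted-objective trace is non-increasing
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("deposition fractions are recovered from a noise-free nasal profile", {
  suite <- generate_fit_suite(seed = 202, noise = noise_free(202))
  fit <- fit_deposition(suite$us_intranasal, default_phys, us_sys,
                        restarts = 3, seed = 1)
  expect_equal(coef(fit)[["F1"]], 0.547, tolerance = 0.01)
  # F2 is identifiable only up to its negligible magnitude
  expect_lt(coef(fit)[["F2"]], 1e-3)
})

test_that("a null nasal deposition is recovered as (near) zero", {
  frac0 <- deposition_fractions(F1 = 0, F2 = 7.6375e-7)
  obs <- generate_observed(default_phys, us_sys, frac0,
                           single_dose_regimen(0.12, "intranasal"),
                           noise = noise_free(7), label = "null F1")
  fit <- fit_deposition(obs, default_phys, us_sys,
                        init = c(F1 = 0.05, F2 = 1e-4),
                        restarts = 3, seed = 2)
  expect_lt(coef(fit)[["F1"]], 1e-6)
})

test_that("fitted F1 scales linearly with the observed concentrations", {
  suite <- generate_fit_suite(seed = 303, noise = noise_free(303))
  obs <- suite$us_intranasal
  half <- observed_series(obs$time_h, obs$conc_ng_ml / 2,
                          dose_ng = attr(obs, "dose_ng"),
                          route = "intranasal")
  f_full <- fit_deposition(obs, default_phys, us_sys, restarts = 2,
                           seed = 3)
  f_half <- fit_deposition(half, default_phys, us_sys, restarts = 2,
                           seed = 3)
  expect_equal(coef(f_full)[["F1"]] / coef(f_half)[["F1"]], 2,
               tolerance = 0.02)
})

test_that("fixed systemic parameters shift F1 smoothly, not into F2", {
  suite <- generate_fit_suite(seed = 404, noise = noise_free(404))
  perturb <- function(f) systemic_params(
    tlag = us_sys$tlag, ka = us_sys$ka, Vc = us_sys$Vc * f,
    CL = us_sys$CL * f, units = "mL")
  f_lo <- fit_deposition(suite$us_intranasal, default_phys, perturb(0.9),
                         restarts = 2, seed = 4)
  f_hi <- fit_deposition(suite$us_intranasal, default_phys, perturb(1.1),
                         restarts = 2, seed = 4)
  # finite, monotone sensitivity around the truth; F2 stays negligible
  expect_lt(coef(f_lo)[["F1"]], 0.547)
  expect_gt(coef(f_hi)[["F1"]], 0.547)
  expect_lt(abs(coef(f_hi)[["F1"]] - coef(f_lo)[["F1"]]), 0.25)
  expect_lt(coef(f_lo)[["F2"]], 1e-3)
  expect_lt(coef(f_hi)[["F2"]], 1e-3)
})

test_that("fit methods: predict, residuals, summary are coherent", {
  suite <- generate_fit_suite(seed = 505, noise = noise_free(505))
  fit <- fit_systemic(suite$us_oral, default_phys, restarts = 1, seed = 1)
  pred <- predict(fit)
  expect_length(pred, nrow(suite$us_oral))
  keep <- suite$us_oral$conc_ng_ml > 0
  expect_equal(residuals(fit), suite$us_oral$conc_ng_ml[keep] - pred[keep],
               tolerance = 1e-12)
  s <- summary(fit)
  expect_lt(s$rmse, 0.05)   # noise-free: near-perfect fit
  expect_error(fit_systemic(suite$us_intranasal, default_phys), "oral")
  expect_error(fit_deposition(suite$us_oral, default_phys, us_sys),
               "intranasal")
})
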