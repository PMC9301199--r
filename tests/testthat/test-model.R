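test_that("right-hand side: equilibrium at zero, GI mass action, closure", {
  z <- nasalpbpk:::zero_state()
  expect_true(all(pbpk_rhs(z, 0, default_phys, us_sys) == 0))

  s <- z; s["GI"] <- 1000
  d <- pbpk_rhs(s, 0, default_phys, us_sys)       # FA 0.9, ka 1.036
  expect_equal(d[["CENTRAL"]], 932.4)
  expect_equal(d[["UNABS"]], 103.6, tolerance = 1e-12)
  expect_equal(d[["GI"]], -1036)

  # closed system: derivative components sum to zero at random states
  set.seed(3)
  for (i in 1:20) {
    s <- nasalpbpk:::zero_state()
    s[] <- runif(length(s), 0, 1e5)
    expect_equal(sum(pbpk_rhs(s, 0, default_phys, us_sys)), 0,
                 tolerance = 1e-7)
  }
})

test_that("compiled and R right-hand sides integrate to the same profiles", {
  reg <- single_dose_regimen(0.12, "intranasal")
  sim_c <- pbpk_simulate(default_phys, us_sys, default_frac, reg)
  sim_r <- pbpk_simulate(default_phys, us_sys, default_frac, reg,
                         engine = "R")
  expect_equal(sim_r$conc$C_plasma, sim_c$conc$C_plasma, tolerance = 1e-6)
  expect_equal(sim_r$conc$C_nasal, sim_c$conc$C_nasal, tolerance = 1e-6)

  reg_o <- single_dose_regimen(1, "oral")
  sim_co <- pbpk_simulate(default_phys, us_sys, default_frac, reg_o)
  sim_ro <- pbpk_simulate(default_phys, us_sys, default_frac, reg_o,
                          engine = "R")
  expect_equal(sim_ro$conc$C_plasma, sim_co$conc$C_plasma, tolerance = 1e-6)
})

test_that("dose application routes amounts by deposition fraction", {
  z <- nasalpbpk:::zero_state()
  s <- apply_dose(z, dose_event(0, "intranasal", 60000), default_frac)
  expect_equal(s[["ELF_Nose"]], 60000 * 0.547)   # 32 820 ng
  expect_equal(s[["GI"]], 60000 * 7.6375e-7)
  expect_equal(sum(s), 60000)                    # conservation incl. vestibule

  null_frac <- deposition_fractions(F1 = 0, F2 = 0)
  s0 <- apply_dose(z, dose_event(0, "intranasal", 60000), null_frac)
  expect_equal(s0[["UNABS"]], 60000)
  expect_true(all(s0[setdiff(names(s0), "UNABS")] == 0))

  so <- apply_dose(z, dose_event(0, "oral", 1e6), default_frac)
  expect_equal(so[["GI"]], 1e6)
  expect_true(all(so[setdiff(names(so), "GI")] == 0))
})

test_that("null deposition leaves plasma at zero forever", {
  null_frac <- deposition_fractions(F1 = 0, F2 = 0)
  sim <- pbpk_simulate(default_phys, us_sys, null_frac,
                       single_dose_regimen(0.12, "intranasal"))
  expect_true(all(sim$conc$C_plasma == 0))
  expect_equal(sim$states[, "UNABS"], rep(0.12e6, length(sim$time)))
})

test_that("empty regimen yields an all-zero simulation", {
  sim <- pbpk_simulate(default_phys, us_sys, default_frac,
                       regimen(list()), grid = c(0, 1, 2, 5))
  expect_true(all(sim$states == 0))
  expect_identical(mass_balance(sim), 0)
})

test_that("oral kinetics match the one-compartment closed form", {
  # respiratory exchange is active but perturbs the oral profile < 1%
  grid <- seq(0, 72, by = 0.02)
  sim <- pbpk_simulate(default_phys, us_sys, default_frac,
                       single_dose_regimen(1, "oral"), grid = grid)
  cp <- sim$conc$C_plasma
  ref <- bateman(grid, 1e6, 0.9, us_sys$ka, us_sys$Vc, us_sys$CL,
                 tlag = us_sys$tlag)
  expect_equal(max(cp), max(ref), tolerance = 0.01)
  expect_true(max(cp) > 3.9 && max(cp) < 4.0)
  expect_equal(grid[which.max(cp)], 3.42, tolerance = 0.05)
  # whole-profile agreement
  expect_lt(max(abs(cp - ref)) / max(ref), 0.01)
})

test_that("nasal tissue AUC0-inf equals deposited dose / (fu_tissue * PS_Nose)", {
  sim <- pbpk_simulate(default_phys, us_sys, default_frac,
                       single_dose_regimen(0.06, "intranasal"))
  res <- nca(sim, "nasal")
  analytic <- 0.06e6 * 0.547 / (default_phys$fu_tissue *
                                  default_phys$PS[["Nose"]])
  expect_equal(res$AUCinf, analytic, tolerance = 0.05)
})

test_that("mass balance holds to 0.1% on all regimen types", {
  regs <- list(single_dose_regimen(1, "oral"),
               single_dose_regimen(0.12, "intranasal"),
               bid_regimen(0.06, "intranasal", days = 7))
  for (reg in regs) {
    sim <- pbpk_simulate(default_phys, us_sys, default_frac, reg)
    expect_lt(mass_balance(sim), 1e-3)
  }
  # mid-lag grid point: the pre-absorption depot keeps the books closed
  sim <- pbpk_simulate(default_phys, us_sys, default_frac,
                       single_dose_regimen(1, "oral"),
                       grid = c(0, 0.1, 0.2, 0.3, 1, 4, 24))
  expect_lt(mass_balance(sim), 1e-3)
})

test_that("superposition linearity holds to 1e-6", {
  single <- single_dose_regimen(0.06, "intranasal")
  two <- regimen(list(dose_event(0, "intranasal", 0.06e6),
                      dose_event(12, "intranasal", 0.06e6)))
  expect_lt(superpose_check(default_phys, us_sys, default_frac,
                            single, two), 1e-6)
  expect_lt(superpose_check(default_phys, us_sys, default_frac,
                            single, bid_regimen(0.06, "intranasal", 7)),
            1e-6)
  expect_identical(superpose_check(default_phys, us_sys, default_frac,
                                   single, single), 0)
})

test_that("doubling the dose doubles every concentration", {
  reg1 <- single_dose_regimen(0.06, "intranasal")
  reg2 <- single_dose_regimen(0.12, "intranasal")
  s1 <- pbpk_simulate(default_phys, us_sys, default_frac, reg1)
  s2 <- pbpk_simulate(default_phys, us_sys, default_frac, reg2)
  expect_equal(s2$conc$C_plasma, 2 * s1$conc$C_plasma, tolerance = 1e-8)
  expect_equal(s2$conc$C_nasal, 2 * s1$conc$C_nasal, tolerance = 1e-8)
})

test_that("a pure-pharynx spray reproduces the unlagged oral profile", {
  # F2 = 1 means the whole intranasal dose is swallowed immediately
  swallow <- deposition_fractions(F1 = 0, F2 = 1)
  grid <- sampling_grid(single_dose_regimen(1, "oral"))
  sim_n <- pbpk_simulate(default_phys, us_sys, swallow,
                         single_dose_regimen(1, "intranasal"), grid = grid)
  sys0 <- systemic_params(tlag = 0, ka = us_sys$ka, Vc = us_sys$Vc,
                          CL = us_sys$CL, units = "mL")
  sim_o <- pbpk_simulate(default_phys, sys0, default_frac,
                         single_dose_regimen(1, "oral"), grid = grid)
  expect_equal(sim_n$conc$C_plasma, sim_o$conc$C_plasma, tolerance = 1e-7)
})

test_that("nasal and plasma terminal slopes run parallel", {
  sim <- pbpk_simulate(default_phys, us_sys, default_frac,
                       single_dose_regimen(0.12, "intranasal"))
  lp <- nca(sim, "plasma")$lambda_z
  ln <- nca(sim, "nasal")$lambda_z
  expect_equal(ln / lp, 1, tolerance = 0.02)
})

test_that("tidy export carries amounts and defined concentrations", {
  sim <- pbpk_simulate(default_phys, us_sys, default_frac,
                       single_dose_regimen(0.06, "intranasal"))
  df <- as.data.frame(sim)
  expect_setequal(unique(df$compartment), nasalpbpk:::.STATES)
  expect_true(all(is.na(df$conc_ng_per_ml[df$compartment == "GI"])))
  cen <- df[df$compartment == "CENTRAL", ]
  expect_equal(cen$conc_ng_per_ml, cen$amount_ng / us_sys$Vc)
})

test_that("simulation guards reject malformed inputs", {
  expect_error(pbpk_simulate(default_phys, us_sys, default_frac,
                             single_dose_regimen(1, "oral"),
                             grid = c(0, 1, 1, 2)),
               "strictly increasing")
  sysp <- us_systemic_params(); sysp$k12 <- 0.1
  expect_error(pbpk_simulate(default_phys, sysp, default_frac,
                             single_dose_regimen(1, "oral")),
               "k12")
})
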