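#' Observed concentration-time series
#'
#' Tidy container for a mean concentration-time profile: a data frame with
#' columns `time_h` and `conc_ng_ml` plus metadata attributes.  Values
#' below the LLOQ are stored as 0 (the convention of the source assays).
#'
#' @param times strictly increasing times, h.
#' @param conc concentrations, ng/mL (>= 0).
#' @param label free-text label.
#' @param dose_ng administered dose, ng.
#' @param route `"oral"` or `"intranasal"`.
#' @param lloq lower limit of quantitation, ng/mL.
#' @param truth optional named list of the generating parameters (kept by
#'   the synthetic generator for recovery tests).
#' @return An object of classes `observed_series` and `data.frame`.
#' @export
observed_series <- function(times, conc, label = "", dose_ng,
                            route = c("oral", "intranasal"), lloq = 0,
                            truth = NULL) {
  route <- match.arg(route)
  stopifnot(length(times) == length(conc), all(diff(times) > 0),
            all(conc >= 0), dose_ng >= 0, lloq >= 0)
  structure(data.frame(time_h = times, conc_ng_ml = conc),
            label = label, dose_ng = dose_ng, route = route, lloq = lloq,
            truth = truth,
            class = c("observed_series", "data.frame"))
}

#' Residual-error and censoring specification
#'
#' Multiplicative lognormal error with coefficient of variation
#' `proportional_sd` (parameterized to have mean 1, so averaging noisy
#' replicates is unbiased), plus additive Gaussian error, followed by
#' LLOQ censoring: values below `lloq` are recorded as 0.
#'
#' @param proportional_sd proportional error CV (default 0.10).
#' @param additive_sd additive error SD, ng/mL (default 0).
#' @param lloq lower limit of quantitation, ng/mL (default 0.05, a
#'   plausible plasma bioanalytical limit; configurable).
#' @param seed RNG seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(proportional_sd = 0.10, additive_sd = 0,
                       lloq = 0.05, seed = 1) {
  stopifnot(proportional_sd >= 0, additive_sd >= 0, lloq >= 0)
  structure(list(proportional_sd = proportional_sd,
                 additive_sd = additive_sd, lloq = lloq,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Generate an observed-like concentration-time series
#'
#' Simulates the true profile with [pbpk_simulate()], applies the residual
#' error of a [noise_spec()] and LLOQ-to-zero censoring.  Deterministic
#' given the seed.
#'
#' @param phys,sys,frac,reg,grid simulation inputs (see
#'   [pbpk_simulate()]).
#' @param noise a [noise_spec()].
#' @param label series label.
#' @return An [observed_series()] whose `truth` attribute records the
#'   generating parameters.
#' @export
generate_observed <- function(phys, sys, frac, reg, grid = NULL,
                              noise = noise_spec(), label = "synthetic") {
  stopifnot(inherits(noise, "noise_spec"))
  if (is.null(grid)) grid <- sampling_grid(reg)
  sim <- pbpk_simulate(phys, sys, frac, reg, grid = grid)
  cp <- sim$conc$C_plasma
  ## drop the pre-dose zero time point from the reported series
  keep <- grid > min(grid) | cp > 0
  tt <- grid[keep]; cp <- cp[keep]

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(noise$seed)
  y <- cp
  if (noise$proportional_sd > 0) {
    sdlog <- sqrt(log(1 + noise$proportional_sd^2))
    y <- y * rlnorm(length(y), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  if (noise$additive_sd > 0)
    y <- y + rnorm(length(y), sd = noise$additive_sd)
  y <- pmax(y, 0)
  y[y < noise$lloq] <- 0

  ev <- reg$events[[1L]]
  observed_series(tt, y, label = label,
                  dose_ng = sum(vapply(reg$events, `[[`, 0, "amount")),
                  route = ev$route, lloq = noise$lloq,
                  truth = list(sys = sys, frac = frac, noise = noise))
}

#' Canonical three-profile fitting suite
#'
#' Emits the three mean profiles the three-step fitting strategy consumes:
#' US oral 1 mg, Chinese oral 1 mg, and US intranasal 0.12 mg (single
#' doses on the default clinical sampling grid, 72 h follow-up), generated
#' from the reference parameter sets and tagged with their ground truth.
#'
#' @param seed base RNG seed (each series uses `seed`, `seed + 1`,
#'   `seed + 2`).
#' @param noise a [noise_spec()]; its seed field is overridden per series.
#'   Use `proportional_sd = 0, lloq = 0` for noise-free profiles.
#' @param phys physiology (default [build_physiology()]).
#' @return Named list of three [observed_series()]: `us_oral`, `cn_oral`,
#'   `us_intranasal`.
#' @export
generate_fit_suite <- function(seed = 20220707, noise = noise_spec(),
                               phys = build_physiology()) {
  mk_noise <- function(k) {
    n <- noise; n$seed <- as.integer(seed + k); n
  }
  frac <- deposition_fractions()
  list(
    us_oral = generate_observed(
      phys, us_systemic_params(), frac, single_dose_regimen(1, "oral"),
      noise = mk_noise(0L), label = "US oral 1 mg"),
    cn_oral = generate_observed(
      phys, cn_systemic_params(), frac, single_dose_regimen(1, "oral"),
      noise = mk_noise(1L), label = "CN oral 1 mg"),
    us_intranasal = generate_observed(
      phys, us_systemic_params(), frac,
      single_dose_regimen(0.12, "intranasal"),
      noise = mk_noise(2L), label = "US intranasal 0.12 mg"))
}

#' Write / read an observed series (tidy CSV + YAML metadata)
#'
#' @param obs an [observed_series()].
#' @param csv path of the CSV (`time_h, conc_ng_ml`).
#' @param meta path of the YAML metadata (default: same path with
#'   `.yaml`); records label, dose (mg), route, and LLOQ.
#' @return `write_observed`: invisibly, the CSV path; `read_observed`: an
#'   `observed_series`.
#' @export
write_observed <- function(obs, csv, meta = sub("\\.csv$", ".yaml", csv)) {
  stopifnot(inherits(obs, "observed_series"))
  write.csv(data.frame(time_h = obs$time_h, conc_ng_ml = obs$conc_ng_ml),
            csv, row.names = FALSE)
  yaml::write_yaml(list(label = attr(obs, "label"),
                        dose_mg = attr(obs, "dose_ng") / 1e6,
                        route = attr(obs, "route"),
                        lloq_ng_ml = attr(obs, "lloq")), meta)
  invisible(csv)
}

#' @rdname write_observed
#' @export
read_observed <- function(csv, meta = sub("\\.csv$", ".yaml", csv)) {
  d <- read.csv(csv)
  m <- yaml::read_yaml(meta)
  observed_series(d$time_h, d$conc_ng_ml, label = m$label,
                  dose_ng = m$dose_mg * 1e6, route = m$route,
                  lloq = m$lloq_ng_ml)
}
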