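#' Weighted least-squares objective for concentration fits
#'
#' Sum of squared residuals between observed and predicted concentrations.
#' Observations recorded as 0 (below the limit of quantitation) are
#' excluded: they carry no least-squares information and the source means
#' were zeroed below the LLOQ.  Weights are based on the model prediction
#' (y-hat): `uniform`, `1/y`, or `1/y^2` (proportional error; the
#' default downstream, and scale-invariant).
#'
#' @param obs observed concentrations, ng/mL (0 = censored).
#' @param pred predicted concentrations aligned to the same times.
#' @param weighting one of `"uniform"`, `"1/y"`, `"1/y^2"`.
#' @return Non-negative scalar.
#' @export
pk_objective <- function(obs, pred, weighting = c("1/y^2", "1/y", "uniform")) {
  weighting <- match.arg(weighting)
  stopifnot(length(obs) == length(pred))
  keep <- obs > 0
  if (!any(keep)) stop("all observations are below the LLOQ (zero)")
  o <- obs[keep]; p <- pred[keep]
  pw <- pmax(p, 1e-12)  # weight floor for non-positive predictions
  w <- switch(weighting, uniform = rep(1, length(o)), `1/y` = 1 / pw,
              `1/y^2` = 1 / pw^2)
  sum(w * (o - p)^2)
}

## bounded/log transforms for the simplex search
.tfm <- function(x, lower, upper) {
  ifelse(is.finite(upper),
         stats::qlogis(pmin(pmax((x - lower) / (upper - lower), 1e-12),
                            1 - 1e-12)),
         log(pmax(x - lower, 1e-300)))
}
.itfm <- function(z, lower, upper) {
  ifelse(is.finite(upper),
         lower + (upper - lower) * stats::plogis(z),
         lower + exp(z))
}

## simplex minimization with restarts from jittered starts; records the
## best-objective trace across accepted (improving) evaluations
simplex_fit <- function(par0, fn, lower, upper, restarts = 5, seed = 1,
                        jitter_sd = 0.3, maxit = 600, reltol = 1e-12) {
  z0 <- .tfm(par0, lower, upper)
  trace_env <- new.env()
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  wrapped <- function(z) {
    v <- fn(.itfm(z, lower, upper))
    if (!is.finite(v)) v <- 1e300
    if (v < trace_env$best) {
      trace_env$best <- v
      trace_env$trace <- c(trace_env$trace, v)
    }
    v
  }
  starts <- list(z0)
  if (restarts > 1) {
    jit <- withr_seed_matrix(seed, restarts - 1L, length(z0), jitter_sd)
    for (i in seq_len(restarts - 1L))
      starts[[i + 1L]] <- z0 + jit[i, ]
  }
  best <- NULL
  for (st in starts) {
    o <- optim(st, wrapped, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ## polish from the incumbent; its convergence code is the one reported
  o <- optim(best$par, wrapped, method = "Nelder-Mead",
             control = list(maxit = 5 * maxit, reltol = reltol))
  if (o$value <= best$value) best <- o
  list(par = .itfm(best$par, lower, upper), value = best$value,
       converged = o$convergence == 0, trace = trace_env$trace)
}

## deterministic jitter matrix without touching the global RNG stream
withr_seed_matrix <- function(seed, n, k, sd) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  matrix(rnorm(n * k, sd = sd), nrow = n)
}

#' Fit systemic disposition parameters to an oral profile
#'
#' Estimates `tlag`, `ka`, `Vc`, `CL` by weighted nonlinear least squares,
#' simulating the full respiratory-tract model for every candidate (the
#' respiratory exchange is active but perturbs an oral profile only
#' marginally).  Derivative-free simplex search on transformed scales
#' (logit for the bounded lag, log for the positive parameters), restarted
#' from jittered starts.
#'
#' @param obs an [observed_series()] with `route == "oral"`.
#' @param phys a [build_physiology()] object.
#' @param init starting [systemic_params()] (default: the American oral
#'   reference values).
#' @param weighting residual weighting scheme (see [pk_objective()]).
#' @param tlag_max upper bound of the lag search, h (default 2).
#' @param restarts number of simplex starts (default 5).
#' @param seed seed for the start jitter (default 1).
#' @param engine simulation engine passed to [pbpk_simulate()].
#' @return An object of class `pbpk_fit` with elements `estimates`
#'   (named: tlag, ka, Vc [mL], CL [mL/h]), `objective`, `converged`,
#'   `n_obs`, `weighting`, `trace`, and enough context to predict.
#' @export
fit_systemic <- function(obs, phys, init = us_systemic_params(),
                         weighting = "1/y^2", tlag_max = 2,
                         restarts = 5, seed = 1,
                         engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(obs, "observed_series"), inherits(phys, "physiology"))
  if (attr(obs, "route") != "oral")
    stop("fit_systemic expects an oral observed series")
  reg <- regimen(dose_event(0, "oral", attr(obs, "dose_ng")))
  frac <- deposition_fractions()  # unused by an oral regimen
  times <- obs$time_h
  grid <- if (times[1L] > 0) c(0, times) else times
  drop1 <- times[1L] > 0

  lower <- c(tlag = 0, ka = 1e-3, Vc = 1, CL = 1e-3)
  upper <- c(tlag = tlag_max, ka = Inf, Vc = Inf, CL = Inf)
  par0 <- c(tlag = min(max(init$tlag, 1e-3), tlag_max - 1e-3),
            ka = init$ka, Vc = init$Vc, CL = init$CL)

  predfun <- function(p) {
    sys <- systemic_params(tlag = p[["tlag"]], ka = p[["ka"]],
                           Vc = p[["Vc"]], CL = p[["CL"]], units = "mL")
    sim <- pbpk_simulate(phys, sys, frac, reg, grid = grid, engine = engine)
    cp <- sim$conc$C_plasma
    if (drop1) cp[-1L] else cp
  }
  fn <- function(p) pk_objective(obs$conc_ng_ml, predfun(p), weighting)

  res <- simplex_fit(par0, fn, lower, upper, restarts = restarts,
                     seed = seed)
  structure(list(estimates = res$par, objective = res$value,
                 converged = res$converged,
                 n_obs = sum(obs$conc_ng_ml > 0), weighting = weighting,
                 trace = res$trace, kind = "systemic",
                 obs = obs, phys = phys, engine = engine),
            class = "pbpk_fit")
}

#' Fit intranasal deposition fractions
#'
#' Estimates the nasal (`F1`) and pharyngeal (`F2`) deposition fractions
#' from an intranasal plasma profile, holding the systemic parameters
#' fixed at their oral-fit values; `F3 = F4 = F5 = 0` (spray droplets do
#' not reach the lower airways) and `F1 + F2 <= 1` (penalized).
#'
#' @param obs an [observed_series()] with `route == "intranasal"`.
#' @param phys a [build_physiology()] object.
#' @param sys_fixed fixed [systemic_params()] (from the oral fit).
#' @param init starting values `c(F1 =, F2 =)`.
#' @inheritParams fit_systemic
#' @return A `pbpk_fit` with `estimates = c(F1, F2)`.
#' @export
fit_deposition <- function(obs, phys, sys_fixed,
                           init = c(F1 = 0.3, F2 = 0.01),
                           weighting = "1/y^2", restarts = 5, seed = 1,
                           engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(obs, "observed_series"),
            inherits(sys_fixed, "systemic_params"))
  if (attr(obs, "route") != "intranasal")
    stop("fit_deposition expects an intranasal observed series")
  reg <- regimen(dose_event(0, "intranasal", attr(obs, "dose_ng")))
  times <- obs$time_h
  grid <- if (times[1L] > 0) c(0, times) else times
  drop1 <- times[1L] > 0

  lower <- c(F1 = 0, F2 = 0)
  upper <- c(F1 = 1, F2 = 1)

  predfun <- function(p) {
    frac <- deposition_fractions(F1 = p[["F1"]], F2 = min(p[["F2"]],
                                                          1 - p[["F1"]]))
    sim <- pbpk_simulate(phys, sys_fixed, frac, reg, grid = grid,
                         engine = engine)
    cp <- sim$conc$C_plasma
    if (drop1) cp[-1L] else cp
  }
  fn <- function(p) {
    pen <- if (p[["F1"]] + p[["F2"]] > 1)
      1e6 * (p[["F1"]] + p[["F2"]] - 1)^2 else 0
    pk_objective(obs$conc_ng_ml, predfun(p), weighting) + pen
  }
  res <- simplex_fit(init, fn, lower, upper, restarts = restarts,
                     seed = seed)
  structure(list(estimates = res$par, objective = res$value,
                 converged = res$converged,
                 n_obs = sum(obs$conc_ng_ml > 0), weighting = weighting,
                 trace = res$trace, kind = "deposition",
                 obs = obs, phys = phys, sys_fixed = sys_fixed,
                 engine = engine),
            class = "pbpk_fit")
}

#' @export
coef.pbpk_fit <- function(object, ...) object$estimates

#' @export
print.pbpk_fit <- function(x, ...) {
  cat(sprintf("PBPK %s fit (%s weighting, %d observations)\n",
              x$kind, x$weighting, x$n_obs))
  est <- x$estimates
  if (x$kind == "systemic") {
    cat(sprintf("  tlag %.4g h | ka %.4g /h | Vc %.4g L | CL %.4g L/h\n",
                est[["tlag"]], est[["ka"]], est[["Vc"]] / 1000,
                est[["CL"]] / 1000))
  } else {
    cat(sprintf("  F1 %.4g | F2 %.4g\n", est[["F1"]], est[["F2"]]))
  }
  cat(sprintf("  objective %.6g | converged: %s\n", x$objective,
              x$converged))
  invisible(x)
}

#' @export
summary.pbpk_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object, residuals = res,
              rmse = sqrt(mean(res^2)),
              max_abs_rel = max(abs(res / fitted_concs(object)$obs)))
  class(out) <- "summary.pbpk_fit"
  out
}

#' @export
print.summary.pbpk_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RMSE %.4g ng/mL | max |rel. residual| %.3g\n",
              x$rmse, x$max_abs_rel))
  invisible(x)
}

fitted_concs <- function(object) {
  obs <- object$obs
  keep <- obs$conc_ng_ml > 0
  pred <- predict(object, times = obs$time_h)
  list(times = obs$time_h[keep], obs = obs$conc_ng_ml[keep],
       pred = pred[keep])
}

#' Predict concentrations from a fit
#'
#' @param object a `pbpk_fit`.
#' @param times prediction times, h (default: the observation times).
#' @param ... unused.
#' @return Predicted plasma concentrations, ng/mL.
#' @export
predict.pbpk_fit <- function(object, times = object$obs$time_h, ...) {
  obs <- object$obs
  est <- object$estimates
  if (object$kind == "systemic") {
    sys <- systemic_params(tlag = est[["tlag"]], ka = est[["ka"]],
                           Vc = est[["Vc"]], CL = est[["CL"]], units = "mL")
    frac <- deposition_fractions()
  } else {
    sys <- object$sys_fixed
    frac <- deposition_fractions(F1 = est[["F1"]],
                                 F2 = min(est[["F2"]], 1 - est[["F1"]]),
                                 F3 = 0, F4 = 0, F5 = 0)
  }
  reg <- regimen(dose_event(0, attr(obs, "route"), attr(obs, "dose_ng")))
  grid <- sort(unique(c(0, times)))
  sim <- pbpk_simulate(object$phys, sys, frac, reg, grid = grid,
                       engine = object$engine)
  sim$conc$C_plasma[match(times, grid)]
}

#' @export
residuals.pbpk_fit <- function(object, ...) {
  f <- fitted_concs(object)
  f$obs - f$pred
}

#' @export
plot.pbpk_fit <- function(x, log = "", ...) {
  obs <- x$obs
  tt <- seq(0, max(obs$time_h), length.out = 200)[-1L]
  pred <- predict(x, times = tt)
  keep <- obs$conc_ng_ml > 0
  plot(obs$time_h[keep], obs$conc_ng_ml[keep], xlab = "time (h)",
       ylab = "plasma conc (ng/mL)", log = log, ...)
  lines(tt, pred)
  legend("topright", legend = c("observed", "fitted"), pch = c(1, NA),
         lty = c(NA, 1), bty = "n")
  invisible(x)
}
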