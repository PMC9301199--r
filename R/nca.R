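#' Linear trapezoidal AUC over a sub-interval
#'
#' Area under the concentration-time curve by the linear trapezoidal rule,
#' with linear interpolation at `t_start` / `t_end` when they fall between
#' grid nodes.  Linear (not log-down) trapezoids keep AUC exactly additive
#' over abutting intervals.
#'
#' @param times strictly increasing times, h.
#' @param conc concentrations, ng/mL (same length).
#' @param t_start,t_end integration bounds, h (must lie within the grid;
#'   `t_end > t_start`).
#' @return AUC, h*ng/mL.
#' @examples
#' auc_trapezoid(c(0, 1, 2), c(0, 2, 2), 0, 2)  # 3
#' @export
auc_trapezoid <- function(times, conc, t_start = min(times),
                          t_end = max(times)) {
  stopifnot(length(times) == length(conc), length(times) >= 2L,
            all(diff(times) > 0))
  if (t_end <= t_start) stop("t_end must exceed t_start")
  if (t_start < times[1L] || t_end > times[length(times)])
    stop("[t_start, t_end] must lie within the sampled interval")
  ## augment the grid with interpolated bounds
  tt <- sort(unique(c(times, t_start, t_end)))
  cc <- stats::approx(times, conc, xout = tt)$y
  keep <- tt >= t_start & tt <= t_end
  tt <- tt[keep]; cc <- cc[keep]
  sum(diff(tt) * (head(cc, -1L) + tail(cc, -1L)) / 2)
}

#' Terminal elimination rate constant
#'
#' Unweighted log-linear regression on the terminal points.  Candidate
#' windows are the last k = 3..6 positive concentrations strictly after
#' Tmax (the Cmax point itself is excluded); the window maximizing the
#' adjusted R-squared is chosen, ties resolved in favour of fewer points.
#'
#' @param times,conc the concentration-time series.
#' @return List with `lambda_z` (1/h), `n_points`, `adj_r2`.  Errors if
#'   fewer than 3 usable points or the fitted slope is not negative (e.g. a
#'   flat profile).
#' @examples
#' t <- c(4, 6, 8, 12, 24); lambda_z(t, 10 * exp(-0.1 * t))$lambda_z  # 0.1
#' @export
lambda_z <- function(times, conc) {
  stopifnot(length(times) == length(conc), all(diff(times) > 0))
  imax <- which.max(conc)
  usable <- which(seq_along(conc) > imax & conc > 0)
  if (length(usable) < 3L)
    stop("lambda_z requires at least 3 positive concentrations after Tmax")
  best <- NULL
  for (k in 3:min(6L, length(usable))) {
    idx <- tail(usable, k)
    fit <- lm(log(conc[idx]) ~ times[idx])
    slope <- coef(fit)[[2L]]
    ## noise-free simulated profiles fit exactly; the "essentially perfect
    ## fit" warning is expected, not a problem
    ar2 <- suppressWarnings(summary(fit)$adj.r.squared)
    if (!is.finite(ar2)) next  # degenerate (e.g. constant) window
    ## require a genuine decline, not rounding noise around a flat profile
    if (-slope * diff(range(times[idx])) < 1e-10) next
    if (slope < 0 && (is.null(best) || ar2 > best$adj_r2 + 1e-12))
      best <- list(lambda_z = -slope, n_points = k, adj_r2 = ar2)
  }
  if (is.null(best))
    stop("no terminal window with a negative log-linear slope")
  best
}

lambda_z_or_null <- function(times, conc) {
  tryCatch(lambda_z(times, conc), error = function(e) NULL)
}

new_nca_result <- function(fields) {
  template <- c("Cmax", "Tmax", "AUClast", "AUCinf", "AUC_tau",
                "AUC_pct_extrap", "lambda_z", "T_half", "CL_F", "V_F",
                "R_Cmax", "R_AUC")
  out <- setNames(rep(NA_real_, length(template)), template)
  out[names(fields)] <- unlist(fields)
  structure(as.list(out), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  v <- unlist(x)
  v <- v[!is.na(v)]
  cat("NCA:", paste(sprintf("%s=%.5g", names(v), v), collapse = "  "), "\n")
  invisible(x)
}

#' @export
as.data.frame.nca_result <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

#' Single-dose noncompartmental analysis
#'
#' Cmax/Tmax are read off the observation grid without interpolation.
#' `AUClast` runs to the last positive concentration; `AUCinf = AUClast +
#' Clast / lambda_z`; `AUC_tau` is the partial AUC over `[0, tau]`;
#' `CL_F = dose / AUCinf`; `V_F = CL_F / lambda_z`.  When no terminal
#' phase can be estimated, the lambda_z-dependent parameters are reported
#' as NA.
#'
#' @param times,conc single-dose concentration-time series starting at the
#'   dose time (t = 0).
#' @param dose administered dose, ng (device/administered amount, not the
#'   deposited fraction).
#' @param tau reporting interval for the partial AUC, h (default 12).
#' @return An `nca_result`.
#' @export
nca_single_dose <- function(times, conc, dose, tau = 12) {
  stopifnot(length(times) == length(conc), all(diff(times) > 0), dose >= 0)
  if (all(conc <= 0)) stop("no positive concentration: NCA undefined")
  imax <- which.max(conc)
  cmax <- conc[imax]; tmax <- times[imax]
  ilast <- max(which(conc > 0))
  auclast <- auc_trapezoid(times, conc, times[1L], times[ilast])
  auctau <- if (max(times) >= tau)
    auc_trapezoid(times, conc, times[1L], tau) else NA_real_

  lz <- lambda_z_or_null(times, conc)
  if (is.null(lz))
    return(new_nca_result(list(Cmax = cmax, Tmax = tmax, AUClast = auclast,
                               AUC_tau = auctau)))
  aucinf <- auclast + conc[ilast] / lz$lambda_z
  clf <- dose / aucinf
  new_nca_result(list(
    Cmax = cmax, Tmax = tmax, AUClast = auclast, AUCinf = aucinf,
    AUC_tau = auctau, AUC_pct_extrap = 100 * (aucinf - auclast) / aucinf,
    lambda_z = lz$lambda_z, T_half = log(2) / lz$lambda_z,
    CL_F = clf, V_F = clf / lz$lambda_z))
}

#' Multidose noncompartmental analysis
#'
#' Computes per-interval Cmax and partial AUC within the first dosing
#' interval `[t1, t1 + tau]` and the final-dose interval `[tN, tN + tau]`,
#' and the accumulation ratios `R_Cmax` and `R_AUC` (final/first).  The
#' terminal slope is estimated from the washout after the final dose;
#' `CL_F` and `V_F` are per-dose apparent values at the final interval
#' (`dose / AUC_tau,final`).
#'
#' @param times,conc the multidose series.
#' @param reg the [regimen()] that produced it (supplies dose times and
#'   `tau`).
#' @param dose per-administration dose, ng.
#' @return An `nca_result` (`Cmax`/`Tmax`/`AUC_tau` refer to the final
#'   interval; `AUClast`/`AUCinf` to the full series).
#' @export
nca_multidose <- function(times, conc, reg, dose) {
  stopifnot(inherits(reg, "regimen"), length(times) == length(conc),
            all(diff(times) > 0))
  if (length(reg$events) < 1L) stop("regimen holds no dose")
  tau <- reg$tau
  ev_times <- vapply(reg$events, `[[`, 0, "time")
  t1 <- min(ev_times); tn <- max(ev_times)
  if (times[1L] > t1 || max(times) < tn + tau)
    stop("series must cover the first and final dosing intervals")

  interval_metrics <- function(a, b) {
    sel <- times >= a & times <= b
    list(cmax = max(conc[sel]),
         tmax = times[sel][which.max(conc[sel])] - a,
         auc = auc_trapezoid(times, conc, a, b))
  }
  first <- interval_metrics(t1, t1 + tau)
  final <- interval_metrics(tn, tn + tau)

  wash <- times > tn
  lz <- lambda_z_or_null(times[wash], conc[wash])

  res <- list(Cmax = final$cmax, Tmax = final$tmax, AUC_tau = final$auc,
              AUClast = auc_trapezoid(times, conc, times[1L],
                                      times[max(which(conc > 0))]),
              R_Cmax = final$cmax / first$cmax,
              R_AUC = final$auc / first$auc)
  if (!is.null(lz)) {
    ilast <- max(which(conc > 0))
    res$lambda_z <- lz$lambda_z
    res$T_half <- log(2) / lz$lambda_z
    res$AUCinf <- res$AUClast + conc[ilast] / lz$lambda_z
    res$CL_F <- dose / final$auc
    res$V_F <- res$CL_F / lz$lambda_z
  }
  new_nca_result(res)
}

#' Time to steady state from trough concentrations
#'
#' Under repeated dosing, the morning pre-dose trough rises towards its
#' steady-state plateau.  Returns the first dosing day whose morning
#' pre-dose trough reaches `threshold` times the final morning trough.
#' Troughs are read (by linear interpolation) at 24-h marks from the first
#' dose, i.e. day d's morning trough is the concentration just before the
#' dose at `t1 + 24 * (d - 1)`.
#'
#' @param times,conc the multidose series.
#' @param reg the [regimen()].
#' @param threshold fraction of the final trough regarded as at steady
#'   state (default 0.95).
#' @return Integer day index (day 1 = first dosing day).
#' @export
time_to_steady_state <- function(times, conc, reg, threshold = 0.95) {
  stopifnot(inherits(reg, "regimen"), threshold >= 0, threshold <= 1)
  ev_times <- sort(vapply(reg$events, `[[`, 0, "time"))
  t1 <- ev_times[1L]
  trough_days <- unique(floor((ev_times - t1) / 24)) + 1L
  if (length(trough_days) < 2L)
    stop("need at least 2 dosing days to extract troughs")
  trough_t <- t1 + 24 * (trough_days - 1L)
  trough_t <- trough_t[trough_t <= max(times)]
  if (length(trough_t) < 2L) stop("fewer than 2 troughs covered by the series")
  trough_days <- trough_days[seq_along(trough_t)]
  troughs <- stats::approx(times, conc, xout = trough_t)$y
  ref <- troughs[length(troughs)]
  if (ref <= 0) stop("final trough is not positive")
  qualifying <- which(troughs >= threshold * ref)
  if (!length(qualifying)) stop("no trough reaches the threshold")
  as.integer(trough_days[qualifying[1L]])
}

#' NCA of a simulated profile
#'
#' Convenience wrapper running [nca_single_dose()] or [nca_multidose()]
#' (chosen by the number of dose events) on the plasma or nasal-tissue
#' concentration series of a [pbpk_simulate()] result.  The dose used for
#' `CL_F`/`V_F` is the administered device dose per administration.
#'
#' @param sim a `pbpk_sim`.
#' @param which `"plasma"` or `"nasal"` series.
#' @return An `nca_result`.
#' @export
nca <- function(sim, which = c("plasma", "nasal")) {
  which <- match.arg(which)
  stopifnot(inherits(sim, "pbpk_sim"))
  conc <- if (which == "plasma") sim$conc$C_plasma else sim$conc$C_nasal
  n_ev <- length(sim$regimen$events)
  if (n_ev == 0L) stop("undosed simulation")
  dose <- sum(vapply(sim$regimen$events, `[[`, 0, "amount")) / n_ev
  if (n_ev == 1L) {
    t0 <- sim$regimen$events[[1L]]$time
    sel <- sim$time >= t0
    nca_single_dose(sim$time[sel] - t0, conc[sel], dose,
                    tau = sim$regimen$tau)
  } else {
    nca_multidose(sim$time, conc, sim$regimen, dose)
  }
}
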