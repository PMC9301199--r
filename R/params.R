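#' Systemic disposition parameters
#'
#' First-order gastrointestinal absorption with lag, one central compartment
#' with linear clearance.  Peripheral exchange rate constants are carried
#' for completeness but fixed at 0 in this model.
#'
#' @param tlag absorption lag time, h (>= 0).
#' @param ka first-order absorption rate constant, 1/h (> 0).
#' @param Vc central volume of distribution (units per `units`, > 0).
#' @param CL systemic clearance (units per `units`, > 0).
#' @param k12,k21,k13,k31 peripheral exchange rate constants, 1/h
#'   (default 0; the simulator requires 0).
#' @param units `"L"` (default): `Vc` in L and `CL` in L/h, converted to the
#'   internal mL / mL/h; `"mL"`: already internal units.
#' @return An object of class `systemic_params` with `Vc` in mL and `CL`
#'   in mL/h.
#' @examples
#' us_systemic_params()
#' @export
systemic_params <- function(tlag, ka, Vc, CL,
                            k12 = 0, k21 = 0, k13 = 0, k31 = 0,
                            units = c("L", "mL")) {
  units <- match.arg(units)
  f <- if (units == "L") 1000 else 1
  p <- list(tlag = tlag, ka = ka, Vc = Vc * f, CL = CL * f,
            k12 = k12, k21 = k21, k13 = k13, k31 = k31)
  validate_systemic(p)
  structure(p, class = "systemic_params")
}

validate_systemic <- function(p) {
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num1(p$tlag) || p$tlag < 0) stop("tlag must be >= 0")
  for (nm in c("ka", "Vc", "CL"))
    if (!num1(p[[nm]]) || p[[nm]] <= 0) stop("'", nm, "' must be > 0")
  for (nm in c("k12", "k21", "k13", "k31"))
    if (!num1(p[[nm]]) || p[[nm]] < 0) stop("'", nm, "' must be >= 0")
  invisible(p)
}

#' @export
print.systemic_params <- function(x, ...) {
  cat(sprintf(
    "Systemic parameters: tlag %.3f h, ka %.3f /h, Vc %.3f L, CL %.3f L/h\n",
    x$tlag, x$ka, x$Vc / 1000, x$CL / 1000))
  if (any(unlist(x[c("k12", "k21", "k13", "k31")]) != 0))
    cat(sprintf("  peripheral: k12 %.3g k21 %.3g k13 %.3g k31 %.3g /h\n",
                x$k12, x$k21, x$k13, x$k31))
  invisible(x)
}

#' @rdname systemic_params
#' @details `us_systemic_params()` and `cn_systemic_params()` return the
#'   fitted oral varenicline disposition parameters for the American
#'   (tlag 0.371 h, ka 1.036 /h, Vc 194.352 L, CL 10.001 L/h) and Chinese
#'   (tlag 0.156 h, ka 1.064 /h, Vc 190.823 L, CL 11.320 L/h) reference
#'   populations.
#' @export
us_systemic_params <- function() {
  systemic_params(tlag = 0.371, ka = 1.036, Vc = 194.352, CL = 10.001)
}

#' @rdname systemic_params
#' @export
cn_systemic_params <- function() {
  systemic_params(tlag = 0.156, ka = 1.064, Vc = 190.823, CL = 11.320)
}

#' Intranasal deposition fractions
#'
#' Split of an intranasal spray dose among the absorbing surfaces: F1 nasal
#' ELF, F2 pharynx (swallowed immediately), F3 bronchial ELF, F4
#' bronchiolar ELF, F5 alveolar ELF.  The remainder `1 - sum(F)` lands on
#' the non-absorbing nasal vestibule and is never absorbed.  Defaults are
#' the fitted varenicline nasal-spray values (F1 = 0.547,
#' F2 = 7.6375e-7, F3 = F4 = F5 = 0: spray droplets are too large to reach
#' the lower airways).
#'
#' @param F1,F2,F3,F4,F5 fractions in \[0, 1\] with `sum <= 1`.
#' @return An object of class `deposition_fractions`.
#' @export
deposition_fractions <- function(F1 = 0.547, F2 = 7.6375e-7,
                                 F3 = 0, F4 = 0, F5 = 0) {
  f <- c(F1 = F1, F2 = F2, F3 = F3, F4 = F4, F5 = F5)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("deposition fractions must lie in [0, 1]")
  if (sum(f) > 1 + 1e-12)
    stop("deposition fractions must sum to at most 1 (remainder = vestibule)")
  structure(as.list(f), class = "deposition_fractions")
}

#' @export
print.deposition_fractions <- function(x, ...) {
  f <- unlist(x)
  cat("Deposition fractions:",
      paste(sprintf("%s=%.4g", names(f), f), collapse = " "),
      sprintf("| vestibule %.4g\n", 1 - sum(f)))
  invisible(x)
}

#' Dosing events and regimens
#'
#' `dose_event()` is a single administration; `regimen()` an ordered series
#' of events with a reporting interval `tau` (h).  `single_dose_regimen()`
#' and `bid_regimen()` are the two canonical schedules: one dose at t = 0,
#' and twice-daily dosing for `days` consecutive days with a single morning
#' dose on the final day (the label regimen: doses at 0, 12, ..., and one
#' at 24*(days-1) h).
#'
#' @param time_h administration time, h (>= 0).
#' @param route `"intranasal"` or `"oral"`.
#' @param amount_ng dose amount, ng (>= 0).
#' @return `dose_event()`: a `dose_event`; the others: a `regimen` (list
#'   with `events`, `tau`).
#' @export
dose_event <- function(time_h, route = c("intranasal", "oral"), amount_ng) {
  route <- match.arg(route)
  if (!is.finite(time_h) || time_h < 0) stop("event time must be >= 0")
  if (!is.finite(amount_ng) || amount_ng < 0) stop("dose amount must be >= 0")
  structure(list(time = time_h, route = route, amount = amount_ng),
            class = "dose_event")
}

#' @rdname dose_event
#' @param events list of `dose_event`s (sorted by time on construction).
#' @param tau reporting dose interval, h (> 0; default 12).
#' @export
regimen <- function(events, tau = 12) {
  if (!length(events)) {
    events <- list()
  } else {
    if (inherits(events, "dose_event")) events <- list(events)
    stopifnot(all(vapply(events, inherits, TRUE, "dose_event")))
    events <- events[order(vapply(events, `[[`, 0, "time"))]
  }
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  structure(list(events = events, tau = tau), class = "regimen")
}

#' @rdname dose_event
#' @param dose_mg dose per administration, mg.
#' @export
single_dose_regimen <- function(dose_mg, route = c("intranasal", "oral"),
                                tau = 12) {
  route <- match.arg(route)
  regimen(dose_event(0, route, dose_mg * 1e6), tau = tau)
}

#' @rdname dose_event
#' @param days number of consecutive dosing days (final day: one dose).
#' @export
bid_regimen <- function(dose_mg = 0.06, route = c("intranasal", "oral"),
                        days = 7, tau = 12) {
  route <- match.arg(route)
  if (days < 1) stop("days must be >= 1")
  times <- if (days == 1) 0 else
    c(seq(0, (days - 1) * 24 - 12, by = 12), (days - 1) * 24)
  regimen(lapply(times, dose_event, route = route, amount_ng = dose_mg * 1e6),
          tau = tau)
}

#' @export
print.regimen <- function(x, ...) {
  n <- length(x$events)
  if (!n) {
    cat("Empty regimen\n"); return(invisible(x))
  }
  amt <- vapply(x$events, `[[`, 0, "amount")
  tms <- vapply(x$events, `[[`, 0, "time")
  rts <- vapply(x$events, `[[`, "", "route")
  cat(sprintf("Regimen: %d dose(s), tau = %g h\n", n, x$tau))
  cat(sprintf("  %s %.4g mg at t = %s h\n", paste(unique(rts), collapse = "/"),
              sum(amt) / n / 1e6,
              paste(format(tms, trim = TRUE), collapse = ", ")))
  invisible(x)
}

## observation offsets within a dosing interval and during washout
.GRID_INTERVAL <- c(0, 0.08, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 12)
.GRID_WASHOUT  <- c(16, 24, 36, 48, 72)

#' Default observation grid for a regimen
#'
#' The clinical-style sampling grid: within each dosing interval the
#' offsets 0, 0.08, 0.25, 0.5, 1, 2, 3, 4, 6, 8, 12 h post dose, and after
#' the final dose additionally 16, 24, 36, 48 h up to `washout_h`.
#'
#' @param reg a [regimen()].
#' @param washout_h follow-up after the final dose, h (default 72).
#' @return Strictly increasing numeric vector of times, h.
#' @export
sampling_grid <- function(reg, washout_h = 72) {
  stopifnot(inherits(reg, "regimen"))
  if (!length(reg$events)) return(seq(0, washout_h, length.out = 25))
  tms <- vapply(reg$events, `[[`, 0, "time")
  grid <- unlist(lapply(tms, function(t0) t0 + .GRID_INTERVAL))
  last <- max(tms)
  wash <- .GRID_WASHOUT[.GRID_WASHOUT <= washout_h]
  if (washout_h > max(.GRID_INTERVAL))
    grid <- c(grid, last + unique(c(wash, washout_h)))
  sort(unique(grid))
}
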