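## state ordering shared with src/pbpk.c
.STATES <- c("ELF_Nose", "ELF_BB", "ELF_bb", "ELF_AL",
             "TIS_Nose", "TIS_BB", "TIS_bb", "TIS_AL",
             "GI", "CENTRAL", "ELIM", "UNABS", "DEPOT")

#' Empty model state
#'
#' Named zero amount vector over the model compartments: ELF and tissue
#' for each respiratory segment (Nose, BB, bb, AL), the GI depot, the
#' central compartment, the cumulative eliminated and unabsorbed pools,
#' and the oral pre-absorption holding depot.
#'
#' @return Named numeric vector of zeros, ng.
#' @export
zero_state <- function() {
  structure(numeric(length(.STATES)), names = .STATES)
}

## parameter vector for the compiled derivative (order fixed in pbpk.c)
pbpk_parms <- function(phys, sys) {
  c(phys$PS[.SEGMENTS], phys$V_ELF[.SEGMENTS], phys$V_tissue[.SEGMENTS],
    phys$fu_ELF, phys$fu_tissue, phys$fu_p,
    phys$kmcc_bb, phys$kmcc_BB,
    phys$FA, sys$ka, sys$Vc, sys$CL)
}

#' Model right-hand side (reference R implementation)
#'
#' Time derivative of the amount state vector.  Epithelial lining fluid
#' (ELF) drug permeates one-way into the segment tissue; tissue exchanges
#' two-way with the central compartment along the free-concentration
#' gradient `fu_tissue * C_tissue - fu_p * C_plasma` with the same PS;
#' mucociliary clearance sweeps bb-ELF to BB-ELF and BB-ELF to the pharynx
#' where it is swallowed into the GI depot; GI drug is absorbed first-order
#' (fraction `FA` reaching plasma) and plasma is cleared linearly.  The
#' system is closed: the components of the derivative sum to zero.
#'
#' The simulator uses an equivalent compiled version of this function; this
#' R implementation is the readable reference (and is available via
#' `pbpk_simulate(..., engine = "R")`).
#'
#' @param state named amount vector (ng) over the model compartments (see
#'   [zero_state()] for the layout).
#' @param t time, h (unused: the system is autonomous).
#' @param phys a [build_physiology()] object.
#' @param sys a [systemic_params()] object.
#' @return Named derivative vector, ng/h.
#' @export
pbpk_rhs <- function(state, t = 0, phys, sys) {
  s <- state[.STATES]
  cp <- s[["CENTRAL"]] / sys$Vc
  d <- zero_state()
  net_to_plasma <- 0
  for (x in .SEGMENTS) {
    elf <- paste0("ELF_", x); tis <- paste0("TIS_", x)
    celf <- s[[elf]] / phys$V_ELF[[x]]
    ctis <- s[[tis]] / phys$V_tissue[[x]]
    perm_in <- phys$PS[[x]] * phys$fu_ELF * celf
    perm_out <- phys$PS[[x]] * (phys$fu_tissue * ctis - phys$fu_p * cp)
    d[elf] <- d[elf] - perm_in
    d[tis] <- d[tis] + perm_in - perm_out
    net_to_plasma <- net_to_plasma + perm_out
  }
  d["ELF_bb"] <- d["ELF_bb"] - phys$kmcc_bb * s[["ELF_bb"]]
  d["ELF_BB"] <- d["ELF_BB"] + phys$kmcc_bb * s[["ELF_bb"]] -
    phys$kmcc_BB * s[["ELF_BB"]]
  d["GI"] <- phys$kmcc_BB * s[["ELF_BB"]] - sys$ka * s[["GI"]]
  d["CENTRAL"] <- phys$FA * sys$ka * s[["GI"]] + net_to_plasma - sys$CL * cp
  d["ELIM"] <- sys$CL * cp
  d["UNABS"] <- (1 - phys$FA) * sys$ka * s[["GI"]]
  d
}

#' Apply a dose to a state vector
#'
#' Intranasal doses are split by the deposition fractions: `F1 * amount`
#' into nasal ELF, `F2 * amount` swallowed straight into the GI depot
#' (pharynx), `F3/F4/F5 * amount` into bronchial/bronchiolar/alveolar ELF,
#' and the residual `(1 - sum(F)) * amount` booked to the cumulative
#' unabsorbed pool (nasal vestibule).  Oral doses are added in full to the
#' GI depot; the absorption lag is a scheduling concern handled by
#' [pbpk_simulate()], which holds oral doses in a pre-absorption depot
#' until `time + tlag`.
#'
#' @param state named amount vector (ng).
#' @param event a [dose_event()].
#' @param frac a [deposition_fractions()] object.
#' @param phys a physiology object (unused; kept for interface symmetry).
#' @return The updated state vector.
#' @export
apply_dose <- function(state, event, frac, phys = NULL) {
  stopifnot(inherits(event, "dose_event"),
            inherits(frac, "deposition_fractions"))
  a <- event$amount
  if (event$route == "oral") {
    state["GI"] <- state["GI"] + a
  } else {
    state["ELF_Nose"] <- state["ELF_Nose"] + a * frac$F1
    state["GI"]       <- state["GI"]       + a * frac$F2
    state["ELF_BB"]   <- state["ELF_BB"]   + a * frac$F3
    state["ELF_bb"]   <- state["ELF_bb"]   + a * frac$F4
    state["ELF_AL"]   <- state["ELF_AL"]   + a * frac$F5
    state["UNABS"]    <- state["UNABS"] +
      a * (1 - (frac$F1 + frac$F2 + frac$F3 + frac$F4 + frac$F5))
  }
  state
}

## expand regimen into deSolve "add" events; oral doses pass through a
## holding depot so that mass balance holds during the absorption lag
build_events <- function(reg, frac, tlag, t0) {
  rows <- list()
  add <- function(var, time, value) {
    rows[[length(rows) + 1L]] <<- data.frame(var = var, time = time,
                                             value = value, method = "add")
  }
  for (ev in reg$events) {
    if (ev$time < t0) stop("dose event precedes the simulation grid")
    a <- ev$amount
    if (a == 0) next
    if (ev$route == "oral") {
      if (tlag > 0) {
        add("DEPOT", ev$time, a)
        add("DEPOT", ev$time + tlag, -a)
        add("GI", ev$time + tlag, a)
      } else add("GI", ev$time, a)
    } else {
      fs <- c(ELF_Nose = frac$F1, GI = frac$F2, ELF_BB = frac$F3,
              ELF_bb = frac$F4, ELF_AL = frac$F5,
              UNABS = 1 - (frac$F1 + frac$F2 + frac$F3 + frac$F4 + frac$F5))
      for (v in names(fs)) if (fs[[v]] > 0) add(v, ev$time, a * fs[[v]])
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Simulate the respiratory-tract PBPK model
#'
#' Integrates the model ODEs over a time grid with dose discontinuities
#' applied as events (with a hard integrator restart at each event).  Oral
#' doses enter the GI depot at `time + tlag`; during the lag the amount sits
#' in a pre-absorption holding state so mass balance holds at all times.
#'
#' @param phys a [build_physiology()] object.
#' @param sys a [systemic_params()] object (peripheral rate constants must
#'   be 0).
#' @param frac a [deposition_fractions()] object.
#' @param reg a [regimen()].
#' @param grid strictly increasing observation times, h; default
#'   [sampling_grid()] of the regimen.
#' @param rtol,atol integrator tolerances (relative; absolute in ng).
#' @param engine `"compiled"` (C right-hand side; default) or `"R"`
#'   (reference implementation, slower).
#' @return An object of class `pbpk_sim`: list with `time` (h), `states`
#'   (matrix of amounts, ng), `conc` (data frame: `time_h`,
#'   `C_plasma` = central amount / Vc, `C_nasal` = nasal tissue amount /
#'   nasal tissue volume, ng/mL, clipped at 0), `dosed_cum` (cumulative
#'   administered amount at each time, ng), `dose_admin` (totals per
#'   route), and the inputs.
#' @examples
#' phys <- build_physiology()
#' sim <- pbpk_simulate(phys, us_systemic_params(), deposition_fractions(),
#'                      single_dose_regimen(0.12, "intranasal"))
#' head(sim$conc)
#' @export
pbpk_simulate <- function(phys, sys, frac, reg, grid = NULL,
                          rtol = 1e-8, atol = 1e-6,
                          engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(phys, "physiology"), inherits(sys, "systemic_params"),
            inherits(frac, "deposition_fractions"), inherits(reg, "regimen"))
  if (any(unlist(sys[c("k12", "k21", "k13", "k31")]) != 0))
    stop("peripheral exchange is not part of this model; k12/k21/k13/k31 must be 0")
  if (is.null(grid)) grid <- sampling_grid(reg)
  if (length(grid) < 2L || any(diff(grid) <= 0))
    stop("grid must be strictly increasing with at least two points")

  y0 <- zero_state()
  ev <- build_events(reg, frac, sys$tlag, grid[1])

  ## events landing exactly at the grid start are applied to y0 directly
  if (!is.null(ev)) {
    at0 <- ev$time == grid[1]
    if (any(at0)) {
      for (i in which(at0)) y0[ev$var[i]] <- y0[ev$var[i]] + ev$value[i]
      ev <- ev[!at0, , drop = FALSE]
      if (!nrow(ev)) ev <- NULL
    }
  }
  if (!is.null(ev) && any(ev$time > max(grid)))
    stop("dose (or lagged GI arrival) falls beyond the simulation grid")

  times <- sort(unique(c(grid, if (!is.null(ev)) ev$time)))
  parms <- pbpk_parms(phys, sys)

  out <- if (engine == "compiled") {
    deSolve::ode(y = y0, times = times, func = "pbpk_derivs", parms = parms,
                 dllname = "nasalpbpk", initfunc = "pbpk_initmod",
                 events = if (!is.null(ev)) list(data = ev),
                 method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = 50000)
  } else {
    rhs_r <- function(t, y, p) list(unname(pbpk_rhs(y, t, phys, sys)))
    deSolve::ode(y = y0, times = times, func = rhs_r, parms = NULL,
                 events = if (!is.null(ev)) list(data = ev),
                 method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = 50000)
  }
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1L] < 0)
    stop("ODE integration failed (istate = ", attr(out, "istate")[1L], ")")

  keep <- match(grid, out[, 1L])
  states <- out[keep, -1L, drop = FALSE]
  colnames(states) <- .STATES
  rownames(states) <- NULL

  total_dose <- if (length(reg$events))
    sum(vapply(reg$events, `[[`, 0, "amount")) else 0
  neg_tol <- 100 * atol + 1e-9 * max(total_dose, 1)
  if (min(states) < -neg_tol)
    stop("negative compartment amount beyond integrator tolerance: ",
         format(min(states)))

  ## the reported state at a dose time is pre-event (deSolve convention);
  ## doses folded into y0 at the grid start are the one exception
  ev_times <- if (length(reg$events))
    vapply(reg$events, `[[`, 0, "time") else numeric(0)
  ev_amts <- if (length(reg$events))
    vapply(reg$events, `[[`, 0, "amount") else numeric(0)
  dosed_cum <- vapply(grid, function(t)
    sum(ev_amts[ev_times < t | ev_times == grid[1L]]), 0)

  routes <- vapply(reg$events, `[[`, "", "route")
  dose_admin <- c(intranasal = sum(ev_amts[routes == "intranasal"]),
                  oral = sum(ev_amts[routes == "oral"]))

  conc <- data.frame(
    time_h = grid,
    C_plasma = pmax(states[, "CENTRAL"] / sys$Vc, 0),
    C_nasal = pmax(states[, "TIS_Nose"] / phys$V_tissue[["Nose"]], 0))

  structure(list(time = grid, states = states, conc = conc,
                 dosed_cum = dosed_cum, dose_admin = dose_admin,
                 phys = phys, sys = sys, frac = frac, regimen = reg),
            class = "pbpk_sim")
}

#' Mass-balance error of a simulation
#'
#' Maximum relative deviation, over the grid, of the summed compartment
#' amounts (including cumulative eliminated and unabsorbed pools) from the
#' cumulative administered dose.
#'
#' @param sim a `pbpk_sim`.
#' @return Scalar relative error (0 for an undosed simulation).
#' @export
mass_balance <- function(sim) {
  stopifnot(inherits(sim, "pbpk_sim"))
  total <- sum(sim$dose_admin)
  if (total == 0) return(0)
  max(abs(rowSums(sim$states) - sim$dosed_cum)) / total
}

#' Superposition (linearity) audit
#'
#' For a multidose regimen that is a train of time-shifted copies of a
#' single-dose regimen, the simulated multidose concentration profile must
#' equal the sum of shifted single-dose profiles (the model is linear and
#' time-invariant).  Returns the maximum absolute deviation relative to the
#' multidose Cmax.
#'
#' @param phys,sys,frac,single,multi model inputs; `single` must hold
#'   exactly one dose event and every event of `multi` must be a copy of it
#'   (same route and amount).
#' @param grid observation grid for the multidose profile (default
#'   [sampling_grid()]).
#' @param ... passed to [pbpk_simulate()].
#' @return Maximum relative deviation of the plasma profile.
#' @export
superpose_check <- function(phys, sys, frac, single, multi, grid = NULL, ...) {
  stopifnot(inherits(single, "regimen"), inherits(multi, "regimen"),
            length(single$events) == 1L)
  e1 <- single$events[[1L]]
  for (ev in multi$events)
    if (ev$route != e1$route || ev$amount != e1$amount)
      stop("multi must be a train of time-shifted copies of single's dose")
  if (is.null(grid)) grid <- sampling_grid(multi)
  sim_m <- pbpk_simulate(phys, sys, frac, multi, grid = grid, ...)

  shifts <- vapply(multi$events, `[[`, 0, "time") - e1$time
  offsets <- sort(unique(round(unlist(
    lapply(shifts, function(s) grid[grid >= s + e1$time] - s)), 10)))
  sim_1 <- pbpk_simulate(phys, sys, frac, single, grid = offsets, ...)

  csum <- numeric(length(grid))
  for (s in shifts) {
    idx <- match(round(grid - s, 10), round(offsets, 10))
    ok <- !is.na(idx) & (grid - s) >= e1$time
    csum[ok] <- csum[ok] + sim_1$conc$C_plasma[idx[ok]]
  }
  cmax <- max(sim_m$conc$C_plasma)
  if (cmax == 0) return(0)
  max(abs(sim_m$conc$C_plasma - csum)) / cmax
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf(
    "PBPK simulation: %d times over [%g, %g] h, dose %g ng (%s)\n",
    length(x$time), min(x$time), max(x$time), sum(x$dose_admin),
    paste(names(x$dose_admin)[x$dose_admin > 0], collapse = "+")))
  cat(sprintf("  plasma Cmax %.4g ng/mL at %g h; nasal Cmax %.4g ng/mL at %g h\n",
              max(x$conc$C_plasma), x$time[which.max(x$conc$C_plasma)],
              max(x$conc$C_nasal), x$time[which.max(x$conc$C_nasal)]))
  cat(sprintf("  mass-balance error %.3g\n", mass_balance(x)))
  invisible(x)
}

#' @export
plot.pbpk_sim <- function(x, which = c("both", "plasma", "nasal"),
                          log = "", ...) {
  which <- match.arg(which)
  cp <- x$conc$C_plasma; cn <- x$conc$C_nasal
  if (which == "plasma") {
    plot(x$time, cp, type = "l", xlab = "time (h)",
         ylab = "plasma conc (ng/mL)", log = log, ...)
  } else if (which == "nasal") {
    plot(x$time, cn, type = "l", xlab = "time (h)",
         ylab = "nasal tissue conc (ng/mL)", log = log, ...)
  } else {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    plot(x$time, cp, type = "l", xlab = "time (h)",
         ylab = "plasma (ng/mL)", log = log, ...)
    plot(x$time, cn, type = "l", xlab = "time (h)",
         ylab = "nasal tissue (ng/mL)", log = log, ...)
  }
  invisible(x)
}

#' Tidy export of a simulation
#'
#' @param x a `pbpk_sim`.
#' @param ... unused.
#' @return Long data frame: `time_h`, `compartment`, `amount_ng`,
#'   `conc_ng_per_ml` (NA where the compartment has no defined volume).
#' @export
as.data.frame.pbpk_sim <- function(x, ...) {
  vols <- c(ELF_Nose = x$phys$V_ELF[["Nose"]], ELF_BB = x$phys$V_ELF[["BB"]],
            ELF_bb = x$phys$V_ELF[["bb"]], ELF_AL = x$phys$V_ELF[["AL"]],
            TIS_Nose = x$phys$V_tissue[["Nose"]],
            TIS_BB = x$phys$V_tissue[["BB"]],
            TIS_bb = x$phys$V_tissue[["bb"]],
            TIS_AL = x$phys$V_tissue[["AL"]],
            GI = NA, CENTRAL = x$sys$Vc, ELIM = NA, UNABS = NA, DEPOT = NA)
  do.call(rbind, lapply(.STATES, function(cmp) {
    data.frame(time_h = x$time, compartment = cmp,
               amount_ng = x$states[, cmp],
               conc_ng_per_ml = x$states[, cmp] / vols[[cmp]])
  }))
}
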