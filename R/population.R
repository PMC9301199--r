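#' Virtual-population specification
#'
#' Inter-individual variability on clearance and central volume only,
#' lognormally distributed and independent, with coefficient of variation
#' on the natural scale (default 38%).  The lognormal is parameterized so
#' that the population MEAN equals the typical value (`mu = -sigma^2/2`
#' on the log scale, `sigma^2 = log(1 + CV^2)`); see the methods vignette
#' for why mean-centring (rather than median-centring) matches the
#' reported population summaries.
#'
#' @param n number of virtual subjects (>= 1).
#' @param cv_CL,cv_Vc coefficients of variation (default 0.38).
#' @param seed RNG seed (default 20220707).
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n, cv_CL = 0.38, cv_Vc = 0.38,
                            seed = 20220707) {
  stopifnot(n >= 1, cv_CL >= 0, cv_Vc >= 0)
  structure(list(n = as.integer(n), cv_CL = cv_CL, cv_Vc = cv_Vc,
                 distribution = "lognormal", seed = as.integer(seed)),
            class = "population_spec")
}

#' Draw virtual subjects
#'
#' `CL_i = CL * exp(eta_1 - sigma_CL^2/2)`, `Vc_i = Vc * exp(eta_2 -
#' sigma_Vc^2/2)` with `eta ~ N(0, sigma^2)`, `sigma^2 = log(1 + CV^2)`,
#' independent across parameters and subjects; `tlag` and `ka` are copied
#' from the typical subject.  Deterministic given the spec's seed.
#'
#' @param typ typical-subject [systemic_params()].
#' @param spec a [population_spec()].
#' @return List of `n` [systemic_params()] objects.
#' @export
sample_subjects <- function(typ, spec) {
  stopifnot(inherits(typ, "systemic_params"),
            inherits(spec, "population_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$seed)
  s2_cl <- log(1 + spec$cv_CL^2)
  s2_vc <- log(1 + spec$cv_Vc^2)
  cl <- typ$CL * exp(rnorm(spec$n, -s2_cl / 2, sqrt(s2_cl)))
  vc <- typ$Vc * exp(rnorm(spec$n, -s2_vc / 2, sqrt(s2_vc)))
  lapply(seq_len(spec$n), function(i)
    systemic_params(tlag = typ$tlag, ka = typ$ka, Vc = vc[i], CL = cl[i],
                    units = "mL"))
}

#' Monte-Carlo population simulation
#'
#' Simulates every virtual subject, runs per-subject NCA on the plasma and
#' nasal-tissue series, and accumulates the population mean concentration
#' profile.  Reproducible by seed.
#'
#' @param typ typical [systemic_params()].
#' @param spec a [population_spec()].
#' @param phys,frac,reg,grid simulation inputs (see [pbpk_simulate()]).
#' @param keep_sims keep the per-subject `pbpk_sim` objects (memory-heavy
#'   for large n; default FALSE).
#' @param do_nca run per-subject NCA (default TRUE; disable for large-n
#'   runs where only the mean profile is of interest).
#' @return An object of class `pbpk_popsim`: list with `subjects`,
#'   `nca_plasma` / `nca_nasal` (lists of `nca_result`), `mean_profile`
#'   (data frame `time_h`, `C_plasma`, `C_nasal`), `typical` (the
#'   typical-subject `pbpk_sim`), `spec`, `regimen`, and optionally
#'   `sims`.
#' @export
popsim <- function(typ, spec, phys, frac, reg, grid = NULL,
                   keep_sims = FALSE, do_nca = TRUE) {
  if (is.null(grid)) grid <- sampling_grid(reg)
  subjects <- sample_subjects(typ, spec)
  mean_cp <- numeric(length(grid))
  mean_cn <- numeric(length(grid))
  nca_p <- vector("list", spec$n)
  nca_n <- vector("list", spec$n)
  sims <- if (keep_sims) vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    sim <- tryCatch(
      pbpk_simulate(phys, subjects[[i]], frac, reg, grid = grid),
      error = function(e) stop("subject ", i, ": ", conditionMessage(e)))
    mean_cp <- mean_cp + sim$conc$C_plasma
    mean_cn <- mean_cn + sim$conc$C_nasal
    if (do_nca) {
      nca_p[[i]] <- nca(sim, "plasma")
      nca_n[[i]] <- nca(sim, "nasal")
    }
    if (keep_sims) sims[[i]] <- sim
  }
  typical <- pbpk_simulate(phys, typ, frac, reg, grid = grid)
  structure(list(subjects = subjects,
                 nca_plasma = nca_p, nca_nasal = nca_n,
                 mean_profile = data.frame(time_h = grid,
                                           C_plasma = mean_cp / spec$n,
                                           C_nasal = mean_cn / spec$n),
                 typical = typical, spec = spec, regimen = reg,
                 phys = phys, frac = frac, sims = sims),
            class = "pbpk_popsim")
}

#' @export
print.pbpk_popsim <- function(x, ...) {
  cat(sprintf("Population simulation: n = %d (seed %d, CV CL %.0f%% / Vc %.0f%%)\n",
              x$spec$n, x$spec$seed, 100 * x$spec$cv_CL, 100 * x$spec$cv_Vc))
  print(summarize_nca(x$nca_plasma))
  invisible(x)
}

#' Summarize per-subject NCA results
#'
#' Arithmetic mean, SD (n - 1 denominator) and CV% for each NCA parameter;
#' median/min/max for Tmax (which is supported on the observation grid).
#'
#' @param ncas non-empty list of `nca_result`s.
#' @return An object of class `population_summary`: data frame with
#'   columns `parameter`, `mean`, `sd`, `cv_pct`, `median`, `min`, `max`
#'   and attribute `n`.
#' @export
summarize_nca <- function(ncas) {
  if (!length(ncas)) stop("empty NCA list")
  stopifnot(all(vapply(ncas, inherits, TRUE, "nca_result")))
  params <- names(unclass(ncas[[1L]]))
  rows <- lapply(params, function(p) {
    v <- vapply(ncas, function(x) x[[p]], numeric(1))
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(parameter = p, mean = NA_real_, sd = NA_real_,
                        cv_pct = NA_real_, median = NA_real_,
                        min = NA_real_, max = NA_real_))
    s <- if (length(v) > 1L) sd(v) else 0
    data.frame(parameter = p, mean = mean(v), sd = s,
               cv_pct = if (mean(v) != 0) 100 * s / mean(v) else NA_real_,
               median = median(v), min = min(v), max = max(v))
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- length(ncas)
  class(out) <- c("population_summary", "data.frame")
  out
}

#' @export
print.population_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Population NCA summary (n = %s)\n",
              attr(x, "n") %||% "?"))
  y <- as.data.frame(x)
  y <- y[!is.na(y$mean), ]
  y[-1L] <- lapply(y[-1L], signif, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
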