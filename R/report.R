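#' Pipeline run configuration
#'
#' Validated configuration for a population simulation run.  May also be
#' read from a YAML file with the same field names via
#' `run_config_from_yaml()`.
#'
#' @param population `"US"` or `"CN"` (selects the reference systemic
#'   parameter set).
#' @param route `"intranasal"` or `"oral"`.
#' @param dose_mg dose per administration, mg (> 0).
#' @param schedule `"single"` (one dose, 72 h follow-up) or `"bid7"`
#'   (twice daily for 6 days plus one morning dose on day 7, 72 h
#'   follow-up).
#' @param n_subjects virtual subjects (>= 1; conventionally 300 for
#'   single-dose evaluation runs and 500 for multidose regimen analyses).
#' @param seed RNG seed recorded in the manifest.
#' @param output_dir directory for the report bundle (created if needed);
#'   `NULL` to keep everything in memory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(population = c("US", "CN"),
                       route = c("intranasal", "oral"),
                       dose_mg = 0.06,
                       schedule = c("single", "bid7"),
                       n_subjects = 300, seed = 20220707,
                       output_dir = NULL) {
  population <- match.arg(population)
  route <- match.arg(route)
  schedule <- match.arg(schedule)
  if (!is.numeric(dose_mg) || dose_mg <= 0) stop("dose_mg must be > 0")
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("n_subjects must be >= 1")
  structure(list(population = population, route = route,
                 dose_mg = dose_mg, schedule = schedule,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the `run_config` fields.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the population-simulation pipeline
#'
#' Builds the physiology, selects the population's systemic parameters,
#' simulates `n_subjects` virtual subjects under the configured regimen,
#' and summarizes per-subject plasma ("systemic") and nasal-tissue NCA.
#' For a multidose schedule the accumulation ratios are computed on the
#' population mean profile (ratio of mean day-7 to mean day-1 exposure)
#' and the time to steady state on the typical-subject trough profile.
#' When `output_dir` is set, writes `summary_systemic.csv`,
#' `summary_nasal.csv`, `nca_subjects.csv`, `mean_profile.csv`, a JSON
#' `manifest.json` (parameters, seed, package version) and a plain-text
#' log.
#'
#' @param config a [run_config()].
#' @return An object of class `pbpk_report`: list with `config`, `pop`
#'   (the [popsim()] result), `summary_systemic`, `summary_nasal`
#'   (population summaries), `mean_nca_systemic`, `mean_nca_nasal`
#'   (NCA of the mean profile), and for multidose `steady_state_day`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  phys <- build_physiology()
  typ <- switch(config$population, US = us_systemic_params(),
                CN = cn_systemic_params())
  frac <- deposition_fractions()
  reg <- switch(config$schedule,
                single = single_dose_regimen(config$dose_mg, config$route),
                bid7 = bid_regimen(config$dose_mg, config$route, days = 7))
  spec <- population_spec(config$n_subjects, seed = config$seed)
  pop <- popsim(typ, spec, phys, frac, reg)

  multidose <- length(reg$events) > 1L
  mp <- pop$mean_profile
  mean_nca <- function(series) {
    if (multidose) nca_multidose(mp$time_h, series, reg,
                                 config$dose_mg * 1e6)
    else nca_single_dose(mp$time_h, series, config$dose_mg * 1e6,
                         tau = reg$tau)
  }
  out <- list(config = config, pop = pop,
              summary_systemic = summarize_nca(pop$nca_plasma),
              summary_nasal = summarize_nca(pop$nca_nasal),
              mean_nca_systemic = mean_nca(mp$C_plasma),
              mean_nca_nasal = mean_nca(mp$C_nasal))
  if (multidose)
    out$steady_state_day <- time_to_steady_state(
      pop$typical$time, pop$typical$conc$C_plasma, reg)
  class(out) <- "pbpk_report"

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$output_dir, f)
    write.csv(as.data.frame(out$summary_systemic), p("summary_systemic.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(out$summary_nasal), p("summary_nasal.csv"),
              row.names = FALSE)
    subj <- do.call(rbind, c(
      lapply(seq_along(pop$nca_plasma), function(i)
        cbind(subject = i, series = "systemic",
              as.data.frame(pop$nca_plasma[[i]]))),
      lapply(seq_along(pop$nca_nasal), function(i)
        cbind(subject = i, series = "nasal",
              as.data.frame(pop$nca_nasal[[i]])))))
    write.csv(subj, p("nca_subjects.csv"), row.names = FALSE)
    write.csv(mp, p("mean_profile.csv"), row.names = FALSE)
    manifest <- list(
      config = unclass(config)[setdiff(names(unclass(config)), "output_dir")],
      package = "nasalpbpk",
      version = as.character(utils::packageVersion("nasalpbpk")),
      steady_state_day = out$steady_state_day,
      generated = format(t_start, "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    writeLines(sprintf("run_pipeline %s %s %g mg %s n=%d seed=%d: %.1f s",
                       config$population, config$route, config$dose_mg,
                       config$schedule, config$n_subjects, config$seed,
                       as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
               p("run.log"))
  }
  out
}

#' @export
print.pbpk_report <- function(x, ...) {
  cat(sprintf("PBPK report: %s %s %g mg %s, n = %d, seed %d\n",
              x$config$population, x$config$route, x$config$dose_mg,
              x$config$schedule, x$config$n_subjects, x$config$seed))
  if (!is.null(x$steady_state_day))
    cat(sprintf("  steady state reached on day %d (typical-subject troughs)\n",
                x$steady_state_day))
  cat("Systemic:\n"); print(x$summary_systemic)
  cat("Nasal tissue:\n"); print(x$summary_nasal)
  invisible(x)
}

#' Between-population parameter ratios
#'
#' Elementwise ratios (second/first population, conventionally CN/US) of
#' the mean NCA parameters of two matched report bundles, for the systemic
#' and nasal series.
#'
#' @param bundle_us,bundle_cn two [run_pipeline()] results with identical
#'   route, dose and schedule.
#' @return Data frame: `parameter`, `systemic_ratio`, `nasal_ratio`.
#' @export
compare_populations <- function(bundle_us, bundle_cn) {
  stopifnot(inherits(bundle_us, "pbpk_report"),
            inherits(bundle_cn, "pbpk_report"))
  a <- bundle_us$config; b <- bundle_cn$config
  if (!identical(a[c("route", "dose_mg", "schedule")],
                 b[c("route", "dose_mg", "schedule")]))
    stop("bundles have mismatched regimens")
  ratio_of <- function(s_cn, s_us) {
    stopifnot(identical(s_cn$parameter, s_us$parameter))
    s_cn$mean / s_us$mean
  }
  data.frame(
    parameter = bundle_us$summary_systemic$parameter,
    systemic_ratio = ratio_of(bundle_cn$summary_systemic,
                              bundle_us$summary_systemic),
    nasal_ratio = ratio_of(bundle_cn$summary_nasal,
                           bundle_us$summary_nasal))
}
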