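#' Run the full life-table analysis of one cohort and write its tables
#'
#' The one-stop driver behind the analysis scripts: builds the age-stage
#' census matrix, the l_x / f_x / m_x schedules, the stage-duration,
#' longevity and reproduction summaries, and the bootstrap population
#' parameters, and writes each as a CSV into \code{out_dir} together with
#' a small run log (package version, seed, B). Output is deterministic:
#' the same cohort, seed and settings give byte-identical files.
#'
#' @param cht a \code{cohort}
#' @param out_dir output directory (created if missing)
#' @param B bootstrap replicates (0 skips the bootstrap)
#' @param seed integer seed; required whenever \code{B > 0}
#' @param alpha significance level recorded in the log
#' @param period oviposition-period convention, see
#'   \code{\link{reproduction_summary}}
#' @return invisibly, a list with every computed object (\code{matrix},
#'   \code{schedule}, \code{durations}, \code{reproduction}, \code{boot})
#' @export
run_lifetable <- function(cht, out_dir, B = 10000L, seed = NULL,
                          alpha = 0.05, period = "span") {
  stopifnot(inherits(cht, "cohort"))
  if (B > 0 && is.null(seed))
    stop("config error: a seed is required when the bootstrap runs (B > 0)")
  v <- validate_cohort(cht)
  if (length(v))
    stop("life_table stage: invalid cohort:\n  ", paste(v, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  mat <- build_age_stage_survival(cht)
  sched <- life_schedule(cht, mat)
  durs <- stage_duration_summary(cht)
  rep_sum <- reproduction_summary(cht, period)

  sxj <- as.data.frame(unclass(mat))
  names(sxj) <- paste0("s_", gsub(" ", "_", names(sxj)))
  utils::write.csv(cbind(age = sched$age, sxj, sched[-1]),
                   file.path(out_dir, "schedules.csv"), row.names = FALSE)
  utils::write.csv(durs$stages, file.path(out_dir, "stage_durations.csv"),
                   row.names = FALSE)
  adults <- durs$adults
  adults$immature_mortality_pct <- durs$immature_mortality_pct
  utils::write.csv(adults, file.path(out_dir, "longevity_mortality.csv"),
                   row.names = FALSE)
  if (!rep_sum$empty)
    utils::write.csv(rep_sum$summary, file.path(out_dir, "reproduction.csv"),
                     row.names = FALSE)

  boot <- NULL
  if (B > 0) {
    boot <- bootstrap_params(cht, B = B, seed = seed)
    utils::write.csv(params_table(boot),
                     file.path(out_dir, "population_params.csv"),
                     row.names = FALSE)
  }
  writeLines(c(
    sprintf("agestage %s", as.character(utils::packageVersion("agestage"))),
    sprintf("treatment: %s  n0: %d", cht$treatment, cht$n0),
    sprintf("bootstrap B: %d  seed: %s  alpha: %g", B,
            if (is.null(seed)) "-" else seed, alpha),
    sprintf("oviposition period convention: %s", period)),
    file.path(out_dir, "run_log.txt"))

  invisible(list(matrix = mat, schedule = sched, durations = durs,
                 reproduction = rep_sum, boot = boot))
}

#' Simulate a cohort to disk with its ground truth
#'
#' Simulates one cohort from a spec and writes the individuals and
#' fecundity CSVs plus a JSON file holding the spec's true population
#' parameters, so that a downstream life-table run can be checked against
#' truth.
#'
#' @param spec a \code{cohort_spec}
#' @param out_dir output directory (created if missing)
#' @param seed integer seed (required)
#' @return invisibly, the simulated \code{cohort}
#' @export
run_simulate <- function(spec, out_dir, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed) || is.null(seed))
    stop("config error: a seed is required to simulate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cht <- simulate_cohort(spec, seed)
  write_cohort(cht, file.path(out_dir,
                              paste0("cohort_", spec$treatment, ".csv")))
  truth <- true_params(spec)
  jsonlite::write_json(
    list(treatment = spec$treatment, n0 = spec$n0,
         true_params = unclass(truth), seed = seed),
    file.path(out_dir, paste0("truth_", spec$treatment, ".json")),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(cht)
}
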