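# Replicate-trial batteries: generate -> allocate -> (inject) -> test,
# repeated N times with deterministic per-trial child seeds.

#' Run one trial with one or several approaches
#'
#' Shares work across approaches where the fitted models coincide: the
#' STDs fits are reused by rcLRT/cLRT (observed statistic) and by MAD
#' (identical model set); IMA mixture fits are warm-started from the
#' placebo fit.
#'
#' @param approaches character vector among \code{"stds", "sss", "clrt",
#'   "rclrt", "mad", "mapd", "ima"}.
#' @param cohort an allocated \code{trt_cohort}.
#' @param candidates a \code{\link{candidate_set}}; for MAPD it must hold
#'   several placebo models (other approaches use the first).
#' @param n_null replicates for the empirical null distributions.
#' @param seed integer seed for null replicates.
#' @param alpha test level.
#' @param options fit options.
#' @return named list of \code{test_result}s.
#' @export
run_trial <- function(approaches, cohort, candidates, n_null = 100,
                      seed = 1L, alpha = 0.05, options = list()) {
  single <- candidate_set(candidates$placebos[[1]], names(candidates$drugs))
  out <- list()
  stds_res <- NULL
  need_stds <- any(c("stds", "clrt", "rclrt", "mad") %in% approaches)
  if (need_stds) {
    stds_res <- run_stds(cohort, single, alpha, options)
  }
  for (ap in approaches) {
    out[[ap]] <- switch(ap,
      stds = stds_res,
      sss = run_sss(cohort, single, alpha, options),
      clrt = run_clrt(cohort, single, n_null, child_seed(seed, 1L, 11L),
                      alpha, options, obs = stds_res),
      rclrt = run_rclrt(cohort, single, n_null, child_seed(seed, 1L, 12L),
                        alpha, options, obs = stds_res),
      mad = run_mad(cohort, single, options, stds_result = stds_res),
      mapd = run_mapd(cohort, candidates, options),
      ima = {
        ini <- if (!is.null(stds_res) &&
                   stds_res$details$h0_fit$status == "converged") {
          stds_res$details$h0_fit$params
        } else NULL
        run_ima(cohort, single, alpha, options, inits = ini)
      },
      stopf("unknown approach '%s'", ap))
  }
  out
}

#' Battery configuration
#'
#' @param approaches approaches to run each trial.
#' @param n_trials number of replicate trials N.
#' @param n_null replicates for empirical null distributions (cLRT/rcLRT).
#' @param n_subjects cohort size per trial.
#' @param generator generator settings (see
#'   \code{\link{default_generator_config}}); \code{n_subjects} overrides
#'   its subject count.
#' @param scenario \code{NULL} for a no-effect (type I error) battery, or an
#'   \code{\link{effect_scenario}} for a power/RMSE battery.
#' @param drug_ids candidate drug components.
#' @param placebo_set \code{"published"} or \code{"preselected"} (published
#'   plus the four alternatives, for MAPD).
#' @param alpha test level.
#' @param seed master seed; all trial-level randomness derives from it.
#' @return a \code{battery_config} list.
#' @export
battery_config <- function(approaches = c("rclrt", "ima"),
                           n_trials = 100, n_null = 100,
                           n_subjects = 150,
                           generator = default_generator_config(
                             misspec = misspec_config(enabled = TRUE)),
                           scenario = NULL,
                           drug_ids = c("offset", "offset_iiv", "dm", "dm_iiv"),
                           placebo_set = "published",
                           alpha = 0.05, seed = 1L) {
  structure(list(approaches = approaches, n_trials = n_trials,
                 n_null = n_null, n_subjects = n_subjects,
                 generator = generator, scenario = scenario,
                 drug_ids = drug_ids, placebo_set = placebo_set,
                 alpha = alpha, seed = seed),
            class = "battery_config")
}

#' Run a battery of replicate trials
#'
#' For each of \code{n_trials} trials: generate a natural-history cohort,
#' randomize the allocation 1:1, optionally inject the scenario's treatment
#' effect into the treated arm, and run every requested approach. All seeds
#' derive deterministically from the master seed and the trial index, so any
#' single trial can be re-run in isolation.
#'
#' @param config a \code{\link{battery_config}}.
#' @param verbose print per-trial progress.
#' @return a \code{battery_result}: per-trial decisions/estimates in
#'   \code{$trials}, plus metadata; summarize with
#'   \code{\link{battery_summary}}.
#' @export
run_battery <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "battery_config"))
  gen <- config$generator
  gen$n_subjects <- config$n_subjects
  placebos <- if (identical(config$placebo_set, "preselected")) {
    c(list(published_placebo()), unname(alternative_placebos()))
  } else {
    published_placebo()
  }
  candidates <- candidate_set(placebos, config$drug_ids)
  rows <- list()
  for (i in seq_len(config$n_trials)) {
    co <- generate_natural_history(gen, seed = child_seed(config$seed, i, 1L))
    co <- randomize_allocation(co, seed = child_seed(config$seed, i, 2L))
    if (!is.null(config$scenario)) {
      co <- inject_treatment_effect(co, config$scenario,
                                    seed = child_seed(config$seed, i, 3L))
    }
    res <- run_trial(config$approaches, co, candidates,
                     n_null = config$n_null,
                     seed = child_seed(config$seed, i, 4L),
                     alpha = config$alpha)
    for (ap in names(res)) {
      r <- res[[ap]]
      rows[[length(rows) + 1L]] <- data.frame(
        trial = i, approach = ap, decision = r$decision,
        selected = r$selected %||% NA_character_,
        dofv = r$dofv, critical_value = r$critical_value,
        effect_estimate = r$effect_estimate,
        h1_weight_fraction = r$h1_weight_fraction,
        excluded_fits = r$excluded_fits)
    }
    if (verbose) {
      message(sprintf("trial %d/%d: %s", i, config$n_trials,
                      paste(vapply(res, `[[`, character(1), "decision"),
                            collapse = " ")))
    }
  }
  trials <- do.call(rbind, rows)
  scen <- config$scenario
  structure(list(trials = trials, config = config,
                 truth_effect = if (is.null(scen)) NULL else scen$typical_effect,
                 scenario_id = if (is.null(scen)) "no-effect" else {
                   sprintf("%s_%g%s", scen$drug_form, scen$typical_effect,
                           if (scen$iiv_cv > 0) "_iiv" else "")
                 }),
            class = "battery_result")
}

#' @export
print.battery_result <- function(x, ...) {
  cat(sprintf("<battery_result> scenario %s | %d trials\n",
              x$scenario_id, x$config$n_trials))
  print(battery_summary(x))
  invisible(x)
}
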