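# Battery-level metrics: rejection rates, exact binomial acceptance bounds,
# RMSE of treatment-effect estimates, and run-status accounting.

#' Rejection rate of a battery, in percent
#'
#' For selection-based approaches: \code{100 * #rejections / #non-excluded
#' trials}. For the model-averaging approaches (MAD, MAPD) the per-trial
#' statistic is the total relative Akaike weight assigned to any alternative
#' model, and the rate is 100 times its mean over trials.
#'
#' @param battery a \code{battery_result} (see \code{\link{run_battery}}),
#'   or a data frame with columns \code{approach}, \code{decision},
#'   \code{h1_weight_fraction}.
#' @param approach approach id; required when the battery holds several.
#' @return rejection rate in percent.
#' @export
rejection_rate <- function(battery, approach = NULL) {
  d <- if (inherits(battery, "battery_result")) battery$trials else battery
  if (!is.null(approach)) d <- d[d$approach == approach, , drop = FALSE]
  if (length(unique(d$approach)) > 1) {
    stopf("several approaches present; pass `approach`")
  }
  d <- d[d$decision != "inconclusive", , drop = FALSE]
  if (nrow(d) == 0) stopf("all trials excluded")
  if (unique(d$approach) %in% c("mad", "mapd")) {
    100 * mean(d$h1_weight_fraction)
  } else {
    100 * mean(d$decision == "reject_h0")
  }
}

#' Exact binomial acceptance region for an empirical type I error
#'
#' Clopper-Pearson-type interval, in percent, around the nominal level for
#' the expected rejection count \code{x = alpha_nominal * n_trials}:
#' lower bound \code{100 * qbeta((1-level)/2, x, n-x+1)}, upper bound
#' \code{100 * qbeta(1-(1-level)/2, x+1, n-x)}. For a nominal 5\% level and
#' 100 trials this gives the printed region (1.64, 11.28).
#'
#' @param alpha_nominal nominal test level (default 0.05).
#' @param n_trials number of replicate trials (default 100).
#' @param level coverage of the acceptance region (default 0.95).
#' @return named numeric vector \code{c(lower, upper)} in percent.
#' @export
binomial_acceptance <- function(alpha_nominal = 0.05, n_trials = 100,
                                level = 0.95) {
  if (n_trials < 1 || alpha_nominal <= 0 || alpha_nominal >= 1 ||
      level <= 0 || level >= 1) {
    stopf("invalid binomial_acceptance inputs")
  }
  x <- round(alpha_nominal * n_trials)
  a2 <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a2, x, n_trials - x + 1)
  upper <- if (x == n_trials) 1 else stats::qbeta(1 - a2, x + 1, n_trials - x)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Root mean squared error of treatment-effect estimates
#'
#' \code{sqrt(mean((estimate - truth)^2))} over non-excluded trials.
#' Estimates from the individual model averaging approach must already be
#' transformed by \code{\link{ima_effect_estimate}} (as \code{run_ima}
#' reports them).
#'
#' @param estimates numeric vector of per-trial effect estimates.
#' @param truth true simulated effect (scalar or per-trial vector).
#' @return the RMSE (scalar).
#' @export
rmse <- function(estimates, truth) {
  estimates <- estimates[!is.na(estimates)]
  if (length(estimates) == 0) stopf("no estimates")
  sqrt(mean((estimates - truth)^2))
}

#' Summarize a battery as a flat table
#'
#' One row per approach: number of trials, exclusions, rejection rate (type
#' I error or power depending on the scenario), and, for effect-injected
#' batteries, the RMSE of the effect estimates.
#'
#' @param battery a \code{battery_result}.
#' @return a data.frame.
#' @export
battery_summary <- function(battery) {
  stopifnot(inherits(battery, "battery_result"))
  d <- battery$trials
  truth <- battery$truth_effect
  out <- do.call(rbind, lapply(split(d, d$approach), function(a) {
    kept <- a[a$decision != "inconclusive", , drop = FALSE]
    data.frame(
      approach = a$approach[1],
      scenario = battery$scenario_id,
      n_trials = nrow(a),
      n_excluded = sum(a$decision == "inconclusive"),
      rate_pct = if (nrow(kept)) rejection_rate(kept) else NA_real_,
      rmse = if (!is.null(truth) && nrow(kept)) {
        rmse(kept$effect_estimate, truth)
      } else NA_real_,
      row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
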