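# The seven treatment-effect testing approaches: standard selection (STDs),
# structural-similarity selection (SSs), combined and randomized-combined
# LRT (cLRT / rcLRT), model averaging across drug models (MAD) and across
# placebo-and-drug models (MAPD), and individual model averaging (IMA).

new_test_result <- function(approach, decision, selected = NA_character_,
                            dofv = NA_real_, critical_value = NA_real_,
                            effect_estimate = NA_real_,
                            h1_weight_fraction = NA_real_,
                            excluded_fits = 0L, details = list()) {
  structure(list(approach = approach, decision = decision,
                 selected = selected, dofv = dofv,
                 critical_value = critical_value,
                 effect_estimate = effect_estimate,
                 h1_weight_fraction = h1_weight_fraction,
                 excluded_fits = excluded_fits, details = details),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: %s | selected %s | dOFV %.3f vs crit %.3f | effect %.3f\n",
              x$approach, x$decision, x$selected, x$dofv, x$critical_value,
              x$effect_estimate))
  invisible(x)
}

#' Akaike weights of a candidate set
#'
#' Standard Akaike weights \code{w_k = exp(-(AIC_k - AIC_min)/2)},
#' normalized to sum to one; the best (minimum-AIC) model receives the
#' largest weight. Non-finite AICs (failed fits) receive weight zero.
#'
#' @param aics numeric vector of AIC values.
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aics) {
  ok <- is.finite(aics)
  if (!any(ok)) stopf("no finite AIC values")
  w <- numeric(length(aics))
  d <- aics[ok] - min(aics[ok])
  w[ok] <- exp(-d / 2)
  w / sum(w)
}

single_placebo <- function(candidates) {
  if (length(candidates$placebos) != 1) {
    stopf("this approach requires a single placebo model")
  }
  candidates$placebos[[1]]
}

fit_drug_set <- function(placebo, candidates, cohort, applies, options,
                         warm = NULL) {
  ids <- names(candidates$drugs)
  stats::setNames(lapply(ids, function(id) {
    m <- add_drug(placebo, candidates$drugs[[id]], applies)
    fit(m, cohort, inits = warm[[id]], options = options)
  }), ids)
}

# AIC selection among converged H1 fits; ties go to the first-listed
# candidate (candidate order is part of the configuration).
select_best <- function(fits) {
  ok <- vapply(fits, function(f) f$status == "converged", logical(1))
  if (!any(ok)) return(NULL)
  aics <- vapply(fits, function(f) if (f$status == "converged") aic(f) else Inf,
                 numeric(1))
  idx <- which.min(aics)
  list(idx = idx, id = names(fits)[idx], fit = fits[[idx]],
       excluded = sum(!ok))
}

#' Standard model selection with the LRT (STDs)
#'
#' Fits the placebo model (H0) and every placebo+drug candidate applied to
#' the treated arm (H1), selects the H1 with minimum AIC, and tests it
#' against H0 with a chi-square LRT whose degrees of freedom equal the
#' number of additional parameters of the selected candidate.
#'
#' @param cohort an allocated \code{trt_cohort}.
#' @param candidates a \code{\link{candidate_set}} with a single placebo.
#' @param alpha test level.
#' @param options fit options, see \code{\link{fit}}.
#' @param h0_fit optional pre-computed placebo fit (reused by the empirical
#'   null construction, where the placebo likelihood does not depend on the
#'   allocation).
#' @param warm optional named list of warm-start parameter vectors per drug
#'   candidate.
#' @return a \code{test_result}; \code{details} carries the underlying fits.
#' @export
run_stds <- function(cohort, candidates, alpha = 0.05, options = list(),
                     h0_fit = NULL, warm = NULL) {
  placebo <- single_placebo(candidates)
  h0 <- h0_fit %||% fit(placebo, cohort, options = options)
  if (h0$status != "converged") {
    return(new_test_result("stds", "inconclusive",
                           details = list(h0_fit = h0)))
  }
  h1 <- fit_drug_set(placebo, candidates, cohort, "treated_only", options, warm)
  sel <- select_best(h1)
  if (is.null(sel)) {
    return(new_test_result("stds", "inconclusive",
                           excluded_fits = length(h1),
                           details = list(h0_fit = h0, h1_fits = h1)))
  }
  df <- sel$fit$n_params - h0$n_params
  dofv <- delta_ofv(h0, sel$fit)
  crit <- chi2_critical(df, alpha)
  new_test_result("stds",
                  if (dofv < crit) "reject_h0" else "retain_h0",
                  selected = sel$id, dofv = dofv, critical_value = crit,
                  effect_estimate = sel$fit$params[["th_de"]],
                  excluded_fits = sel$excluded,
                  details = list(h0_fit = h0, h1_fits = h1, df = df))
}

#' Structural-similarity selection (SSs)
#'
#' For each drug candidate the null fits placebo+drug to all subjects with
#' shared drug parameters; the alternative duplicates the drug parameters
#' per arm. The best pair is selected by the H1 AIC and tested with df equal
#' to the number of duplicated drug parameters.
#'
#' @inheritParams run_stds
#' @return a \code{test_result}; the effect estimate is the between-arm
#'   difference of the duplicated drug effect.
#' @export
run_sss <- function(cohort, candidates, alpha = 0.05, options = list()) {
  placebo <- single_placebo(candidates)
  pairs <- lapply(names(candidates$drugs), function(id) {
    d <- candidates$drugs[[id]]
    f0 <- fit(add_drug(placebo, d, "all"), cohort, options = options)
    warm <- NULL
    if (f0$status == "converged") {
      warm <- f0$params
      nm <- names(warm)
      warm <- c(warm,
                th_de0 = unname(warm[["th_de"]]),
                th_de1 = unname(warm[["th_de"]]))
      if (d$iiv) {
        warm <- c(warm, om2_de0 = unname(warm[["om2_de"]]),
                  om2_de1 = unname(warm[["om2_de"]]))
      }
    }
    f1 <- fit(add_drug(placebo, d, "arm_specific"), cohort, inits = warm,
              options = options)
    list(id = id, h0 = f0, h1 = f1,
         ok = f0$status == "converged" && f1$status == "converged")
  })
  ok <- vapply(pairs, `[[`, logical(1), "ok")
  if (!any(ok)) {
    return(new_test_result("sss", "inconclusive",
                           excluded_fits = sum(!ok)))
  }
  aics <- vapply(pairs, function(pr) if (pr$ok) aic(pr$h1) else Inf, numeric(1))
  best <- pairs[[which.min(aics)]]
  df <- best$h1$n_params - best$h0$n_params
  dofv <- delta_ofv(best$h0, best$h1)
  crit <- chi2_critical(df, alpha)
  eff <- best$h1$params[["th_de1"]] - best$h1$params[["th_de0"]]
  new_test_result("sss", if (dofv < crit) "reject_h0" else "retain_h0",
                  selected = best$id, dofv = dofv, critical_value = crit,
                  effect_estimate = eff, excluded_fits = sum(!ok),
                  details = list(pairs = pairs, df = df))
}

#' Empirical null distribution of the selected-model dOFV
#'
#' Replicates the full STDs selection procedure on data sets carrying no
#' treatment effect by construction: either cohorts simulated from the
#' fitted placebo model (\code{"h0_simulation"}, the combined LRT) or the
#' observed cohort with permuted treatment allocation
#' (\code{"permutation"}, the randomized combined LRT). Failed replicates
#' are dropped and counted; more than 20\% failures is an error.
#'
#' @inheritParams run_stds
#' @param source \code{"h0_simulation"} or \code{"permutation"}.
#' @param n number of replicates (at least 20).
#' @param seed integer master seed for the replicates.
#' @param h1_fits optional observed-data H1 fits used as warm starts.
#' @return a \code{null_distribution} with the dOFV draws.
#' @export
build_null <- function(cohort, candidates, source = c("permutation",
                                                      "h0_simulation"),
                       n = 100, seed, alpha = 0.05, options = list(),
                       h0_fit = NULL, h1_fits = NULL) {
  source <- match.arg(source)
  if (n < 20) stopf("need at least 20 null replicates")
  placebo <- single_placebo(candidates)
  if (is.null(h0_fit)) h0_fit <- fit(placebo, cohort, options = options)
  if (h0_fit$status != "converged") {
    stopf("placebo model did not converge on the observed cohort")
  }
  warm <- lapply(h1_fits %||% list(), function(f) {
    if (inherits(f, "fit_result") && f$status == "converged") f$params else NULL
  })
  vals <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    rep_seed <- child_seed(seed, r)
    res <- tryCatch({
      if (source == "permutation") {
        co_r <- permute_allocation(cohort, rep_seed)
        h0_r <- h0_fit # placebo likelihood does not involve TRT: exact reuse
      } else {
        co_r <- simulate_from_fit(h0_fit, cohort, rep_seed)
        h0_r <- fit(placebo, co_r, inits = h0_fit$params, options = options)
      }
      if (h0_r$status != "converged") NA_real_ else {
        h1_r <- fit_drug_set(placebo, candidates, co_r, "treated_only",
                             options, warm)
        sel <- select_best(h1_r)
        if (is.null(sel)) NA_real_ else delta_ofv(h0_r, sel$fit)
      }
    }, error = function(e) NA_real_)
    vals[r] <- res
  }
  n_failed <- sum(is.na(vals))
  if (n_failed > 0.2 * n) {
    stopf("%d of %d null replicates failed; distribution unreliable",
          n_failed, n)
  }
  structure(list(values = vals[!is.na(vals)], source = source,
                 n_requested = n, n_failed = n_failed,
                 quantile_alpha = alpha),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s | %d values (%d failed)\n",
              x$source, length(x$values), x$n_failed))
  invisible(x)
}

null_cutoff <- function(null, alpha, rule = c("quantile", "r_plus_1")) {
  rule <- match.arg(rule)
  v <- sort(null$values)
  if (rule == "quantile") {
    as.numeric(stats::quantile(v, alpha, type = 7))
  } else {
    # value such that the (r+1)/(n+1) p-value of the observed dOFV is alpha
    k <- max(1L, floor(alpha * (length(v) + 1)))
    v[k]
  }
}

run_xlrt <- function(approach, source, cohort, candidates, n, seed,
                     alpha, options, obs = NULL, rule = "quantile") {
  obs <- obs %||% run_stds(cohort, candidates, alpha, options)
  if (obs$decision == "inconclusive") {
    out <- obs; out$approach <- approach
    return(out)
  }
  null <- build_null(cohort, candidates, source, n, seed, alpha, options,
                     h0_fit = obs$details$h0_fit,
                     h1_fits = obs$details$h1_fits)
  crit <- null_cutoff(null, alpha, rule)
  new_test_result(approach,
                  if (obs$dofv < crit) "reject_h0" else "retain_h0",
                  selected = obs$selected, dofv = obs$dofv,
                  critical_value = crit,
                  effect_estimate = obs$effect_estimate,
                  excluded_fits = obs$excluded_fits,
                  details = list(null = null, obs = obs))
}

#' Combined LRT (cLRT): empirical null by simulation under H0
#'
#' Same observed statistic as \code{\link{run_stds}}, but the critical value
#' is the empirical alpha-quantile of the selected-model dOFV over \code{n}
#' cohorts simulated from the fitted placebo model.
#'
#' @inheritParams build_null
#' @param rule cutoff convention: plain empirical quantile (default) or the
#'   \code{(r+1)/(n+1)} randomization-test variant.
#' @return a \code{test_result}.
#' @export
run_clrt <- function(cohort, candidates, n = 100, seed, alpha = 0.05,
                     options = list(), obs = NULL, rule = "quantile") {
  run_xlrt("clrt", "h0_simulation", cohort, candidates, n, seed, alpha,
           options, obs, rule)
}

#' Randomized combined LRT (rcLRT): empirical null by permutation
#'
#' The critical value is the empirical alpha-quantile of the selected-model
#' dOFV over \code{n} permutations of the treatment allocation, which makes
#' no placebo-model assumption and is calibrated by exchangeability even
#' under placebo model misspecification.
#'
#' @inheritParams run_clrt
#' @return a \code{test_result}.
#' @export
run_rclrt <- function(cohort, candidates, n = 100, seed, alpha = 0.05,
                      options = list(), obs = NULL, rule = "quantile") {
  run_xlrt("rclrt", "permutation", cohort, candidates, n, seed, alpha,
           options, obs, rule)
}

ma_weights_result <- function(approach, fits, is_h1, effects) {
  aics <- vapply(fits, function(f) if (f$status == "converged") aic(f) else Inf,
                 numeric(1))
  if (!any(is.finite(aics))) {
    return(new_test_result(approach, "inconclusive",
                           excluded_fits = length(fits)))
  }
  w <- akaike_weights(aics)
  h1w <- sum(w[is_h1])
  eff <- sum(w * effects)
  new_test_result(approach,
                  if (h1w > 0.5) "reject_h0" else "retain_h0",
                  selected = names(fits)[which.max(w)],
                  effect_estimate = eff, h1_weight_fraction = h1w,
                  excluded_fits = sum(!is.finite(aics)),
                  details = list(weights = stats::setNames(w, names(fits)),
                                 aics = aics))
}

#' Model averaging across drug models (MAD)
#'
#' Fits the placebo model and every placebo+drug candidate, assigns each an
#' Akaike weight, and reports the total weight of the drug-containing
#' (alternative) models. No selection or LRT is performed; at the battery
#' level a trial contributes its H1 weight fraction to the rejection rate.
#'
#' @inheritParams run_stds
#' @param stds_result optional \code{\link{run_stds}} result whose fits are
#'   reused (the fitted models are identical).
#' @return a \code{test_result} with \code{h1_weight_fraction} set.
#' @export
run_mad <- function(cohort, candidates, options = list(), stds_result = NULL) {
  placebo <- single_placebo(candidates)
  if (!is.null(stds_result) && !is.null(stds_result$details$h1_fits)) {
    h0 <- stds_result$details$h0_fit
    h1 <- stds_result$details$h1_fits
  } else {
    h0 <- fit(placebo, cohort, options = options)
    h1 <- fit_drug_set(placebo, candidates, cohort, "treated_only", options)
  }
  fits <- c(list(h0 = h0), h1)
  effects <- vapply(fits, function(f) {
    if (f$status == "converged" && "th_de" %in% names(f$params)) {
      f$params[["th_de"]]
    } else 0
  }, numeric(1))
  res <- ma_weights_result("mad", fits, c(FALSE, rep(TRUE, length(h1))), effects)
  res
}

#' Model averaging across placebo and drug models (MAPD)
#'
#' Akaike-weight averaging over the full grid of placebo models (published
#' plus alternatives) crossed with \{no drug, each drug candidate\}.
#'
#' @inheritParams run_stds
#' @return a \code{test_result} with \code{h1_weight_fraction} set.
#' @export
run_mapd <- function(cohort, candidates, options = list()) {
  if (length(candidates$placebos) < 2) {
    stopf("MAPD requires at least two placebo models")
  }
  fits <- list(); is_h1 <- logical(0)
  for (pm in candidates$placebos) {
    pid <- model_id(pm)
    fits[[pid]] <- fit(pm, cohort, options = options)
    is_h1 <- c(is_h1, FALSE)
    for (id in names(candidates$drugs)) {
      m <- add_drug(pm, candidates$drugs[[id]], "treated_only")
      fits[[paste0(pid, "+", id)]] <- fit(m, cohort, options = options)
      is_h1 <- c(is_h1, TRUE)
    }
  }
  effects <- vapply(fits, function(f) {
    if (f$status == "converged" && "th_de" %in% names(f$params)) {
      f$params[["th_de"]]
    } else 0
  }, numeric(1))
  ma_weights_result("mapd", fits, is_h1, effects)
}

#' Treatment effect estimate of the individual model averaging approach
#'
#' Accounts for the estimated sub-model allocation probability:
#' \code{(2 * theta_mix - 1) * theta_de}. At \code{theta_mix = 0.5} (the
#' null allocation rate) the estimate is exactly 0 whatever
#' \code{theta_de}; at \code{theta_mix = 1} it equals \code{theta_de}.
#'
#' @param theta_mix estimated mixing probability.
#' @param theta_de estimated drug effect parameter.
#' @return the transformed effect estimate.
#' @export
ima_effect_estimate <- function(theta_mix, theta_de) {
  (2 * theta_mix - 1) * theta_de
}

#' Individual model averaging (IMA)
#'
#' Every subject is described by a two-component mixture of the placebo and
#' the placebo+drug model. Under H0 the mixing probability is fixed at the
#' allocation rate (0.5); under H1 it is estimated with arm-dependent
#' component probabilities. For each drug candidate both mixtures are
#' fitted; the candidate with the best H1 AIC is selected and tested with a
#' 1-df LRT on the mixing parameter.
#'
#' @inheritParams run_stds
#' @param inits optional warm-start parameters (e.g. a placebo fit).
#' @return a \code{test_result}; \code{effect_estimate} is already
#'   transformed by \code{\link{ima_effect_estimate}}.
#' @export
run_ima <- function(cohort, candidates, alpha = 0.05, options = list(),
                    inits = NULL) {
  placebo <- single_placebo(candidates)
  pairs <- lapply(names(candidates$drugs), function(id) {
    d <- candidates$drugs[[id]]
    f0 <- fit(mixture_model(placebo, d, theta_mix_fixed = 0.5), cohort,
              inits = inits, options = options)
    warm <- inits
    if (f0$status == "converged") {
      warm <- f0$params
      warm[["th_mix"]] <- 0.6
    }
    f1 <- fit(mixture_model(placebo, d, theta_mix_fixed = NA), cohort,
              inits = warm, options = options)
    list(id = id, h0 = f0, h1 = f1,
         ok = f0$status == "converged" && f1$status == "converged")
  })
  ok <- vapply(pairs, `[[`, logical(1), "ok")
  if (!any(ok)) {
    return(new_test_result("ima", "inconclusive", excluded_fits = sum(!ok)))
  }
  aics <- vapply(pairs, function(pr) if (pr$ok) aic(pr$h1) else Inf, numeric(1))
  best <- pairs[[which.min(aics)]]
  dofv <- delta_ofv(best$h0, best$h1)
  crit <- chi2_critical(1, alpha)
  eff <- ima_effect_estimate(best$h1$params[["th_mix"]],
                             best$h1$params[["th_de"]])
  new_test_result("ima", if (dofv < crit) "reject_h0" else "retain_h0",
                  selected = best$id, dofv = dofv, critical_value = crit,
                  effect_estimate = eff, excluded_fits = sum(!ok),
                  details = list(pairs = pairs, df = 1,
                                 theta_mix = best$h1$params[["th_mix"]]))
}
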