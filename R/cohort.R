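# Synthetic natural-history cohorts: generation, treatment-effect injection,
# randomization and permutation of the allocation.

#' Default generator configuration for an ADAS-cog-like cohort
#'
#' The defaults emulate the structure of a mild-cognitive-impairment /
#' early-Alzheimer natural-history population: a baseline ADAS-cog score
#' driven linearly by the Baseline Mini-Mental State score (BMMS), an
#' approximately linear progression whose slope also depends on BMMS,
#' inter-individual variability on baseline and slope, and additive
#' residual error. An optional latent subject-level component
#' \code{gamma_i * (t/36)^2} (omitted by any fitted linear placebo model)
#' makes the cohort deliberately misspecified with respect to the
#' published placebo model; its default magnitude was calibrated once so
#' that the single-fit dOFV impact of the best drug candidate greatly
#' exceeds the -5.99 LRT cutoff (see the methods vignette).
#'
#' @param n_subjects number of subjects.
#' @param schedule visit times in months, strictly increasing, starting at 0.
#' @param th_base,th_int fixed effects of the baseline model
#'   \code{baseline = th_base + th_int * BMMS + eta1}.
#' @param th_slp,th_slp_bmms fixed effects of the slope model
#'   \code{slope = th_slp + th_slp_bmms * BMMS + eta2} (points/month).
#' @param om2_base,om2_slp variances of \code{eta1}, \code{eta2}.
#' @param sig2 residual error variance.
#' @param bmms_mean,bmms_sd distribution of the BMMS covariate.
#' @param misspec list from \code{misspec_config()}.
#' @param dropout_rate probability that each post-baseline visit is missing
#'   (missing at random); 0 keeps complete data.
#' @param clip_scores clamp scores into the 0-70 ADAS-cog range (off by
#'   default; the scores are modelled as continuous).
#' @return a named list of generator settings.
#' @export
default_generator_config <- function(n_subjects = 817,
                                     schedule = c(0, 6, 12, 18, 24, 36),
                                     th_base = 65, th_int = -1.8,
                                     th_slp = 0.75, th_slp_bmms = -0.02,
                                     om2_base = 25, om2_slp = 0.02,
                                     sig2 = 9,
                                     bmms_mean = 25, bmms_sd = 2.5,
                                     misspec = misspec_config(),
                                     dropout_rate = 0,
                                     clip_scores = FALSE) {
  list(n_subjects = n_subjects, schedule = schedule,
       th_base = th_base, th_int = th_int,
       th_slp = th_slp, th_slp_bmms = th_slp_bmms,
       om2_base = om2_base, om2_slp = om2_slp, sig2 = sig2,
       bmms_mean = bmms_mean, bmms_sd = bmms_sd,
       misspec = misspec, dropout_rate = dropout_rate,
       clip_scores = clip_scores)
}

#' Latent misspecification component settings
#'
#' Additive subject-level term \code{gamma_i * g(t)} with
#' \code{g(t) = (t/36)^power} and \code{gamma_i ~ N(gamma_mean, gamma_sd^2)}.
#' A mildly convex \code{g} (default quadratic) gives the data a curvature
#' and a between-subject heterogeneity that a linear placebo model cannot
#' describe, the mechanism behind type I error inflation of LRT-based
#' selection on real natural-history data.
#'
#' @param enabled logical.
#' @param gamma_mean,gamma_sd mean and SD of the subject-level magnitude
#'   (score points at month 36).
#' @param power exponent of the normalized time transform.
#' @return a named list.
#' @export
misspec_config <- function(enabled = FALSE, gamma_mean = 10, gamma_sd = 10,
                           power = 2) {
  list(enabled = enabled, gamma_mean = gamma_mean, gamma_sd = gamma_sd,
       power = power)
}

new_cohort <- function(data, truth = NULL, meta = list()) {
  stopifnot(all(c("ID", "TIME", "DV", "TRT", "BMMS") %in% names(data)))
  data <- as.data.frame(data)[, c("ID", "TIME", "DV", "TRT", "BMMS")]
  structure(list(data = data, truth = truth, meta = meta),
            class = "trt_cohort")
}

#' @export
print.trt_cohort <- function(x, ...) {
  d <- x$data
  cat(sprintf("<trt_cohort> %d subjects, %d observations\n",
              length(unique(d$ID)), nrow(d)))
  cat(sprintf("  provenance: %s | allocated: %s | arms (0/1): %d/%d\n",
              x$meta$provenance %||% "file",
              isTRUE(x$meta$allocated),
              length(unique(d$ID[d$TRT == 0])),
              length(unique(d$ID[d$TRT == 1]))))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a \code{trt_cohort}.
#' @return integer count.
#' @export
n_subjects <- function(cohort) length(unique(cohort$data$ID))

#' Generate a natural-history cohort
#'
#' Simulates per-subject trajectories
#' \code{score(t) = baseline + slope * t + latent(t) + eps} with
#' \code{baseline = th_base + th_int * BMMS + eta1},
#' \code{slope = th_slp + th_slp_bmms * BMMS + eta2}, Gaussian random effects
#' and residual error, and the optional latent misspecification component.
#' No arm labels are assigned (\code{TRT = 0} for everyone); use
#' \code{\link{randomize_allocation}} afterwards.
#'
#' @param config generator settings, see \code{\link{default_generator_config}}.
#' @param seed integer seed (mandatory: cohorts are reproducible by contract).
#' @return a \code{trt_cohort} with a populated \code{truth} record.
#' @export
generate_natural_history <- function(config = default_generator_config(),
                                     seed) {
  if (missing(seed) || is.null(seed)) stopf("a seed is required")
  n <- config$n_subjects
  if (is.null(n) || n < 2) stopf("n_subjects must be >= 2")
  sch <- config$schedule
  if (length(sch) == 0) stopf("empty visit schedule")
  if (any(sch < 0) || is.unsorted(sch, strictly = TRUE)) {
    stopf("schedule must be non-negative and strictly increasing")
  }
  vars <- c(config$om2_base, config$om2_slp, config$sig2,
            if (isTRUE(config$misspec$enabled)) config$misspec$gamma_sd^2)
  if (any(vars < 0)) stopf("variances must be non-negative")

  with_seed(seed, {
    bmms <- stats::rnorm(n, config$bmms_mean, config$bmms_sd)
    eta1 <- stats::rnorm(n, 0, sqrt(config$om2_base))
    eta2 <- stats::rnorm(n, 0, sqrt(config$om2_slp))
    gamma <- if (isTRUE(config$misspec$enabled)) {
      stats::rnorm(n, config$misspec$gamma_mean, config$misspec$gamma_sd)
    } else rep(0, n)

    baseline <- config$th_base + config$th_int * bmms + eta1
    slope <- config$th_slp + config$th_slp_bmms * bmms + eta2

    nt <- length(sch)
    id <- rep(seq_len(n), each = nt)
    tt <- rep(sch, n)
    g <- if (isTRUE(config$misspec$enabled)) {
      (tt / 36)^config$misspec$power
    } else 0
    eps <- stats::rnorm(n * nt, 0, sqrt(config$sig2))
    dv <- baseline[id] + slope[id] * tt + gamma[id] * g + eps
    if (isTRUE(config$clip_scores)) dv <- pmin(pmax(dv, 0), 70)

    keep <- rep(TRUE, n * nt)
    if (config$dropout_rate > 0) {
      keep <- tt == 0 | stats::runif(n * nt) >= config$dropout_rate
    }
    data <- data.frame(ID = id[keep], TIME = tt[keep], DV = dv[keep],
                       TRT = 0L, BMMS = bmms[id][keep])
    truth <- list(
      subjects = data.frame(ID = seq_len(n), bmms = bmms, eta1 = eta1,
                            eta2 = eta2, gamma = gamma, baseline = baseline,
                            slope = slope, e_drug = 0),
      scenario = NULL
    )
    new_cohort(data, truth,
               meta = list(config = config, seed = seed,
                           provenance = "natural", allocated = FALSE))
  })
}

#' Treatment-effect scenario
#'
#' @param drug_form \code{"offset"} (constant additive effect at t > 0) or
#'   \code{"tlin"} (effect growing linearly in time, scaled so that its value
#'   at month 36 equals \code{typical_effect}).
#' @param typical_effect typical effect size in score points at month 36
#'   (non-negative).
#' @param iiv_cv coefficient of variation of the individual effect: the
#'   per-subject effect is \code{typical_effect + eta} with
#'   \code{eta ~ N(0, (iiv_cv * typical_effect)^2)}.
#' @return an \code{effect_scenario} object.
#' @export
effect_scenario <- function(drug_form = c("offset", "tlin"),
                            typical_effect, iiv_cv = 0) {
  drug_form <- match.arg(drug_form)
  if (typical_effect < 0) stopf("typical_effect must be non-negative")
  if (iiv_cv < 0) stopf("iiv_cv must be non-negative")
  structure(list(drug_form = drug_form, typical_effect = typical_effect,
                 iiv_cv = iiv_cv), class = "effect_scenario")
}

#' The eight treatment-effect scenarios of the evaluation battery
#'
#' Offset and time-linear drug models, low (2-point) or high (8-point)
#' typical effect at month 36, with (30\% CV) or without inter-individual
#' variability on the effect.
#'
#' @return a list of 8 \code{effect_scenario} objects.
#' @export
default_scenarios <- function() {
  grid <- expand.grid(drug_form = c("offset", "tlin"),
                      typical_effect = c(2, 8),
                      iiv_cv = c(0, 0.3),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    effect_scenario(grid$drug_form[i], grid$typical_effect[i], grid$iiv_cv[i])
  })
}

#' Inject a simulated treatment effect into the treated arm
#'
#' For subjects with \code{TRT = 1} an individual effect
#' \code{e_i = typical_effect + eta_i} is added to post-baseline scores:
#' the offset form adds \code{e_i} at every t > 0, the time-linear form adds
#' \code{e_i * t / 36}. Placebo-arm subjects and baseline values are
#' unchanged. With \code{typical_effect = 0} and no IIV the cohort is
#' returned unchanged apart from provenance metadata.
#'
#' @param cohort an allocated \code{trt_cohort}.
#' @param scenario an \code{\link{effect_scenario}}.
#' @param seed integer seed for the effect IIV draws.
#' @return the modified \code{trt_cohort}.
#' @export
inject_treatment_effect <- function(cohort, scenario, seed = NULL) {
  stopifnot(inherits(cohort, "trt_cohort"), inherits(scenario, "effect_scenario"))
  if (!isTRUE(cohort$meta$allocated)) {
    stopf("cohort has no arm labels; call randomize_allocation() first")
  }
  d <- cohort$data
  ids <- unique(d$ID)
  sd_e <- scenario$iiv_cv * scenario$typical_effect
  e <- with_seed(seed, {
    scenario$typical_effect + if (sd_e > 0) stats::rnorm(length(ids), 0, sd_e) else 0
  })
  e <- rep_len(e, length(ids))
  names(e) <- as.character(ids)
  treated <- d$TRT == 1
  post <- d$TIME > 0
  ei <- e[as.character(d$ID)]
  add <- ifelse(treated & post,
                if (scenario$drug_form == "offset") ei else ei * d$TIME / 36,
                0)
  d$DV <- d$DV + add
  truth <- cohort$truth
  if (!is.null(truth)) {
    tr_ids <- unique(d$ID[d$TRT == 1])
    truth$subjects$e_drug <- ifelse(truth$subjects$ID %in% tr_ids,
                                    e[as.character(truth$subjects$ID)], 0)
    truth$scenario <- scenario
    truth$injected <- data.frame(ID = d$ID, TIME = d$TIME, effect = add)
  }
  meta <- cohort$meta
  meta$provenance <- "effect-injected"
  new_cohort(d, truth, meta)
}

#' Randomize subjects 1:1 to two arms
#'
#' Assigns exactly \code{floor(n/2)} or \code{ceiling(n/2)} subjects per arm,
#' uniformly over balanced allocations.
#'
#' @param cohort a \code{trt_cohort} with at least 2 subjects.
#' @param seed integer seed.
#' @return the cohort with \code{TRT} labels set.
#' @export
randomize_allocation <- function(cohort, seed) {
  stopifnot(inherits(cohort, "trt_cohort"))
  ids <- unique(cohort$data$ID)
  n <- length(ids)
  if (n < 2) stopf("need at least 2 subjects to randomize")
  with_seed(seed, {
    n1 <- floor(n / 2)
    if (n %% 2 == 1 && stats::runif(1) < 0.5) n1 <- n1 + 1
    treated <- sample(ids, n1)
    d <- cohort$data
    d$TRT <- as.integer(d$ID %in% treated)
    meta <- cohort$meta
    meta$allocated <- TRUE
    new_cohort(d, cohort$truth, meta)
  })
}

#' Permute the treatment allocation
#'
#' Permutes arm labels across subjects, preserving the two arm sizes exactly;
#' scores and covariates are untouched.
#'
#' @param cohort an allocated \code{trt_cohort}.
#' @param seed integer seed.
#' @return the permuted cohort.
#' @export
permute_allocation <- function(cohort, seed) {
  stopifnot(inherits(cohort, "trt_cohort"))
  if (!isTRUE(cohort$meta$allocated)) {
    stopf("cohort has no arm labels to permute")
  }
  d <- cohort$data
  ids <- unique(d$ID)
  n1 <- length(unique(d$ID[d$TRT == 1]))
  with_seed(seed, {
    treated <- sample(ids, n1)
    d$TRT <- as.integer(d$ID %in% treated)
    meta <- cohort$meta
    meta$provenance <- "permuted"
    new_cohort(d, cohort$truth, meta)
  })
}
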