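# Marginal likelihood evaluation and population predictions.

full_params <- function(obj, params) {
  fx <- obj$fixed
  miss <- setdiff(names(fx), names(params))
  full <- c(params, fx[miss])
  need <- param_names(obj$spec)
  absent <- setdiff(need, names(full))
  if (length(absent)) stopf("missing parameters: %s", paste(absent, collapse = ", "))
  full[need]
}

#' Marginal objective function value (-2 log likelihood)
#'
#' Computes \code{-2 * sum_i log L_i} at the given parameters. For models
#' linear in all (Gaussian) random effects, \code{L_i} is the closed-form
#' multivariate normal density of subject i's observation vector; otherwise
#' it is a Laplace approximation around the per-subject empirical-Bayes
#' mode. For mixture models \code{L_i} is the probability-weighted sum of
#' the two sub-model likelihoods.
#'
#' @param model a \code{\link{model_spec}}.
#' @param cohort a \code{trt_cohort}.
#' @param params named numeric vector of parameters on the natural scale
#'   (see \code{\link{model_spec}} for names). Fixed parameters may be
#'   omitted.
#' @param method \code{"auto"} picks the exact closed form when available;
#'   \code{"closed_form"} errors for models that have none;
#'   \code{"laplace"} forces the generic per-subject Laplace approximation
#'   (the reference path, exact for linear-Gaussian models).
#' @return the OFV (scalar).
#' @export
marginal_ofv <- function(model, cohort, params,
                         method = c("auto", "closed_form", "laplace")) {
  method <- match.arg(method)
  obj <- compile_model(model, cohort)
  par <- full_params(obj, params)
  validate_params(par)
  if (method == "auto") return(sum(obj$nll_subj(par)))
  if (method == "closed_form") {
    if (obj$family != "linear") {
      stopf("model '%s' has no closed-form marginal likelihood", model_id(model))
    }
    return(sum(obj$nll_subj(par)))
  }
  # method == "laplace": generic reference path
  sum(laplace_ofv_subjects(model, obj, par))
}

laplace_ofv_subjects <- function(model, obj, par) {
  if (obj$family == "mixture") {
    p <- obj$p
    spec <- obj$spec
    c1 <- make_cond(model_spec(spec$placebo_form), p)
    c2 <- make_cond(model_spec(spec$placebo_form, spec$drug_form,
                               spec$drug_iiv, "all"), p)
    nll1 <- laplace_nll_subjects(c1, par)
    nll2 <- laplace_nll_subjects(c2, par)
    pm <- par[["th_mix"]]
    p1 <- (1 - p$trt_i) * pm + p$trt_i * (1 - pm)
    return(-2 * logsumexp2(log(p1) - nll1 / 2, log(1 - p1) - nll2 / 2))
  }
  cond <- obj$cond %||% make_cond(obj$spec, obj$p)
  laplace_nll_subjects(cond, par)
}

validate_params <- function(par) {
  vn <- grep("^om2", names(par), value = TRUE)
  if (any(par[vn] < 0)) stopf("variance components must be >= 0")
  if (par[["sig2"]] <= 0) stopf("sig2 must be > 0")
  if ("th_mix" %in% names(par) &&
      (par[["th_mix"]] < 0 || par[["th_mix"]] > 1)) {
    stopf("th_mix must be in [0, 1]")
  }
  if ("nu" %in% names(par) && par[["nu"]] <= 2) stopf("nu must exceed 2")
  invisible(TRUE)
}

#' Population mean prediction (random effects at zero)
#'
#' @inheritParams marginal_ofv
#' @return numeric vector of predictions, one per observation row (in
#'   subject-grouped order).
#' @export
predict_mean <- function(model, cohort, params) {
  obj <- compile_model(model, cohort)
  obj$mu(full_params(obj, params))
}
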