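# Declarative model library: placebo structural models, drug components,
# mixture models, and the string-id registry.

PLACEBO_FORMS <- c("pub", "texp", "ruviiv", "boxcox", "tdist")
DRUG_FORMS <- c("none", "offset", "tlin", "dm")
APPLIES <- c("treated_only", "all", "arm_specific", "mixture")

#' Construct a model specification
#'
#' A \code{model_spec} declares a placebo structural model, an optional drug
#' component, the population the drug component applies to, and any
#' parameters held fixed. Parameters are named:
#' \code{th_base, th_int} (baseline fixed effects), \code{th_slp,
#' th_slp_bmms} (slope fixed effects), \code{om2_base, om2_slp} (IIV
#' variances), \code{sig2} (residual variance), plus per form:
#' \code{th_rate} (time-exponential), \code{om2_ruv} (IIV on residual error),
#' \code{lambda} (Boxcox), \code{nu} (t-distribution df), \code{th_de}
#' and \code{om2_de} (drug effect, duplicated as \code{th_de0/th_de1},
#' \code{om2_de0/om2_de1} for arm-specific fits), \code{th_mix} (mixture
#' probability).
#'
#' @param placebo_form one of \code{"pub"} (published linear model),
#'   \code{"texp"} (time-exponential progression), \code{"ruviiv"} (IIV on
#'   residual error), \code{"boxcox"} (Boxcox-transformed baseline random
#'   effect), \code{"tdist"} (t-distributed baseline random effect).
#' @param drug_form one of \code{"none"}, \code{"offset"}, \code{"tlin"},
#'   \code{"dm"} (disease-modifying: multiplies the progression slope by
#'   \code{1 - (th_de + eta)}).
#' @param drug_iiv add a random effect on the drug parameter.
#' @param drug_applies_to \code{"treated_only"} (standard alternative
#'   hypothesis), \code{"all"} (shared drug model, structural-similarity
#'   null), \code{"arm_specific"} (duplicated drug parameters per arm,
#'   structural-similarity alternative), or \code{"mixture"} (subject-level
#'   two-component mixture, individual model averaging).
#' @param theta_mix_fixed for mixtures: fix the mixing probability at this
#'   value (e.g. 0.5 under the null) or \code{NA} to estimate it on the
#'   logit scale with arm-dependent component probabilities.
#' @param fixed named numeric vector of additional parameters held constant.
#' @return a \code{model_spec}.
#' @export
model_spec <- function(placebo_form = "pub", drug_form = "none",
                       drug_iiv = FALSE, drug_applies_to = "treated_only",
                       theta_mix_fixed = NULL, fixed = NULL) {
  placebo_form <- match.arg(placebo_form, PLACEBO_FORMS)
  drug_form <- match.arg(drug_form, DRUG_FORMS)
  drug_applies_to <- match.arg(drug_applies_to, APPLIES)
  if (drug_form == "none" && drug_iiv) stopf("drug_iiv requires a drug component")
  if (drug_form == "none" && drug_applies_to == "mixture") {
    stopf("a mixture model requires a drug component")
  }
  if (!is.null(theta_mix_fixed) && !is.na(theta_mix_fixed)) {
    if (theta_mix_fixed < 0 || theta_mix_fixed > 1) {
      stopf("theta_mix_fixed must be in [0, 1]")
    }
  }
  spec <- structure(list(placebo_form = placebo_form, drug_form = drug_form,
                         drug_iiv = drug_iiv,
                         drug_applies_to = drug_applies_to,
                         theta_mix_fixed = theta_mix_fixed,
                         fixed = fixed),
                    class = "model_spec")
  spec
}

#' The published placebo (disease) model
#'
#' Linear progression with baseline and slope both linear in the BMMS
#' covariate, additive Gaussian random effects on baseline and slope, and
#' additive residual error: 7 estimated parameters.
#'
#' @return a \code{model_spec}.
#' @export
published_placebo <- function() model_spec("pub")

#' A drug model component
#'
#' @param form \code{"offset"}: adds \code{th_de (+ eta)} at t > 0;
#'   \code{"tlin"}: adds \code{(th_de (+ eta)) * t / 36};
#'   \code{"dm"}: disease-modifying, multiplies the subject slope by
#'   \code{1 - (th_de (+ eta))}.
#' @param iiv logical, add inter-individual variability on the effect.
#' @return a \code{drug_component}.
#' @export
drug_model <- function(form = c("offset", "tlin", "dm"), iiv = FALSE) {
  form <- match.arg(form)
  structure(list(form = form, iiv = iiv), class = "drug_component")
}

#' Attach a drug component to a placebo model
#'
#' @param placebo a \code{model_spec} without drug component.
#' @param drug a \code{\link{drug_model}} component.
#' @param applies_to see \code{\link{model_spec}}.
#' @return a \code{model_spec}.
#' @export
add_drug <- function(placebo, drug, applies_to = "treated_only") {
  stopifnot(inherits(placebo, "model_spec"), inherits(drug, "drug_component"))
  model_spec(placebo$placebo_form, drug$form, drug$iiv, applies_to,
             theta_mix_fixed = placebo$theta_mix_fixed, fixed = placebo$fixed)
}

#' The four alternative placebo models
#'
#' The published model modified one component at a time: time-exponential
#' structural progression, IIV on the residual error magnitude, Boxcox
#' transformation of the baseline random effect, and t-distributed baseline
#' random effect. Each has exactly one more estimated parameter than the
#' published model.
#'
#' @return a named list of 4 \code{model_spec}s.
#' @export
alternative_placebos <- function() {
  list(texp = model_spec("texp"), ruviiv = model_spec("ruviiv"),
       boxcox = model_spec("boxcox"), tdist = model_spec("tdist"))
}

#' Subject-level mixture model (individual model averaging)
#'
#' Every subject is, with probability depending on its arm and the mixing
#' parameter, described either by the placebo model or by the placebo+drug
#' model (the drug component applies within the second mixture component
#' regardless of arm). Under the null the mixing probability is fixed at the
#' allocation rate (0.5); under the alternative it is estimated with
#' arm-dependent component probabilities
#' \code{Pr(placebo component) = (1 - TRT) * th_mix + TRT * (1 - th_mix)}.
#'
#' @param placebo a placebo \code{model_spec}.
#' @param drug a \code{\link{drug_model}} component.
#' @param theta_mix_fixed fix the mixing probability (0.5 for the null) or
#'   \code{NA} to estimate it.
#' @return a \code{model_spec} with \code{drug_applies_to = "mixture"}.
#' @export
mixture_model <- function(placebo, drug, theta_mix_fixed = 0.5) {
  stopifnot(inherits(placebo, "model_spec"), inherits(drug, "drug_component"))
  model_spec(placebo$placebo_form, drug$form, drug$iiv, "mixture",
             theta_mix_fixed = theta_mix_fixed, fixed = placebo$fixed)
}

# Names of the estimated parameters of a spec (order fixed).
param_names <- function(spec) {
  nm <- c("th_base", "th_int", "th_slp", "th_slp_bmms")
  nm <- c(nm, switch(spec$placebo_form, texp = "th_rate", boxcox = "lambda",
                     tdist = "nu", NULL))
  if (spec$drug_form != "none") {
    if (spec$drug_applies_to == "arm_specific") {
      nm <- c(nm, "th_de0", "th_de1")
    } else {
      nm <- c(nm, "th_de")
    }
  }
  nm <- c(nm, "om2_base", "om2_slp")
  if (spec$placebo_form == "ruviiv") nm <- c(nm, "om2_ruv")
  if (spec$drug_form != "none" && spec$drug_iiv) {
    nm <- c(nm, if (spec$drug_applies_to == "arm_specific") {
      c("om2_de0", "om2_de1")
    } else "om2_de")
  }
  nm <- c(nm, "sig2")
  if (spec$drug_applies_to == "mixture") nm <- c(nm, "th_mix")
  nm
}

# Transform kind per parameter name.
param_trans <- function(name) {
  if (grepl("^om2", name) || name == "sig2") return("log")
  if (name == "th_mix") return("logit")
  if (name == "nu") return("log2p")
  "id"
}

# Names of parameters fixed (not estimated) for a spec.
fixed_param_values <- function(spec) {
  fx <- spec$fixed %||% numeric(0)
  if (spec$drug_applies_to == "mixture" &&
      !is.null(spec$theta_mix_fixed) && !is.na(spec$theta_mix_fixed)) {
    fx <- c(fx, th_mix = spec$theta_mix_fixed)
  }
  fx
}

#' Number of estimated parameters of a model
#'
#' @param spec a \code{model_spec}.
#' @return integer count; the AIC penalty derives solely from this count.
#' @export
n_params <- function(spec) {
  length(setdiff(param_names(spec), names(fixed_param_values(spec))))
}

#' Resolve a model id string from the registry
#'
#' Ids are \code{"<placebo>"} or \code{"<placebo>+<drug>"} with placebo in
#' \code{pub, texp, ruviiv, boxcox, tdist} and drug in \code{offset, tlin,
#' dm}, optionally suffixed \code{_iiv}, e.g. \code{"pub+offset_iiv"}.
#'
#' @param id registry id string.
#' @param applies_to drug population, see \code{\link{model_spec}}.
#' @return a \code{model_spec}.
#' @export
model_from_id <- function(id, applies_to = "treated_only") {
  parts <- strsplit(id, "+", fixed = TRUE)[[1]]
  if (!parts[1] %in% PLACEBO_FORMS) stopf("unknown placebo form '%s'", parts[1])
  if (length(parts) == 1 || parts[2] == "none") return(model_spec(parts[1]))
  dr <- parts[2]
  iiv <- grepl("_iiv$", dr)
  form <- sub("_iiv$", "", dr)
  if (!form %in% c("offset", "tlin", "dm")) stopf("unknown drug form '%s'", form)
  model_spec(parts[1], form, iiv, applies_to)
}

#' Registry id of a model
#' @param spec a \code{model_spec}.
#' @return a string id.
#' @export
model_id <- function(spec) {
  if (spec$drug_form == "none") return(spec$placebo_form)
  paste0(spec$placebo_form, "+", spec$drug_form,
         if (spec$drug_iiv) "_iiv" else "",
         switch(spec$drug_applies_to, treated_only = "", all = "@all",
                arm_specific = "@arms", mixture = "@mix"))
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%d estimated parameters)\n",
              model_id(x), n_params(x)))
  invisible(x)
}

#' Candidate model set for the testing approaches
#'
#' @param placebos a single placebo \code{model_spec} (list of several for
#'   the placebo-and-drug model-averaging approach).
#' @param drug_ids character vector of drug component ids among
#'   \code{"offset", "offset_iiv", "tlin", "tlin_iiv", "dm", "dm_iiv"}.
#'   Defaults to the type-I-error set (offset and disease-modifying, with and
#'   without IIV).
#' @return a \code{candidate_set}.
#' @export
candidate_set <- function(placebos = published_placebo(),
                          drug_ids = c("offset", "offset_iiv", "dm", "dm_iiv")) {
  if (inherits(placebos, "model_spec")) placebos <- list(placebos)
  if (length(placebos) == 0 || length(drug_ids) == 0) {
    stopf("candidate set must contain a placebo model and drug models")
  }
  if (anyDuplicated(drug_ids)) stopf("drug models must be distinct")
  drugs <- lapply(drug_ids, function(id) {
    iiv <- grepl("_iiv$", id)
    drug_model(sub("_iiv$", "", id), iiv)
  })
  names(drugs) <- drug_ids
  structure(list(placebos = placebos, drugs = drugs), class = "candidate_set")
}

#' Drug candidate ids used for power assessment
#'
#' Offset and time-linear components (no disease-model assumption in the
#' simulated effect), each with and without IIV.
#' @return character vector of drug ids.
#' @export
power_drug_set <- function() c("offset", "offset_iiv", "tlin", "tlin_iiv")
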