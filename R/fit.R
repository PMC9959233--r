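# Maximum-likelihood fitting, fit results, dOFV and the chi-square cutoff.

#' Fit a model to a cohort by maximum likelihood
#'
#' Variance parameters are optimized on the log scale (floor 1e-10), the
#' mixing probability on the logit scale. Models linear in all random
#' effects are fitted with the fixed effects and the residual variance
#' profiled out by generalized least squares, so the numerical search runs
#' only over variance ratios (plus any structural nonlinear parameter);
#' other families are fitted over the full transformed parameter vector.
#' Optimization uses a quasi-Newton search with up to \code{max_restarts}
#' deterministically jittered restarts before a fit is declared failed.
#' Failures are reported through \code{status}, never raised.
#'
#' @param model a \code{\link{model_spec}}.
#' @param cohort a \code{trt_cohort}.
#' @param inits optional named vector of initial values on the natural
#'   scale (overrides the data-driven defaults; used for warm starts).
#' @param options list: \code{max_restarts} (default 3), \code{grad_tol}
#'   (projected-gradient infinity-norm tolerance on the fitting scale,
#'   default 0.5), \code{iter_max}, \code{eval_max}.
#' @return a \code{fit_result} with elements \code{params} (full named
#'   vector on the natural scale), \code{ofv}, \code{n_params},
#'   \code{status} ("converged" or "failed") and \code{diagnostics}.
#' @export
fit <- function(model, cohort, inits = NULL, options = list()) {
  opt <- utils::modifyList(list(max_restarts = 3L, grad_tol = 1.0,
                                iter_max = 500L, eval_max = 2000L), options)
  obj <- tryCatch(compile_model(model, cohort), error = function(e) e)
  if (inherits(obj, "error")) {
    return(new_fit_failed(model, conditionMessage(obj)))
  }
  ini <- obj$inits()
  if (!is.null(inits)) {
    keep <- intersect(names(inits), param_names(model))
    ini[keep] <- inits[keep]
  }
  res <- tryCatch({
    if (obj$fit_path == "profiled") fit_profiled(obj, ini, opt)
    else fit_full(obj, ini, opt)
  }, error = function(e) list(error = conditionMessage(e)))
  if (!is.null(res$error)) return(new_fit_failed(model, res$error))

  status <- if (is.finite(res$ofv) && res$grad_norm <= opt$grad_tol) {
    "converged"
  } else "failed"
  structure(list(spec = model, model_id = model_id(model),
                 params = res$params, ofv = res$ofv,
                 n_params = n_params(model), status = status,
                 diagnostics = list(grad_norm = res$grad_norm,
                                    convergence = res$convergence,
                                    iterations = res$iterations,
                                    restarts = res$restarts,
                                    message = res$message)),
            class = "fit_result")
}

new_fit_failed <- function(model, msg) {
  structure(list(spec = model, model_id = model_id(model),
                 params = NULL, ofv = NA_real_, n_params = n_params(model),
                 status = "failed",
                 diagnostics = list(grad_norm = NA_real_, convergence = NA,
                                    iterations = NA, restarts = NA,
                                    message = msg)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s | ofv %.3f | %d params | %s\n",
              x$model_id, x$ofv, x$n_params, x$status))
  invisible(x)
}

# infinity norm of the gradient projected on the feasible directions
proj_grad_norm <- function(f, x, lower, upper) {
  g <- tryCatch(num_grad(f, x), error = function(e) rep(NA_real_, length(x)))
  if (anyNA(g)) return(Inf)
  at_lo <- x <= lower + 1e-8
  at_hi <- x >= upper - 1e-8
  g[at_lo & g > 0] <- 0
  g[at_hi & g < 0] <- 0
  max(abs(g))
}

jitter_start <- function(x0, k) {
  if (k == 0) return(x0)
  s <- rep_len(c(1, -1), length(x0)) * (1 + (seq_along(x0) %% 3))
  x0 + 0.35 * k * s / max(abs(s))
}

run_nlminb <- function(f, x0, lower, upper, opt) {
  best <- NULL
  best_gn <- Inf
  restarts <- 0L
  for (k in 0:opt$max_restarts) {
    xk <- pmin(pmax(jitter_start(x0, k), lower), upper)
    ans <- tryCatch(
      stats::nlminb(xk, f, lower = lower, upper = upper,
                    control = list(iter.max = opt$iter_max,
                                   eval.max = opt$eval_max,
                                   rel.tol = 1e-9)),
      error = function(e) NULL)
    restarts <- k
    if (is.null(ans) || !is.finite(ans$objective)) next
    if (ans$convergence != 0) {
      # quasi-Newton stalls ("false convergence") on objectives that carry
      # ~1e-8 noise from per-subject inner optimizations; a simplex polish
      # followed by one more descent reliably escapes
      fn <- function(x) f(pmin(pmax(x, lower), upper))
      nm <- tryCatch(stats::optim(ans$par, fn, method = "Nelder-Mead",
                                  control = list(maxit = 500,
                                                 reltol = 1e-12)),
                     error = function(e) NULL)
      if (!is.null(nm) && is.finite(nm$value) &&
          nm$value < ans$objective - 1e-10) {
        st <- pmin(pmax(nm$par, lower), upper)
        ans2 <- tryCatch(
          stats::nlminb(st, f, lower = lower, upper = upper,
                        control = list(iter.max = opt$iter_max,
                                       eval.max = opt$eval_max,
                                       rel.tol = 1e-9)),
          error = function(e) NULL)
        if (!is.null(ans2) && is.finite(ans2$objective) &&
            ans2$objective <= nm$value) {
          ans <- ans2
        } else {
          ans$par <- st
          ans$objective <- nm$value
        }
      }
    }
    gn <- proj_grad_norm(f, ans$par, lower, upper)
    if (is.null(best) || ans$objective < best$objective) {
      best <- ans
      best_gn <- gn
    }
    if (gn <= opt$grad_tol) {
      return(list(ans = ans, grad_norm = gn, restarts = k))
    }
  }
  if (is.null(best)) return(NULL)
  list(ans = best, grad_norm = best_gn, restarts = restarts)
}

fit_profiled <- function(obj, ini, opt) {
  struct <- obj$struct
  om_names <- c("om2_base", "om2_slp")
  spec <- obj$spec
  if (spec$drug_iiv && spec$drug_form %in% c("offset", "tlin")) {
    om_names <- c(om_names, if (spec$drug_applies_to == "arm_specific") {
      c("om2_de0", "om2_de1")
    } else "om2_de")
  }
  x0 <- c(unname(ini[struct]), log(pmax(ini[om_names] / ini[["sig2"]], 1e-8)))
  lower <- c(ifelse(struct == "th_rate", -0.12, -1e3), rep(log(1e-12), length(om_names)))
  upper <- c(ifelse(struct == "th_rate", 0.12, 1e3), rep(log(1e8), length(om_names)))
  bigpen <- 1e12
  f <- function(outer) {
    v <- obj$profiled(outer)$ofv
    if (!is.finite(v)) bigpen else v
  }
  f0 <- f(x0)
  sc <- vapply(seq_along(x0), function(k) {
    h <- 1e-3 * max(1, abs(x0[k]))
    xp <- x0; xp[k] <- min(xp[k] + h, upper[k])
    xm <- x0; xm[k] <- max(xm[k] - h, lower[k])
    hk <- (f(xp) - 2 * f0 + f(xm)) / ((xp[k] - x0[k]) * (x0[k] - xm[k]) +
                                        1e-300)
    min(1 / sqrt(max(hk, 1e-2)), 10)
  }, numeric(1))
  fs <- function(z) f(z * sc)
  r <- run_nlminb(fs, x0 / sc, lower / sc, upper / sc, opt)
  if (is.null(r)) stop("optimizer failed on all starts")
  r$ans$par <- r$ans$par * sc
  sol <- obj$profiled(r$ans$par)
  ns <- length(struct)
  spar <- if (ns) stats::setNames(r$ans$par[seq_len(ns)], struct) else numeric(0)
  des <- linear_design(obj, c(spar, obj$fixed))
  beta <- stats::setNames(as.vector(sol$beta), des$xnames)
  psi <- exp(r$ans$par[(ns + 1):length(r$ans$par)])
  om <- stats::setNames(psi * sol$sig2, om_names)
  params <- c(beta, spar, om, sig2 = sol$sig2)
  params <- full_params(obj, params)
  list(params = params, ofv = sol$ofv, grad_norm = r$grad_norm,
       convergence = r$ans$convergence, iterations = r$ans$iterations,
       restarts = r$restarts, message = r$ans$message)
}

fit_full <- function(obj, ini, opt) {
  est <- obj$est
  kinds <- obj$trans
  x0 <- mapply(to_trans, ini[est], kinds)
  lower <- vapply(kinds, trans_lower, numeric(1))
  upper <- vapply(kinds, trans_upper, numeric(1))
  lower[est == "th_rate"] <- -0.12; upper[est == "th_rate"] <- 0.12
  lower[est == "lambda"] <- -3; upper[est == "lambda"] <- 3
  bigpen <- 1e12
  # fast inverse transforms and fixed-parameter merge for the hot objective
  i_log <- which(kinds == "log")
  i_logit <- which(kinds == "logit")
  i_log2p <- which(kinds == "log2p")
  pnames <- param_names(obj$spec)
  fxm <- obj$fixed[setdiff(names(obj$fixed), est)]
  f <- function(tv) {
    nat <- tv
    if (length(i_log)) nat[i_log] <- exp(tv[i_log])
    if (length(i_logit)) nat[i_logit] <- stats::plogis(tv[i_logit])
    if (length(i_log2p)) nat[i_log2p] <- 2 + exp(tv[i_log2p])
    names(nat) <- est
    full <- c(nat, fxm)[pnames]
    v <- sum(obj$nll_subj(full))
    if (!is.finite(v)) bigpen else v
  }
  # one-time diagonal-curvature scaling: the transformed coordinates have
  # curvatures spanning several orders of magnitude (e.g. covariate-by-time
  # fixed effects), which cripples the quasi-Newton search otherwise
  f0 <- f(x0)
  sc <- vapply(seq_along(x0), function(k) {
    h <- 1e-3 * max(1, abs(x0[k]))
    xp <- x0; xp[k] <- min(xp[k] + h, upper[k])
    xm <- x0; xm[k] <- max(xm[k] - h, lower[k])
    hk <- (f(xp) - 2 * f0 + f(xm)) / ((xp[k] - x0[k]) * (x0[k] - xm[k]) +
                                        1e-300)
    min(1 / sqrt(max(hk, 1e-2)), 10)
  }, numeric(1))
  fs <- function(z) f(z * sc)
  r <- run_nlminb(fs, x0 / sc, lower / sc, upper / sc, opt)
  if (is.null(r)) stop("optimizer failed on all starts")
  nat <- stats::setNames(mapply(from_trans, r$ans$par * sc, kinds), est)
  params <- full_params(obj, nat)
  list(params = params, ofv = r$ans$objective, grad_norm = r$grad_norm,
       convergence = r$ans$convergence, iterations = r$ans$iterations,
       restarts = r$restarts, message = r$ans$message)
}

#' Akaike information criterion of a fit
#' @param fit a \code{fit_result}.
#' @return \code{ofv + 2 * n_params}.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  fit$ofv + 2 * fit$n_params
}

#' Flat summary table of a set of fits
#'
#' One row per fit: model id, OFV, number of estimated parameters, AIC and
#' convergence status (the layout of a model-comparison appendix table).
#'
#' @param fits a \code{fit_result} or list of them.
#' @return a data.frame.
#' @export
fit_summary <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model_id, ofv = f$ofv, n_params = f$n_params,
               aic = if (is.finite(f$ofv)) aic(f) else NA_real_,
               status = f$status)
  }))
  rownames(out) <- NULL
  out
}

#' Likelihood ratio test statistic dOFV
#'
#' \code{ofv(H1) - ofv(H0)}: negative values favor the alternative.
#'
#' @param fit_h0,fit_h1 converged \code{fit_result}s of nested models.
#' @return the dOFV (scalar).
#' @export
delta_ofv <- function(fit_h0, fit_h1) {
  stopifnot(inherits(fit_h0, "fit_result"), inherits(fit_h1, "fit_result"))
  if (fit_h0$status != "converged" || fit_h1$status != "converged") {
    stopf("delta_ofv requires two converged fits")
  }
  fit_h1$ofv - fit_h0$ofv
}

#' Chi-square critical dOFV cutoff
#'
#' Returns the negative of the upper-alpha quantile of a chi-square
#' distribution: the null hypothesis is rejected when the observed dOFV is
#' below this (negative) cutoff. Every additional parameter, including
#' variance components, counts as one degree of freedom.
#'
#' @param df degrees of freedom (number of additional H1 parameters).
#' @param alpha test level.
#' @return negative scalar cutoff.
#' @export
chi2_critical <- function(df, alpha = 0.05) {
  if (df < 1 || df != round(df)) stopf("df must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  -stats::qchisq(1 - alpha, df)
}

#' Simulate a new cohort from a fitted linear-Gaussian model
#'
#' Draws new random effects and residual errors at the observed design
#' points (same subjects, visits, covariates and arm labels) from the
#' fitted model. Used to build the simulated null distribution of the
#' combined LRT.
#'
#' @param fit a converged \code{fit_result} of a model linear in its random
#'   effects (e.g. the published placebo model).
#' @param cohort the cohort the model was fitted to.
#' @param seed integer seed.
#' @return a new \code{trt_cohort} with simulated scores.
#' @export
simulate_from_fit <- function(fit, cohort, seed) {
  stopifnot(inherits(fit, "fit_result"))
  if (fit$status != "converged") stopf("cannot simulate from a failed fit")
  obj <- compile_model(fit$spec, cohort)
  if (obj$family != "linear") {
    stopf("simulation is supported for linear-Gaussian models only")
  }
  p <- obj$p
  dv <- obj$sim_dv(full_params(obj, fit$params), seed)
  d <- data.frame(ID = rep(p$ids, p$len), TIME = p$t, DV = dv,
                  TRT = p$trt, BMMS = p$bmms)
  meta <- cohort$meta
  meta$provenance <- "h0-simulated"
  new_cohort(d, NULL, meta)
}
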