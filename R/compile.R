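# Internal: compile a model_spec against a cohort into likelihood evaluators.
#
# Families:
#   linear  - linear-Gaussian in all random effects: closed-form marginal
#             likelihood; fitted with beta and sig2 profiled out by GLS.
#   dmfast  - published placebo + disease-modifying drug with IIV: joint
#             Laplace computed in C++ by exact profiling of the two linear
#             random effects and a 1-D Newton search over the drug effect.
#   laplace - everything else (Boxcox / t-distributed baseline effect, IIV
#             on residual error, disease-modifying IIV on non-linear
#             placebos): generic per-subject Laplace approximation in R.
#   mixture - subject-level two-component mixture of two compiled models.

prep_cohort <- function(cohort) {
  d <- cohort$data
  ids <- unique(d$ID)
  ord <- order(match(d$ID, ids))
  d <- d[ord, , drop = FALSE]
  id_idx <- match(d$ID, ids)
  len <- as.integer(tabulate(id_idx, nbins = length(ids)))
  start <- as.integer(cumsum(c(1L, len[-length(len)])))
  first <- start
  list(y = d$DV, t = d$TIME, bmms = d$BMMS, trt = d$TRT,
       id_idx = id_idx, start = start, len = len,
       m = length(ids), n_obs = nrow(d),
       trt_i = d$TRT[first], bmms_i = d$BMMS[first], ids = ids)
}

# progression time transform g(t); linear placebo: g = t
gt_build <- function(spec, p) {
  if (spec$placebo_form == "texp") {
    function(par) {
      r <- par[["th_rate"]]
      if (abs(r) < 1e-8) p$t else (exp(r * p$t) - 1) / r
    }
  } else {
    function(par) p$t
  }
}

# subject-level drug indicator
drug_flag <- function(spec, p) {
  switch(spec$drug_applies_to,
    treated_only = p$trt_i,
    all = rep(1L, p$m),
    arm_specific = rep(1L, p$m),
    mixture = rep(1L, p$m))
}

# per-subject drug fixed effect / variance names resolved to values
subj_drug_pars <- function(spec, p, par) {
  if (spec$drug_applies_to == "arm_specific") {
    th <- c(par[["th_de0"]], par[["th_de1"]])[p$trt_i + 1L]
    om <- if (spec$drug_iiv) {
      c(par[["om2_de0"]], par[["om2_de1"]])[p$trt_i + 1L]
    } else rep(0, p$m)
  } else {
    th <- rep(par[["th_de"]], p$m)
    om <- rep(if (spec$drug_iiv) par[["om2_de"]] else 0, p$m)
  }
  list(th = th, om = om)
}

compile_model <- function(spec, cohort) {
  p <- prep_cohort(cohort)
  if (spec$drug_applies_to == "mixture") {
    return(compile_mixture(spec, cohort, p))
  }
  family <- if (spec$placebo_form %in% c("boxcox", "tdist", "ruviiv")) {
    "laplace"
  } else if (spec$drug_form == "dm" && spec$drug_iiv) {
    if (spec$placebo_form == "pub") "dmfast" else "laplace"
  } else {
    "linear"
  }
  est <- setdiff(param_names(spec), names(fixed_param_values(spec)))
  obj <- list(spec = spec, p = p, family = family, est = est,
              fixed = fixed_param_values(spec),
              trans = vapply(est, param_trans, character(1)),
              gt = gt_build(spec, p), dflag = drug_flag(spec, p))
  obj <- switch(family,
    linear = compile_linear(obj),
    dmfast = compile_dmfast(obj),
    laplace = compile_laplace_family(obj))
  obj$cond <- make_cond(spec, p)
  obj$inits <- make_inits(spec, p)
  obj
}

# ---- linear-Gaussian family -------------------------------------------------

# Shared design pattern columns G plus the mapping of fixed-effect columns
# onto (pattern column, bmms power): column a of X_i is
# G_i[, xg[a]] * bmms_i^xs[a]; the random-effect design is G[, zg].
linear_design <- function(obj, par) {
  spec <- obj$spec; p <- obj$p
  gt <- obj$gt(par)
  dobs <- obj$dflag[p$id_idx]
  cobs <- rep(1, p$n_obs)
  if (spec$drug_form == "dm") {
    thd <- subj_drug_pars(spec, p, par)$th
    cobs <- 1 - thd[p$id_idx] * dobs
  }
  G <- cbind(rep(1, p$n_obs), gt * cobs)
  xnames <- c("th_base", "th_int", "th_slp", "th_slp_bmms")
  xg <- c(1L, 1L, 2L, 2L)
  xs <- c(0L, 1L, 0L, 1L)
  zg <- c(1L, 2L)
  om_names <- c("om2_base", "om2_slp")
  if (spec$drug_form %in% c("offset", "tlin")) {
    base_col <- if (spec$drug_form == "offset") as.numeric(p$t > 0) else p$t / 36
    if (spec$drug_applies_to == "arm_specific") {
      G <- cbind(G, base_col * (p$trt == 0), base_col * (p$trt == 1))
      xnames <- c(xnames, "th_de0", "th_de1")
      xg <- c(xg, 3L, 4L); xs <- c(xs, 0L, 0L)
      if (spec$drug_iiv) {
        zg <- c(zg, 3L, 4L)
        om_names <- c(om_names, "om2_de0", "om2_de1")
      }
    } else {
      G <- cbind(G, base_col * dobs)
      xnames <- c(xnames, "th_de")
      xg <- c(xg, 3L); xs <- c(xs, 0L)
      if (spec$drug_iiv) {
        zg <- c(zg, 3L)
        om_names <- c(om_names, "om2_de")
      }
    }
  }
  list(G = G, xg = xg, xs = xs, zg = zg, xnames = xnames,
       om_names = om_names)
}

# mean X beta expressed through the pattern columns
design_mu <- function(des, p, beta) {
  mu <- numeric(p$n_obs)
  bobs <- p$bmms
  for (a in seq_along(des$xnames)) {
    col <- des$G[, des$xg[a]]
    if (des$xs[a] == 1L) col <- col * bobs
    mu <- mu + beta[[des$xnames[a]]] * col
  }
  mu
}

# subject design groups: subjects with the same visit pattern, arm and drug
# flag share their marginal covariance for any parameter value
design_groups <- function(p, dflag) {
  tkey <- vapply(seq_len(p$m), function(i) {
    paste(p$t[seq.int(p$start[i], length.out = p$len[i])], collapse = ",")
  }, character(1))
  key <- paste(tkey, p$trt_i, dflag, sep = "|")
  gid <- match(key, unique(key))
  list(gid = as.integer(gid), gfirst = as.integer(match(seq_len(max(gid)), gid)))
}

compile_linear <- function(obj) {
  spec <- obj$spec; p <- obj$p
  struct <- character(0)
  if (spec$placebo_form == "texp") struct <- "th_rate"
  if (spec$drug_form == "dm") {
    struct <- c(struct, if (spec$drug_applies_to == "arm_specific") {
      c("th_de0", "th_de1")
    } else "th_de")
  }
  obj$struct <- struct
  grp <- design_groups(p, obj$dflag)
  # the design depends on parameters only through `struct`; cache it when
  # there are none (the common offset / time-linear / placebo case)
  des_cache <- if (length(struct) == 0) linear_design(obj, obj$fixed) else NULL
  get_des <- function(par) des_cache %||% linear_design(obj, par)

  obj$nll_subj <- function(par) {
    des <- get_des(par)
    mu <- design_mu(des, p, par)
    om <- unname(par[des$om_names])
    cpp_nll_lin(p$y - mu, des$G, des$zg, om, par[["sig2"]],
                p$start, p$len, grp$gid, grp$gfirst)
  }
  obj$mu <- function(par) design_mu(get_des(par), p, par)
  obj$sim_dv <- function(par, seed) {
    des <- get_des(par)
    mu <- design_mu(des, p, par)
    om <- unname(par[des$om_names])
    Z <- des$G[, des$zg, drop = FALSE]
    with_seed(seed, {
      eta <- matrix(stats::rnorm(p$m * length(om), 0,
                                 rep(sqrt(pmax(om, 0)), each = p$m)),
                    p$m, length(om))
      mu + rowSums(Z * eta[p$id_idx, , drop = FALSE]) +
        stats::rnorm(p$n_obs, 0, sqrt(par[["sig2"]]))
    })
  }
  # profiled objective over (struct params, log variance ratios)
  obj$fit_path <- "profiled"
  obj$profiled <- function(outer) {
    ns <- length(struct)
    par <- numeric(0)
    if (ns) { par <- outer[seq_len(ns)]; names(par) <- struct }
    des <- get_des(c(par, obj$fixed))
    psi <- exp(outer[(ns + 1):length(outer)])
    cpp_gls_profile(p$y, des$G, des$xg, des$xs, des$zg, psi, p$bmms_i,
                    p$start, p$len, grp$gid, grp$gfirst)
  }
  obj
}

# ---- dmfast family ----------------------------------------------------------

compile_dmfast <- function(obj) {
  spec <- obj$spec; p <- obj$p
  sums <- list(
    n = as.numeric(p$len),
    St = as.vector(rowsum(p$t, p$id_idx)),
    Stt = as.vector(rowsum(p$t^2, p$id_idx)),
    Sy = as.vector(rowsum(p$y, p$id_idx)),
    Sty = as.vector(rowsum(p$t * p$y, p$id_idx)),
    Syy = as.vector(rowsum(p$y^2, p$id_idx)))
  obj$nll_subj <- function(par) {
    dp <- subj_drug_pars(spec, p, par)
    base <- par[["th_base"]] + par[["th_int"]] * p$bmms_i
    slope <- par[["th_slp"]] + par[["th_slp_bmms"]] * p$bmms_i
    cpp_nll_dm_iiv(sums$n, sums$St, sums$Stt, sums$Sy, sums$Sty, sums$Syy,
                   base, slope, as.numeric(obj$dflag), dp$th, dp$om,
                   par[["om2_base"]], par[["om2_slp"]], par[["sig2"]])
  }
  obj$mu <- function(par) {
    dp <- subj_drug_pars(spec, p, par)
    base <- par[["th_base"]] + par[["th_int"]] * p$bmms
    slope <- par[["th_slp"]] + par[["th_slp_bmms"]] * p$bmms
    cf <- 1 - (dp$th * obj$dflag)[p$id_idx]
    base + slope * cf * p$t
  }
  obj$fit_path <- "full"
  obj
}

# ---- generic Laplace family -------------------------------------------------

compile_laplace_family <- function(obj) {
  cond <- make_cond(obj$spec, obj$p)
  obj$nll_subj <- function(par) laplace_nll_subjects(cond, par)
  obj$mu <- function(par) cond_mu_pop(cond, par)
  obj$fit_path <- "full"
  obj
}

# ---- mixture family ---------------------------------------------------------

compile_mixture <- function(spec, cohort, p) {
  comp1 <- compile_model(model_spec(spec$placebo_form), cohort)
  comp2 <- compile_model(model_spec(spec$placebo_form, spec$drug_form,
                                    spec$drug_iiv, "all"), cohort)
  est <- setdiff(param_names(spec), names(fixed_param_values(spec)))
  obj <- list(spec = spec, p = p, family = "mixture", est = est,
              fixed = fixed_param_values(spec),
              trans = vapply(est, param_trans, character(1)),
              comp1 = comp1, comp2 = comp2, fit_path = "full")
  obj$nll_subj <- function(par) {
    nll1 <- comp1$nll_subj(par)
    nll2 <- comp2$nll_subj(par)
    pm <- par[["th_mix"]]
    p1 <- (1 - p$trt_i) * pm + p$trt_i * (1 - pm)
    -2 * logsumexp2(log(p1) - nll1 / 2, log(1 - p1) - nll2 / 2)
  }
  obj$mu <- function(par) {
    pm <- par[["th_mix"]]
    p1 <- ((1 - p$trt_i) * pm + p$trt_i * (1 - pm))[p$id_idx]
    p1 * comp1$mu(par) + (1 - p1) * comp2$mu(par)
  }
  obj$inits <- make_inits(spec, p)
  obj$cond <- NULL # reference Laplace handled per component in marginal_ofv
  obj
}

# ---- data-driven initial values --------------------------------------------

make_inits <- function(spec, p) {
  function() {
    n <- p$len; idx <- p$id_idx
    St <- as.vector(rowsum(p$t, idx)); Stt <- as.vector(rowsum(p$t^2, idx))
    Sy <- as.vector(rowsum(p$y, idx)); Sty <- as.vector(rowsum(p$t * p$y, idx))
    Syy <- as.vector(rowsum(p$y^2, idx))
    denom <- Stt - St^2 / n
    slope_i <- ifelse(denom > 1e-9, (Sty - St * Sy / n) / pmax(denom, 1e-9), 0)
    int_i <- (Sy - slope_i * St) / n
    sse <- Syy + n * int_i^2 + slope_i^2 * Stt + 2 * int_i * slope_i * St -
      2 * int_i * Sy - 2 * slope_i * Sty
    dfree <- pmax(n - 2, 0)
    sig2_0 <- if (sum(dfree) > 0) max(sum(sse) / sum(dfree), 0.5) else 1
    fit2 <- function(yv) { # OLS of yv on bmms
      b <- stats::cov(p$bmms_i, yv) / max(stats::var(p$bmms_i), 1e-9)
      a <- mean(yv) - b * mean(p$bmms_i)
      c(a, b, stats::var(yv - a - b * p$bmms_i))
    }
    fb <- fit2(int_i); fs <- fit2(slope_i)
    ini <- c(th_base = fb[1], th_int = fb[2],
             th_slp = fs[1], th_slp_bmms = fs[2],
             om2_base = max(fb[3] - sig2_0 / mean(n), 0.05),
             om2_slp = max(fs[3] * 0.8, 1e-4), sig2 = sig2_0)
    if (spec$placebo_form == "texp") ini["th_rate"] <- 0.005
    if (spec$placebo_form == "boxcox") ini["lambda"] <- 0.2
    if (spec$placebo_form == "tdist") ini["nu"] <- 10
    if (spec$placebo_form == "ruviiv") ini["om2_ruv"] <- 0.01
    if (spec$drug_form != "none") {
      # crude arm contrast from per-subject OLS intercepts and slopes
      d1 <- p$trt_i == 1
      de0 <- if (any(d1) && any(!d1)) {
        mean(slope_i[d1]) * 36 - mean(slope_i[!d1]) * 36 +
          mean(int_i[d1]) - mean(int_i[!d1])
      } else 0
      de0 <- max(min(de0, 50), -50)
      if (spec$drug_form == "dm") de0 <- 0.05
      if (spec$drug_applies_to == "arm_specific") {
        ini["th_de0"] <- de0 / 2; ini["th_de1"] <- de0 / 2
        if (spec$drug_iiv) { ini["om2_de0"] <- 0.2; ini["om2_de1"] <- 0.2 }
      } else {
        ini["th_de"] <- de0
        if (spec$drug_iiv) {
          ini["om2_de"] <- if (spec$drug_form == "dm") 0.02 else
            max((0.3 * abs(de0))^2, 0.2)
        }
      }
    }
    if (spec$drug_applies_to == "mixture") ini["th_mix"] <- 0.6
    ini
  }
}
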