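# Generic per-subject Laplace approximation of the marginal likelihood.
#
# This is the reference integration path: it works for every non-mixture
# model family (and is exact for models linear in Gaussian random effects,
# where the joint -2 log density is quadratic). The hot code paths use the
# closed form or the specialised C++ kernel instead; tests assert agreement.
#
# The per-subject conditional objective is built by a factory that hoists
# every parameter into a local once per outer evaluation: the inner search
# runs this function thousands of times per fit.

LOG2PI <- log(2 * pi)

make_cond <- function(spec, p) {
  if (spec$drug_applies_to == "mixture") {
    stopf("make_cond is defined per mixture component")
  }
  eta_names <- c("e_base", "e_slp",
                 if (spec$placebo_form == "ruviiv") "e_ruv",
                 if (spec$drug_form != "none" && spec$drug_iiv) "e_de")
  q <- length(eta_names)
  rows <- lapply(seq_len(p$m), function(i) {
    seq.int(p$start[i], length.out = p$len[i])
  })
  yl <- lapply(rows, function(r) p$y[r])
  tl <- lapply(rows, function(r) p$t[r])
  postl <- lapply(tl, function(tt) as.numeric(tt > 0))
  n_i <- p$len
  dflag <- drug_flag(spec, p)
  has_ruv <- spec$placebo_form == "ruviiv"
  has_drug <- spec$drug_form != "none"
  has_de_eta <- has_drug && spec$drug_iiv
  k_ruv <- 3L
  k_de <- if (has_ruv) 4L else 3L
  form <- spec$drug_form
  pform <- spec$placebo_form

  factory <- function(par) {
    basev <- par[["th_base"]] + par[["th_int"]] * p$bmms_i
    slopev <- par[["th_slp"]] + par[["th_slp_bmms"]] * p$bmms_i
    gtl <- if (pform == "texp") {
      r <- par[["th_rate"]]
      if (abs(r) < 1e-8) tl else lapply(tl, function(tt) expm1(r * tt) / r)
    } else tl
    sig2 <- par[["sig2"]]
    om2_base <- par[["om2_base"]]; om2_slp <- par[["om2_slp"]]
    lam <- if (pform == "boxcox") par[["lambda"]] else 0
    nu <- if (pform == "tdist") par[["nu"]] else 0
    s1t <- sqrt(om2_base)
    inv_ob <- 1 / om2_base; lob <- LOG2PI + log(om2_base)
    inv_os <- 1 / om2_slp; los <- LOG2PI + log(om2_slp)
    om2_ruv <- if (has_ruv) par[["om2_ruv"]] else 0
    inv_or <- if (has_ruv) 1 / om2_ruv else 0
    lor <- if (has_ruv) LOG2PI + log(om2_ruv) else 0
    if (has_drug) {
      dp <- subj_drug_pars(spec, p, par)
      thd <- dp$th * (dflag > 0)
      omd <- dp$om * (dflag > 0)
    }
    # prior scales standardizing the inner search
    sds <- matrix(1, q, p$m)
    sds[1, ] <- s1t
    sds[2, ] <- sqrt(om2_slp)
    if (has_ruv) sds[k_ruv, ] <- sqrt(om2_ruv)
    if (has_de_eta) sds[k_de, ] <- ifelse(omd > 0, sqrt(omd), 1)
    sds <- pmax(sds, 1e-6)

    h <- function(i, eta) {
      e1 <- eta[1]
      b1 <- if (pform == "boxcox") {
        if (abs(lam) < 1e-12) e1 else expm1(lam * e1) / lam
      } else e1
      base <- basev[i] + b1
      slope <- slopev[i] + eta[2]
      gt <- gtl[[i]]
      if (has_drug) {
        de <- thd[i] + if (has_de_eta && dflag[i] > 0) eta[k_de] else 0
        mu <- switch(form,
          offset = base + slope * gt + de * postl[[i]],
          tlin = base + slope * gt + de * tl[[i]] / 36,
          dm = base + slope * (1 - de) * gt)
      } else {
        mu <- base + slope * gt
      }
      s2 <- if (has_ruv) sig2 * exp(2 * eta[k_ruv]) else sig2
      r <- yl[[i]] - mu
      v <- sum(r * r) / s2 + n_i[i] * (LOG2PI + log(s2))
      # random-effect priors
      v <- v + if (pform == "tdist") {
        -2 * (stats::dt(e1 / s1t, df = nu, log = TRUE) - log(s1t))
      } else {
        e1 * e1 * inv_ob + lob
      }
      v <- v + eta[2]^2 * inv_os + los
      if (has_ruv) v <- v + eta[k_ruv]^2 * inv_or + lor
      if (has_de_eta) {
        ed <- eta[k_de]
        v <- v + if (dflag[i] > 0 && omd[i] > 0) {
          ed * ed / omd[i] + LOG2PI + log(omd[i])
        } else {
          # unused drug eta: standard normal prior integrating to 1
          ed * ed + LOG2PI
        }
      }
      if (!is.finite(v)) 1e10 else v
    }
    list(h = h, sds = sds)
  }

  # population prediction (all random effects at zero)
  mu_pop <- function(par) {
    unlist(lapply(seq_len(p$m), function(i) {
      basev <- par[["th_base"]] + par[["th_int"]] * p$bmms_i[i]
      slopev <- par[["th_slp"]] + par[["th_slp_bmms"]] * p$bmms_i[i]
      gt <- if (pform == "texp") {
        r <- par[["th_rate"]]
        if (abs(r) < 1e-8) tl[[i]] else expm1(r * tl[[i]]) / r
      } else tl[[i]]
      if (has_drug) {
        thd <- subj_drug_pars(spec, p, par)$th[i] * (dflag[i] > 0)
        switch(form,
          offset = basev + slopev * gt + thd * postl[[i]],
          tlin = basev + slopev * gt + thd * tl[[i]] / 36,
          dm = basev + slopev * (1 - thd) * gt)
      } else {
        basev + slopev * gt
      }
    }), use.names = FALSE)
  }

  list(spec = spec, p = p, q = q, eta_names = eta_names,
       factory = factory, mu_pop = mu_pop,
       cache = new.env(parent = emptyenv()))
}

# Per-subject -2 log marginal likelihood by q-dimensional Laplace.
# The inner search runs in prior-standardized coordinates z = eta / sd so
# that near-degenerate variance components do not produce a stiff inner
# problem; the Jacobian of the standardization is accounted for exactly.
# Cached per-subject modes from the previous call warm-start the search
# along an outer optimization path.
laplace_nll_subjects <- function(cond, par) {
  q <- cond$q
  fac <- cond$factory(par)
  modes <- cond$cache$modes
  if (is.null(modes) || nrow(modes) != q) {
    modes <- matrix(0, q, cond$p$m)
  }
  ctl <- list(rel.tol = 1e-12, iter.max = 200)
  out <- vapply(seq_len(cond$p$m), function(i) {
    s <- fac$sds[, i]
    h <- function(z) fac$h(i, z * s)
    ft <- stats::nlminb(modes[, i], h, control = ctl)
    if (!is.finite(ft$objective)) ft <- stats::nlminb(rep(0, q), h, control = ctl)
    if (!is.finite(ft$objective)) ft <- stats::nlminb(rep(0.3, q), h, control = ctl)
    if (!is.finite(ft$objective)) return(Inf)
    modes[, i] <<- ft$par
    H <- num_hess(h, ft$par) / 2
    dt <- suppressWarnings(determinant(H, logarithm = TRUE))
    if (dt$sign <= 0 || !is.finite(dt$modulus)) return(Inf)
    ft$objective - q * LOG2PI + as.numeric(dt$modulus) - 2 * sum(log(s))
  }, numeric(1))
  cond$cache$modes <- modes
  out
}

# Population-level (eta = 0) mean prediction from a conditional model.
cond_mu_pop <- function(cond, par) cond$mu_pop(par)
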