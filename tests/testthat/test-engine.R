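# Likelihood engine: closed forms, Laplace equivalences, fitting, dOFV.

test_that("one observation, trivial model: ofv equals log(2*pi)", {
  co <- cohort_from_df(data.frame(ID = 1, TIME = 0, DV = 5, TRT = 0L,
                                  BMMS = 0))
  par <- c(th_base = 5, th_int = 0, th_slp = 0, th_slp_bmms = 0,
           om2_base = 1e-12, om2_slp = 1e-12, sig2 = 1)
  expect_equal(marginal_ofv(published_placebo(), co, par), log(2 * pi),
               tolerance = 1e-9)
})

test_that("two-observation subject matches a hand-computed bivariate normal", {
  y <- c(21.3, 24.9); tt <- c(0, 12); b <- 24
  co <- cohort_from_df(data.frame(ID = 1, TIME = tt, DV = y, TRT = 0L,
                                  BMMS = b))
  par <- c(th_base = 60, th_int = -1.6, th_slp = 0.4, th_slp_bmms = -0.01,
           om2_base = 20, om2_slp = 0.03, sig2 = 7)
  # independent oracle: explicit 2x2 multivariate normal algebra
  Z <- cbind(1, tt)
  V <- Z %*% diag(c(par[["om2_base"]], par[["om2_slp"]])) %*% t(Z) +
    par[["sig2"]] * diag(2)
  mu <- (par[["th_base"]] + par[["th_int"]] * b) +
    (par[["th_slp"]] + par[["th_slp_bmms"]] * b) * tt
  r <- y - mu
  ofv_oracle <- 2 * log(2 * pi) + as.numeric(determinant(V)$modulus) +
    drop(t(r) %*% solve(V) %*% r)
  expect_equal(marginal_ofv(published_placebo(), co, par), ofv_oracle,
               tolerance = 1e-10)
})

test_that("Laplace equals the closed form for linear-Gaussian models", {
  co <- small_cohort(20, seed = 71, misspec = TRUE)
  base <- default_true_params()
  cases <- list(
    list(published_placebo(), base),
    list(add_drug(published_placebo(), drug_model("offset", TRUE)),
         c(base, th_de = 2, om2_de = 1)),
    list(add_drug(published_placebo(), drug_model("tlin", TRUE)),
         c(base, th_de = 3, om2_de = 0.5)),
    list(add_drug(published_placebo(), drug_model("dm")),
         c(base, th_de = 0.4)))
  for (cs in cases) {
    cf <- marginal_ofv(cs[[1]], co, cs[[2]], method = "closed_form")
    lp <- marginal_ofv(cs[[1]], co, cs[[2]], method = "laplace")
    expect_lt(abs(lp - cf) / abs(cf), 1e-6)
  }
  # perturbed parameter sets keep the equivalence (property-style)
  for (k in 1:5) {
    pk <- base * (1 + 0.1 * sin(seq_along(base) + k))
    pk["sig2"] <- max(pk["sig2"], 1)
    cf <- marginal_ofv(published_placebo(), co, pk, method = "closed_form")
    lp <- marginal_ofv(published_placebo(), co, pk, method = "laplace")
    expect_lt(abs(lp - cf) / abs(cf), 1e-6)
  }
})

test_that("the C++ disease-modifying IIV kernel matches the generic Laplace", {
  co <- small_cohort(20, seed = 72, misspec = TRUE)
  m <- add_drug(published_placebo(), drug_model("dm", TRUE))
  for (k in 1:3) {
    par <- c(default_true_params(), th_de = c(0.1, 0.3, -0.2)[k],
             om2_de = c(0.05, 0.2, 0.01)[k])
    fast <- marginal_ofv(m, co, par)                    # C++ kernel
    ref <- marginal_ofv(m, co, par, method = "laplace") # generic R path
    expect_lt(abs(fast - ref) / abs(ref), 1e-5)
  }
})

test_that("mixture of identical components equals the plain model", {
  co <- small_cohort(15, seed = 73)
  par <- default_true_params()
  mix <- mixture_model(published_placebo(), drug_model("offset", TRUE),
                       theta_mix_fixed = 0.5)
  o_mix <- marginal_ofv(mix, co, c(par, th_de = 0, om2_de = 0))
  o_pub <- marginal_ofv(published_placebo(), co, par)
  expect_equal(o_mix, o_pub, tolerance = 1e-10)
})

test_that("parameter validation rejects out-of-domain values", {
  co <- small_cohort(5, seed = 74)
  par <- default_true_params()
  bad <- par; bad[["om2_base"]] <- -1
  expect_error(marginal_ofv(published_placebo(), co, bad), "variance")
  bad <- par; bad[["sig2"]] <- 0
  expect_error(marginal_ofv(published_placebo(), co, bad), "sig2")
  expect_error(marginal_ofv(published_placebo(), co, par[-1]), "missing")
  expect_error(marginal_ofv(model_spec("boxcox"), co, c(par, lambda = 0.5),
                            method = "closed_form"), "closed-form")
})

test_that("noise-free cohort: fixed effects recovered to optimizer tolerance", {
  gen <- default_generator_config(n_subjects = 12, om2_base = 0, om2_slp = 0,
                                  sig2 = 1e-6)
  co <- generate_natural_history(gen, seed = 75)
  f <- fit(published_placebo(), co)
  expect_equal(f$status, "converged")
  expect_lt(abs(f$params[["th_base"]] - gen$th_base), 0.05)
  expect_lt(abs(f$params[["th_slp"]] - gen$th_slp), 0.01)
})

test_that("parameter recovery within 3 analytic standard errors at n = 500", {
  gen <- default_generator_config(n_subjects = 500, th_slp = 0.3)
  co <- generate_natural_history(gen, seed = 76)
  f <- fit(published_placebo(), co)
  expect_equal(f$status, "converged")
  # oracle: Fisher information of the fixed effects at the true parameters
  p <- nlmetrt:::prep_cohort(co)
  tt <- p$t[1:6]
  Z <- cbind(1, tt)
  V <- Z %*% diag(c(gen$om2_base, gen$om2_slp)) %*% t(Z) +
    gen$sig2 * diag(6)
  Vi <- solve(V)
  info <- matrix(0, 4, 4)
  for (i in seq_len(p$m)) {
    X <- cbind(1, p$bmms_i[i], tt, p$bmms_i[i] * tt)
    info <- info + t(X) %*% Vi %*% X
  }
  se <- sqrt(diag(solve(info)))
  est <- f$params[c("th_base", "th_int", "th_slp", "th_slp_bmms")]
  tru <- c(gen$th_base, gen$th_int, gen$th_slp, gen$th_slp_bmms)
  expect_true(all(abs(est - tru) < 3 * se))
})

test_that("nesting: the richer model never fits worse", {
  co <- small_cohort(30, seed = 77, misspec = TRUE)
  f0 <- fit(published_placebo(), co)
  for (id in c("offset", "offset_iiv", "dm", "dm_iiv")) {
    f1 <- fit(add_drug(published_placebo(),
                       drug_model(sub("_iiv", "", id), grepl("_iiv", id))), co)
    expect_lte(f1$ofv, f0$ofv + 1e-6)
  }
  # Laplace-family nesting holds up to the optimizer's flat-region tolerance
  fr <- fit(model_spec("ruviiv"), co)
  expect_lte(fr$ofv, f0$ofv + 0.1)
})

test_that("fit reports failure through status, never raises", {
  co <- cohort_from_df(data.frame(ID = rep(1:2, each = 2),
                                  TIME = rep(c(0, 6), 2),
                                  DV = rep(c(10, 11), 2), TRT = c(0, 0, 1, 1),
                                  BMMS = rep(25, 4)))
  f <- fit(add_drug(published_placebo(), drug_model("offset", TRUE)), co,
           options = list(iter_max = 2L, eval_max = 4L, max_restarts = 0L,
                          grad_tol = 1e-12))
  expect_s3_class(f, "fit_result")
  expect_true(f$status %in% c("converged", "failed"))
})

test_that("delta_ofv and aic follow their definitions", {
  co <- small_cohort(20, seed = 78)
  f0 <- fit(published_placebo(), co)
  f1 <- fit(add_drug(published_placebo(), drug_model("offset")), co)
  expect_equal(delta_ofv(f0, f1), f1$ofv - f0$ofv)
  expect_equal(delta_ofv(f0, f0), 0)
  expect_lte(delta_ofv(f0, f1), 0)
  expect_equal(aic(f1), f1$ofv + 2 * 8)
  expect_gte(aic(f0), f0$ofv)
  bad <- nlmetrt:::new_fit_failed(published_placebo(), "x")
  expect_error(delta_ofv(f0, bad), "converged")
})

test_that("fit_summary lays fits out as a flat comparison table", {
  co <- small_cohort(15, seed = 80)
  f0 <- fit(published_placebo(), co)
  f1 <- fit(add_drug(published_placebo(), drug_model("offset")), co)
  s <- fit_summary(list(f0, f1))
  expect_equal(names(s), c("model", "ofv", "n_params", "aic", "status"))
  expect_equal(s$model, c("pub", "pub+offset"))
  expect_equal(s$aic, s$ofv + 2 * s$n_params)
})

test_that("chi-square critical values match the standard quantiles", {
  expect_equal(round(chi2_critical(2, 0.05), 2), -5.99)
  expect_equal(round(chi2_critical(1, 0.05), 2), -3.84)
  expect_equal(chi2_critical(1, 0.9999), 0, tolerance = 1e-4)
  expect_error(chi2_critical(0, 0.05), "df")
  expect_error(chi2_critical(2, 1.2), "alpha")
})

test_that("simulation from a fitted placebo reproduces the design", {
  co <- small_cohort(25, seed = 79)
  f <- fit(published_placebo(), co)
  sim <- simulate_from_fit(f, co, seed = 3)
  expect_equal(sim$data$ID, co$data$ID)
  expect_equal(sim$data$TIME, co$data$TIME)
  expect_equal(sim$data$TRT, co$data$TRT)
  expect_false(isTRUE(all.equal(sim$data$DV, co$data$DV)))
  expect_identical(simulate_from_fit(f, co, seed = 3)$data$DV, sim$data$DV)
})
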