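# Model library: parameter counts, registry, structural limits.

test_that("estimated parameter counts match the model structure", {
  expect_equal(n_params(published_placebo()), 7)
  for (m in alternative_placebos()) expect_equal(n_params(m), 8)
  pp <- published_placebo()
  expect_equal(n_params(add_drug(pp, drug_model("offset"))), 8)
  expect_equal(n_params(add_drug(pp, drug_model("offset", TRUE))), 9)
  expect_equal(n_params(add_drug(pp, drug_model("dm", TRUE))), 9)
  # structural-similarity pair: duplicated drug parameters per arm
  h0 <- add_drug(pp, drug_model("offset", TRUE), "all")
  h1 <- add_drug(pp, drug_model("offset", TRUE), "arm_specific")
  expect_equal(n_params(h1) - n_params(h0), 2)
  h0 <- add_drug(pp, drug_model("offset"), "all")
  h1 <- add_drug(pp, drug_model("offset"), "arm_specific")
  expect_equal(n_params(h1) - n_params(h0), 1)
  # mixture: estimating the mixing probability adds exactly one parameter
  m0 <- mixture_model(pp, drug_model("offset", TRUE), theta_mix_fixed = 0.5)
  m1 <- mixture_model(pp, drug_model("offset", TRUE), theta_mix_fixed = NA)
  expect_equal(n_params(m1) - n_params(m0), 1)
})

test_that("registry ids resolve and invalid specs are rejected", {
  m <- model_from_id("pub+offset_iiv")
  expect_equal(m$drug_form, "offset")
  expect_true(m$drug_iiv)
  expect_equal(model_id(m), "pub+offset_iiv")
  expect_equal(model_from_id("boxcox")$placebo_form, "boxcox")
  expect_error(model_from_id("nope+offset"), "unknown placebo")
  expect_error(model_from_id("pub+magic"), "unknown drug")
  expect_error(model_spec("pub", "none", drug_iiv = TRUE), "drug")
  expect_error(mixture_model(published_placebo(), drug_model("offset"),
                             theta_mix_fixed = 1.5), "0, 1")
  expect_error(candidate_set(published_placebo(), c("offset", "offset")),
               "distinct")
})

test_that("zero drug effect reproduces the placebo model exactly", {
  co <- small_cohort(15, seed = 61)
  par <- default_true_params()
  o0 <- marginal_ofv(published_placebo(), co, par)
  for (form in c("offset", "tlin", "dm")) {
    m <- add_drug(published_placebo(), drug_model(form, iiv = TRUE))
    o1 <- marginal_ofv(m, co, c(par, th_de = 0, om2_de = 0))
    expect_equal(o1, o0, tolerance = 1e-10)
  }
})

test_that("full disease arrest: dm with th_de = 1 flattens treated subjects", {
  co <- small_cohort(12, seed = 62)
  par <- c(default_true_params(), th_de = 1)
  mu <- predict_mean(add_drug(published_placebo(), drug_model("dm")), co, par)
  p <- nlmetrt:::prep_cohort(co)
  tr_obs <- p$trt_i[p$id_idx] == 1
  base <- par[["th_base"]] + par[["th_int"]] * p$bmms
  expect_equal(mu[tr_obs], base[tr_obs], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(mu[!tr_obs], base[!tr_obs])))
})

test_that("time-exponential model reduces to the linear model as rate -> 0", {
  co <- small_cohort(15, seed = 63)
  par <- default_true_params()
  expect_equal(marginal_ofv(model_spec("texp"), co, c(par, th_rate = 1e-9)),
               marginal_ofv(published_placebo(), co, par),
               tolerance = 1e-8)
})

test_that("t-distributed baseline effect recovers the Gaussian model as df -> Inf", {
  co <- small_cohort(15, seed = 64)
  par <- default_true_params()
  expect_equal(marginal_ofv(model_spec("tdist"), co, c(par, nu = 1e6)),
               marginal_ofv(published_placebo(), co, par),
               tolerance = 1e-3)
})

test_that("Boxcox transform of the baseline effect has the identity limit", {
  co <- small_cohort(15, seed = 65)
  par <- default_true_params()
  expect_equal(marginal_ofv(model_spec("boxcox"), co, c(par, lambda = 1e-9)),
               marginal_ofv(published_placebo(), co, par),
               tolerance = 1e-5)
  # at lambda = 1 the transform is exp(eta) - 1: a genuinely different model
  expect_gt(abs(marginal_ofv(model_spec("boxcox"), co, c(par, lambda = 1)) -
                  marginal_ofv(published_placebo(), co, par)), 0.1)
})

test_that("mixture arm probabilities follow the allocation rule", {
  # Pr(placebo component) = (1 - TRT) * th_mix + TRT * (1 - th_mix):
  # at th_mix = 1, placebo-arm subjects are all placebo, treated all drug.
  co <- small_cohort(10, seed = 66)
  spec <- mixture_model(published_placebo(), drug_model("offset"),
                        theta_mix_fixed = NA)
  obj <- nlmetrt:::compile_model(spec, co)
  par <- c(default_true_params(), th_de = 5, th_mix = 1)
  nll_mix <- obj$nll_subj(par)
  n1 <- obj$comp1$nll_subj(par)
  n2 <- obj$comp2$nll_subj(par)
  p <- nlmetrt:::prep_cohort(co)
  expect_equal(nll_mix[p$trt_i == 0], n1[p$trt_i == 0], tolerance = 1e-12)
  expect_equal(nll_mix[p$trt_i == 1], n2[p$trt_i == 1], tolerance = 1e-12)
})
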