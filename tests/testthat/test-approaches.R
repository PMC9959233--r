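# The seven testing approaches on small cohorts.

test_that("akaike weights follow exp(-dAIC/2) and sum to one", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  w <- akaike_weights(c(100, 102))
  expect_equal(round(w, 3), c(0.731, 0.269))
  expect_equal(w, exp(-c(0, 2) / 2) / sum(exp(-c(0, 2) / 2)))
  # a ~110-point AIC gap drives the disfavored weight to ~1e-24
  w <- akaike_weights(c(0, 110))
  expect_lt(w[2], 1e-23)
  expect_gt(w[2], 1e-25)
  # property: sums to 1, best model gets the largest weight
  for (k in 1:10) {
    set.seed(k)
    a <- rnorm(5, 1000, 20)
    w <- akaike_weights(a)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(which.max(w), which.min(a))
  }
  # failed fits get zero weight; all-failed errors
  w <- akaike_weights(c(Inf, 100, NA))
  expect_equal(w, c(0, 1, 0))
  expect_error(akaike_weights(c(Inf, NA)), "finite")
})

test_that("STDs rejects a large injected effect and reports the -5.99 cutoff", {
  co <- small_cohort(100, seed = 81)
  co <- inject_treatment_effect(co, effect_scenario("offset", 8, 0), seed = 1)
  res <- run_stds(co, typei_candidates())
  expect_equal(res$decision, "reject_h0")
  expect_lt(res$dofv, res$critical_value)
  expect_gt(res$effect_estimate, 4)
  # with a selected 2-parameter drug component the cutoff is -5.99
  res2 <- run_stds(co, candidate_set(published_placebo(), "offset_iiv"))
  expect_equal(round(res2$critical_value, 2), -5.99)
  expect_equal(res2$details$df, 2)
})

test_that("STDs mostly retains under a correctly specified null", {
  rejections <- vapply(1:10, function(s) {
    co <- small_cohort(60, seed = 500 + s)
    run_stds(co, candidate_set(published_placebo(), c("offset", "dm")))$decision
  }, character(1))
  expect_lt(mean(rejections == "reject_h0"), 0.5)
})

test_that("SSs: identical arms give matching estimates and near-zero dOFV", {
  co <- generate_natural_history(small_gen(12), seed = 82)
  d0 <- co$data
  d1 <- d0; d1$ID <- d1$ID + 1000; d1$TRT <- 1L   # duplicate subjects as arm 1
  co2 <- cohort_from_df(rbind(d0, d1))
  res <- run_sss(co2, candidate_set(published_placebo(), c("offset", "offset_iiv")))
  expect_lt(abs(res$dofv), 0.1)
  expect_lt(abs(res$effect_estimate), 0.2)
  expect_equal(res$decision, "retain_h0")
  # df bookkeeping: offset without IIV duplicates exactly one parameter
  res1 <- run_sss(co2, candidate_set(published_placebo(), "offset"))
  expect_equal(res1$details$df, 1)
})

test_that("null distribution bookkeeping and permutation reuse", {
  co <- small_cohort(25, seed = 83)
  cand <- candidate_set(published_placebo(), c("offset", "dm"))
  nl <- build_null(co, cand, "permutation", n = 20, seed = 5)
  expect_s3_class(nl, "null_distribution")
  expect_length(nl$values, 20)
  expect_equal(nl$n_failed, 0)
  expect_true(all(is.finite(nl$values)))
  expect_error(build_null(co, cand, "permutation", n = 5, seed = 1),
               "at least 20")
})

test_that("rcLRT decision rule is consistent with its empirical cutoff", {
  co <- small_cohort(40, seed = 84, misspec = TRUE)
  cand <- candidate_set(published_placebo(), c("offset", "offset_iiv"))
  res <- run_rclrt(co, cand, n = 25, seed = 7)
  expect_equal(res$decision,
               if (res$dofv < res$critical_value) "reject_h0" else "retain_h0")
  expect_length(res$details$null$values, 25)
  # same cohort, same seed: identical decision (reproducibility)
  res2 <- run_rclrt(co, cand, n = 25, seed = 7)
  expect_equal(res2$critical_value, res$critical_value)
  # large injected effect: rejection
  coE <- inject_treatment_effect(small_cohort(80, seed = 85),
                                 effect_scenario("offset", 8, 0), seed = 2)
  rE <- run_rclrt(coE, cand, n = 25, seed = 9)
  expect_equal(rE$decision, "reject_h0")
})

test_that("cLRT null cutoff approaches the chi-square quantile when the placebo is correct", {
  # single 1-df drug candidate, correctly specified placebo: the null dOFV is
  # asymptotically -chi2(1), so the 5% cutoff approaches -3.84
  co <- small_cohort(40, seed = 86)
  cand <- candidate_set(published_placebo(), "offset")
  res <- run_clrt(co, cand, n = 400, seed = 11)
  expect_lt(abs(res$critical_value - chi2_critical(1, 0.05)), 1.2)
})

test_that("MAD weight bookkeeping matches the underlying fits", {
  co <- small_cohort(40, seed = 87, misspec = TRUE)
  cand <- candidate_set(published_placebo(), c("offset", "offset_iiv"))
  stds <- run_stds(co, cand)
  res <- run_mad(co, cand, stds_result = stds)
  w <- res$details$weights
  expect_length(w, 3)       # placebo + two drug candidates
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(res$h1_weight_fraction, sum(w[-1]), tolerance = 1e-12)
  aics <- c(aic(stds$details$h0_fit),
            vapply(stds$details$h1_fits, aic, numeric(1)))
  expect_equal(unname(w), akaike_weights(aics), tolerance = 1e-12)
  expect_true(res$h1_weight_fraction >= 0 && res$h1_weight_fraction <= 1)
})

test_that("MAPD fits the full placebo x drug grid", {
  placebos <- c(list(published_placebo()), unname(alternative_placebos()))
  cand <- candidate_set(placebos, c("offset", "offset_iiv", "dm", "dm_iiv"))
  co <- small_cohort(16, seed = 88, schedule = c(0, 12, 24, 36))
  res <- run_mapd(co, cand)
  expect_length(res$details$weights, 25)   # 5 placebos x (1 + 4 drug models)
  expect_equal(sum(res$details$weights), 1, tolerance = 1e-10)
  expect_true(res$h1_weight_fraction >= 0 && res$h1_weight_fraction <= 1)
  expect_error(run_mapd(co, typei_candidates()), "two placebo")
})

test_that("IMA effect transform and decision logic", {
  expect_equal(ima_effect_estimate(0.5, 7), 0)
  expect_equal(ima_effect_estimate(1, 8), 8)
  expect_equal(ima_effect_estimate(0, 8), -8)
  co <- inject_treatment_effect(small_cohort(80, seed = 89),
                                effect_scenario("offset", 8, 0), seed = 3)
  res <- run_ima(co, candidate_set(published_placebo(),
                                   c("offset", "offset_iiv")))
  expect_equal(res$decision, "reject_h0")
  expect_equal(res$critical_value, chi2_critical(1, 0.05))
  expect_gt(res$details$theta_mix, 0.8)
  expect_gt(res$effect_estimate, 4)
  # the H0 mixture (fixed 0.5) nests in H1: dOFV can never be positive
  expect_lte(res$dofv, 1e-6)
})

test_that("decisions are invariant to candidate order (ties documented first-wins)", {
  co <- small_cohort(50, seed = 90, misspec = TRUE)
  ids <- c("offset", "offset_iiv", "dm", "dm_iiv")
  r1 <- run_stds(co, candidate_set(published_placebo(), ids))
  r2 <- run_stds(co, candidate_set(published_placebo(), rev(ids)))
  expect_equal(r1$decision, r2$decision)
  expect_equal(r1$selected, r2$selected)
  expect_equal(r1$dofv, r2$dofv, tolerance = 1e-6)
})
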