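# Synthetic cohort generator, effect injection, allocation and permutation.

test_that("noise-free degenerate generation is exactly linear", {
  gen <- default_generator_config(n_subjects = 5, th_base = 10, th_int = 0,
                                  th_slp = 0.1, th_slp_bmms = 0,
                                  om2_base = 0, om2_slp = 0, sig2 = 0)
  co <- generate_natural_history(gen, seed = 1)
  expect_equal(co$data$DV, 10 + 0.1 * co$data$TIME, tolerance = 1e-12)
})

test_that("default ADNI-like configuration gives 817 subjects x 6 visits", {
  co <- generate_natural_history(default_generator_config(), seed = 7)
  expect_equal(n_subjects(co), 817)
  expect_equal(nrow(co$data), 817 * 6)
  expect_true(all(table(co$data$ID) == 6))
  expect_true(all(co$data$TRT == 0))
  expect_false(isTRUE(co$meta$allocated))
})

test_that("generation is reproducible by seed and truth is recorded", {
  gen <- small_gen(20)
  a <- generate_natural_history(gen, seed = 5)
  b <- generate_natural_history(gen, seed = 5)
  d <- generate_natural_history(gen, seed = 6)
  expect_identical(a$data, b$data)
  expect_false(isTRUE(all.equal(a$data$DV, d$data$DV)))
  expect_equal(nrow(a$truth$subjects), 20)
  expect_true(all(c("eta1", "eta2", "gamma") %in% names(a$truth$subjects)))
})

test_that("generator validates its inputs", {
  expect_error(generate_natural_history(small_gen(1), seed = 1), "n_subjects")
  expect_error(generate_natural_history(small_gen(5, om2_base = -1), seed = 1),
               "variance")
  expect_error(
    generate_natural_history(default_generator_config(n_subjects = 5,
                                                      schedule = numeric(0)),
                             seed = 1), "schedule")
  expect_error(generate_natural_history(small_gen(5)), "seed")
})

test_that("baseline score variance matches its analytic decomposition", {
  gen <- default_generator_config(n_subjects = 10000)
  co <- generate_natural_history(gen, seed = 42)
  v0 <- var(co$data$DV[co$data$TIME == 0])
  expected <- gen$th_int^2 * gen$bmms_sd^2 + gen$om2_base + gen$sig2
  expect_lt(abs(v0 - expected) / expected, 0.05)
})

test_that("dropout thins post-baseline visits only", {
  gen <- default_generator_config(n_subjects = 200, dropout_rate = 0.32)
  co <- generate_natural_history(gen, seed = 3)
  expect_equal(sum(co$data$TIME == 0), 200)
  post <- sum(co$data$TIME > 0)
  expect_lt(post, 200 * 5)
  expect_lt(abs(post / (200 * 5) - 0.68), 0.05)
})

test_that("offset injection adds exactly the typical effect at t > 0", {
  co <- small_cohort(20, seed = 11)
  out <- inject_treatment_effect(co, effect_scenario("offset", 8, 0), seed = 2)
  diffs <- out$data$DV - co$data$DV
  treated_post <- co$data$TRT == 1 & co$data$TIME > 0
  expect_equal(diffs[treated_post], rep(8, sum(treated_post)))
  expect_equal(diffs[!treated_post], rep(0, sum(!treated_post)))
})

test_that("time-linear injection scales the effect with t / 36", {
  co <- small_cohort(20, seed = 12)
  out <- inject_treatment_effect(co, effect_scenario("tlin", 2, 0), seed = 2)
  d <- out$data$DV - co$data$DV
  tr <- co$data$TRT == 1
  expect_equal(d[tr & co$data$TIME == 36], rep(2, sum(tr & co$data$TIME == 36)))
  expect_equal(d[tr & co$data$TIME == 18], rep(1, sum(tr & co$data$TIME == 18)))
  expect_equal(d[tr & co$data$TIME == 0], rep(0, sum(tr & co$data$TIME == 0)))
})

test_that("null effect injection is an identity on the scores", {
  co <- small_cohort(15, seed = 13)
  out <- inject_treatment_effect(co, effect_scenario("offset", 0, 0), seed = 2)
  expect_equal(out$data$DV, co$data$DV)
})

test_that("injection with IIV stores per-subject effects in the truth record", {
  co <- small_cohort(40, seed = 14)
  out <- inject_treatment_effect(co, effect_scenario("offset", 8, 0.3), seed = 9)
  tr <- out$truth$subjects
  e <- tr$e_drug[tr$ID %in% unique(out$data$ID[out$data$TRT == 1])]
  expect_gt(stats::sd(e), 0)   # 30% CV spreads the individual effects
  expect_lt(abs(mean(e) - 8), 3 * 0.3 * 8 / sqrt(length(e)) + 1)
  expect_error(inject_treatment_effect(
    generate_natural_history(small_gen(10), seed = 1),
    effect_scenario("offset", 8, 0)), "arm labels")
})

test_that("randomization is balanced and uniform over allocations", {
  co <- generate_natural_history(small_gen(17), seed = 1)
  arms <- randomize_allocation(co, seed = 2)$data
  sizes <- table(tapply(arms$TRT, arms$ID, unique))
  expect_setequal(as.integer(sizes), c(8L, 9L))

  # brute force over the 6 balanced allocations of 4 subjects
  co4 <- generate_natural_history(small_gen(4), seed = 1)
  keys <- vapply(1:3000, function(s) {
    d <- randomize_allocation(co4, seed = s)$data
    paste(tapply(d$TRT, d$ID, unique), collapse = "")
  }, character(1))
  freq <- table(keys) / length(keys)
  expect_equal(length(freq), 6L)
  expect_true(all(abs(freq - 1 / 6) < 0.04))

  expect_identical(randomize_allocation(co4, seed = 77)$data,
                   randomize_allocation(co4, seed = 77)$data)
  expect_error(randomize_allocation(
    generate_natural_history(small_gen(2), seed = 1), seed = 1), NA)
})

test_that("permutation conserves arm sizes and touches nothing else", {
  co <- small_cohort(21, seed = 31)
  pe <- permute_allocation(co, seed = 5)
  expect_equal(sum(tapply(pe$data$TRT, pe$data$ID, unique)),
               sum(tapply(co$data$TRT, co$data$ID, unique)))
  expect_equal(pe$data$DV, co$data$DV)
  expect_equal(pe$data$BMMS, co$data$BMMS)
  expect_equal(pe$meta$provenance, "permuted")
  expect_error(permute_allocation(
    generate_natural_history(small_gen(5), seed = 1), seed = 1), "arm labels")
})

test_that("permuting twice has the same allocation distribution as once", {
  co4 <- randomize_allocation(generate_natural_history(small_gen(4), seed = 1),
                              seed = 1)
  key <- function(d) paste(tapply(d$TRT, d$ID, unique), collapse = "")
  once <- table(vapply(1:2000, function(s) {
    key(permute_allocation(co4, seed = s)$data)
  }, character(1))) / 2000
  twice <- table(vapply(1:2000, function(s) {
    key(permute_allocation(permute_allocation(co4, seed = s),
                           seed = s + 5000)$data)
  }, character(1))) / 2000
  expect_setequal(names(once), names(twice))
  expect_true(all(abs(once[names(twice)] - twice) < 0.05))
})

test_that("the eight evaluation scenarios are as specified", {
  sc <- default_scenarios()
  expect_length(sc, 8)
  key <- vapply(sc, function(s) {
    sprintf("%s_%g_%g", s$drug_form, s$typical_effect, s$iiv_cv)
  }, character(1))
  expect_equal(sort(key), sort(c(
    "offset_2_0", "offset_8_0", "tlin_2_0", "tlin_8_0",
    "offset_2_0.3", "offset_8_0.3", "tlin_2_0.3", "tlin_8_0.3")))
  expect_error(effect_scenario("offset", -1), "non-negative")
})
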