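# Shared fixtures: small cohorts and generator configurations built in code.

small_gen <- function(n = 30, misspec = FALSE, ...) {
  default_generator_config(n_subjects = n,
                           misspec = misspec_config(enabled = misspec), ...)
}

# a small allocated natural-history cohort
small_cohort <- function(n = 30, seed = 101, misspec = FALSE, ...) {
  co <- generate_natural_history(small_gen(n, misspec, ...), seed = seed)
  randomize_allocation(co, seed = seed + 1)
}

# cohort built directly from a data frame (no truth record)
cohort_from_df <- function(df, allocated = any(df$TRT == 1)) {
  nlmetrt:::new_cohort(df, meta = list(provenance = "natural",
                                       allocated = allocated))
}

# true parameters matching default_generator_config()
default_true_params <- function(gen = default_generator_config()) {
  c(th_base = gen$th_base, th_int = gen$th_int, th_slp = gen$th_slp,
    th_slp_bmms = gen$th_slp_bmms, om2_base = gen$om2_base,
    om2_slp = gen$om2_slp, sig2 = gen$sig2)
}

# candidate sets used throughout
typei_candidates <- function() {
  candidate_set(published_placebo(), c("offset", "offset_iiv", "dm", "dm_iiv"))
}
power_candidates <- function() {
  candidate_set(published_placebo(), power_drug_set())
}
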