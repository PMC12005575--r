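# Shared fixtures: everything is generated in code at test time.

small_cohort <- function(sex = "male", n = 500, seed = 101) {
  generate_baseline(n, sex, seed = seed)
}

# Cohort whose random intercepts are redrawn independently of baseline_hb,
# matching the exogeneity assumption of the mixed-model fitter (the default
# generator couples them to create persistent donor-level hemoglobin).
decoupled_cohort <- function(sex = "male", n = 1000, seed = 101, ri_sd = 5) {
  coh <- generate_baseline(n, sex, seed = seed)
  coh$random_intercept <- with_seed(seed + 1, stats::rnorm(n, 0, ri_sd))
  coh
}

with_seed <- pdtsim:::with_seed

# Generating bundle with known hemoglobin coefficients for recovery tests;
# p_catch = 0 removes the on-session screening selection so every
# under-threshold attendee's hemoglobin is recorded.
recovery_true_params <- function(sex = "male", ri_sd = 5, residual_sd = 6) {
  p <- default_params(sex)
  p$hb <- hb_model_params(
    sex,
    intercept = 30,
    coefficients = c(recovery = 20, baseline_hb = 0.8, age = 0.05),
    random_intercept_sd = ri_sd, residual_sd = residual_sd
  )
  p$probs <- event_probs(sex, p_catch = 0, p_other_deferral = 0.05,
                         p_failed_donation = 0.01, p_dropout = 0.05,
                         baseline = p$probs$baseline)
  p
}

table4_current <- function(sex) observed_current_row(sex)
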