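test_that("mean_return_hb is the linear predictor plus the donor intercept", {
  donor <- data.frame(sex = "female", age = 40, ethnicity = "white",
                      blood_group = "O+", baseline_hb = 130,
                      random_intercept = 5, donated_last_2y = TRUE,
                      is_new_donor = FALSE)
  p0 <- hb_model_params("female", intercept = 139, random_intercept_sd = 7,
                        residual_sd = 6)
  expect_equal(mean_return_hb(p0, donor, 10), 144)   # 139 + 5

  pid <- hb_model_params("female", intercept = 0,
                         coefficients = c(baseline_hb = 1),
                         random_intercept_sd = 7, residual_sd = 6)
  donor0 <- donor; donor0$random_intercept <- 0
  expect_equal(mean_return_hb(pid, donor0, 3), donor0$baseline_hb)

  expect_error(mean_return_hb(p0, donor, -1), ">= 0")
})

test_that("recovery is monotone and matches a direct basis evaluation", {
  donor <- data.frame(sex = "male", age = 50, ethnicity = "other",
                      blood_group = "A+", baseline_hb = 150,
                      random_intercept = -2, donated_last_2y = FALSE,
                      is_new_donor = FALSE)
  p <- default_hb_params("male")
  m12 <- mean_return_hb(p, donor, 12)
  m26 <- mean_return_hb(p, donor, 26)
  expect_gte(m26, m12)
  # independent oracle: evaluate the saturating basis directly
  direct <- function(t) {
    p$intercept + donor$random_intercept +
      p$coefficients[["recovery"]] * (1 - exp(-t / p$basis$tau))
  }
  expect_equal(m12, direct(12), tolerance = 1e-12)
  expect_equal(m26, direct(26), tolerance = 1e-12)
  # never-donated donors sit at the recovery plateau
  expect_equal(mean_return_hb(p, donor, Inf),
               p$intercept + p$coefficients[["recovery"]] + donor$random_intercept)
})

test_that("sample_return_hb adds reproducible Gaussian residual noise", {
  donor <- data.frame(sex = "male", age = 50, ethnicity = "white",
                      blood_group = "O+", baseline_hb = 150,
                      random_intercept = 0, donated_last_2y = TRUE,
                      is_new_donor = FALSE)
  p <- hb_model_params("male", intercept = 150, random_intercept_sd = 0,
                       residual_sd = 0.01)
  draws <- with_seed(1, sample_return_hb(p, donor, 12, n = 200))
  expect_true(all(abs(draws - 150) < 0.05))
  a <- with_seed(2, sample_return_hb(p, donor, 12, n = 50))
  b <- with_seed(2, sample_return_hb(p, donor, 12, n = 50))
  expect_identical(a, b)
})

test_that("parameter bundles validate and serialise round-trip", {
  expect_error(hb_model_params("male", intercept = 150, random_intercept_sd = 7,
                               residual_sd = 0), "residual_sd")
  expect_error(hb_model_params("male", intercept = 150,
                               coefficients = c(recovery = -5),
                               random_intercept_sd = 7, residual_sd = 6),
               "nondecreasing")
  expect_error(hb_basis("spline_cubic"), "unknown recovery basis")

  p <- default_hb_params("female")
  f <- withr::local_tempfile(fileext = ".json")
  write_hb_params(p, f)
  q <- read_hb_params(f)
  expect_equal(q$intercept, p$intercept)
  expect_equal(q$coefficients, p$coefficients)
  expect_equal(q$basis$tau, p$basis$tau)

  # a bundle naming an unimplemented basis must be refused
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$basis$name <- "pchip"
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_error(read_hb_params(f), "unknown recovery basis")
})

test_that("fitting recovers known generating coefficients", {
  coh <- decoupled_cohort("male", n = 3000, seed = 7)
  true <- recovery_true_params("male")
  log <- generate_training_log(coh, true, horizon = 78, missing_rate = 0, seed = 9)
  fit <- fit_hb_model(log, "male")
  expect_lt(abs(fit$coefficients[["baseline_hb"]] - 0.8), 0.05)
  expect_lt(abs(fit$residual_sd - 6) / 6, 0.05)
  expect_lt(abs(fit$random_intercept_sd - 5), 0.5)
  expect_true(is.finite(fit$logLik))
  expect_true(all(c("recovery", "baseline_hb", "age") %in% names(fit$se)))
})

test_that("fitting on 40% MCAR-masked hemoglobin matches the unmasked fit", {
  coh <- decoupled_cohort("male", n = 3000, seed = 17)
  true <- recovery_true_params("male")
  full <- generate_training_log(coh, true, horizon = 78, missing_rate = 0, seed = 19)
  masked <- generate_training_log(coh, true, horizon = 78, missing_rate = 0.4, seed = 19)
  f_full <- fit_hb_model(full, "male")
  f_mask <- fit_hb_model(masked, "male")
  expect_lt(abs(f_full$coefficients[["baseline_hb"]] - f_mask$coefficients[["baseline_hb"]]), 0.03)
  expect_lt(abs(f_full$residual_sd - f_mask$residual_sd), 0.2)
  expect_lt(abs(f_full$intercept - f_mask$intercept), 2.5)
})

test_that("the noise-free limit recovers fixed coefficients almost exactly", {
  coh <- decoupled_cohort("female", n = 500, seed = 23, ri_sd = 0)
  coh$random_intercept <- 0
  p <- default_params("female")
  p$hb <- hb_model_params("female", intercept = 100,
                          coefficients = c(recovery = 30, baseline_hb = 0.25,
                                           age = 0.1),
                          random_intercept_sd = 0, residual_sd = 0.01)
  p$probs <- event_probs("female", p_catch = 0, p_other_deferral = 0.02,
                         p_failed_donation = 0, p_dropout = 0.02)
  log <- generate_training_log(coh, p, horizon = 78, missing_rate = 0, seed = 29)
  fit <- fit_hb_model(log, "female")
  expect_equal(fit$coefficients[["baseline_hb"]], 0.25, tolerance = 1e-3)
  expect_equal(fit$coefficients[["age"]], 0.1, tolerance = 1e-3)
  expect_equal(fit$coefficients[["recovery"]], 30, tolerance = 2e-3)
})

test_that("an all-masked log is rejected with an informative error", {
  coh <- small_cohort("male", n = 200, seed = 31)
  p <- default_params("male")
  log <- generate_training_log(coh, p, horizon = 78, missing_rate = 0, seed = 33)
  log$observed_hb <- NA_real_
  expect_error(fit_hb_model(log, "male"), "masked")
  # too few repeat donors is also named as the cause
  log2 <- generate_training_log(small_cohort("male", n = 10, seed = 35), p,
                                horizon = 78, missing_rate = 0, seed = 33)
  expect_error(fit_hb_model(log2, "male"), "donors")
})

test_that("Wald intervals cover the generating coefficients at nominal rate", {
  # 50 replicates at 1000 donors; each fixed coefficient's 95% interval
  # should cover its generating value in at least 90% of replicates
  true <- recovery_true_params("male")
  gen <- c(recovery = 20, baseline_hb = 0.8, age = 0.05)
  hits <- matrix(FALSE, 50, 3, dimnames = list(NULL, names(gen)))
  for (r in seq_len(50)) {
    coh <- decoupled_cohort("male", n = 1000, seed = 4000 + r)
    log <- generate_training_log(coh, true, horizon = 78, missing_rate = 0,
                                 seed = 5000 + r)
    fit <- fit_hb_model(log, "male")
    for (nm in names(gen)) {
      est <- fit$coefficients[[nm]]
      se <- fit$se[[nm]]
      hits[r, nm] <- abs(est - gen[[nm]]) <= 1.96 * se
    }
  }
  expect_true(all(colMeans(hits) >= 0.90))
})
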