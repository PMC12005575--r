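test_that("event percentages reproduce the published current-strategy rows", {
  pm <- event_percentages(2601, 65, 155, 2821)
  expect_equal(unname(round(pm[1:3], 1)), c(92.2, 2.3, 5.5))
  expect_equal(unname(pm[["pct_tests"]]), 100)
  pw <- event_percentages(1773, 92, 182, 2047)
  expect_equal(unname(round(pw[1:3], 1)), c(86.6, 4.5, 8.9))
  # strategy C men: 703 tests against 2749 donations + deferrals
  pc <- event_percentages(2574, 83, 92, 703)
  expect_equal(round(pc[["pct_tests"]], 1), 25.6)
  expect_equal(round(pc[["pct_under"]], 1), 3.0)
  z <- event_percentages(0, 0, 0, 0)
  expect_true(all(z == 0))
})

test_that("cost per donation follows the unit-cost identity", {
  costs <- cost_params()
  # no tests, no deferrals: exactly the base cost
  expect_equal(cost_per_donation(c(over_threshold_donation = 2527,
                                   under_threshold_donation = 177,
                                   low_hb_deferral = 0, onsession_tests = 0),
                                 costs),
               26.20)
  # derived default unit costs reproduce the printed current-strategy costs
  expect_equal(cost_per_donation(c(over_threshold_donation = 2601,
                                   under_threshold_donation = 65,
                                   low_hb_deferral = 155, onsession_tests = 2821),
                                 costs),
               27.03, tolerance = 1e-4)
  expect_equal(cost_per_donation(c(over_threshold_donation = 1773,
                                   under_threshold_donation = 92,
                                   low_hb_deferral = 182, onsession_tests = 2047),
                                 costs),
               27.39, tolerance = 1e-4)
  d <- derive_unit_costs()
  expect_equal(unname(d[["onsession_test"]]), 0.30, tolerance = 0.01)
  expect_equal(unname(d[["low_hb_deferral"]]), 8.8, tolerance = 0.1)
  # plain arithmetic case
  c0 <- cost_params(0, 1, 0)
  expect_equal(cost_per_donation(c(over_threshold_donation = 50,
                                   under_threshold_donation = 0,
                                   low_hb_deferral = 0, onsession_tests = 100),
                                 c0), 2)
  expect_error(cost_per_donation(c(over_threshold_donation = 0,
                                   under_threshold_donation = 0,
                                   low_hb_deferral = 3, onsession_tests = 1),
                                 costs), "no donations")
})

test_that("utility is linear in counts with the stated exchange rates", {
  w20 <- preference_weights(20, 20)
  expect_equal(utility(c(over_threshold_donation = 100,
                         under_threshold_donation = 0, low_hb_deferral = 0), w20),
               100)
  expect_equal(utility(c(over_threshold_donation = 2601,
                         under_threshold_donation = 65, low_hb_deferral = 155), w20),
               -1734)
  w0 <- preference_weights(0, 0)
  expect_equal(utility(c(over_threshold_donation = 2601,
                         under_threshold_donation = 65, low_hb_deferral = 155), w0),
               2666)
  base <- c(over_threshold_donation = 500, under_threshold_donation = 20,
            low_hb_deferral = 30)
  u0 <- utility(base, preference_weights(15, 7))
  plus_over <- base + c(1, 0, 0)
  plus_under <- base + c(0, 1, 0)
  expect_equal(utility(plus_over, preference_weights(15, 7)) - u0, 1)
  expect_equal(utility(plus_under, preference_weights(15, 7)) - u0, 1 - 15)
  expect_error(preference_weights(-1, 5), "nonnegative")
})

test_that("national projection reproduces the published current male row", {
  row <- project_national(c(over_threshold_donation = 2601,
                            under_threshold_donation = 65,
                            low_hb_deferral = 155), sex = "male")
  expect_equal(row$annual_donations_sex, 840000)  # 1.4M x 1.50 / 2.50
  expect_equal(row$over_thousand, 820)
  expect_equal(row$under_thousand, 20)
  expect_equal(row$low_hb_deferral_thousand, 49)
  expect_equal(row$total_visits_thousand,
               row$over_thousand + row$under_thousand + row$low_hb_deferral_thousand)
  roww <- project_national(c(over_threshold_donation = 1773,
                             under_threshold_donation = 92,
                             low_hb_deferral = 182), sex = "female")
  expect_equal(roww$annual_donations_sex, 560000)
  zero <- project_national(c(over_threshold_donation = 1000,
                             under_threshold_donation = 0,
                             low_hb_deferral = 0), sex = "male")
  expect_equal(zero$under_thousand, 0)
  expect_equal(zero$low_hb_deferral_thousand, 0)
  expect_error(project_national(c(over_threshold_donation = 0,
                                  under_threshold_donation = 0,
                                  low_hb_deferral = 10), sex = "male"),
               "no donations")
})

test_that("internal validation tables compare simulated and observed rows", {
  r <- run_strategy(small_cohort("male", 800, seed = 99), strategy_spec("current"),
                    default_hb_params("male"), default_attendance_params("male"),
                    default_event_probs("male"), seed = 1, keep_log = FALSE)
  self <- validate_current(r, r$per_1000)
  expect_true(all(self$abs_diff == 0))
  obs0 <- c(over_threshold_donation = 0, under_threshold_donation = 0,
            low_hb_deferral = 0)
  v0 <- validate_current(r, obs0)
  got <- v0$simulated[match(c("over_threshold_donation", "under_threshold_donation",
                              "low_hb_deferral"), v0$metric)]
  expect_equal(v0$abs_diff[match("over_threshold_donation", v0$metric)],
               unname(r$per_1000[["over_threshold_donation"]]))
  expect_true(all(is.na(v0$rel_diff[v0$observed == 0])))
  expect_error(validate_current(r, r$per_1000, horizon = 52), "horizon mismatch")
})

test_that("the PSA produces coherent intervals and probability grids", {
  coh <- small_cohort("male", n = 1200, seed = 110)
  p <- default_params("male")
  psa <- run_psa(coh, p, strategies = c("current", "B"), n_samples = 12,
                 seed = 7, weights_grid = c(10, 20))
  expect_true(all(psa$prob_better$prob_better >= 0 & psa$prob_better$prob_better <= 1))
  expect_true(all(psa$ui$lower <= psa$ui$upper))
  expect_equal(nrow(psa$prob_better), 4)  # one non-current strategy x 2x2 grid
  expect_error(run_psa(coh, p, n_samples = 1, seed = 1), "n_samples")

  # probability-better is invariant to a strictly monotone utility transform
  d <- psa$draws
  ub <- d$utility_20_20[d$strategy == "B"]
  uc <- d$utility_20_20[d$strategy == "current"]
  raw <- mean(ub > uc)
  expect_equal(mean(exp(ub / 1000) > exp(uc / 1000)), raw)
  expect_equal(psa$prob_better$prob_better[psa$prob_better$T_UD == 20 &
                                             psa$prob_better$T_LD == 20], raw)
})

test_that("degenerate parameter uncertainty collapses the intervals", {
  coh <- small_cohort("male", n = 800, seed = 111)
  p <- default_params("male")
  p$hb$se <- NULL; p$hb$vcov <- NULL
  p$attendance$se <- NULL; p$attendance$vcov <- NULL
  p$probs$shapes <- NULL
  psa <- run_psa(coh, p, strategies = c("current", "A"), n_samples = 5,
                 seed = 9, weights_grid = 20, vary_run_seed = FALSE)
  width <- psa$ui$upper - psa$ui$lower
  expect_true(all(width == 0))
})

test_that("summaries carry the per-1000 scale and percentage denominators", {
  r <- run_strategy(small_cohort("female", 1000, seed = 120), strategy_spec("B"),
                    default_hb_params("female"), default_attendance_params("female"),
                    default_event_probs("female"), seed = 2, keep_log = FALSE)
  s <- summarize_result(r)
  expect_equal(s$over_per_1000, unname(r$per_1000[["over_threshold_donation"]]))
  denom <- r$per_1000[["over_threshold_donation"]] +
    r$per_1000[["under_threshold_donation"]] + r$per_1000[["low_hb_deferral"]]
  expect_equal(s$pct_under, unname(100 * r$per_1000[["under_threshold_donation"]] / denom))
  expect_equal(s$pct_tests, unname(100 * r$per_1000[["onsession_tests"]] / denom))
})
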