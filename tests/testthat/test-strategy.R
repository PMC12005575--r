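test_that("hemoglobin categorisation uses left-closed sex-specific bounds", {
  expect_equal(categorize_hb(153, "male"), "high")
  expect_equal(categorize_hb(c(124, 125, 134, 135, 144, 145), "male"),
               c("very_low", "low", "low", "medium", "medium", "high"))
  expect_equal(categorize_hb(c(114, 115, 125, 135), "female"),
               c("very_low", "low", "medium", "high"))
  expect_error(categorize_hb(0, "male"), "positive")
})

test_that("the on-session test trigger matches each strategy's rule", {
  cats <- c("very_low", "low", "medium", "high")
  expected <- list(
    current = function(cat, def) TRUE,
    A = function(cat, def) FALSE,
    B = function(cat, def) cat %in% c("very_low", "low") || def,
    C = function(cat, def) cat %in% c("very_low", "low", "medium") || def,
    D = function(cat, def) cat %in% c("very_low", "low", "medium") || def
  )
  for (st in names(expected)) {
    spec <- strategy_spec(st)
    for (cat in cats) {
      for (def in c(FALSE, TRUE)) {
        expect_identical(
          needs_onsession_test(spec, cat, def, FALSE),
          expected[[st]](cat, def),
          info = sprintf("%s / %s / deferred=%s", st, cat, def)
        )
      }
    }
    # new donors are always tested, with or without history
    expect_true(needs_onsession_test(spec, NA, FALSE, TRUE))
    expect_true(needs_onsession_test(spec, "high", FALSE, TRUE))
  }
  # no history, returning donor: only universal testing applies
  expect_true(needs_onsession_test(strategy_spec("current"), NA, FALSE, FALSE))
  expect_false(needs_onsession_test(strategy_spec("B"), NA, FALSE, FALSE))
})

test_that("the on-session test passes over-threshold and defers by band", {
  probs1 <- event_probs("male", p_catch = 1, p_other_deferral = 0,
                        p_failed_donation = 0, p_dropout = 0)
  expect_equal(apply_onsession_test(140, "male", probs1, u = 0.99), "pass")
  expect_equal(apply_onsession_test(130, "male", probs1, u = 0.5), "defer_borderline")
  expect_equal(apply_onsession_test(118, "male", probs1, u = 0.5), "defer_very_low")
  probs0 <- event_probs("male", p_catch = 0, p_other_deferral = 0,
                        p_failed_donation = 0, p_dropout = 0)
  expect_equal(apply_onsession_test(118, "male", probs0, u = 0.5), "pass")

  pc <- event_probs("male", p_catch = 155 / 220, p_other_deferral = 0,
                    p_failed_donation = 0, p_dropout = 0)
  out <- with_seed(61, apply_onsession_test(rep(130, 10000), "male", pc))
  expect_lt(abs(mean(out != "pass") - 155 / 220), 0.015)
})

test_that("next_action reproduces every strategy's interval table", {
  cats <- c("very_low", "low", "medium", "high")
  std <- c(male = 12, female = 16)
  donation_expected <- list(
    current = function(cat, sex) std[[sex]],
    A = function(cat, sex) c(very_low = 52, low = 26, medium = std[[sex]], high = std[[sex]])[[cat]],
    B = function(cat, sex) c(very_low = 52, low = 26, medium = std[[sex]], high = std[[sex]])[[cat]],
    C = function(cat, sex) c(very_low = 52, low = 26, medium = std[[sex]], high = std[[sex]])[[cat]],
    D = function(cat, sex) c(very_low = 52, low = std[[sex]], medium = std[[sex]], high = std[[sex]])[[cat]]
  )
  test_expected <- list(
    current = function(cat) TRUE,
    A = function(cat) FALSE,
    B = function(cat) cat %in% c("very_low", "low"),
    C = function(cat) cat %in% c("very_low", "low", "medium"),
    D = function(cat) cat %in% c("very_low", "low", "medium")
  )
  for (st in names(donation_expected)) {
    spec <- strategy_spec(st)
    for (sex in c("male", "female")) {
      for (cat in cats) {
        act <- next_action(spec, "donation", sex, cat)
        expect_equal(act$interval, donation_expected[[st]](cat, sex),
                     info = sprintf("%s/%s/%s", st, sex, cat))
        expect_identical(act$test_next, test_expected[[st]](cat),
                         info = sprintf("%s/%s/%s", st, sex, cat))
        expect_true(act$interval %in% c(4, 12, 16, 26, 52))
      }
      # deferral bands, other deferrals, failed donations
      if (st != "A") {
        expect_equal(next_action(spec, "onsession_deferral", sex, "low")$interval, 12)
        expect_equal(next_action(spec, "onsession_deferral", sex, "very_low")$interval, 52)
        expect_true(next_action(spec, "onsession_deferral", sex, "low")$test_next)
      }
      oth <- next_action(spec, "other_deferral", sex)
      expect_equal(oth$interval, 4)
      expect_true(is.na(oth$test_next))
      fl <- next_action(spec, "failed_donation", sex)
      expect_equal(fl$interval, std[[sex]])
      expect_true(is.na(fl$test_next))
    }
  }
  # strategy D never reinvites a low-category donor later than the standard
  for (sex in c("male", "female")) {
    expect_lte(next_action(strategy_spec("D"), "donation", sex, "low")$interval,
               std[[sex]])
  }
})

test_that("inconsistent outcome/strategy combinations are rejected", {
  expect_error(next_action(strategy_spec("A"), "onsession_deferral", "male", "low"),
               "PDT-only")
  expect_error(next_action(strategy_spec("B"), "donation", "male", NA), "category")
  expect_error(next_action(strategy_spec("B"), "walked_out", "male"), "invalid visit outcome")
})

test_that("under universal testing with perfect catch no donation is under threshold", {
  # exhaustive branch check over categories: any under-threshold attendee is
  # deferred before donating
  probs <- event_probs("male", p_catch = 1, p_other_deferral = 0,
                       p_failed_donation = 0, p_dropout = 0)
  for (hb in c(110, 124, 125, 130, 134, 134.9)) {
    expect_match(apply_onsession_test(hb, "male", probs, u = 0.999999), "^defer")
  }
  for (hb in c(135, 140, 150)) {
    expect_equal(apply_onsession_test(hb, "male", probs, u = 0.999999), "pass")
  }
})

test_that("strategy specs serialise to JSON and back", {
  f <- withr::local_tempfile(fileext = ".json")
  for (st in c("current", "A", "B", "C", "D")) {
    spec <- strategy_spec(st)
    write_strategy_spec(spec, f)
    back <- read_strategy_spec(f)
    expect_equal(back$donation_interval, spec$donation_interval)
    expect_identical(back$test_rule, spec$test_rule)
    expect_identical(back$name, st)
  }
  custom <- strategy_spec("custom",
                          donation_interval = strategy_spec("B")$donation_interval,
                          test_rule = "always")
  write_strategy_spec(custom, f)
  expect_identical(read_strategy_spec(f)$test_rule, "always")
  expect_error(strategy_spec("E"), "unknown strategy")
})
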