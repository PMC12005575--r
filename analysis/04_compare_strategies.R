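#!/usr/bin/env Rscript

# Head-to-head comparison of the five screening strategies: per-1000-donor
# event counts, event percentages and cost per donation for 10,000 resampled
# donors of each sex followed for 78 weeks (means over 5 common-random-
# number seed replicates). This is the simulated analogue of the published
# 18-month event table.

suppressPackageStartupMessages(library(pdtsim))
dir.create("results", showWarnings = FALSE)

costs <- cost_params()
rows <- list()
for (sex in c("male", "female")) {
  n_base <- if (sex == "male") 8680 else 8261
  base <- generate_baseline(n_base, sex, seed = 301)
  coh <- resample_cohort(base, 10000, seed = 302)
  p <- default_params(sex)
  for (st in c("current", "A", "B", "C", "D")) {
    reps <- lapply(1:5, function(s) {
      run_strategy(coh, strategy_spec(st), p$hb, p$attendance, p$probs,
                   seed = 400 + s, keep_log = FALSE)
    })
    per1000 <- rowMeans(vapply(reps, `[[`, numeric(8), "per_1000"))
    pct <- event_percentages(per1000[["over_threshold_donation"]],
                             per1000[["under_threshold_donation"]],
                             per1000[["low_hb_deferral"]],
                             per1000[["onsession_tests"]])
    cost <- mean(vapply(reps, cost_per_donation, numeric(1), costs = costs))
    rows[[paste(sex, st)]] <- data.frame(
      sex = sex, strategy = st,
      over_per_1000 = round(per1000[["over_threshold_donation"]]),
      under_per_1000 = round(per1000[["under_threshold_donation"]]),
      low_hb_deferral_per_1000 = round(per1000[["low_hb_deferral"]]),
      tests_per_1000 = round(per1000[["onsession_tests"]]),
      pct_over = round(pct[["pct_over"]], 1),
      pct_under = round(pct[["pct_under"]], 1),
      pct_low_hb_deferral = round(pct[["pct_low_hb_deferral"]], 1),
      pct_tests = round(pct[["pct_tests"]], 1),
      cost_per_donation = round(cost, 2)
    )
  }
}
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write_results(list(table4_analogue = tab), "results")

cat("Simulated 18-month event table (per 1000 donors, 5-seed means):\n\n")
print(tab, row.names = FALSE)
cat("\nPublished current rows: men 92.2/2.3/5.5 (cost 27.03);",
    "women 86.6/4.5/8.9 (27.39).\n")
cat("Published strategy A under-threshold: 6.5% (men), 11.8% (women).\n")
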