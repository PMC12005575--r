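result_counts <- function(result) {
  if (inherits(result, "sim_result")) return(result$counts)
  if (is.numeric(result) && !is.null(names(result))) {
    out <- stats::setNames(numeric(6), c(visit_event_types()))
    out["onsession_tests"] <- 0
    keep <- intersect(names(result), names(out))
    out[keep] <- result[keep]
    if ("onsession_tests" %in% names(result)) out["onsession_tests"] <- result[["onsession_tests"]]
    return(out)
  }
  stop_config("expected a sim_result or a named counts vector")
}

#' Event percentages from raw tallies
#'
#' Percentages of over-threshold donations, under-threshold donations and
#' low-hemoglobin deferrals are taken over (donations + low-Hb deferrals);
#' the on-session test percentage is tests / (donations + low-Hb deferrals)
#' x 100. Non-hemoglobin deferrals and failed donations are excluded from
#' these denominators.
#'
#' @param over,under,low_hb_deferrals,tests Raw tallies.
#' @return Named vector `pct_over, pct_under, pct_low_hb_deferral,
#'   pct_tests`.
#' @export
#' @examples
#' event_percentages(2601, 65, 155, 2821)  # 92.2 / 2.3 / 5.5 / 100
event_percentages <- function(over, under, low_hb_deferrals, tests = NA_real_) {
  denom <- over + under + low_hb_deferrals
  if (denom == 0) {
    return(c(pct_over = 0, pct_under = 0, pct_low_hb_deferral = 0, pct_tests = 0))
  }
  c(pct_over = 100 * over / denom,
    pct_under = 100 * under / denom,
    pct_low_hb_deferral = 100 * low_hb_deferrals / denom,
    pct_tests = 100 * tests / denom)
}

#' Summarise a simulation as a per-1000-donor table row
#'
#' @param result A [run_strategy()] result (or a named counts vector with a
#'   `n_donors` attribute).
#' @return A one-row `data.frame`: strategy, sex, counts per 1000 donors and
#'   the event percentages of [event_percentages()].
#' @export
summarize_result <- function(result) {
  if (!inherits(result, "sim_result")) stop_config("expected a sim_result")
  p <- result$per_1000
  pct <- event_percentages(p[["over_threshold_donation"]],
                           p[["under_threshold_donation"]],
                           p[["low_hb_deferral"]],
                           p[["onsession_tests"]])
  data.frame(
    strategy = result$strategy, sex = result$sex, n_donors = result$n_donors,
    horizon = result$horizon,
    over_per_1000 = p[["over_threshold_donation"]],
    under_per_1000 = p[["under_threshold_donation"]],
    low_hb_deferral_per_1000 = p[["low_hb_deferral"]],
    other_deferral_per_1000 = p[["other_deferral"]],
    failed_per_1000 = p[["failed_donation"]],
    tests_per_1000 = p[["onsession_tests"]],
    pct_over = pct[["pct_over"]],
    pct_under = pct[["pct_under"]],
    pct_low_hb_deferral = pct[["pct_low_hb_deferral"]],
    pct_tests = pct[["pct_tests"]],
    stringsAsFactors = FALSE
  )
}

#' Unit costs
#'
#' `base_cost_per_donation` covers collection plus the post-donation
#' laboratory test; the on-session test and the low-hemoglobin deferral add
#' their unit costs on top. Defaults are derived with [derive_unit_costs()]
#' from the published per-1000 event tallies and costs per donation of the
#' current strategy for men and women against the fixed 26.20 GBP base.
#'
#' @param base_cost_per_donation,onsession_test_unit_cost,low_hb_deferral_unit_cost
#'   GBP, all >= 0.
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(base_cost_per_donation = 26.20,
                        onsession_test_unit_cost = NULL,
                        low_hb_deferral_unit_cost = NULL) {
  if (is.null(onsession_test_unit_cost) || is.null(low_hb_deferral_unit_cost)) {
    d <- derive_unit_costs()
    onsession_test_unit_cost <- onsession_test_unit_cost %||% d[["onsession_test"]]
    low_hb_deferral_unit_cost <- low_hb_deferral_unit_cost %||% d[["low_hb_deferral"]]
  }
  v <- c(base_cost_per_donation, onsession_test_unit_cost, low_hb_deferral_unit_cost)
  if (any(!is.finite(v)) || any(v < 0)) stop_config("costs must be nonnegative")
  structure(
    list(base_cost_per_donation = base_cost_per_donation,
         onsession_test_unit_cost = onsession_test_unit_cost,
         low_hb_deferral_unit_cost = low_hb_deferral_unit_cost),
    class = "cost_params"
  )
}

#' Derive on-session test and deferral unit costs
#'
#' Solves the 2 x 2 linear system formed by the current-strategy cost
#' identity `base + (c_test * tests + c_deferral * deferrals) / donations =
#' cost per donation` for men and women, using the published per-1000 event
#' tallies and printed costs per donation.
#'
#' @param base Base cost per donation (GBP).
#' @param men,women Named vectors `c(donations, deferrals, tests, cost)`.
#' @return Named vector `c(onsession_test, low_hb_deferral)` in GBP.
#' @export
derive_unit_costs <- function(base = 26.20,
                              men = c(donations = 2666, deferrals = 155,
                                      tests = 2821, cost = 27.03),
                              women = c(donations = 1865, deferrals = 182,
                                        tests = 2047, cost = 27.39)) {
  A <- rbind(c(men[["tests"]], men[["deferrals"]]),
             c(women[["tests"]], women[["deferrals"]]))
  b <- c((men[["cost"]] - base) * men[["donations"]],
         (women[["cost"]] - base) * women[["donations"]])
  x <- solve(A, b)
  c(onsession_test = x[1], low_hb_deferral = x[2])
}

#' Cost per donation
#'
#' `(base x donations + test cost x on-session tests + deferral cost x
#' low-Hb deferrals) / donations`, over the return-visit tallies.
#'
#' @param result A [run_strategy()] result or named counts vector (needs
#'   `over_threshold_donation`, `under_threshold_donation`,
#'   `low_hb_deferral`, `onsession_tests`).
#' @param costs A [cost_params()] bundle.
#' @return GBP per donation.
#' @export
cost_per_donation <- function(result, costs = cost_params()) {
  ct <- result_counts(result)
  donations <- ct[["over_threshold_donation"]] + ct[["under_threshold_donation"]]
  if (donations <= 0) stop_config("cost per donation undefined: no donations")
  (costs$base_cost_per_donation * donations +
      costs$onsession_test_unit_cost * ct[["onsession_tests"]] +
      costs$low_hb_deferral_unit_cost * ct[["low_hb_deferral"]]) / donations
}

#' Preference weights
#'
#' `T_UD` and `T_LD` are the numbers of donations the blood service is
#' willing to lose to avoid one under-threshold donation and one
#' low-hemoglobin deferral respectively.
#'
#' @param T_UD,T_LD Nonnegative weights.
#' @return An object of class `preference_weights`.
#' @export
preference_weights <- function(T_UD, T_LD) {
  if (!is.finite(T_UD) || !is.finite(T_LD) || T_UD < 0 || T_LD < 0) {
    stop_config("preference weights must be nonnegative")
  }
  structure(list(T_UD = T_UD, T_LD = T_LD), class = "preference_weights")
}

#' Utility of a strategy in donation-equivalents
#'
#' `total donations - T_UD x under-threshold donations - T_LD x low-Hb
#' deferrals` (linear in counts).
#'
#' @param result A [run_strategy()] result or named counts vector.
#' @param w A [preference_weights()] object.
#' @return Utility in donation-equivalents.
#' @export
utility <- function(result, w) {
  if (!inherits(w, "preference_weights")) stop_config("w must be preference_weights")
  ct <- result_counts(result)
  (ct[["over_threshold_donation"]] + ct[["under_threshold_donation"]]) -
    w$T_UD * ct[["under_threshold_donation"]] -
    w$T_LD * ct[["low_hb_deferral"]]
}

#' National projection of annual event counts
#'
#' Splits the annual national donation total by the male:female donation
#' ratio (men get `mf_ratio / (mf_ratio + 1)`), converts the simulated
#' per-1000-donor tallies into a donors-equivalent for that many donations,
#' and scales every event count accordingly. Counts are reported in
#' thousands (rounded); the total-visits column is the sum of the rounded
#' event columns (non-hemoglobin deferrals are not considered).
#'
#' @param result A [run_strategy()] result, or a named *per-1000-donor*
#'   vector (`over_threshold_donation`, `under_threshold_donation`,
#'   `low_hb_deferral`) together with `sex`.
#' @param annual_donations National annual whole-blood donations.
#' @param mf_ratio Male:female donation ratio.
#' @param sex Needed only when `result` is a raw vector.
#' @return A one-row `data.frame` with event counts in thousands.
#' @export
#' @examples
#' project_national(c(over_threshold_donation = 2601,
#'                    under_threshold_donation = 65,
#'                    low_hb_deferral = 155), sex = "male")
project_national <- function(result, annual_donations = 1.4e6, mf_ratio = 1.50,
                             sex = NULL) {
  if (inherits(result, "sim_result")) {
    per1000 <- result$per_1000
    sex <- result$sex
    strategy <- result$strategy
  } else {
    per1000 <- result
    strategy <- NA_character_
    if (is.null(sex)) stop_config("sex must be supplied with raw per-1000 counts")
  }
  check_sex(sex)
  donations_per_1000 <- per1000[["over_threshold_donation"]] + per1000[["under_threshold_donation"]]
  if (donations_per_1000 <= 0) stop_config("projection undefined: no donations")
  share <- if (sex == "male") mf_ratio / (mf_ratio + 1) else 1 / (mf_ratio + 1)
  sex_donations <- annual_donations * share
  donors_equiv <- sex_donations / (donations_per_1000 / 1000)
  k <- function(x) round(x * donors_equiv / 1000 / 1000)  # thousands
  over_k <- k(per1000[["over_threshold_donation"]])
  under_k <- k(per1000[["under_threshold_donation"]])
  def_per_1000 <- if ("low_hb_deferral" %in% names(per1000)) per1000[["low_hb_deferral"]] else 0
  def_k <- k(def_per_1000)
  data.frame(
    sex = sex, strategy = strategy,
    annual_donations_sex = sex_donations,
    donors_equivalent = donors_equiv,
    over_thousand = over_k, under_thousand = under_k,
    low_hb_deferral_thousand = def_k,
    total_visits_thousand = over_k + under_k + def_k,
    stringsAsFactors = FALSE
  )
}

#' Internal validation against an observed event row
#'
#' Side-by-side simulated vs observed per-1000 tallies with absolute and
#' relative differences and event-percentage differences.
#'
#' @param sim A [run_strategy()] result for the current strategy.
#' @param observed Named per-1000 vector (`over_threshold_donation`,
#'   `under_threshold_donation`, `low_hb_deferral`, optionally
#'   `onsession_tests`).
#' @param horizon Follow-up the observed row covers (weeks).
#' @return A `data.frame` comparison table.
#' @export
validate_current <- function(sim, observed, horizon = 78) {
  if (!inherits(sim, "sim_result")) stop_config("sim must be a sim_result")
  if (!isTRUE(all.equal(sim$horizon, horizon))) {
    stop_config("horizon mismatch: simulated %g vs observed %g weeks", sim$horizon, horizon)
  }
  metrics <- intersect(c("over_threshold_donation", "under_threshold_donation",
                         "low_hb_deferral", "onsession_tests"), names(observed))
  simv <- sim$per_1000[metrics]
  obsv <- observed[metrics]
  simpct <- event_percentages(sim$per_1000[["over_threshold_donation"]],
                              sim$per_1000[["under_threshold_donation"]],
                              sim$per_1000[["low_hb_deferral"]])
  obspct <- event_percentages(observed[["over_threshold_donation"]],
                              observed[["under_threshold_donation"]],
                              observed[["low_hb_deferral"]])
  out <- data.frame(
    metric = c(metrics, names(simpct)[1:3]),
    simulated = c(unname(simv), unname(simpct[1:3])),
    observed = c(unname(obsv), unname(obspct[1:3])),
    stringsAsFactors = FALSE
  )
  out$abs_diff <- out$simulated - out$observed
  out$rel_diff <- ifelse(out$observed != 0, out$abs_diff / out$observed, NA_real_)
  out
}
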