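#' Regulatory hemoglobin threshold
#'
#' 135 g/L for men and 125 g/L for women; donations below this are
#' under-threshold and the on-session test aims to defer them.
#'
#' @param sex `"male"` or `"female"` (vectorised).
#' @return Threshold in g/L.
#' @export
hb_threshold <- function(sex) {
  ifelse(sex == "male", 135, 125)
}

hb_categories <- function() c("very_low", "low", "medium", "high")

#' Categorise a hemoglobin value
#'
#' Sex-specific strata: men `<125 / 125-134 / 135-144 / >=145` g/L and women
#' `<115 / 115-124 / 125-134 / >=135` g/L, labelled `very_low, low, medium,
#' high`. Boundaries are closed on the left, so 125 g/L is `low` for a man
#' and `medium` for a woman; the donation threshold coincides with the
#' low/medium boundary.
#'
#' @param hb Hemoglobin in g/L (> 0), vectorised.
#' @param sex `"male"` or `"female"`, recycled.
#' @return Character vector of category labels.
#' @export
#' @examples
#' categorize_hb(c(124, 125, 135, 153), "male")
categorize_hb <- function(hb, sex) {
  if (any(hb <= 0, na.rm = TRUE)) stop_config("hemoglobin must be positive")
  offs <- ifelse(rep(sex, length.out = length(hb)) == "male", 0, -10)
  cut_idx <- 1L + (hb >= 125 + offs) + (hb >= 135 + offs) + (hb >= 145 + offs)
  hb_categories()[cut_idx]
}

standard_interval <- function(sex) ifelse(sex == "male", 12, 16)

#' Strategy specification
#'
#' Encodes one screening strategy: the post-donation-hemoglobin
#' category-to-reinvitation-interval map per sex, the on-session test
#' triggering rule, and the deferral reinvitation bands. Five built-ins:
#'
#' * `current`: universal on-session testing; every donation reinvited at
#'   the standard interval (12 weeks men / 16 weeks women).
#' * `A` (PDT-only): no on-session testing for returning donors;
#'   reinvitation 52/26/standard/standard weeks for very-low/low/medium/high
#'   post-donation hemoglobin.
#' * `B`: as A, but on-session testing if low (or very low) hemoglobin at
#'   the previous visit or previously deferred; under-threshold donations
#'   reinvited after R2 = 26 weeks.
#' * `C`: as B but testing also after a medium previous visit.
#' * `D`: as C but without delayed reinvitation -- R2 = 12 weeks (men) /
#'   16 weeks (women), the standard interval.
#'
#' An on-session low-hemoglobin deferral always triggers reinvitation after
#' R1 = 12 weeks (borderline band) or 52 weeks (very-low band) and an
#' on-session test at the next visit; other deferrals reinvite after 4
#' weeks. New donors are always tested.
#'
#' @param name One of `"current", "A", "B", "C", "D"`, or `"custom"`.
#' @param donation_interval For `custom`: a 4 x 2 numeric matrix of weeks,
#'   rows `very_low, low, medium, high`, columns `male, female`.
#' @param test_rule For `custom`: one of `"always"`, `"new_only"`,
#'   `"low_or_deferred"`, `"low_medium_or_deferred"`.
#' @param R1 Reinvitation interval after an on-session borderline deferral.
#' @param deferral_intervals Named vector `c(borderline =, very_low =)`.
#' @param other_deferral_interval Reinvitation after a non-Hb deferral.
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name,
                          donation_interval = NULL,
                          test_rule = NULL,
                          R1 = 12,
                          deferral_intervals = c(borderline = 12, very_low = 52),
                          other_deferral_interval = 4) {
  builtin <- c("current", "A", "B", "C", "D")
  if (!(name %in% c(builtin, "custom"))) {
    stop_config("unknown strategy \"%s\"", name)
  }
  std <- c(male = 12, female = 16)
  mk <- function(vl, lo, me = std, hi = std) {
    m <- rbind(very_low = rep(vl, length.out = 2), low = rep(lo, length.out = 2),
               medium = me, high = hi)
    colnames(m) <- c("male", "female")
    m
  }
  if (name != "custom") {
    donation_interval <- switch(name,
      current = mk(std, std),
      A = mk(52, 26),
      B = mk(52, 26),
      C = mk(52, 26),
      D = mk(52, std)
    )
    test_rule <- switch(name,
      current = "always",
      A = "new_only",
      B = "low_or_deferred",
      C = "low_medium_or_deferred",
      D = "low_medium_or_deferred"
    )
  }
  if (is.null(donation_interval) || is.null(test_rule)) {
    stop_config("custom strategies must supply donation_interval and test_rule")
  }
  if (!identical(rownames(donation_interval), hb_categories()) ||
      !identical(colnames(donation_interval), c("male", "female"))) {
    stop_config("donation_interval must have rows very_low/low/medium/high and columns male/female")
  }
  if (any(donation_interval <= 0) || any(deferral_intervals <= 0) ||
      R1 <= 0 || other_deferral_interval <= 0) {
    stop_config("all intervals must be positive")
  }
  if (!test_rule %in% c("always", "new_only", "low_or_deferred", "low_medium_or_deferred")) {
    stop_config("unknown test_rule \"%s\"", test_rule)
  }
  structure(
    list(name = name, donation_interval = donation_interval,
         test_rule = test_rule, R1 = R1,
         deferral_intervals = deferral_intervals[c("borderline", "very_low")],
         other_deferral_interval = other_deferral_interval),
    class = "strategy_spec"
  )
}

#' @export
print.strategy_spec <- function(x, ...) {
  cat(sprintf("Strategy \"%s\" (test rule: %s)\n", x$name, x$test_rule))
  print(x$donation_interval)
  cat(sprintf("  deferral bands: borderline %g w, very low %g w; other deferral %g w\n",
              x$deferral_intervals[["borderline"]], x$deferral_intervals[["very_low"]],
              x$other_deferral_interval))
  invisible(x)
}

#' Does this visit get an on-session hemoglobin test?
#'
#' Current strategy: always. Strategy A: new donors only. Strategy B:
#' previous-visit category very low or low, or previously deferred.
#' Strategies C and D: previous-visit category very low, low or medium, or
#' previously deferred. New donors are tested under every strategy.
#'
#' @param spec A [strategy_spec()].
#' @param prev_category Previous-visit hemoglobin category (`NA` if none),
#'   vectorised.
#' @param prev_deferred Was the donor's last hemoglobin-tested visit an
#'   on-session low-Hb deferral? Vectorised.
#' @param is_new_donor Vectorised.
#' @return Logical vector.
#' @export
needs_onsession_test <- function(spec, prev_category, prev_deferred, is_new_donor) {
  n <- max(length(prev_category), length(prev_deferred), length(is_new_donor))
  prev_category <- rep(prev_category, length.out = n)
  prev_deferred <- rep(prev_deferred, length.out = n)
  is_new_donor <- rep(is_new_donor, length.out = n)
  base <- switch(spec$test_rule,
    always = rep(TRUE, n),
    new_only = rep(FALSE, n),
    low_or_deferred =
      (!is.na(prev_category) & prev_category %in% c("very_low", "low")) | prev_deferred,
    low_medium_or_deferred =
      (!is.na(prev_category) & prev_category %in% c("very_low", "low", "medium")) | prev_deferred
  )
  base | is_new_donor
}

#' Apply the on-session hemoglobin test
#'
#' Over-threshold attendees pass with probability `1 - p_false_deferral`
#' (default 1). Under-threshold attendees are deferred with probability
#' `p_catch`; the deferral band follows [categorize_hb()] (very low: 52-week
#' deferral; borderline: 12-week deferral). An uncaught under-threshold
#' attendee passes and donates under threshold.
#'
#' @param true_hb True hemoglobin in g/L, vectorised.
#' @param sex `"male"` or `"female"`, recycled.
#' @param probs An [event_probs()] bundle (supplies `p_catch` and
#'   `p_false_deferral`).
#' @param u Optional uniforms; otherwise drawn from the current stream.
#' @return Character vector in `pass, defer_borderline, defer_very_low`.
#' @export
apply_onsession_test <- function(true_hb, sex, probs, u = NULL) {
  n <- length(true_hb)
  sex <- rep(sex, length.out = n)
  if (is.null(u)) u <- stats::runif(n)
  under <- true_hb < hb_threshold(sex)
  cat <- categorize_hb(true_hb, sex)
  out <- rep("pass", n)
  deferred <- (under & u < probs$p_catch) | (!under & u < probs$p_false_deferral)
  out[deferred] <- ifelse(cat[deferred] == "very_low", "defer_very_low", "defer_borderline")
  out
}

#' Reinvitation interval and next-visit test flag after a visit
#'
#' Maps a visit outcome to the scheduling action the strategy prescribes:
#'
#' * donation (with its post-donation hemoglobin category): the strategy's
#'   category interval; the test flag follows the strategy's rule applied to
#'   the new category.
#' * on-session deferral: R1 = 12 weeks for the borderline band, 52 weeks
#'   for the very-low band; test at next visit.
#' * other deferral: 4 weeks, test flag unchanged (`NA`).
#' * failed donation: standard interval, test flag unchanged (`NA`).
#'
#' @param spec A [strategy_spec()].
#' @param outcome One of `"donation"`, `"onsession_deferral"`,
#'   `"other_deferral"`, `"failed_donation"`, vectorised.
#' @param sex `"male"` or `"female"`, recycled.
#' @param category For donations, the post-donation hemoglobin category; for
#'   on-session deferrals, the deferral band category. Vectorised.
#' @return A `data.frame` with columns `interval` (weeks) and `test_next`
#'   (logical; `NA` means "leave the flag unchanged").
#' @export
next_action <- function(spec, outcome, sex, category = NA_character_) {
  n <- max(length(outcome), length(sex), length(category))
  outcome <- rep(outcome, length.out = n)
  sex <- rep(sex, length.out = n)
  category <- rep(category, length.out = n)
  ok <- outcome %in% c("donation", "onsession_deferral", "other_deferral", "failed_donation")
  if (any(!ok)) stop_config("invalid visit outcome: %s", paste(unique(outcome[!ok]), collapse = ", "))
  if (spec$test_rule == "new_only" && any(outcome == "onsession_deferral")) {
    stop_config("a returning donor cannot receive an on-session deferral under a PDT-only strategy")
  }
  needs_cat <- outcome %in% c("donation", "onsession_deferral")
  if (any(needs_cat & (is.na(category) | !category %in% hb_categories()))) {
    stop_config("donations and on-session deferrals require a valid hemoglobin category")
  }

  interval <- numeric(n)
  test_next <- rep(NA, n)

  don <- outcome == "donation"
  if (any(don)) {
    interval[don] <- spec$donation_interval[cbind(category[don], sex[don])]
    test_next[don] <- needs_onsession_test(spec, category[don], FALSE, FALSE)
  }
  def <- outcome == "onsession_deferral"
  if (any(def)) {
    interval[def] <- ifelse(category[def] == "very_low",
                            spec$deferral_intervals[["very_low"]],
                            spec$deferral_intervals[["borderline"]])
    test_next[def] <- spec$test_rule != "new_only"
  }
  oth <- outcome == "other_deferral"
  interval[oth] <- spec$other_deferral_interval
  fail <- outcome == "failed_donation"
  interval[fail] <- standard_interval(sex[fail])

  data.frame(interval = interval, test_next = test_next)
}

#' Serialise / load a strategy specification as JSON
#'
#' @param spec A [strategy_spec()].
#' @param path File path.
#' @export
write_strategy_spec <- function(spec, path) {
  obj <- list(
    type = "strategy_spec",
    name = spec$name,
    test_rule = spec$test_rule,
    donation_interval = list(
      male = as.list(stats::setNames(spec$donation_interval[, "male"], hb_categories())),
      female = as.list(stats::setNames(spec$donation_interval[, "female"], hb_categories()))
    ),
    R1 = spec$R1,
    deferral_intervals = as.list(spec$deferral_intervals),
    other_deferral_interval = spec$other_deferral_interval
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_strategy_spec
#' @export
read_strategy_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "strategy_spec")) stop_config("%s is not a strategy spec", path)
  di <- cbind(male = unlist(obj$donation_interval$male),
              female = unlist(obj$donation_interval$female))
  rownames(di) <- hb_categories()
  strategy_spec(
    name = if (obj$name %in% c("current", "A", "B", "C", "D")) "custom" else obj$name,
    donation_interval = di,
    test_rule = obj$test_rule,
    R1 = obj$R1,
    deferral_intervals = unlist(obj$deferral_intervals),
    other_deferral_interval = obj$other_deferral_interval
  ) -> sp
  sp$name <- obj$name
  sp
}
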