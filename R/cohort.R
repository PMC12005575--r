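#' Cohort generating parameters
#'
#' Parameter bundle for the synthetic donor cohort generator, with defaults
#' matching the baseline characteristics of the study population the model
#' emulates: 8680 men / 8261 women, age ~ N(48.7, 14.2) / N(46.1, 14.0)
#' truncated to \[17, 80\], ~92% white ethnicity, the observed eight-category
#' ABO/RhD distribution, and baseline hemoglobin with marginal distribution
#' N(153, 10) g/L (men) / N(139, 9) g/L (women) truncated below at 80 g/L.
#'
#' Baseline hemoglobin is constructed as \code{hb_mean + random_intercept +
#' e0}, where the donor-level random intercept has SD \code{intercept_sd}
#' (default 7 g/L) and \code{e0} has SD \code{sqrt(hb_sd^2 - intercept_sd^2)},
#' so the marginal SD equals \code{hb_sd} while donors carry a persistent
#' hemoglobin level that also drives their return-visit values.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_mean,age_sd Age distribution (years) before truncation.
#' @param age_min,age_max Age truncation bounds (years).
#' @param hb_mean,hb_sd Marginal baseline hemoglobin mean and SD (g/L).
#' @param intercept_sd SD of the donor random intercept (g/L); must be
#'   strictly less than `hb_sd`.
#' @param hb_floor Physiological floor for baseline hemoglobin (g/L).
#' @param p_white Proportion of white ethnicity.
#' @param blood_group_probs Named probability vector over the eight groups
#'   `A+ A- B+ B- O+ O- AB+ AB-`; must sum to 1.
#' @param p_donated_last_2y Proportion who donated in the previous 2 years.
#'
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(sex,
                          age_mean = NULL, age_sd = NULL,
                          age_min = 17, age_max = 80,
                          hb_mean = NULL, hb_sd = NULL,
                          intercept_sd = 7,
                          hb_floor = 80,
                          p_white = NULL,
                          blood_group_probs = NULL,
                          p_donated_last_2y = NULL) {
  check_sex(sex)
  male <- sex == "male"
  age_mean <- age_mean %||% if (male) 48.7 else 46.1
  age_sd <- age_sd %||% if (male) 14.2 else 14.0
  hb_mean <- hb_mean %||% if (male) 153 else 139
  hb_sd <- hb_sd %||% if (male) 10 else 9
  p_white <- p_white %||% if (male) 0.917 else 0.928
  p_donated_last_2y <- p_donated_last_2y %||% if (male) 0.682 else 0.616
  blood_group_probs <- blood_group_probs %||% default_blood_group_probs(sex)

  if (age_sd <= 0 || hb_sd <= 0) stop_config("age_sd and hb_sd must be > 0")
  if (intercept_sd < 0 || intercept_sd >= hb_sd) {
    stop_config("intercept_sd must be in [0, hb_sd)")
  }
  if (age_min < 0 || age_max <= age_min) stop_config("invalid age bounds")
  for (p in c(p_white, p_donated_last_2y)) {
    if (!is.finite(p) || p < 0 || p > 1) stop_config("proportions must be in [0, 1]")
  }
  if (!identical(sort(names(blood_group_probs)), sort(blood_groups()))) {
    stop_config("blood_group_probs must be named with the eight ABO/RhD groups")
  }
  check_prob_vector(blood_group_probs, "blood_group_probs")

  structure(
    list(
      sex = sex,
      age_mean = age_mean, age_sd = age_sd,
      age_min = age_min, age_max = age_max,
      hb_mean = hb_mean, hb_sd = hb_sd,
      intercept_sd = intercept_sd, hb_floor = hb_floor,
      p_white = p_white,
      blood_group_probs = blood_group_probs[blood_groups()],
      p_donated_last_2y = p_donated_last_2y
    ),
    class = "cohort_params"
  )
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Cohort parameters (", x$sex, ")\n", sep = "")
  cat(sprintf("  age: N(%.1f, %.1f) on [%g, %g]\n", x$age_mean, x$age_sd, x$age_min, x$age_max))
  cat(sprintf("  baseline Hb: N(%g, %g) g/L, intercept SD %g, floor %g\n",
              x$hb_mean, x$hb_sd, x$intercept_sd, x$hb_floor))
  cat(sprintf("  white ethnicity: %.1f%%; donated in last 2y: %.1f%%\n",
              100 * x$p_white, 100 * x$p_donated_last_2y))
  invisible(x)
}

blood_groups <- function() c("A+", "A-", "B+", "B-", "O+", "O-", "AB+", "AB-")

# Observed eight-category blood-group frequencies by sex.
default_blood_group_probs <- function(sex) {
  counts <- if (sex == "male") {
    c("A+" = 2293, "A-" = 660, "B+" = 647, "B-" = 231,
      "O+" = 3037, "O-" = 1421, "AB+" = 319, "AB-" = 72)
  } else {
    c("A+" = 2239, "A-" = 835, "B+" = 573, "B-" = 252,
      "O+" = 2783, "O-" = 1535, "AB+" = 8, "AB-" = 36)
  }
  counts / sum(counts)
}

#' Generate a synthetic baseline donor cohort
#'
#' Draws `n` donors of one sex with ages truncated-Gaussian on
#' \[`age_min`, `age_max`\], ethnicity and blood group categorical, a donor
#' random intercept ~ N(0, `intercept_sd`), and baseline hemoglobin
#' `hb_mean + random_intercept + e0` truncated below at `hb_floor`.
#' Deterministic given `seed`.
#'
#' @param n Number of donors (>= 0).
#' @param sex `"male"` or `"female"`.
#' @param params A [cohort_params()] bundle for the same sex.
#' @param seed Integer seed.
#' @param id_prefix Prefix for donor identifiers.
#'
#' @return A `data.frame` with columns `donor_id, sex, age, ethnicity,
#'   blood_group, baseline_hb, random_intercept, donated_last_2y,
#'   is_new_donor` (the fixed CSV column order).
#' @export
#' @examples
#' men <- generate_baseline(500, "male", seed = 1)
#' mean(men$baseline_hb)
generate_baseline <- function(n, sex, params = cohort_params(sex), seed,
                              id_prefix = substr(sex, 1, 1)) {
  check_sex(sex)
  if (!inherits(params, "cohort_params")) stop_config("params must be a cohort_params object")
  if (!identical(params$sex, sex)) stop_config("params are for sex %s, not %s", params$sex, sex)
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != floor(n)) {
    stop_config("n must be a nonnegative integer")
  }
  n <- as.integer(n)

  cols <- function(age, eth, bg, u, hb, d2y) {
    data.frame(
      donor_id = if (n > 0) sprintf("%s%06d", id_prefix, seq_len(n)) else character(0),
      sex = rep(sex, n),
      age = age,
      ethnicity = eth,
      blood_group = bg,
      baseline_hb = hb,
      random_intercept = u,
      donated_last_2y = d2y,
      is_new_donor = rep(FALSE, n),
      stringsAsFactors = FALSE
    )
  }
  if (n == 0L) {
    return(cols(numeric(0), character(0), character(0), numeric(0), numeric(0), logical(0)))
  }

  with_seed(seed, {
    age <- rnorm_trunc(n, params$age_mean, params$age_sd, params$age_min, params$age_max)
    ethnicity <- ifelse(stats::runif(n) < params$p_white, "white", "other")
    bg <- sample(blood_groups(), n, replace = TRUE, prob = params$blood_group_probs)
    u <- stats::rnorm(n, 0, params$intercept_sd)
    e_sd <- sqrt(params$hb_sd^2 - params$intercept_sd^2)
    # inverse-CDF truncation of the residual so baseline_hb >= hb_floor
    e0 <- rnorm_trunc(n, 0, e_sd, lower = params$hb_floor - params$hb_mean - u)
    hb <- params$hb_mean + u + e0
    d2y <- stats::runif(n) < params$p_donated_last_2y
    cols(age, ethnicity, bg, u, hb, d2y)
  })
}

#' Generate a longitudinal training visit log with missing hemoglobin
#'
#' Simulates the cohort under the *current* strategy with known ground-truth
#' parameters and masks the recorded post-donation hemoglobin of each
#' donation independently with probability `missing_rate` (missing
#' completely at random). Event types are never masked. Both the true and
#' the observed (possibly `NA`) hemoglobin are returned so that model
#' recovery can be checked against the generating values.
#'
#' @param donors A cohort from [generate_baseline()].
#' @param true_params A list with elements `hb` ([hb_model_params()]),
#'   `attendance` ([attendance_params()]) and `probs` ([event_probs()]).
#' @param horizon Follow-up horizon in weeks (> 0).
#' @param missing_rate Probability a donation's hemoglobin record is masked,
#'   in \[0, 1).
#' @param seed Integer seed.
#'
#' @return A visit-log `data.frame` (see [run_strategy()]) with columns
#'   `true_hb` and `observed_hb`; masked records have `observed_hb = NA`.
#' @export
generate_training_log <- function(donors, true_params, horizon = 78,
                                  missing_rate, seed) {
  if (!is.numeric(horizon) || horizon <= 0) stop_config("horizon must be > 0")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop_config("missing_rate must be in [0, 1)")
  }
  for (el in c("hb", "attendance", "probs")) {
    if (is.null(true_params[[el]])) stop_config("true_params$%s missing", el)
  }
  sex <- unique(donors$sex)
  if (length(sex) != 1L) stop_config("donors must be single-sex")

  res <- run_strategy(
    donors, strategy_spec("current"),
    hb_params = true_params$hb,
    att_params = true_params$attendance,
    probs = true_params$probs,
    horizon = horizon,
    seed = derive_seed(seed, "training_log"),
    keep_log = TRUE
  )
  log <- res$log
  is_donation <- log$event %in% c("over_threshold_donation", "under_threshold_donation")
  log$observed_hb <- log$true_hb
  mask <- with_seed(derive_seed(seed, "training_mask"),
                    stats::runif(nrow(log)) < missing_rate)
  log$observed_hb[is_donation & mask] <- NA_real_
  # hemoglobin is only ever recorded for donations (post-donation sample)
  log$observed_hb[!is_donation] <- NA_real_
  log
}

#' Write / read a donor cohort as CSV
#'
#' Fixed column order `donor_id, sex, age, ethnicity, blood_group,
#' baseline_hb, random_intercept, donated_last_2y, is_new_donor`; UTF-8,
#' comma separator, header row, `.` decimal.
#'
#' @param donors A cohort `data.frame`.
#' @param path File path.
#' @return `path`, invisibly (writer) or the cohort `data.frame` (reader).
#' @export
write_cohort_csv <- function(donors, path) {
  cols <- c("donor_id", "sex", "age", "ethnicity", "blood_group",
            "baseline_hb", "random_intercept", "donated_last_2y", "is_new_donor")
  missing <- setdiff(cols, names(donors))
  if (length(missing)) stop_config("cohort is missing columns: %s", paste(missing, collapse = ", "))
  utils::write.csv(donors[, cols], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
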