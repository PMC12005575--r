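# Natural cubic spline basis on log time used by the flexible parametric
# (Royston-Parmar) survival model: columns 1, x, v_2(x), ..., v_{K-1}(x)
# with v_j(x) = (x - k_j)^3_+ - lambda_j (x - k_1)^3_+ -
# (1 - lambda_j)(x - k_K)^3_+ and lambda_j = (k_K - k_j) / (k_K - k_1).
rp_basis <- function(x, knots) {
  K <- length(knots)
  out <- matrix(0, length(x), K)
  out[, 1] <- 1
  out[, 2] <- x
  if (K > 2) {
    k1 <- knots[1]; kK <- knots[K]
    pos3 <- function(z) pmax(z, 0)^3
    for (j in 2:(K - 1)) {
      lam <- (kK - knots[j]) / (kK - k1)
      out[, j + 1] <- pos3(x - knots[j]) - lam * pos3(x - k1) - (1 - lam) * pos3(x - kK)
    }
  }
  out
}

#' Invitation-to-attendance delay model parameters
#'
#' Flexible parametric (Royston-Parmar) survival model on the log
#' cumulative-hazard scale with four knots:
#' `log H(t | x) = s(log t; gamma, knots) + x' beta`, where `s` is a
#' restricted cubic spline and covariates act proportionally on the hazard.
#' Covariates are `age10` (= (age - 45) / 10), `ethnicity_other` (0/1) and
#' `donated_last_2y` (0/1). A Weibull distribution is the special case
#' `gamma = (g0, g1, 0, 0)`.
#'
#' @param sex `"male"` or `"female"`.
#' @param gamma Numeric length-4 spline coefficients.
#' @param knots Numeric length-4 strictly increasing knot positions on the
#'   log-week scale.
#' @param beta Named covariate log-hazard-ratios (subset of `age10,
#'   ethnicity_other, donated_last_2y`; missing terms are 0).
#' @param se,vcov Optional standard errors / covariance of
#'   `c(gamma, beta)`, used by the probabilistic sensitivity analysis.
#' @return An object of class `attendance_params`.
#' @export
attendance_params <- function(sex, gamma, knots, beta = numeric(0),
                              se = NULL, vcov = NULL) {
  check_sex(sex)
  if (length(gamma) != 4L || any(!is.finite(gamma))) stop_config("gamma must be 4 finite values")
  if (length(knots) != 4L || any(diff(knots) <= 0)) {
    stop_config("knots must be 4 strictly increasing log-time positions")
  }
  allowed <- c("age10", "ethnicity_other", "donated_last_2y")
  b <- stats::setNames(numeric(3), allowed)
  if (length(beta)) {
    unknown <- setdiff(names(beta), allowed)
    if (length(unknown)) stop_config("unknown delay covariates: %s", paste(unknown, collapse = ", "))
    b[names(beta)] <- beta
  }
  p <- structure(
    list(sex = sex, gamma = as.numeric(gamma), knots = as.numeric(knots),
         beta = b, se = se, vcov = vcov),
    class = "attendance_params"
  )
  # the implied cumulative hazard must be nondecreasing over the support
  xs <- seq(min(knots) - 0.5, max(knots) + 0.5, length.out = 201)
  s <- drop(rp_basis(xs, p$knots) %*% p$gamma)
  if (any(diff(s) < -1e-9)) {
    stop_config("spline coefficients imply a decreasing cumulative hazard")
  }
  p
}

#' @export
print.attendance_params <- function(x, ...) {
  cat(sprintf("Attendance delay parameters (%s)\n", x$sex))
  cat("  gamma:", paste(sprintf("%.4f", x$gamma), collapse = ", "), "\n")
  cat("  knots (log weeks):", paste(sprintf("%.3f", x$knots), collapse = ", "), "\n")
  nz <- x$beta[x$beta != 0]
  if (length(nz)) cat("  covariate effects:", paste(sprintf("%s=%.3f", names(nz), nz), collapse = ", "), "\n")
  invisible(x)
}

delay_covariate_lp <- function(params, donors) {
  params$beta[["age10"]] * (donors$age - 45) / 10 +
    params$beta[["ethnicity_other"]] * (donors$ethnicity == "other") +
    params$beta[["donated_last_2y"]] * as.numeric(donors$donated_last_2y)
}

#' Delay model survival and cumulative hazard
#'
#' @param params An [attendance_params()] bundle.
#' @param t Weeks (> 0), vectorised.
#' @param lp Covariate linear predictor (default 0, the reference donor).
#' @return Survival probability / cumulative hazard at `t`.
#' @export
delay_survival <- function(params, t, lp = 0) {
  exp(-delay_cumhaz(params, t, lp))
}

#' @rdname delay_survival
#' @export
delay_cumhaz <- function(params, t, lp = 0) {
  if (any(t <= 0)) stop_config("t must be > 0")
  exp(drop(rp_basis(log(t), params$knots) %*% params$gamma) + lp)
}

#' Sample invitation-to-attendance delays
#'
#' Inverse-CDF sampling by numerical root-finding on the spline cumulative
#' hazard: for `u ~ U(0, 1)` the delay solves
#' `H(t | x) = -log(u)`. Draws come from R's current random stream.
#'
#' @param params An [attendance_params()] bundle.
#' @param donor Donor row(s) supplying covariates; `NULL` for the reference
#'   donor.
#' @param n Number of draws (recycled over donors).
#' @param u Optional uniforms (for reproducibility checks); otherwise drawn.
#' @return Delays in weeks (strictly positive).
#' @export
sample_delay <- function(params, donor = NULL, n = 1, u = NULL) {
  lp <- if (is.null(donor)) 0 else delay_covariate_lp(params, donor)
  if (is.null(u)) u <- stats::runif(max(n, length(lp)))
  lp <- rep(lp, length.out = length(u))
  target <- log(-log(u)) - lp  # solve s(log t) = target
  vapply(target, function(tg) {
    f <- function(x) drop(rp_basis(x, params$knots) %*% params$gamma) - tg
    lo <- params$knots[1] - 10
    hi <- params$knots[4] + 10
    while (f(lo) > 0) lo <- lo - 5
    while (f(hi) < 0) hi <- hi + 5
    exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
  }, numeric(1))
}

# Precompute a monotone inverse table for fast vectorised sampling inside
# the event loop; agrees with sample_delay() to interpolation tolerance.
delay_sampler_grid <- function(params, n_grid = 512) {
  xs <- seq(params$knots[1] - 8, params$knots[4] + 8, length.out = n_grid)
  s <- drop(rp_basis(xs, params$knots) %*% params$gamma)
  list(x = xs, s = s)
}

sample_delay_grid <- function(grid, u, lp) {
  target <- log(-log(u)) - lp
  x <- stats::approx(grid$s, grid$x, xout = target, rule = 2)$y
  exp(x)
}

#' Fit the flexible parametric delay model
#'
#' Maximum-likelihood Royston-Parmar spline fit with four knots (two
#' internal), via [flexsurv::flexsurvspline()] with `scale = "hazard"`;
#' default knots at the 0/33/67/100 percentiles of the uncensored log
#' delays. The coefficient covariance is stored for the probabilistic
#' sensitivity analysis.
#'
#' @param delays A `data.frame` with columns `delay_weeks` (> 0) and
#'   `censored` (logical, `TRUE` = right-censored).
#' @param covariates Optional `data.frame` (same row order) with columns
#'   `age`, `ethnicity`, `donated_last_2y`; `NULL` fits the marginal model.
#' @param sex `"male"` or `"female"`.
#' @return An [attendance_params()] bundle.
#' @export
fit_delay_model <- function(delays, covariates = NULL, sex) {
  check_sex(sex)
  if (!all(c("delay_weeks", "censored") %in% names(delays))) {
    stop_config("delays must have columns delay_weeks and censored")
  }
  obs <- delays$delay_weeks[!delays$censored]
  if (length(obs) < 100) stop_config("need >= 100 uncensored delays (got %d)", length(obs))
  if (stats::sd(obs) < 1e-12) stop_config("cannot fit delay model: uncensored delays are all equal")
  dat <- data.frame(time = delays$delay_weeks, status = as.numeric(!delays$censored))
  fml <- survival::Surv(time, status) ~ 1
  if (!is.null(covariates)) {
    dat$age10 <- (covariates$age - 45) / 10
    dat$ethnicity_other <- as.numeric(covariates$ethnicity == "other")
    dat$donated_last_2y <- as.numeric(covariates$donated_last_2y)
    fml <- survival::Surv(time, status) ~ age10 + ethnicity_other + donated_last_2y
  }
  fit <- flexsurv::flexsurvspline(fml, data = dat, k = 2, scale = "hazard")
  cf <- fit$res[, "est"]
  gamma <- cf[c("gamma0", "gamma1", "gamma2", "gamma3")]
  beta <- cf[setdiff(names(cf), c("gamma0", "gamma1", "gamma2", "gamma3"))]
  attendance_params(
    sex = sex, gamma = unname(gamma), knots = fit$knots,
    beta = beta,
    se = fit$res[, "se"], vcov = fit$cov
  )
}

#' Attendance-related event probabilities
#'
#' @param sex `"male"` or `"female"`.
#' @param p_catch Probability an under-threshold attendee is deferred when
#'   an on-session test is applied (the only screening-misclassification
#'   channel).
#' @param p_other_deferral Per-attendance probability of a
#'   non-hemoglobin-related deferral.
#' @param p_failed_donation Per-attempted-donation probability the donation
#'   fails after passing screening.
#' @param p_dropout Per-invitation probability the donor permanently exits.
#' @param baseline Probability vector over the baseline-visit event types
#'   `donation, low_hb_deferral, failed_donation`; must sum to 1.
#' @param p_false_deferral Probability an over-threshold attendee is
#'   deferred by the on-session test (0 for the copper-sulphate + HemoCue
#'   cascade; nonzero under a HemoCue-only policy variant).
#' @param shapes Optional named list of Beta shape pairs `c(a, b)` per
#'   probability, used by the probabilistic sensitivity analysis.
#' @return An object of class `event_probs`.
#' @export
event_probs <- function(sex, p_catch, p_other_deferral, p_failed_donation,
                        p_dropout,
                        baseline = c(donation = 0.989, low_hb_deferral = 0.008,
                                     failed_donation = 0.003),
                        p_false_deferral = 0, shapes = NULL) {
  check_sex(sex)
  for (p in c(p_catch, p_other_deferral, p_failed_donation, p_dropout, p_false_deferral)) {
    if (!is.finite(p) || p < 0 || p > 1) stop_config("probabilities must be in [0, 1]")
  }
  if (!identical(sort(names(baseline)), sort(c("donation", "low_hb_deferral", "failed_donation")))) {
    stop_config("baseline must be named donation/low_hb_deferral/failed_donation")
  }
  check_prob_vector(baseline, "baseline event probabilities")
  structure(
    list(sex = sex, p_catch = p_catch, p_other_deferral = p_other_deferral,
         p_failed_donation = p_failed_donation, p_dropout = p_dropout,
         baseline = baseline[c("donation", "low_hb_deferral", "failed_donation")],
         p_false_deferral = p_false_deferral, shapes = shapes),
    class = "event_probs"
  )
}

#' @export
print.event_probs <- function(x, ...) {
  cat(sprintf("Event probabilities (%s)\n", x$sex))
  cat(sprintf("  p_catch %.4f | other deferral %.4f | failed donation %.4f | dropout %.4f\n",
              x$p_catch, x$p_other_deferral, x$p_failed_donation, x$p_dropout))
  cat(sprintf("  baseline: donation %.3f, low-Hb deferral %.3f, failed %.3f\n",
              x$baseline[1], x$baseline[2], x$baseline[3]))
  invisible(x)
}

#' Estimate event probabilities from an observed tally
#'
#' `p_catch` is estimated under the observed over-to-under-threshold
#' donation ratio assumption as
#' `deferrals / (deferrals + under-threshold donations)`; the remaining
#' probabilities are simple proportions. Binomial numerator/denominator
#' pairs are retained as Beta shapes for the probabilistic sensitivity
#' analysis.
#'
#' @param observed_counts Named numeric vector with (at least)
#'   `low_hb_deferrals` and `under_threshold_donations`; optionally
#'   `other_deferrals`, `failed_donations`, `attendances`, `dropouts`,
#'   `invitations`.
#' @param sex `"male"` or `"female"`.
#' @param ... Passed on to [event_probs()] (e.g. `baseline`, `p_dropout`).
#' @return An [event_probs()] bundle.
#' @export
#' @examples
#' # observed current-strategy counts per 1000 male donors
#' estimate_event_probs(c(low_hb_deferrals = 155, under_threshold_donations = 65),
#'                      sex = "male")$p_catch  # 155 / 220
estimate_event_probs <- function(observed_counts, sex, ...) {
  need <- c("low_hb_deferrals", "under_threshold_donations")
  missing <- setdiff(need, names(observed_counts))
  if (length(missing)) stop_config("observed_counts missing: %s", paste(missing, collapse = ", "))
  oc <- observed_counts
  if (any(oc < 0, na.rm = TRUE)) stop_config("tallies must be nonnegative")
  denom <- oc[["low_hb_deferrals"]] + oc[["under_threshold_donations"]]
  if (denom <= 0) {
    stop_config("cannot estimate p_catch: low_hb_deferrals + under_threshold_donations is zero")
  }
  p_catch <- oc[["low_hb_deferrals"]] / denom
  shapes <- list(p_catch = c(oc[["low_hb_deferrals"]], oc[["under_threshold_donations"]]))

  ratio <- function(num, den) {
    if (!all(c(num, den) %in% names(oc))) return(NULL)
    if (oc[[den]] <= 0) stop_config("cannot estimate %s/%s: %s tally is zero", num, den, den)
    oc[[num]] / oc[[den]]
  }
  p_other <- ratio("other_deferrals", "attendances")
  p_failed <- ratio("failed_donations", "attendances")
  p_drop <- ratio("dropouts", "invitations")
  if (!is.null(p_other)) shapes$p_other_deferral <- c(oc[["other_deferrals"]], oc[["attendances"]] - oc[["other_deferrals"]])
  if (!is.null(p_failed)) shapes$p_failed_donation <- c(oc[["failed_donations"]], oc[["attendances"]] - oc[["failed_donations"]])
  if (!is.null(p_drop)) shapes$p_dropout <- c(oc[["dropouts"]], oc[["invitations"]] - oc[["dropouts"]])

  args <- list(...)
  event_probs(
    sex = sex,
    p_catch = p_catch,
    p_other_deferral = p_other %||% args$p_other_deferral %||% 0,
    p_failed_donation = p_failed %||% args$p_failed_donation %||% 0,
    p_dropout = p_drop %||% args$p_dropout %||% 0,
    baseline = args$baseline %||% c(donation = 0.989, low_hb_deferral = 0.008,
                                    failed_donation = 0.003),
    p_false_deferral = args$p_false_deferral %||% 0,
    shapes = shapes
  )
}
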