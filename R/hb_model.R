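#' Hemoglobin recovery basis
#'
#' The time-since-last-donation predictor enters the return-visit hemoglobin
#' model through a named saturating basis. The default,
#' `saturating_exp`, is `1 - exp(-t / tau)` with `tau` a fixed basis
#' constant (default 8 weeks), so predicted recovery is monotone in time and
#' plateaus at a donor-specific level; at `t = Inf` (no prior donation) the
#' basis equals 1, i.e. the donor sits at their plateau.
#'
#' @param name Basis name; only `"saturating_exp"` is implemented.
#' @param tau Time constant in weeks (> 0).
#' @return A `hb_basis` object.
#' @export
hb_basis <- function(name = "saturating_exp", tau = 8) {
  if (!identical(name, "saturating_exp")) {
    stop_config("unknown recovery basis \"%s\" (implemented: saturating_exp)", name)
  }
  if (!is.numeric(tau) || tau <= 0) stop_config("tau must be > 0")
  structure(list(name = name, tau = tau), class = "hb_basis")
}

#' @rdname hb_basis
#' @param basis A `hb_basis` object.
#' @param t Weeks since last donation (>= 0; `Inf` allowed).
#' @export
eval_hb_basis <- function(basis, t) {
  if (any(t < 0, na.rm = TRUE)) stop_config("time since donation must be >= 0")
  out <- 1 - exp(-t / basis$tau)
  out[is.infinite(t)] <- 1
  out
}

hb_coef_names <- function() {
  c("recovery", "baseline_hb", "age", "ethnicity_other",
    paste0("blood_group", setdiff(blood_groups(), "O+")))
}

#' Hemoglobin model parameters
#'
#' Parameter bundle for the sex-specific linear mixed model of hemoglobin at
#' return visits: `hb = intercept + coef["recovery"] * basis(t) +
#' coef["baseline_hb"] * baseline_hb + coef["age"] * age + ethnicity and
#' blood-group contrasts + donor random intercept + residual`. Blood group
#' enters as treatment contrasts against O+ (the most frequent group).
#'
#' @param sex `"male"` or `"female"`.
#' @param intercept Fixed intercept (g/L).
#' @param coefficients Named numeric vector; any subset of
#'   `recovery, baseline_hb, age, ethnicity_other, blood_groupA+, ...`
#'   (unnamed terms default to 0).
#' @param random_intercept_sd Donor-level SD (g/L), >= 0.
#' @param residual_sd Within-donor residual SD (g/L), > 0.
#' @param basis A [hb_basis()].
#' @param se Optional named vector of standard errors for
#'   `c("(Intercept)", coefficient names)`, used by the probabilistic
#'   sensitivity analysis.
#' @param vcov Optional covariance matrix of the fixed effects.
#' @param logLik Optional fitted log-likelihood.
#' @return An object of class `hb_model_params`.
#' @export
hb_model_params <- function(sex, intercept, coefficients = numeric(0),
                            random_intercept_sd, residual_sd,
                            basis = hb_basis(), se = NULL, vcov = NULL,
                            logLik = NULL) {
  check_sex(sex)
  if (random_intercept_sd < 0) stop_config("random_intercept_sd must be >= 0")
  if (residual_sd <= 0) stop_config("residual_sd must be > 0")
  coefs <- stats::setNames(numeric(length(hb_coef_names())), hb_coef_names())
  if (length(coefficients)) {
    unknown <- setdiff(names(coefficients), names(coefs))
    if (length(unknown)) stop_config("unknown coefficients: %s", paste(unknown, collapse = ", "))
    coefs[names(coefficients)] <- coefficients
  }
  p <- structure(
    list(sex = sex, intercept = intercept, coefficients = coefs,
         random_intercept_sd = random_intercept_sd, residual_sd = residual_sd,
         basis = basis, se = se, vcov = vcov, logLik = logLik),
    class = "hb_model_params"
  )
  # mean recovery must be nondecreasing over the plausible range
  tt <- seq(2, 80, by = 0.5)
  rec <- p$intercept + coefs[["recovery"]] * eval_hb_basis(basis, tt)
  if (any(diff(rec) < -1e-9)) {
    stop_config("predicted mean recovery must be nondecreasing over [2, 80] weeks")
  }
  p
}

#' @export
print.hb_model_params <- function(x, ...) {
  cat(sprintf("Hemoglobin mixed-model parameters (%s)\n", x$sex))
  cat(sprintf("  intercept %.3f; random intercept SD %.3f; residual SD %.3f\n",
              x$intercept, x$random_intercept_sd, x$residual_sd))
  cat(sprintf("  basis: %s (tau = %g weeks)\n", x$basis$name, x$basis$tau))
  nz <- x$coefficients[x$coefficients != 0]
  if (length(nz)) {
    cat("  nonzero coefficients:\n")
    for (nm in names(nz)) cat(sprintf("    %-16s %8.4f\n", nm, nz[[nm]]))
  }
  invisible(x)
}

# Static (time-invariant) part of the linear predictor for each donor,
# excluding the random intercept: baseline Hb, age, ethnicity and blood
# group contributions plus the fixed intercept.
hb_static_lp <- function(params, donors) {
  co <- params$coefficients
  lp <- params$intercept +
    co[["baseline_hb"]] * donors$baseline_hb +
    co[["age"]] * donors$age +
    co[["ethnicity_other"]] * (donors$ethnicity == "other")
  for (g in setdiff(blood_groups(), "O+")) {
    cg <- co[[paste0("blood_group", g)]]
    if (cg != 0) lp <- lp + cg * (donors$blood_group == g)
  }
  lp
}

#' Expected hemoglobin at a return visit
#'
#' Deterministic linear predictor plus the donor's random intercept; no
#' residual noise. Vectorised over donors (rows) and `t` jointly.
#'
#' @param params A [hb_model_params()] bundle.
#' @param donor One or more donor rows from [generate_baseline()].
#' @param t_since_donation Weeks since the donor's most recent donation
#'   (>= 0; `Inf` if the donor has never donated).
#' @return Expected hemoglobin in g/L.
#' @export
mean_return_hb <- function(params, donor, t_since_donation) {
  if (!inherits(params, "hb_model_params")) stop_config("params must be hb_model_params")
  if (any(t_since_donation < 0, na.rm = TRUE)) {
    stop_config("t_since_donation must be >= 0")
  }
  hb_static_lp(params, donor) + donor$random_intercept +
    params$coefficients[["recovery"]] * eval_hb_basis(params$basis, t_since_donation)
}

#' Sample hemoglobin at a return visit
#'
#' [mean_return_hb()] plus a Gaussian residual with SD `residual_sd`. Draws
#' come from R's current random stream; wrap in `set.seed()` (or pass the
#' containing simulation a seed) for reproducibility.
#'
#' @inheritParams mean_return_hb
#' @param n Number of draws per donor/time combination.
#' @return Sampled hemoglobin in g/L.
#' @export
sample_return_hb <- function(params, donor, t_since_donation, n = 1) {
  mu <- mean_return_hb(params, donor, t_since_donation)
  mu <- rep(mu, length.out = max(length(mu), n))
  mu + stats::rnorm(length(mu), 0, params$residual_sd)
}

#' Fit the sex-specific hemoglobin linear mixed model
#'
#' Fits `observed_hb ~ basis(t since last donation) + baseline_hb + age +
#' ethnicity + blood group + (1 | donor)` by REML with [lme4::lmer()] on the
#' return-visit donation records with observed (unmasked) hemoglobin.
#' Masked records are ignored. The fitted coefficient standard errors and
#' covariance are stored for the probabilistic sensitivity analysis.
#'
#' @param log A visit log (from [run_strategy()] or
#'   [generate_training_log()]) with an `observed_hb` column.
#' @param sex `"male"` or `"female"`.
#' @param donors Donor covariate table; defaults to the cohort attached to
#'   the log.
#' @param basis The recovery [hb_basis()] (fixed, not estimated).
#' @param min_donors Minimum number of donors with >= 2 observed visits.
#' @return A fitted [hb_model_params()] bundle.
#' @export
fit_hb_model <- function(log, sex, donors = attr(log, "donors"),
                         basis = hb_basis(), min_donors = 30) {
  check_sex(sex)
  if (is.null(donors)) stop_config("donor covariates not supplied and not attached to log")
  if (!"observed_hb" %in% names(log)) log$observed_hb <- log$true_hb

  dat <- log[log$event %in% c("over_threshold_donation", "under_threshold_donation") &
               log$time > 0 & is.finite(log$t_since_donation), , drop = FALSE]
  dat <- dat[!is.na(dat$observed_hb), , drop = FALSE]
  if (nrow(dat) == 0L) {
    stop_config("cannot fit hemoglobin model: all return-visit hemoglobin records are masked or absent")
  }
  n_rep <- sum(table(dat$donor_id) >= 2)
  if (n_rep < min_donors) {
    stop_config("cannot fit hemoglobin model: only %d donors have >= 2 observed return visits (need >= %d)",
                n_rep, min_donors)
  }

  dat <- merge(dat, donors[, c("donor_id", "baseline_hb", "age", "ethnicity", "blood_group")],
               by = "donor_id", sort = FALSE)
  dat$rec <- eval_hb_basis(basis, dat$t_since_donation)
  dat$blood_group <- stats::relevel(factor(dat$blood_group, levels = blood_groups()), ref = "O+")
  dat$eth_other <- as.numeric(dat$ethnicity == "other")

  terms <- c("rec", "baseline_hb", "age")
  if (length(unique(dat$eth_other)) > 1) terms <- c(terms, "eth_other")
  if (nlevels(droplevels(dat$blood_group)) > 1) terms <- c(terms, "blood_group")
  fml <- stats::as.formula(paste("observed_hb ~", paste(terms, collapse = " + "), "+ (1 | donor_id)"))

  fit <- suppressMessages(lme4::lmer(
    fml, data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore", calc.derivs = FALSE)
  ))

  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  vc <- lme4::VarCorr(fit)
  ri_sd <- attr(vc$donor_id, "stddev")[[1]]
  res_sd <- stats::sigma(fit)

  rename <- function(nm) {
    nm[nm == "rec"] <- "recovery"
    nm[nm == "eth_other"] <- "ethnicity_other"
    nm <- sub("^blood_group(?=[ABO])", "blood_group", nm, perl = TRUE)
    nm
  }
  names(fe) <- rename(names(fe))
  dimnames(V) <- list(rename(rownames(V)), rename(colnames(V)))
  se <- sqrt(diag(V))

  hb_model_params(
    sex = sex,
    intercept = fe[["(Intercept)"]],
    coefficients = fe[setdiff(names(fe), "(Intercept)")],
    random_intercept_sd = ri_sd,
    residual_sd = res_sd,
    basis = basis,
    se = se, vcov = V,
    logLik = as.numeric(stats::logLik(fit))
  )
}

#' Serialise hemoglobin model parameters as JSON
#'
#' The JSON records the basis name explicitly; [read_hb_params()] refuses a
#' bundle whose basis it does not implement.
#'
#' @param params A [hb_model_params()] bundle.
#' @param path File path.
#' @export
write_hb_params <- function(params, path) {
  obj <- list(
    type = "hb_model_params",
    sex = params$sex,
    intercept = params$intercept,
    coefficients = as.list(params$coefficients),
    random_intercept_sd = params$random_intercept_sd,
    residual_sd = params$residual_sd,
    basis = list(name = params$basis$name, tau = params$basis$tau),
    se = if (!is.null(params$se)) as.list(params$se) else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_hb_params
#' @export
read_hb_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "hb_model_params")) stop_config("%s is not a hemoglobin parameter bundle", path)
  basis <- hb_basis(obj$basis$name, obj$basis$tau)  # rejects unknown bases
  hb_model_params(
    sex = obj$sex,
    intercept = obj$intercept,
    coefficients = unlist(obj$coefficients),
    random_intercept_sd = obj$random_intercept_sd,
    residual_sd = obj$residual_sd,
    basis = basis,
    se = if (!is.null(obj$se)) unlist(obj$se) else NULL
  )
}
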