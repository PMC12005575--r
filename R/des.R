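#' Resample a donor cohort with replacement
#'
#' Draws `n` donors with replacement from a base cohort, copying profiles
#' and assigning fresh donor identifiers. Deterministic given `seed`.
#'
#' @param base A cohort `data.frame` (nonempty).
#' @param n Number of donors to draw.
#' @param seed Integer seed.
#' @return A cohort `data.frame` with `n` rows.
#' @export
resample_cohort <- function(base, n, seed) {
  if (!is.data.frame(base) || nrow(base) == 0L) stop_config("base cohort must be nonempty")
  if (n < 1) stop_config("n must be >= 1")
  idx <- with_seed(seed, sample.int(nrow(base), n, replace = TRUE))
  out <- base[idx, , drop = FALSE]
  out$donor_id <- sprintf("r%07d", seq_len(n))
  rownames(out) <- NULL
  out
}

visit_event_types <- function() {
  c("over_threshold_donation", "under_threshold_donation", "low_hb_deferral",
    "other_deferral", "failed_donation", "no_show")
}

#' Simulate one strategy over the follow-up horizon
#'
#' Per-donor discrete event simulation. Every donor attends a baseline visit
#' at week 0 (event type drawn from the baseline probabilities; all donors
#' are tested at baseline under every strategy). Thereafter each cycle is:
#' invitation at the end of the mandated interval, a per-invitation dropout
#' check (permanent exit), a sampled invitation-to-attendance delay, then at
#' attendance a possible non-hemoglobin deferral, an on-session test if the
#' strategy requires one, and a donation or deferral, with the post-donation
#' hemoglobin category driving the next reinvitation via [next_action()]
#' rules. The loop runs until the horizon; donors whose sampled attendance
#' falls beyond it contribute no further events.
#'
#' All randomness comes from a single seeded stream consumed in a fixed
#' per-cycle order that does not depend on the strategy, so results are
#' reproducible and two strategies run with the same seed share common
#' random numbers donor by donor.
#'
#' The reported event tallies (`counts`, `per_1000`) cover the return visits
#' over the follow-up period, mirroring the study's 18-month event table;
#' baseline-visit events are tallied separately in `baseline_counts`.
#'
#' @param cohort A single-sex cohort from [generate_baseline()] /
#'   [resample_cohort()].
#' @param spec A [strategy_spec()].
#' @param hb_params A [hb_model_params()] bundle for the cohort's sex.
#' @param att_params An [attendance_params()] bundle for the cohort's sex.
#' @param probs An [event_probs()] bundle for the cohort's sex.
#' @param horizon Follow-up in weeks (default 78, i.e. 18 months).
#' @param seed Integer seed.
#' @param keep_log Keep the full visit log (set `FALSE` in large batch runs).
#' @return An object of class `sim_result`: strategy name, sex, `n_donors`,
#'   `horizon`, `seed`, return-visit `counts` and `per_1000` tallies,
#'   `baseline_counts`, and (if kept) the visit `log` with columns
#'   `donor_id, time, event, true_hb, category, tested_onsession,
#'   t_since_donation`.
#' @export
run_strategy <- function(cohort, spec, hb_params, att_params, probs,
                         horizon = 78, seed, keep_log = TRUE) {
  sex <- unique(cohort$sex)
  if (length(sex) != 1L) stop_config("cohort must be single-sex")
  for (b in list(hb_params, att_params, probs)) {
    if (!identical(b$sex, sex)) {
      stop_config("parameter bundle sex (%s) does not match cohort sex (%s)", b$sex, sex)
    }
  }
  if (!inherits(spec, "strategy_spec")) stop_config("spec must be a strategy_spec")
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 0 || !is.finite(horizon)) {
    stop_config("invalid horizon")
  }
  n <- nrow(cohort)
  thr <- hb_threshold(sex)[1]
  std <- standard_interval(sex)[1]
  bounds <- if (sex == "male") c(125, 135, 145) else c(115, 125, 135)
  cats <- hb_categories()

  # strategy lookups on integer category codes 1..4 (very_low..high)
  iv_don <- unname(spec$donation_interval[, sex])
  iv_def <- c(spec$deferral_intervals[["very_low"]],
              rep(spec$deferral_intervals[["borderline"]], 3))
  rule <- spec$test_rule
  test_cut <- switch(rule, always = 4L, new_only = 0L,
                     low_or_deferred = 2L, low_medium_or_deferred = 3L)

  static_hb <- hb_static_lp(hb_params, cohort) + cohort$random_intercept
  c_rec <- hb_params$coefficients[["recovery"]]
  res_sd <- hb_params$residual_sd
  tau <- hb_params$basis$tau
  delay_lp <- delay_covariate_lp(att_params, cohort)
  grid <- delay_sampler_grid(att_params)
  is_new <- cohort$is_new_donor

  K <- max(1L, as.integer(floor(horizon / spec$other_deferral_interval)) + 2L)

  tally <- stats::setNames(numeric(8), c(visit_event_types(), "onsession_tests", "attendances"))
  base_tally <- stats::setNames(
    numeric(5), c("over_threshold_donation", "under_threshold_donation",
                  "low_hb_deferral", "failed_donation", "onsession_tests"))

  log_acc <- if (keep_log) vector("list", K + 1L) else NULL

  with_seed(seed, {
    ## -- baseline visit at t = 0 (all attend, all tested) --------------------
    u_base <- stats::runif(n)
    cum <- cumsum(probs$baseline)
    hb0 <- cohort$baseline_hb
    cat0 <- findInterval(hb0, bounds) + 1L

    invite <- numeric(n)
    last_don <- rep(NA_real_, n)
    prev_cat <- rep(99L, n)   # 99 = no hemoglobin-tested visit yet
    prev_def <- rep(FALSE, n)
    exited <- rep(FALSE, n)

    don0 <- u_base < cum[1]
    def0 <- !don0 & u_base < cum[2]
    fail0 <- !don0 & !def0
    und0 <- don0 & hb0 < thr
    base_tally[["onsession_tests"]] <- n
    base_tally[["over_threshold_donation"]] <- sum(don0 & !und0)
    base_tally[["under_threshold_donation"]] <- sum(und0)
    base_tally[["low_hb_deferral"]] <- sum(def0)
    base_tally[["failed_donation"]] <- sum(fail0)

    last_don[don0] <- 0
    prev_cat[don0] <- cat0[don0]
    invite[don0] <- iv_don[cat0[don0]]
    invite[def0] <- iv_def[pmin(cat0[def0], 2L)]  # band: very-low or borderline
    prev_def[def0] <- TRUE
    prev_cat[def0] <- cat0[def0]
    invite[fail0] <- std

    if (keep_log) {
      ev0 <- character(n)
      ev0[don0 & !und0] <- "over_threshold_donation"
      ev0[und0] <- "under_threshold_donation"
      ev0[def0] <- "low_hb_deferral"
      ev0[fail0] <- "failed_donation"
      log_acc[[1L]] <- data.frame(
        donor_id = cohort$donor_id, time = 0, event = ev0, true_hb = hb0,
        category = cats[cat0], tested_onsession = TRUE,
        t_since_donation = NA_real_, stringsAsFactors = FALSE
      )
    }

    ## -- return-visit cycles -------------------------------------------------
    if (horizon > 0) {
      for (k in seq_len(K)) {
        idx <- which(!exited & invite <= horizon)
        if (!length(idx)) break
        # fixed per-cycle draw order, independent of the strategy
        u_drop <- stats::runif(n)
        u_delay <- stats::runif(n)
        u_other <- stats::runif(n)
        z_hb <- stats::rnorm(n)
        u_catch <- stats::runif(n)
        u_fail <- stats::runif(n)

        drop <- u_drop[idx] < probs$p_dropout
        if (any(drop)) {
          di <- idx[drop]
          tally[["no_show"]] <- tally[["no_show"]] + length(di)
          if (keep_log) {
            log_acc[[k + 1L]] <- data.frame(
              donor_id = cohort$donor_id[di], time = invite[di], event = "no_show",
              true_hb = NA_real_, category = NA_character_, tested_onsession = FALSE,
              t_since_donation = NA_real_, stringsAsFactors = FALSE
            )
          }
          exited[di] <- TRUE
          idx <- idx[!drop]
          if (!length(idx)) next
        }

        t_att <- invite[idx] + sample_delay_grid(grid, u_delay[idx], delay_lp[idx])
        beyond <- t_att > horizon
        if (any(beyond)) {
          exited[idx[beyond]] <- TRUE
          idx <- idx[!beyond]
          t_att <- t_att[!beyond]
          if (!length(idx)) next
        }
        m <- length(idx)
        tally[["attendances"]] <- tally[["attendances"]] + m

        tsd <- t_att - last_don[idx]
        rec <- 1 - exp(-tsd / tau)
        rec[is.na(tsd)] <- 1          # never donated: at recovery plateau
        hb <- static_hb[idx] + c_rec * rec + res_sd * z_hb[idx]
        cat_i <- findInterval(hb, bounds) + 1L

        other <- u_other[idx] < probs$p_other_deferral
        pc <- prev_cat[idx]
        tested_base <- if (rule == "always") TRUE else if (rule == "new_only") FALSE else
          (pc <= test_cut | prev_def[idx])
        tested <- !other & (is_new[idx] | tested_base)
        under <- hb < thr
        uc <- u_catch[idx]
        caught <- tested & ((under & uc < probs$p_catch) |
                              (!under & uc < probs$p_false_deferral))
        failed <- !other & !caught & u_fail[idx] < probs$p_failed_donation
        donated <- !other & !caught & !failed

        n_under <- sum(donated & under)
        n_don <- sum(donated)
        tally[["over_threshold_donation"]] <- tally[["over_threshold_donation"]] + n_don - n_under
        tally[["under_threshold_donation"]] <- tally[["under_threshold_donation"]] + n_under
        tally[["low_hb_deferral"]] <- tally[["low_hb_deferral"]] + sum(caught)
        tally[["other_deferral"]] <- tally[["other_deferral"]] + sum(other)
        tally[["failed_donation"]] <- tally[["failed_donation"]] + sum(failed)
        tally[["onsession_tests"]] <- tally[["onsession_tests"]] + sum(tested)

        nxt <- numeric(m)
        nxt[other] <- spec$other_deferral_interval
        nxt[failed] <- std
        if (any(caught)) {
          nxt[caught] <- iv_def[pmin(cat_i[caught], 2L)]
          prev_def[idx[caught]] <- TRUE
          prev_cat[idx[caught]] <- cat_i[caught]
        }
        if (n_don) {
          nxt[donated] <- iv_don[cat_i[donated]]
          di <- idx[donated]
          last_don[di] <- t_att[donated]
          prev_cat[di] <- cat_i[donated]
          prev_def[di] <- FALSE
        }
        invite[idx] <- t_att + nxt

        if (keep_log) {
          ev <- character(m)
          ev[other] <- "other_deferral"
          ev[caught] <- "low_hb_deferral"
          ev[failed] <- "failed_donation"
          ev[donated & under] <- "under_threshold_donation"
          ev[donated & !under] <- "over_threshold_donation"
          hb_v <- ifelse(other, NA_real_, hb)
          lg <- data.frame(
            donor_id = cohort$donor_id[idx], time = t_att, event = ev,
            true_hb = hb_v, category = ifelse(other, NA_character_, cats[cat_i]),
            tested_onsession = tested, t_since_donation = tsd,
            stringsAsFactors = FALSE
          )
          log_acc[[k + 1L]] <- if (is.null(log_acc[[k + 1L]])) lg else
            rbind(log_acc[[k + 1L]], lg)
        }
      }
    }
    NULL
  })

  log <- NULL
  if (keep_log) {
    log <- do.call(rbind, log_acc[!vapply(log_acc, is.null, logical(1))])
    log <- log[order(log$donor_id, log$time), , drop = FALSE]
    rownames(log) <- NULL
    attr(log, "donors") <- cohort
  }

  structure(
    list(
      strategy = spec$name, sex = sex, n_donors = n, horizon = horizon,
      seed = seed,
      counts = tally,
      per_1000 = tally * 1000 / n,
      baseline_counts = base_tally,
      log = log
    ),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Strategy \"%s\" (%s): %d donors over %g weeks (seed %s)\n",
              x$strategy, x$sex, x$n_donors, x$horizon, format(x$seed)))
  p <- x$per_1000
  cat(sprintf("  per 1000 donors: %.0f over / %.0f under / %.0f low-Hb deferrals / %.0f tests\n",
              p[["over_threshold_donation"]], p[["under_threshold_donation"]],
              p[["low_hb_deferral"]], p[["onsession_tests"]]))
  invisible(x)
}
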