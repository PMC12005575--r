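# One perturbed copy of a hemoglobin parameter bundle: Gaussian draw on the
# fixed-effect scale (joint, via the stored covariance when available,
# otherwise independent normals from the stored SEs); variance components
# stay fixed. The recovery coefficient is truncated at 0 so the perturbed
# bundle keeps the monotone-recovery property.
perturb_hb_params <- function(params) {
  est <- c("(Intercept)" = params$intercept, params$coefficients)
  if (!is.null(params[["vcov"]])) {
    nm <- intersect(names(est), rownames(params[["vcov"]]))
    V <- params[["vcov"]][nm, nm, drop = FALSE]
    z <- stats::rnorm(length(nm))
    est[nm] <- est[nm] + drop(chol(V + diag(1e-12, nrow(V))) %*% z)
  } else if (!is.null(params[["se"]])) {
    nm <- intersect(names(est), names(params[["se"]]))
    est[nm] <- est[nm] + stats::rnorm(length(nm), 0, params[["se"]][nm])
  }
  est["recovery"] <- max(est[["recovery"]], 0)
  hb_model_params(
    sex = params$sex, intercept = est[["(Intercept)"]],
    coefficients = est[setdiff(names(est), "(Intercept)")],
    random_intercept_sd = params$random_intercept_sd,
    residual_sd = params$residual_sd,
    basis = params$basis
  )
}

# Perturbed attendance bundle; retries until the drawn spline keeps a
# nondecreasing cumulative hazard, falling back to the point estimate.
perturb_attendance_params <- function(params, max_tries = 20) {
  est <- c(params$gamma, params$beta)
  nm_g <- seq_len(4)
  for (i in seq_len(max_tries)) {
    cand <- est
    if (!is.null(params[["se"]])) {
      se <- rep(0, length(est))
      se[seq_along(params[["se"]])] <- params[["se"]]
      cand <- est + stats::rnorm(length(est), 0, se)
    }
    ok <- tryCatch({
      attendance_params(params$sex, gamma = cand[nm_g], knots = params$knots,
                        beta = stats::setNames(cand[-nm_g], names(params$beta)))
    }, error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
  params
}

# Perturbed event probabilities: Beta draws where Beta shapes are stored,
# otherwise the point value. Baseline event probabilities are redrawn from
# their trinomial proportions with the stored effective sample size.
perturb_event_probs <- function(probs) {
  draw <- function(name, value) {
    sh <- probs$shapes[[name]]
    if (is.null(sh) || any(sh <= 0)) return(value)
    stats::rbeta(1, sh[1], sh[2])
  }
  baseline <- probs$baseline
  n0 <- probs$shapes[["baseline_n"]]
  if (!is.null(n0) && n0 > 0) {
    cnt <- stats::rmultinom(1, size = n0, prob = probs$baseline)[, 1]
    baseline <- (cnt + 0.5) / sum(cnt + 0.5)
    names(baseline) <- names(probs$baseline)
  }
  event_probs(
    sex = probs$sex,
    p_catch = draw("p_catch", probs$p_catch),
    p_other_deferral = draw("p_other_deferral", probs$p_other_deferral),
    p_failed_donation = draw("p_failed_donation", probs$p_failed_donation),
    p_dropout = draw("p_dropout", probs$p_dropout),
    baseline = baseline,
    p_false_deferral = probs$p_false_deferral,
    shapes = probs$shapes
  )
}

#' Probabilistic sensitivity analysis
#'
#' Repeatedly redraws all model parameters from their uncertainty
#' distributions (Gaussian on the coefficient scale using stored
#' covariances or SEs; Beta for probabilities), re-runs every strategy on
#' the same cohort with common random numbers within each draw, and
#' summarises the draws by 95% percentile uncertainty intervals and by the
#' probability that each strategy beats the current strategy in utility
#' over a lattice of preference weights.
#'
#' @param cohort Single-sex cohort (typically [resample_cohort()] output).
#' @param base_params List with `hb`, `attendance`, `probs` bundles carrying
#'   uncertainty (SEs / covariances / Beta shapes).
#' @param strategies Character vector of strategy names (must include
#'   `"current"` for the probability-better comparison).
#' @param n_samples Number of PSA draws (>= 2; the study design uses 500).
#' @param horizon Follow-up in weeks.
#' @param seed Integer seed (drives both parameter draws and simulations).
#' @param weights_grid Values for both `T_UD` and `T_LD`; the
#'   probability-better grid is their Cartesian product.
#' @param costs A [cost_params()] bundle.
#' @param vary_run_seed If `FALSE`, every draw reuses the same simulation
#'   seed, so with degenerate (point-mass) parameter uncertainty the draws
#'   are identical and the intervals collapse.
#' @return An object of class `psa_result` with elements `draws` (long
#'   `data.frame`), `ui` (2.5/50/97.5 percentiles per strategy and metric),
#'   `prob_better` (grid over `(T_UD, T_LD)`), `n_samples`, `seed`.
#' @export
run_psa <- function(cohort, base_params, strategies = c("current", "A", "B", "C", "D"),
                    n_samples = 500, horizon = 78, seed,
                    weights_grid = c(10, 20, 40), costs = cost_params(),
                    vary_run_seed = TRUE) {
  if (n_samples < 2) stop_config("n_samples must be >= 2")
  specs <- lapply(strategies, strategy_spec)
  names(specs) <- strategies
  wgrid <- expand.grid(T_UD = weights_grid, T_LD = weights_grid)

  param_seed <- derive_seed(seed, "psa_params")
  rows <- vector("list", n_samples * length(strategies))
  r <- 0L
  for (s in seq_len(n_samples)) {
    drawn <- with_seed(param_seed + s, list(
      hb = perturb_hb_params(base_params$hb),
      attendance = perturb_attendance_params(base_params$attendance),
      probs = perturb_event_probs(base_params$probs)
    ))
    run_seed <- if (vary_run_seed) derive_seed(seed, paste0("psa_run", s)) else derive_seed(seed, "psa_run")
    for (st in strategies) {
      res <- run_strategy(cohort, specs[[st]], drawn$hb, drawn$attendance,
                          drawn$probs, horizon = horizon, seed = run_seed,
                          keep_log = FALSE)
      ct <- res$per_1000
      pct <- event_percentages(ct[["over_threshold_donation"]],
                               ct[["under_threshold_donation"]],
                               ct[["low_hb_deferral"]], ct[["onsession_tests"]])
      util <- vapply(seq_len(nrow(wgrid)), function(i) {
        utility(res, preference_weights(wgrid$T_UD[i], wgrid$T_LD[i]))
      }, numeric(1))
      r <- r + 1L
      rows[[r]] <- data.frame(
        draw = s, strategy = st,
        over_per_1000 = ct[["over_threshold_donation"]],
        under_per_1000 = ct[["under_threshold_donation"]],
        low_hb_deferral_per_1000 = ct[["low_hb_deferral"]],
        tests_per_1000 = ct[["onsession_tests"]],
        pct_over = pct[["pct_over"]], pct_under = pct[["pct_under"]],
        pct_low_hb_deferral = pct[["pct_low_hb_deferral"]],
        cost_per_donation = cost_per_donation(res, costs),
        t(stats::setNames(util, sprintf("utility_%g_%g", wgrid$T_UD, wgrid$T_LD))),
        stringsAsFactors = FALSE
      )
    }
  }
  draws <- do.call(rbind, rows)

  metric_cols <- setdiff(names(draws), c("draw", "strategy"))
  ui <- do.call(rbind, lapply(strategies, function(st) {
    d <- draws[draws$strategy == st, metric_cols, drop = FALSE]
    qs <- t(vapply(d, stats::quantile, numeric(3), probs = c(0.025, 0.5, 0.975), names = FALSE))
    data.frame(strategy = st, metric = metric_cols,
               lower = qs[, 1], median = qs[, 2], upper = qs[, 3],
               stringsAsFactors = FALSE)
  }))
  rownames(ui) <- NULL

  prob_better <- NULL
  if ("current" %in% strategies && length(strategies) > 1) {
    cur <- draws[draws$strategy == "current", , drop = FALSE]
    cur <- cur[order(cur$draw), , drop = FALSE]
    prob_better <- do.call(rbind, lapply(setdiff(strategies, "current"), function(st) {
      d <- draws[draws$strategy == st, , drop = FALSE]
      d <- d[order(d$draw), , drop = FALSE]
      data.frame(
        strategy = st,
        T_UD = wgrid$T_UD, T_LD = wgrid$T_LD,
        prob_better = vapply(seq_len(nrow(wgrid)), function(i) {
          col <- sprintf("utility_%g_%g", wgrid$T_UD[i], wgrid$T_LD[i])
          mean(d[[col]] > cur[[col]])
        }, numeric(1)),
        stringsAsFactors = FALSE
      )
    }))
    rownames(prob_better) <- NULL
  }

  structure(
    list(draws = draws, ui = ui, prob_better = prob_better,
         n_samples = n_samples, strategies = strategies,
         weights_grid = weights_grid, seed = seed,
         sex = unique(cohort$sex), n_donors = nrow(cohort)),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA (%s): %d draws x %d strategies, %d donors\n",
              x$sex, x$n_samples, length(x$strategies), x$n_donors))
  if (!is.null(x$prob_better)) {
    cat("probability better than current at T_UD = T_LD = 20:\n")
    pb <- x$prob_better[x$prob_better$T_UD == 20 & x$prob_better$T_LD == 20, ]
    for (i in seq_len(nrow(pb))) {
      cat(sprintf("  %s: %.3f\n", pb$strategy[i], pb$prob_better[i]))
    }
  }
  invisible(x)
}
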