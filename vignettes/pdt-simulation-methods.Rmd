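---
title: "Simulating stratified post-donation testing for whole-blood donors: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating stratified post-donation testing for whole-blood donors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pdtsim` is an individual-level discrete event simulation of whole-blood
donor attendance in England, built to compare the current on-session
hemoglobin screening strategy against four stratified post-donation-testing
(PDT) strategies. This vignette documents the model, its assumptions, the
calibration of the shipped parameter defaults, and the design choices made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The simulated process

Each donor is simulated independently (there are no shared resources such
as venue capacity, so a per-donor sequential loop is behaviourally
equivalent to a global event queue and much simpler). Time is continuous,
in weeks.

Every donor attends a **baseline visit** at week 0. The baseline event is
drawn from the observed baseline proportions — donation 98.9% (men) /
98.5% (women), low-Hb deferral 0.8% / 1.2%, failed donation 0.3% — and all
donors are tested at baseline under every strategy. A baseline donation is
under-threshold when the donor's baseline hemoglobin is below the
regulatory threshold (135 g/L men, 125 g/L women). Because the baseline
event type is drawn from fixed proportions rather than cascaded through
the screening model, a baseline low-Hb deferral can in principle be drawn
for an over-threshold donor; its deferral band then defaults to the
borderline (12-week) band.

Each subsequent **cycle** is:

1. *Invitation* at the end of the mandated interval set by the previous
   visit's outcome.
2. *Dropout*: with per-invitation probability `p_dropout` the donor
   permanently exits (recorded as a no-show). Dropout is memoryless; the
   study names dropout among the attendance events but does not print its
   mechanism, so a per-invitation Bernoulli exit is the simplest process
   with one interpretable rate.
3. *Delay*: an invitation-to-attendance delay is sampled from the flexible
   parametric survival model. Attendance beyond the 78-week horizon is
   censored.
4. *Attendance*: first a non-hemoglobin ("other") deferral check
   (probability `p_other_deferral`, reinvitation after 4 weeks, performed
   before any hemoglobin test); then, if the strategy requires it, the
   on-session test; then the donation attempt, which fails with
   probability `p_failed_donation` (standard-interval reinvitation, test
   flag unchanged, and the attendance consumes a test only if one was
   required).
5. *Scheduling*: a completed donation yields a post-donation hemoglobin
   category that sets the next interval and the next-visit test flag per
   the strategy's rules; an on-session deferral reinvites after 12 weeks
   (borderline band) or 52 weeks (very-low band) with a mandatory test at
   the next visit.

All randomness is consumed from one seeded stream in a fixed per-cycle
order that does not depend on the strategy, so two strategies run with the
same seed share common random numbers donor by donor. This makes paired
strategy comparisons (e.g. "strategy C catches at least as many
under-threshold attendees as B") low-variance, though still stochastic in
the downstream trajectories of the donors whose outcomes differ.

The reported tallies (`counts`, `per_1000`) cover the *return visits* over
the horizon, mirroring the study's 18-month event table, whose current-
strategy row (2601 + 65 donations per 1000 male donors) matches the
printed return-visit totals (23,140 donations / 8680 men); baseline events
are tallied separately. Event percentages use donations + low-Hb deferrals
as the denominator; other deferrals and failed donations are tallied but
excluded, and the on-session test percentage uses the same denominator.

## 2. Hemoglobin at return visits

Return-visit hemoglobin follows a sex-specific linear mixed model

```
Hb_ij = beta_0 + gamma * (1 - exp(-t_ij / tau)) + x_i' beta + u_i + e_ij,
u_i ~ N(0, sigma_u^2),  e_ij ~ N(0, sigma_e^2),
```

where `t_ij` is the time since donor *i*'s most recent donation (weeks),
and `x_i` holds baseline hemoglobin, baseline age, ethnicity (white
vs. other) and blood group (treatment contrasts against O+, the most
frequent group). The recovery predictor enters through a *named saturating
basis* `1 - exp(-t/tau)` with `tau = 8` weeks fixed: the exact functional
form used in the original analysis is not published, and a saturating
basis guarantees that predicted recovery is monotone nondecreasing in time
(an invariant the parameter constructor enforces) and plateaus at a
donor-specific level. A donor who has never donated sits at the plateau
(`t = Inf`). Parameter bundles serialise to JSON with the basis name
recorded; a bundle naming an unimplemented basis is refused.

Fitting uses `lme4::lmer` (REML) on the return-visit donation records with
observed (unmasked) hemoglobin, requiring at least 30 donors with two or
more observed visits; coefficient standard errors and the fixed-effect
covariance are stored for the probabilistic sensitivity analysis.

**Missing hemoglobin.** The study had ~39.6% (men) / 38.4% (women) of
donation hemoglobin values missing, argued to be missing at random. The
training-log generator masks each donation's *recorded* hemoglobin
independently with the configured probability — missing completely at
random, the literal testable version of that assumption — and never masks
the event type. The test suite verifies that fitting on a 40%-masked log
agrees with fitting on the unmasked log to Monte-Carlo tolerance.

## 3. The synthetic cohort

No study data are public, so a generator stands in for the baseline
cohort: 8680 men / 8261 women; age truncated-Gaussian N(48.7, 14.2²) /
N(46.1, 14.0²) on [17, 80]; ethnicity 91.7% / 92.8% white; the observed
eight-category blood-group distribution; 68.2% / 61.6% donated in the
previous two years. `is_new_donor` defaults to `FALSE` (the study enrolled
returning donors); the flag exists because new donors are always tested
under every strategy.

Baseline hemoglobin is built as `hb_mean + u_i + e0`, with `u_i` the donor
random intercept (SD 7 g/L) and `e0` sized so the *marginal* SD equals the
printed 10 (men) / 9 (women) g/L, truncated below at a physiological floor
of 80 g/L (negligible mass). Coupling the baseline value to the random
intercept gives donors a persistent hemoglobin level, which is what makes
low-hemoglobin donors cycle through repeated deferrals under the current
strategy — the mechanism behind the visit-level below-threshold fractions
being about twice the baseline ones (next section). The published
category table (men 0.2/3.0/19.8/77.0% for very-low/low/medium/high;
women 0.4/6.2/29.1/64.3%) is treated as a *baseline* marginal; the
Gaussian defaults reproduce it to within 2.5 points for men and 3 points
for women — the women's high-category mass implied by N(139, 9²) is
67.2% against the printed 64.3%, an irreducible 2.9-point gap of the
Gaussian form at the printed moments.

For mixed-model *parameter-recovery* tests the random intercepts are
redrawn independently of baseline hemoglobin (the exogeneity the fitter
assumes), and the generating `p_catch` is set to 0 so that screening does
not selectively remove low-hemoglobin donations from the training log;
with screening on, under-threshold donations are under-represented in the
log and the recovery coefficient is attenuated. What passing these tests
shows is that the estimators recover the generating process of the
synthetic cohort — not that the shipped coefficients equal the study's
(unpublished) fitted values.

## 4. Attendance delay

The invitation-to-attendance delay follows a Royston–Parmar flexible
parametric model with four knots: `log H(t|x) = s(log t) + x'beta`, with
`s` a restricted cubic spline and proportional covariate effects for
centred age, ethnicity and recent-donation history. Fitting uses
`flexsurv::flexsurvspline(k = 2, scale = "hazard")` (two internal knots,
i.e. four knots total, placed at the 0/33/67/100 percentiles of the
uncensored log delays — the package default). Sampling inverts the spline
cumulative hazard: `sample_delay()` root-finds to full precision, while
the event loop uses a 512-point monotone interpolation grid that agrees
with the root-finder to 0.1% relative tolerance (tested). Delay is
measured from the reinvitation date, consistent with a 12-week minimum
interval producing the observed ~15-week median inter-donation interval
for men. The shipped default is a Weibull — the `gamma = (g0, g1, 0, 0)`
special case of the spline family — with shape 1.3 and median 3.4 weeks.

## 5. Strategy rules

Hemoglobin categories are left-closed sex-specific strata (men <125 /
125–134 / 135–144 / ≥145 g/L; women shifted 10 g/L down), with the
donation threshold on the low/medium boundary. The five built-in
strategies differ in the test-triggering rule (always; new donors only;
low-or-deferred; low-medium-or-deferred) and in the reinvitation interval
after an under-threshold donation (26 weeks for B and C; the standard
12/16 weeks for D, the "no delayed reinvitation" variant). The on-session
test defers an under-threshold attendee with probability `p_catch`,
estimated under the study's observed over-to-under-threshold donation
ratio assumption as deferrals / (deferrals + under-threshold donations):
155/220 ≈ 0.705 (men), 182/274 ≈ 0.664 (women). The deferral *band* is
determined from the true simulated hemoglobin via the category bounds —
the study estimates only a deferral probability, not a measurement-error
model, so `p_catch` is the single misclassification channel. A HemoCue-
only on-session policy is expressible through a user-supplied `p_catch`
plus a false-deferral probability for over-threshold attendees (default
0; the relevant estimates are not published, so no numbers ship for it).

Two interpretation points, resolved as follows: the test flag follows the
*latest* hemoglobin-tested visit (a medium donation after a low episode
clears strategy B's flag); and under strategy A a deferral can only arise
at baseline, after which the flag is moot because A never tests returning
donors.

## 6. Calibration of the shipped defaults

The structural constants were fixed in advance: `tau = 8`,
`sigma_u = 7`, `sigma_e = 6`, `p_catch` at the published count ratios,
baseline event probabilities at their observed proportions. The free
knobs — the recovery amplitude `gamma` per sex, the per-invitation dropout
probability, the per-attendance other-deferral and failed-donation
probabilities, and the Weibull delay parameters — were tuned
(`analysis/03_calibrate.R` verifies the result) so that the simulated
current strategy reproduces the observed current-strategy row: per-donor
return attendances (3.28 men / 2.42 women), donations per 1000 donors
(2666 / 1865) and the event percentages (92.2/2.3/5.5 men; 86.6/4.5/8.9
women) each within one percentage point.

The calibrated amplitudes are `gamma = 38` g/L (men) and `50` g/L
(women). With the 8-week time constant these are *effective* depletion
amplitudes, not physiological post-donation drops: at the attendance times
the model actually visits (≥12 weeks since donation) they imply mean
deficits of ~3–6 g/L, which is what the observed visit-level
below-threshold fractions (7.8% of male and 13.4% of female
hemoglobin-relevant attendances, versus 3.2% / 6.6% of baselines) require.
The short time constant and the large amplitude jointly absorb the
longer-term iron-depletion dynamics that a single-visit recovery model
cannot represent; extrapolations of the recovery curve below ~8 weeks
since donation should not be interpreted.

Strategy A's headline under-threshold percentages (6.5% men, 11.8% women)
are *not* calibration targets; they emerge from the calibrated current
strategy plus the strategy rules, and the acceptance suite checks them to
±1.5 points.

## 7. Costs, utility, PSA, projection

Cost per donation is `(base × donations + c_test × tests + c_def ×
low-Hb deferrals) / donations` with base 26.20 GBP (which includes the
post-donation laboratory test; a PDT-only strategy therefore costs exactly
the base). The unit costs are not printed, so `derive_unit_costs()` solves
the 2×2 linear system formed by the men's and women's printed
current-strategy costs (27.03 / 27.39 GBP) against the base, giving
c_test ≈ 0.30 GBP and c_def ≈ 8.83 GBP; both are overridable.

Utility is linear, `U = donations − T_UD·under − T_LD·deferrals`: the
preference weights are defined verbally as exchange rates (donations the
service would forgo to avoid one adverse event), which implies linearity;
the exact published specification is in an unavailable supplement, so the
form is isolated behind the single `utility()` operation.

The PSA redraws all parameters per draw — jointly Gaussian on coefficient
scales using stored covariances (or independent SEs), Beta for
probabilities using shapes from the observed study tallies (e.g.
`p_catch ~ Beta(1345, 564)` for men); draws violating a structural
invariant (negative recovery slope, non-monotone cumulative hazard) are
redrawn, falling back to the point estimate. Within a draw, all strategies
run on the same cohort and the same random numbers, so the
probability-better grid reflects parameter uncertainty plus within-draw
stochasticity as a matched comparison; the uncertainty intervals are
percentile (2.5/97.5) rather than normal-approximation. The intervals
therefore include simulation noise as well as parameter uncertainty —
with 10,000 donors per run the parameter component dominates. For the
shipped calibrated (rather than fitted) coefficient bundles, the SEs are
fixed values of the order obtained when fitting the models to one
study-sized synthetic log; they exist to propagate plausible uncertainty,
not to replicate the study's (unpublished) covariances.

The national projection scales per-1000 rates to 1.4M annual donations
split by the 1.50 male:female donation ratio (0.84M / 0.56M), reports
thousands, and defines total visits as the sum of the rounded event
columns (non-hemoglobin deferrals excluded).

## 8. Problem sizes and reproducibility

The analysis scripts use the study-design sizes: cohorts of 8680/8261,
10,000 resampled donors, 78-week horizon, 500 PSA draws with the
{10, 20, 40}² weight lattice (the full PSA across both sexes and all five
strategies runs in minutes on one core; `analysis/05_psa.R` records its
wall time in `results/psa_timing.txt`, and takes `--quick` for a reduced
60-draw version). The test suite exercises the same code at reduced sizes
(cohorts of 500–3000, 12–50 PSA draws, 50 mixed-model replicates at 1000
donors for the Wald-coverage property) chosen so the whole suite runs in
well under a minute of simulation time while keeping Monte-Carlo margins
comfortable. Every stochastic function takes an explicit seed (or uses
R's stream, documented per function); a single seed expands into named
per-purpose child streams so adding one component never perturbs
another's draws.

## 9. Known limitations

- The synthetic generator emulates marginal distributions and the
  calibrated event flow, not real covariance between age, blood group and
  hemoglobin, nor seasonal recruitment, behavioural feedback of deferral
  on return, or measurement-device differences (Sysmex vs HemoCue).
  Passing tests show internal consistency with the published aggregate
  tables, not fidelity to individual-level study data.
- Recovery depends only on time since the last donation; cumulative
  multi-donation iron depletion is absorbed into the calibrated amplitude
  rather than modelled.
- Strategy B–D event rates depend on coefficients the study did not
  publish; they are reproduced qualitatively (ordering, direction) rather
  than to printed precision. The same holds for the probability-better
  grid: the equal-weights (20/20) behaviour and the general preference
  for the current strategy at a 40/10 weighting reproduce, but
  fine-grained exceptions in single cells of the grid need not.
- Missingness is handled as MCAR; the study's MAR claim is broader than
  what is testable here.
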