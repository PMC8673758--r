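---
title: "Methods: task simulation, the reward-state learning model, and hierarchical fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: task simulation, the reward-state learning model, and hierarchical fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(creditassign)
```

## The scientific problem

When a reward follows a choice, a learner can do two different things with
it.  It can *assign credit*: attribute that particular reward to the
particular choice that produced it, and update only that choice's value.
Or it can treat the reward as evidence that the environment is currently
good — a *global reward state* (GRS) — and become more likely to repeat
whatever it has been doing recently, regardless of which choice earned the
reward.  Distinguishing these two modes behaviourally requires a task in
which the same reward history is compatible with both readings, and a
model that carries separate machinery for each.

`creditassign` implements the full computational pipeline for such a
study: a three-option restless-bandit task in which only two options are
offered per trial; a reinforcement-learning model in which a reward trace
enters the prediction error alongside outcome-independent choice-memory
traces; hierarchical empirical-Bayes fitting; the behavioural statistics
that separate contingent learning from reward tracking
(occasion-lagged win-stay/lose-shift regressions and credit-assignment
matrices); construction of the event regressors an imaging analysis
would use; and synthetic cohorts with injected condition effects
(a "TUS" stimulation condition that lowers the learning rate) for
validating the whole chain end to end.

## Task environment

Each session has three stimuli (A, B, C) with drifting reward
probabilities; two of the three are offered per trial, sides assigned at
random, and reward is a Bernoulli draw from the chosen option's current
probability.

The schedule generator reproduces the printed constraints of the task:

* option A spans 90% to 10%, option B 70% to 30%, option C 10% to 90%;
* A and C exchange their high/low roles near the middle of the session
  (`reversal_fraction = 0.5`), so the learner always faces one
  high-probability option and two low ones;
* the three probability trajectories share less than 22% variance on
  average (mean pairwise squared Pearson correlation), so that each
  option's value history is separately identifiable.

The drift's functional form is not dictated by the task description, only
its envelope; we use a logistic high-to-low transition (width 8% of the
session) for A and its mirror image for C, a free smooth path for B, and
add Gaussian-smoothed white noise (kernel width 10 trials, amplitude 0.3
in probability units) to every trajectory before rescaling each column
affinely onto its exact printed range.  Rescaling rather than clipping
guarantees that every generated schedule attains both endpoints of its
range.  The noise amplitude was chosen so that a draw satisfies the
shared-variance bound roughly 60% of the time; `generate_schedule()`
rejection-samples up to `max_attempts` draws and reports an infeasible
configuration otherwise (for example, a zero shared-variance bound, which
finite sample correlations can never meet).

Offers are drawn i.i.d. uniformly over the three unordered pairs and
sides by a fair coin.  The task description says only "pseudo-random";
uniform i.i.d. sampling is the simplest scheme consistent with it, and
the offer-frequency tests document the consequence (each pair appears
with frequency 1/3 up to sampling error).

```{r schedule}
sch <- generate_schedule(schedule_config(seed = 42))
round(mean_shared_variance(sch), 3)
matplot(sch, type = "l", lty = 1, ylab = "p(reward)", xlab = "trial")
```

## The choice model

Three Q values (initialized at 0.5 each session; stimuli are new every
session so no state carries over) are updated at feedback for the chosen
stimulus only:

$$\mathrm{PE}_t = r_t + w_R\,R_t - Q_t(c), \qquad
  Q_{t+1}(c) = Q_t(c) + \alpha\,\mathrm{PE}_t$$

The *R-trace* $R_t$ is a running average of rewards irrespective of
choice, $R_{t+1} = R_t + \alpha_R (r_t - R_t)$, initialized at zero.  Its
weight $w_R$ inside the prediction error is the model's GRS pathway: with
$w_R > 0$, a rewarding recent environment inflates the update of whatever
was chosen, producing reward-driven perseveration without credit
assignment.  The overall influence of GRS on learning is therefore the
product $w_R \times \alpha$ (`grs_influence()`).

Two outcome-independent memory traces bias the decision: a location trace
$CL$ updated toward the chosen side (left $+1$, right $-1$) at rate
$\alpha_{CL}$, and per-stimulus traces $CS$ that decay by $\lambda_{CS}$
each trial, with the chosen stimulus reset to 1 at the end of its trial.
The decision value for a rightward choice is

$$DV_t = Q_t(\mathrm{right}) - Q_t(\mathrm{left}) + b
  + w_{CL}\,(-CL_t) + w_{CS}\,\big(CS_t(\mathrm{right}) -
  CS_t(\mathrm{left})\big)$$

passed through a softmax with inverse temperature $\beta$.  Parameters
are bounded: rates and the decay in $[0,1]$, weights and the side bias in
$[-1,1]$, $\beta \ge 0$.

Within-trial ordering follows the subscripts of the update equations:
(1) decay the CS traces; (2) form the DV and choice probability from the
current Q values, CL trace and *decayed* CS traces; (3) observe choice
and reward; (4) compute the PE with the *pre-update* R-trace; (5) update
the chosen Q; (6) update the R-trace; (7) set the chosen CS trace to 1;
(8) update the CL trace.  Steps 5–8 are mutually independent, so their
relative order is immaterial.  Two conventions are not pinned down by the
equations and are fixed here: a positive side bias favours *rightward*
choices, and all three CS traces decay on every trial, whether or not the
stimulus was on screen (the decay equation is unconditional).

The forward pass is implemented once in compiled code and used by both
the simulator and the likelihood, so simulate-then-evaluate round trips
are bit-consistent.  Choice log-probabilities go through a stable
log-sigmoid, so arbitrarily large $\beta$ cannot overflow.  With all
auxiliary parameters zero the model reduces exactly to two-option
Rescorla–Wagner with softmax, which the test suite checks against an
independently coded textbook implementation at `1e-10`.

## Hierarchical (iterative MAP) fitting

Session-level estimates use the group as prior.  Bounded parameters are
mapped to an unconstrained space (logistic sigmoid for $[0,1]$, doubled
sigmoid for $[-1,1]$, log/exp for $\beta$), where the group distribution
is Gaussian.  Fitting alternates:

* **E-step** — each session maximizes its choice log-likelihood plus the
  log prior density (MAP), via `nlminb()` in unconstrained space; the
  first iteration uses multiple starts drawn from the prior, later
  iterations warm-start from the previous estimates;
* **M-step** — the prior mean is set to the empirical mean of the
  session estimates; the prior variance is the second moment of the
  estimates *plus* the mean Laplace posterior variance of each estimate
  (diagonal of the inverse Hessian of the negative log posterior at the
  MAP), with a floor of `1e-4` for the degenerate identical-fits case.
  The uncertainty term matters: MAP point estimates are themselves shrunk
  toward the prior mean, so moments of the point estimates alone
  understate the group variance, and the resulting feedback loop drives
  the prior variance onto its floor within a few iterations — on a
  60-session cohort every parameter except the inverse temperature
  collapses to a single value, which destroys parameter recovery and all
  between-session contrasts.  Adding the Laplace term is how the
  empirical-Bayes scheme this procedure descends from re-estimates its
  group variances, and it is the package's reading of "recomputed the
  Gaussian distribution over parameters".

Priors are initialized uninformatively with means 0.1 plus seeded
Gaussian noise (SD 0.01; the magnitude of the "added noise" is not
printed anywhere, so a token value is used) and variance 100.  Iteration
stops when the posterior likelihood summed over the group — read as
$\sum_s (\log L_s + \log \pi(\hat\theta_s))$ evaluated at the MAP
estimates, the natural reading when no integration is mentioned — changes
by less than 0.001, or after 800 iterations (returning `converged =
FALSE` rather than an error).  The recorded posterior sequence is
non-decreasing up to optimizer tolerance, which the tests assert at
`1e-6`.  On study-scale cohorts the summed posterior typically keeps
creeping upward along a soft ridge between the stimulus-trace decay and
its weight, so the 0.001 absolute threshold is rarely reached before the
800-iteration cap; the cap is then reported, the trace remains monotone,
and the estimates are stable to far more precision than any downstream
analysis uses.

Sessions from both compared conditions (pooled sham plus one stimulation
condition) are always fitted together under one shared prior, so a
condition difference in fitted parameters can never be an artifact of
different priors.

The dual-learning-rate variant (separate $\alpha^+/\alpha^-$ for positive
and negative prediction errors) is fitted with identical machinery;
`fit_dual_rate_variant()` compares the two models by session-level BIC
summed over sessions, a standard penalized score chosen because no
criterion is printed for the comparison.

## Behavioural analytics

**Occasion-lagged win-stay/lose-shift.**  Because only two of three
options appear per trial, lags count *occasions on which the same
stimulus was offered again*, not raw trials.  For every occasion a
stimulus was chosen, `build_strategy_events()` records whether it was
re-chosen on the 1st/2nd/3rd subsequent occasion it was available;
occasions that never recur produce no row.  `wsls_regression()` fits, per
stimulus and session, logistic regressions of the stay indicator on the
outcome history, averaging coefficients over stimuli so each session
contributes one coefficient per regressor.  The combined scheme uses one
±1 outcome predictor per lag (centred, scaled, with intercept).  The
separate win-stay/lose-shift and maladaptive schemes are cell-means
models without an intercept — centring per-lag win and lose indicators
would make them exactly collinear with the implicit intercept, so columns
are scaled to unit SD but not centred — with lose-side coefficients
reported as *shift* log-odds so that positive values are adaptive
throughout.

**Credit-assignment matrices.**  Per stimulus X, the choice of X on
trials where X is offered is regressed on all 16 conjunctions "X chosen
at trial $t-i$" × "reward delivered at trial $t-j$", $i,j \in 1..4$;
the 3×3 sub-grid over lags 1–3 is interpreted and the lag-4 cells only
absorb longer-term trends.  Trials where X is not on screen contribute no
outcome row (the choice of X is undefined there).  The lagged choice
indicator is 0 whenever X was not chosen at that lag — including because
it was absent.  The alternative reading (set lagged indicators to missing
and drop rows listwise) leaves only $(2/3)^4 \approx 20\%$ of rows and a
rank-deficient design on essentially every 200-trial session, so it
cannot be what a working analysis does.  Diagonal dominance of the grid
(`diagonal_dominance()`) indexes contingent credit assignment; the
reward-lag margin of the grid (`grs_reward_history_profile()`) is the
behavioural GRS profile.  The conjunction (product) coding is used for
the "choices and/or reward" construction; the inclusive-or reading makes
the 16 regressors nearly collinear and was rejected.

**Performance.**  `performance_stats()` scores the frequency of choosing
the offered option with the higher model value (exact ties excluded from
the denominator), total rewards, and a rolling accuracy (window 20
trials).

**Condition contrasts.**  `condition_contrast()` fits
`value ~ condition (+ lag) + (1 | subject)` with `lmerTest`
(Satterthwaite degrees of freedom), falling back to a fixed-effects
linear model, with the downgrade recorded, when the random-effect fit is
singular — with four subjects a near-zero subject variance is not rare.
No multiplicity correction is applied; replicate-level summaries report
raw rejection rates.

## Design matrices

`build_glm1()` and `build_glm2()` emit the 16 and 15 named behavioural
regressor time series of the two imaging analyses (strategy regressors
and model-value regressors respectively), sampled on a TR = 2.28 s scan
grid.  Parametric heights are standardized (mean 0, SD 1) across their
events *before* convolution with a gamma HRF of mean 3 s and SD 1.5 s
(shape 4, scale 0.75, unit area); nuisance boxcars (left/right response,
reward/no-reward) of one TR are left unconvolved and raw.  Reaction
times are not simulated, so the decision event uses a fixed 0.5 s
duration; trials are spaced by a configurable 8 s inter-trial interval
and feedback follows decision onset by 1.5 s — trial timing is not
printed, and these choices only set the regressors' sampling phase.  The
"100 ms Dirac" outcome event is a 100 ms boxcar.  The location-trace
regressor is emitted decision-locked (`locT`) and the choice-location
regressor response-locked (`cClo`), keeping both readings of the
ambiguous timing under distinct names.  An empty event category (for
example, lose-shift events in a session without losses) yields an
identically zero regressor plus a warning rather than an error.

## Synthetic cohorts and the injected stimulation effect

`cohort_spec()` mirrors the study design: 4 subjects × 5 sessions per
condition per experiment, sham sessions of the two experiments pooled
(40 sham versus 20 stimulation sessions), up to 200 trials per session.
Subject-level effects are Gaussian in unconstrained space (SD 0.3), so
the mixed models see genuine between-subject variance; sessions add
smaller jitter (SD 0.1, a once-chosen value giving realistic
session-to-session wobble).  Group means default to a moderate-learning
regime (α = 0.4, α_R = 0.35, w_R = 0.3, α_CL = 0.2, λ_CS = 0.6,
w_CL = 0.1, w_CS = 0.25, bias 0, β = 5), plausible for macaques
performing above chance on this task.  The stimulation effect is an
additive native-space shift, by default α − 0.15: the study reports
*lower* learning rates after 47/12o stimulation without printing a
magnitude, so the size is an artifact choice (configurable), picked to be
detectable at the study's sample size without being dramatic.

`run_recovery()` fits a cohort hierarchically and reports per-parameter
correlation, bias and RMSE between true and recovered values.
`run_tus_experiment()` replicates cohort → fit → contrast pipelines and
summarizes effect directions and rejection rates; with
`fit_model = FALSE` it contrasts only model-free measures (reward totals,
win-stay coefficients), which is what the 50-replicate null calibration
uses — the null distribution of the contrast does not depend on whether
the measure came through the fitting stage, and the model-free path keeps
the calibration affordable.

What the generator deliberately does not emulate: reaction times,
satiety or motivation drifts, session-order effects, stimulus-identity
biases, and any direct neural consequence of stimulation — the "TUS"
label is only a parameter shift.  Passing tests therefore demonstrate
that the pipeline detects and dissociates parameter-level effects of the
injected kind, not that real stimulation acts this way.

## Problem sizes and numerical choices

The shipped tests exercise the study-scale cohort (60 sessions × 200
trials, fitted once and reused across checks) plus smaller cohorts
(8–20 sessions) for optimizer-level properties; the dissociation checks
run on the full-size cohort and the null calibration on 50 model-free
replicates.  Optimization uses `nlminb` with up to 500 iterations per
session; multi-start only where no warm start exists.  The M-step
variance floor (`1e-4`), the MAP/MLE agreement tolerance (`1e-3` on
log-likelihoods), and the EM ascent slack (`1e-6`) are all optimizer
resolutions, not scientific tolerances.  Exact Q-value ties (possible
early in a session, before values separate) are excluded from accuracy
denominators; degenerate stay/shift columns or separated logistic fits
are dropped with warnings rather than silently zeroed.

## Known limitations

* The model's GRS influence is the product $w_R \alpha$, so an injected
  learning-rate reduction mechanically lowers it by $w_R \Delta\alpha$
  (about 0.02 at the defaults) even when $w_R$ is untouched.  Because
  empirical-Bayes shrinkage leaves the session estimates with very little
  spread, a within-2-SE "no change" check on this product fails under a
  pure α injection: only the *behavioural* half of the GRS dissociation
  (the reward-history profile of choice) is reproduced.  A flat fitted
  product would require either much noisier per-session estimates or a
  stimulation mechanism that is not a pure learning-rate shift.
* MLE of weakly identified parameters (for example, trace rates in
  sessions with little perseveration) walks to the link-space bounds —
  this is the well-known pathology that the hierarchical prior exists to
  fix, and is visible in the flat-prior tests.
* With four subjects the subject-level variance is estimated from four
  draws; singular random-effect fits and the fixed-effects fallback are
  expected in a minority of replicates.
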