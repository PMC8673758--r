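# creditassign

Simulation and model-based analysis of **credit assignment** in a
three-option restless-bandit task.

When a choice is followed by reward, a learner may attribute that reward
to the specific choice that caused it (credit assignment) or merely to
the current goodness of the environment — the **global reward state
(GRS)**.  This package implements, end to end, the computational pipeline
used to dissociate the two in macaque decision-making experiments with
prefrontal ultrasound stimulation (TUS):

* **Task engine** — three stimuli with drifting reward probabilities
  (ranges 90–10%, 70–30% and 10–90%, two options reversing mid-session,
  under 22% mean shared variance between trajectories); two options
  offered per trial, probabilistic reward.
* **Choice model** — Rescorla–Wagner values over three stimuli, with a
  reward trace entering the prediction error
  (`PE = r + w_R·R − Q(chosen)`, `Q ← Q + α·PE`), outcome-independent
  stimulus and location choice traces biasing the decision value, and a
  softmax choice rule — available both as a generative agent and as a
  session log-likelihood (compiled, numerically stable).
* **Hierarchical fitting** — iterative maximum a posteriori
  (empirical-Bayes EM): per-session MAP estimates under a group Gaussian
  prior in link-transformed space, priors re-estimated each iteration
  (init mean 0.1, variance 100; stop at posterior change < 0.001 or 800
  steps), plus a dual-learning-rate variant compared by BIC.
* **Behavioral analytics** — occasion-lagged win-stay/lose-shift
  logistic regressions, 4×4 credit-assignment matrices (3×3 grid of
  interest), the reward-history (GRS) profile, the GRS influence
  `w_R × α`, value-guided accuracy and reward intake, and mixed-effects
  condition contrasts (subject as random effect).
* **Design matrices** — the 16- and 15-regressor behavioural design
  matrices of the associated imaging analyses, standardized and convolved
  with a gamma HRF (mean 3 s, SD 1.5 s) on a TR = 2.28 s grid.
* **Synthetic cohorts** — experiment-shaped datasets (4 subjects,
  40 pooled sham + 20 TUS sessions, 200 trials each) with injected
  condition effects (default: learning rate −0.15 under TUS), for
  parameter-recovery and effect-detection experiments.

## Worked example

```r
library(creditassign)

# a session: schedule, model agent, likelihood
sch <- generate_schedule(schedule_config(seed = 42))
round(mean_shared_variance(sch), 3)
#> [1] 0.125

s <- simulate_agent(model_params(alpha = 0.4, w_R = 0.3, beta = 5),
                    sch, seed = 1)
s
#> <session_log> 200 trials | subject sim | condition sham | rewards 118

round(session_loglik(model_params(), s), 2)
#> [1] -62.6

# a small cohort with a TUS-induced learning-rate reduction, fitted
# hierarchically; one shared prior across conditions
spec <- cohort_spec(sessions_per_condition = 2, n_trials = 150,
                    master_seed = 8)
cohort <- make_cohort(spec)
fit <- iterative_map(cohort$sessions, seed = 8, max_iter = 150)
fit
#> <cohort_fit> 24 sessions | 150 iterations | converged: FALSE

est <- as.data.frame(fit, sessions = cohort$sessions)
tapply(est$alpha, est$condition, mean)
#>       sham tus_47_12o 
#>  0.3239667  0.2232778

condition_contrast(data.frame(value = est$alpha,
                              condition = est$condition,
                              subject = est$subject))
#> <condition_contrast> tus_47_12o: estimate -0.1007, t(19) = -7.421, p = 5.02e-07
#>   [linear mixed-effects (subject random intercept)]
```

The fitted learning rate is lower in the stimulation condition (the
injected effect was −0.15), while win-stay coefficients, accuracy and
reward totals move in the same direction and the behavioral
reward-history (GRS) profile stays flat — the dissociation the analysis
is built to expose.  (`max_iter` caps the EM run here; the summed
posterior keeps improving marginally long after the estimates have
stabilized — see the methods vignette.)

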