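---
title: "Modelling choice in the two-stage decision task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling choice in the two-stage decision task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepRL)
```

## The task and what it dissociates

`twostepRL` models behaviour in a two-stage Markov decision task. On each
trial a first choice between two options (`x`, `y`) leads probabilistically
to one of two second-stage states (`B`, `C`): each option has a majority
("common", probability 0.7) successor and a minority ("rare", 0.3) one, with
the mapping fixed throughout. A second two-option choice is then reinforced
at one of three outcome levels (low / medium / high), realized as a juice
duration drawn from non-overlapping per-level windows with a small Gaussian
drift; the low level delivers nothing. To force continual learning, each of
the four second-stage options holds its level for a uniformly drawn 5–9
trials and then redraws it uniformly over the three levels (so it stays with
probability 1/3). Fifteen percent of trials are forced (a single option
shown at one stage) and real sessions contain a few percent of error trials
(fixation breaks and the like), both excluded from analysis.

The transition asymmetry is what separates learning strategies. A
*model-free* (MF) learner repeats first-stage choices that were rewarded,
regardless of how the reward was reached. A *model-sensitive* (MS) learner
exploits the transition structure: a high reward obtained through a *rare*
transition is credited to the *other* first-stage option, for which that
second-stage state is the likely successor. In a lagged logistic regression
of current choice this appears as a reward × transition × choice
interaction; in the stay-probability table it appears as a crossover between
common and rare columns.

## The model family

All models share a state-action value function over the three states.
Second-stage values are temporal-difference estimates of the immediate
(normalized) reward; a fictitious zero-valued terminal state makes the
second-stage prediction error simply `r - Q(s2, a2)`. The first stage has no
reward, and the two MF variants differ in how they evaluate the successor
state: SARSA uses the value of the action actually taken there, Q-learning
the maximum available value. Values update with stage-specific learning
rates, and an eligibility-trace parameter `lambda` passes the second-stage
error through to the first-stage value within a trial (eligibility never
carries across trials, matching the task's episodic structure).

The MS learner values each first-stage action as the
transition-probability-weighted best second-stage value. Its three variants
differ only in where the transition probabilities come from: `Forward1`
knows the true 70/30 structure (plausible for heavily trained subjects);
`Forward2` counts which action–state mapping has occurred more often and
assigns it 0.7 (0.5/0.5 at ties); `Forward3` weighs a structured 70/30
account against an uninformative 50/50 one. Counts reset at session start.

The `Hybrid` model mixes the two systems' first-stage values with a weight
`omega` (0 = pure MF, 1 = pure MS). `Hybrid+` additionally gives the
previous trial's first-stage choice a transient value boost `+L_j` after a
common transition and `-L_j` after a rare one, with `L_1, L_2, L_3` indexed
by the previous outcome level (high, medium, low). The boost is recomputed
each trial from the immediately preceding completed trial only — it is a
one-trial, outcome- and transition-dependent form of perseveration, not an
accumulating value change. Choices at both stages are softmax in
`beta * (Q + kappa * rep)`, where `rep` marks the action taken on the
previous visit to the same state (states B and C tracked separately) and
`kappa` captures outcome-independent perseveration.

```{r family}
model_registry()$HybridPlus
```

## Design choices the task description leaves open

Several implementation details are not pinned down by the task description;
the package resolves them as follows and treats them as fixed conventions.

* **Q initialisation and session boundaries.** All values start at 0,
  transition counts at 0, and nothing carries across sessions; parameters
  are per-session quantities in every fitting mode.
* **Dwell counter at stays.** A fresh dwell length is drawn at every redraw
  event, including redraws that keep the level, so observable segment
  lengths between redraws are always 5–9 trials.
* **Juice drift.** The drawn juice duration follows a Gaussian random walk
  (SD 200 ms for high, 100 ms for medium) clipped to the level's window, and
  restarts uniformly inside the window when the level changes; windows
  therefore never overlap.
* **Forced trials.** Placement is i.i.d. per trial at the configured rate
  with the stage chosen equiprobably, and the single presented option is
  drawn uniformly. Forced stages contribute probability 1 to the likelihood
  but the learner still updates values, perseveration and the one-trial
  summary from them.
* **Error trials.** The likelihood skips them and the learner's state is
  carried through unchanged (no outcome was observed). Simulated agents
  cannot commit fixation errors, so the generator's error rate defaults to
  0; a nonzero rate injects aborted trials for pipeline testing.
* **Hybrid+ scope.** The displayed update rules modify only the previously
  chosen action; a mirrored variant that also suppresses the unchosen action
  is exposed as an option (`boost_unchosen`) but is off by default and
  unused elsewhere.
* **`Forward3`'s hypothesis test.** Implemented as the likelihood ratio of
  the observed transition counts under the structured 70/30 account (with
  the majority mapping) versus the uniform one, converted to beliefs as a
  `zeta`-weighted mixture of the two transition matrices. This is one
  defensible reading of an under-specified mechanism; `zeta` acts as a prior
  weight on structure.
* **Action identity.** Actions are picture identities, not screen sides;
  sides are carried only for reaction-time preprocessing.

## Fitting

`fit_ml_session()` maximizes the session likelihood by quasi-Newton search
(finite-difference gradients) in an unconstrained space: logistic transforms
for (0,1)-bounded parameters, log for the inverse temperatures, identity for
the unbounded perseveration and boost weights. The best of `n_restarts`
starts is kept (default 20; the first from a neutral point, the rest drawn
standard-normal in transformed space).

`fit_empirical_bayes()` implements the mixed-effects scheme: a diagonal
Gaussian empirical prior over transformed parameters, estimated by EM. Each
E-step computes per-session MAP estimates (default 101 restarts: one warm
start plus draws from the prior) and Laplace posterior variances from the
diagonal of the inverse Hessian; the M-step sets the prior mean to the
average MAP and the prior variance to the average second moment minus the
squared mean. The loop starts from the trimmed moments of the per-session
maximum-likelihood fits (25% total trimming, i.e. 12.5% per tail; a switch
reads the fraction per tail instead) and stops when no session's MAP moves
by more than 0.005, after which a final E-step is run.

Numerical choices worth knowing about:

* The search is confined to a generous box, |θ| ≤ 8 in transformed space
  (inverse temperatures up to e⁸ ≈ 3000), by a quadratic barrier. Inside the
  box the objective is the exact (penalized) likelihood; the barrier only
  prevents excursions along the flat plateaus that arise when a session's
  choices are consistent with an effectively deterministic policy.
* The EM initialisation clamps the starting prior SD to [0.01, 2.5] so the
  first E-step has a proper, moderately informative prior even when a few
  unregularized session fits sit at the box edge. Subsequent M-steps are
  pure moment matching (variances floored at 1e-8 with a warning only in
  the degenerate all-identical case).
* A non-positive-definite Hessian at a MAP falls back to the reciprocal of
  its diagonal and is flagged (`hessian_ok = FALSE`).
* The E-step posterior "SD" entering the M-step is the Laplace *variance*
  from the inverse Hessian diagonal; the moment-matching update is only
  consistent on that reading.

## Model comparison

Fixed-effects comparisons use `bic()` per session and likelihood-ratio tests
for nested pairs (nesting is checked structurally on the specifications).
Mixed-effects comparisons use `bic_int()`: each session's likelihood is
integrated over the converged empirical prior by Monte-Carlo sampling
(K = 1000 draws, averaged in the log domain), and the penalty counts two
prior parameters (mean, variance) per free model parameter, with the trial
count taken as the likelihood-contributing (non-error) trials.
`protected_exceedance_probability()` re-implements random-effects Bayesian
model selection — a variational Dirichlet model over model frequencies —
rather than wrapping an external toolbox, and protects the exceedance
probabilities with the Bayes omnibus risk against the equal-frequency null;
the tests validate it against brute-force integration over the model
simplex. Per-session evidences fed to it are the integrated (prior-sampled)
session evidences by default; MAP likelihoods can be supplied instead, as
both readings of the original procedure are defensible.
`predictive_probability()` summarizes fit quality as the geometric mean
per-choice probability, tested against the 0.5 chance level of a two-option
choice by a one-sided binomial tail at the implied success count (our
reading of an ambiguously printed expression).

## Behavioural statistics

`stay_table()` tabulates first-stage repetition by the previous trial's
outcome level and transition. `build_choice_design()` constructs the 5-lag
logistic design (choice, outcome level, transition, and all their two- and
three-way interactions per lag; 36 coefficients with the constant); all base
variables are mean-centred within session and the continuous outcome level
is scaled by twice its SD *before* interactions are formed, so coefficient
magnitudes are comparable. Excluded (error/forced) trials are removed before
lagging by default — lags index the analyzed-trial sequence — with a
`calendar_lags` switch for the raw-sequence alternative. Reaction times are
log-transformed and z-scored within session × response side (fixation
latencies within session only), with 3-SD outliers removed; the RT design
adds a linear fatigue term and omits the choice interactions (17
coefficients). `fit_decay()` fits `A·exp(b·lag)` to the signed mean
coefficients over lags 1–5 (a switch to absolute values is a one-liner on
the caller's side); `b` is reported as the decay constant, negative for
fading magnitudes, and the adjusted R² uses the two-parameter correction.
Across-session inference uses per-session fixed-effects estimates with
two-tailed one-sample t-tests; `fit_mixed_regression()` provides the
random-coefficients summary through the standard two-stage approach
(per-session fits pooled per coefficient by DerSimonian–Laird random-effects
meta-analysis), which is the same contract as a joint random-coefficient
GLMM at a fraction of its cost and fragility at this design size (36
correlated random slopes).

## What the synthetic data do and do not show

`subject_profile()` + `generate_subject_dataset()` produce surrogate
subjects under the study conditions: per-session parameters drawn from a
Gaussian hyperprior in transformed space around the bundled preset means,
fresh outcome schedules per session, and the agent playing the full task
including forced trials. The default desk scale is 10 sessions × 500 trials
(the study scale, 30 × 520 with SD 66, is one argument away); the default
between-session SD of 0.2 transformed units is a choice — large enough that
hierarchical pooling matters, small enough that sessions remain
recognizably one subject. Passing tests on these data demonstrate that the
estimation and selection machinery is self-consistent under the task's
generative structure. They cannot demonstrate anything about features the
generator lacks: real reaction-time distributions (the toy lognormal RT
generator exists solely to exercise the preprocessing pipeline), slow
session-to-session drift, motivational structure, or error-trial mechanics.

`simulate_from_fit()` is the validation loop: agents with fitted per-session
MAP parameters (reused across runs, 100 runs per session by default) replay
each observed session's exact outcome schedule and forced-trial script,
while transitions are regenerated at 70/30 — they must be, because the
simulated agent's own first-stage choice selects the transition row. A
consequence worth noting: even a deterministic (huge `beta`) agent does not
produce identical runs, since the regenerated transitions differ; run-level
identity holds only conditionally on the transition draws.

`parameter_recovery()` and `model_recovery()` wrap the generate–fit loop
into recovery reports (bias, RMSE, rank correlation; a model-selection
confusion matrix across SARSA, Forward1, Hybrid, Hybrid+). At desk scale,
the model-sensitive weight `omega` recovers with rank correlation above 0.8
across generating values {0.1, 0.5, 0.9}; the weakly identified boost
parameters (`L2`, `L3`, magnitudes well below 0.1) recover in sign and order
but with wide posteriors — a genuine property of the design, not a code
limitation.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline at the desk
scale the package defaults to: 30 × 500 trials for the regression
signatures, 10 × 500 for hierarchical recovery, EM at 3 restarts and at most
8 iterations, K = 500–1000 prior draws for the integrated BIC. These are the
package's chosen demonstration sizes; the same functions run at the full
study scale (30 sessions, 101 restarts, convergence-terminated EM) by
changing the corresponding arguments.

## Reading deposited data

`read_deposited_dataset()` ingests a per-trial table through a glossary that
maps each source column to a canonical trial-record field, because the
internal variable names of a deposit are only discoverable from its
glossary. The reader accepts the plain-text (CSV) export of such a deposit;
exclusions (error trials, forced trials) are applied on demand and every
dropped trial is counted and reported. A miniature synthetic fixture in the
test suite defines the reference layout.

## A worked example

```{r example, eval = FALSE}
prof <- subject_profile("HybridPlus", n_sessions = 10, trials_mean = 500,
                        trials_sd = 0, seed = 1)
ds <- generate_subject_dataset(prof)
stay_table(ds)$mean

fit <- fit_empirical_bayes(ds, model_registry()$HybridPlus,
                           n_restarts_ml = 3, n_restarts_e = 3, max_iter = 8,
                           seed = 2)
round(fit$prior$mu_natural, 3)
```

## Known limitations

* The EM scheme uses a diagonal prior; parameter correlations across
  sessions are not modelled (no full-covariance prior, no MCMC).
* Only behavioural data are modelled: no eye-position, pupil or neural
  streams, and no generative account of reaction times.
* The deposited `.mat` container itself is not parsed; the reader consumes
  its tidy CSV export, keeping the package free of binary-format
  dependencies.
* Devaluation/transfer manipulations and successor-representation or
  plan-until-habit variants are out of scope.
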