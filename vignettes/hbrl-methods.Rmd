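---
title: "Models and estimation methods in hbrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimation methods in hbrl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`hbrl` analyses two-alternative probabilistic instrumental learning data of
the kind collected in pharmacological studies of serotonergic modulation of
learning: two matched arms (placebo vs drug), each subject completing
interleaved reward, punishment and neutral stimulus pairs with 70%/30%
outcome contingencies. This vignette is the package's account of its models,
priors, sampler, and the design decisions behind them.

## The task and the simulator

The default `task_design()` has 3 blocks with fresh stimulus pairs in each,
32 trials per valence per block (96 per valence in total), a 70% outcome
probability for the better option and 30% for the worse one, unit wins and
losses, and a 2 s response window. We read "32 trials of each valence" as
per block; the total per valence is what enters the likelihood, and both the
count and the contingencies are configurable if a different reading is
wanted.

`generate_schedule()` pre-draws both options' probabilistic outcomes for
every trial with independent Bernoulli draws (no pseudo-randomisation to
exact frequencies), so realised feedback is a property of the schedule and
identical agents on the same schedule are exactly comparable. Only the
chosen option's outcome ever reaches the agent or the data file, matching a
task that shows chosen feedback only.

`simulate_cohort()` draws subject-level parameters non-centredly
(`mu_arm + sd * z` on the unconstrained scale, then transformed), so an
injected natural-scale arm difference on a group mean is exact by
construction. Defaults — learning rates near 0.35, reinforcement sensitivity
near 3, stickiness 0.4, between-subject sd 0.5 on the unconstrained scale —
were chosen once as representative of healthy-volunteer fits in this
literature. Covariates (age, sex, IQ) are drawn to match the study cohort's
demographic summaries. Omitted responses are off by default
(`p_lapse = 0`) because omission rates are rarely reported; reaction times
are decorative log-normal draws uncorrelated with the learning model —
RT generative modelling is out of scope, RT analysis in the package is
purely descriptive.

What the simulator does *not* emulate: sequential effects beyond the model
family (fatigue, attention lapses that correlate with difficulty),
subject-specific contingency misperception, and any RT–choice coupling.
Passing recovery tests therefore validates the estimation machinery under
the generating model, not the adequacy of that model for any particular
empirical dataset.

## The four learning models

All models value the two stimuli of each pair separately, start values at 0,
update only the chosen stimulus (the task shows no counterfactual feedback),
and choose via a softmax.

* **M1** — reward learning rate $\alpha_r$, punishment learning rate
  $\alpha_p$, reinforcement sensitivity $\rho$:
  $V \leftarrow V + \alpha\,(\rho r - V)$, choice by softmax on $V$ with
  temperature fixed at 1.
* **M2** — M1 plus stimulus stickiness $\tau$, an additive bonus to repeat
  the previously chosen stimulus *of the same pair* (the indicator resets
  with the fresh stimuli of a new block).
* **M3** — a single learning rate $\alpha$, $\rho$ and $\tau$; exactly the
  equal-rates submodel of M2.
* **M4** — experience-weighted attraction: for the chosen stimulus
  $n \leftarrow \rho_{ew} n_{prev} + 1$,
  $V \leftarrow (\phi\, n_{prev}\, V + r)/n$, with a free softmax inverse
  temperature $\beta$. Experience weights start at 1 and, like the values,
  decay only for the chosen stimulus.

Two conventions deserve comment. First, $\rho$ scales the reinforcement
*inside* the delta rule while the M1–M3 softmax temperature is fixed at 1;
$\rho$ and a free temperature are not simultaneously identifiable, which is
why only M4 frees the temperature. Second, a no-change outcome ($r = 0$) is
the relatively bad outcome on a reward trial and the relatively good one on
a punishment trial, so it engages the *opposite* learning rate
($\alpha_p$ on reward trials, $\alpha_r$ on punishment trials). This keeps
"reward learning rate" meaning "rate for the better outcome within a
context". Both conventions are isolated in `update_state()` should a
variant be needed.

Reward-trial and punishment-trial data are fitted separately (two
independent hierarchical fits); neutral trials carry no value signal and
are excluded from all likelihoods.

The likelihood core is compiled (Rcpp); an R reference implementation
(`subject_loglik(..., engine = "r")`) built from the exported state-update
and choice-probability functions is kept alongside, and the test suite
checks both against an independently written naive loop to 1e-10.

## Hierarchical model and priors

Per model and valence condition, on the unconstrained scale (logit for
unit-interval parameters, log for positive ones, identity for stickiness):

$$
\mu_{p,a} \sim \mathcal N(0, 1), \qquad
\sigma_p \sim \mathrm{HalfNormal}(1), \qquad
z_{i,p} \sim \mathcal N(0,1),
$$

with subject $i$ in arm $a$ having
$\theta_{i,p} = \mathrm{link}^{-1}(\mu_{p,a} + \sigma_p z_{i,p})$. Arms get
separate means and share the group sds (a parsimony choice at 32 subjects
per arm; the prior scales are arguments of `hbrl_priors()` for sensitivity
analyses at 0.5 or 2). A standard-normal prior on a logit-scale mean is
mildly regularising and close to uniform on (0.12, 0.88) coverage for the
rates; half-normal(1) keeps group sds in the range where partial pooling is
meaningful.

Group mean differences are computed per posterior draw by transforming each
arm's group mean to the natural scale and subtracting (drug − placebo); the
unconstrained-scale alternative is available via the `scale` argument of
`group_difference()`. Reported intervals are 90% and 95% highest density
intervals — the narrowest window containing `ceiling(mass * n)` sorted
draws, ties broken to the left-most window — and the decision rule for a
"credible difference" is an HDI that excludes zero.

## Sampler

No gradient-based sampler is used; the posterior is explored with an
adaptive Metropolis-within-Gibbs scheme designed around the model's
structure:

* subject effects $z_i$ are proposed jointly per subject, with a
  per-subject proposal covariance learned during warmup (Haario-style);
  only that subject's likelihood is re-evaluated;
* group-level parameters take scalar random-walk updates plus one joint
  proposal over the whole group-level block with an adapted covariance,
  which traverses the correlated learning-rate/sensitivity directions;
* each sweep ends with an interweaved centred-parameterisation move: with
  every subject's unconstrained parameter held fixed, the arm means are
  exact conjugate-normal draws and each group sd takes a Metropolis step on
  its closed-form conditional, after which the $z_i$ are back-solved. This
  ancillarity–sufficiency interweaving costs no likelihood evaluations and
  removes the slow random-walk drift of the group level that a purely
  non-centred scheme exhibits here.

All step sizes adapt by Robbins–Monro during warmup only, so kept draws come
from a fixed kernel. Convergence is summarised by split R-hat and a
Geyer-truncated effective sample size per group-level parameter; any R-hat
above 1.05 triggers a warning and is flagged in the fit's convergence
report rather than silenced. With the package defaults (2 chains, 1000
warmup + 1000 kept draws for a 64-subject condition) the arm means — the
quantities entering every reported group difference — converge cleanly;
the group sds of weakly identified pairs (e.g. reward learning rate vs
sensitivity) can sit slightly above the threshold and are reported as such.
For publication-grade runs, increase `warmup`/`iter` and `chains`.

## Marginal likelihoods and model comparison

`bridge_sample_logml()` implements the Meng–Wong optimal bridge: posterior
draws are split in half, a moment-matched multivariate-normal proposal is
fitted to the first half (on the unconstrained sampling scale, with a small
ridge on the covariance), an equal-size proposal sample is drawn, and the
optimal-bridge fixed point is iterated on the second half to relative
tolerance 1e-10 (at most 1000 iterations). Non-finite evaluations are
dropped and counted; failure to converge is flagged, and a comparison with
any non-converged estimate withholds the winner while still emitting the
table. The Monte-Carlo standard error assumes approximately independent
draws; it is accurate for the toys used in validation and indicative for
MCMC output.

In high dimensions (a 64-subject M2 fit samples ~270 coordinates) the
normal-proposal bridge carries a small positive bias (a few nats at 2000
draws against known-normalised targets, as the test suite shows at smaller
scale). Model ranking subtracts estimates of similarly sized models, which
cancels most of it; absolute evidence values should be treated with more
caution than differences.

Comparisons are run separately per valence condition, mirroring the
separate fits; an overall winner is declared only when the same model wins
in every fitted condition, and ties (within 1 nat) are reported rather than
broken.

A note on when the dual-rate sticky model (M2) is selectable: if the two
learning rates are in fact equal, the data are exactly M3-distributed and
the marginal likelihood *should* prefer M3. The package's model-selection
validation therefore generates cohorts with clearly distinct rates
(0.55 vs 0.15), stickiness 0.6 and between-subject sd 0.3 — a design point
chosen on identifiability grounds, where the richer model is the true and
detectable one.

## Classical statistics layer

`mixed_ancova()` reproduces the `aov`-style repeated-measures ANCOVA:
sequential (Type I) sums of squares with mean-centred age and IQ and binary
sex entered before the group and feedback factors, a subject error stratum
by default (flat long-format fit behind `stratum = FALSE`), partial
eta-squared within each stratum. `welch_t()` and `cohens_d()` work from
summary statistics so published tables can be recomputed directly;
`chi_square_2x2()` is the uncorrected Pearson statistic by default (the
Yates-corrected variant is a flag) with `phi = sqrt(chi2/N)`;
`bh_adjust()` wraps the Benjamini–Hochberg step-up at q = 0.05.

The blinding-integrity table used in the worked examples is a documented
reconstruction: with one non-respondent (N = 63), the printed percentages
(53% of the drug arm, 16.12% of the placebo arm) pin the cell counts at
17/32 and 5/31.

## Numerical choices and degenerate inputs

* Boundary parameter values (rate 0 or 1, decay 1) are accepted in direct
  likelihood evaluation — they are meaningful limits — while the
  hierarchical transform only produces interior points.
* Choice log-probabilities are computed as `-log1p(exp(d))` on the signed
  propensity difference, stable for extreme values.
* `hdi()` requires a finite sample and errors on an empty one; a point-mass
  sample yields a zero-width interval.
* Unresponded trials contribute nothing to likelihoods and do not update
  state; files violating that invariant are rejected at parse time with the
  offending line number.
* All randomness funnels through explicit integer seeds; cohorts, fits and
  pipeline outputs are bit-reproducible given the seed.

## Problem sizes used in the packaged experiments

The packaged validation experiments run at the study's scale where that
matters for the question (32 + 32 subjects, 96 trials per valence,
5 replicates for the recovery and model-selection experiments) with 2
chains of 800–1000 kept draws per fit, sizes chosen as the package's
defaults for a laptop-class machine. The recovery experiment injects a
−0.15 natural-scale deficit on the punishment learning rate — the magnitude
of the group difference this design is meant to resolve — and checks the
sign and the 90% HDI exclusion of zero; the null experiment checks 95% HDI
coverage. Larger replicate counts sharpen the binomial summaries but do not
change the design.

## Known limitations

* The sampler is random-walk based; posteriors with much larger subject
  counts or strongly correlated hierarchies will mix more slowly than a
  gradient-based sampler would.
* The bridge-sampling MC error underestimates slightly for autocorrelated
  draws, and absolute log-evidence values in high dimensions carry a small
  positive bias (differences largely cancel).
* Group sds are shared across arms by default; per-arm sds would require
  more subjects to be well identified.
* The experience-weighted model is fitted with the same hierarchical
  machinery but its decay parameters are weakly identified at 96 trials per
  condition; expect wide posteriors.
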