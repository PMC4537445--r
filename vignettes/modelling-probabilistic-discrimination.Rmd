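---
title: "Modelling probabilistic discrimination learning with sticky softmax delta-rule agents"
author: "pvdrl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling probabilistic discrimination learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvdrl)
```

## The task and the data it produces

`pvdrl` models two-choice probabilistic visual discrimination and
reversal learning, the paradigm used in primate studies of serotonin's
role in reinforcement processing. On each trial two abstract stimuli are
shown left and right of centre; one is designated "correct". Choosing it
earns reward with the valid-reinforcement probability $p$ (0.8 in most
stages, 0.7 in one) and punishment otherwise; the incorrect stimulus has
the inverse contingency. Feedback congruent with the contingency is
called *true*, the misleading minority feedback *false*. Sessions hold a
fixed trial count with each stimulus on each side equally often; a
subject advances to the next discrimination after a session at or above
90% correct. Reversal stages keep the stimulus pair and flip the
contingency.

Because no trial-by-trial data are publicly available for this
paradigm's primate studies, the package's synthetic-data generator
(`simulate_cohort()` and friends) is a first-class module: it emulates
the study structure — 3 groups × 4 subjects, discriminations D5–D8 at 40
trials/day, two reversals — with choices produced by the same model
family the inference machinery fits.

## The model family

Choice follows a softmax with inverse temperature fixed at 1 over a
per-stimulus decision value

$$x_{i,t} = v_{i,t} + c_{i,t} + l_{i,t},$$

where $v$ is a reinforcement value, $c$ a stimulus-stickiness trace and
$l$ a side-stickiness trace ($l_{i,t}$ is the trace of the side stimulus
$i$ currently occupies). After each trial the chosen stimulus's value
follows a delta rule with reinforcement coded $r = +1$ (reward) or $-1$
(punishment):

$$v \leftarrow v + \tau\,(r - v),$$

with separate rates $\tau_r, \tau_p$ when the model splits valences.
Stickiness traces track a choice indicator scaled to a maximum:

$$c_i \leftarrow c_i + \tau_c\,(d_c\,\mathbb{1}[i\ \text{chosen}] - c_i),$$

and identically for sides with $\tau_l, d_l$. Toggling valence
splitting, stimulus stickiness and side stickiness gives the
eight-member family returned by `model_family()`; a disabled mechanism
contributes zero to $x$. Because $\beta$ is pinned at 1, reinforcement
sensitivity is expressed through $\tau$ rather than through a
temperature, and the stickiness maxima $d_c, d_l$ are interpretable as
effect sizes *relative to* reinforcement (whose values live in
$[-1, 1]$).

Two design points here were genuinely open and are worth recording. The
exact stickiness dynamics are not fully specified by the field's
published model descriptions ("rate" plus "maximum effect relative to
reinforcement"); the exponential-tracking form above realises exactly
those two degrees of freedom and is isolated in `update_state()` and the
compiled core, so an alternative form is a one-function change.
Punishment updates use $r = -1$ (not 0), so a single $\tau$ treats the
valences symmetrically — the natural reading of a model whose winning
variant needs no valence split.

State handling across stages: $v$ and $c$ are zeroed whenever a stage
introduces a new stimulus pair (novel stimuli have no history), reversal
stages keep pair and state, and the side trace $l$ persists throughout —
sides are fixtures of the apparatus, not of the discrimination. When
fitting, reversals are detected from the data (same pair as the previous
stage), so trial logs need no extra annotation.

## Estimation

`map_fit()` maximises each subject's log-likelihood plus log prior
(logit/log transformed coordinates, BFGS, 16 prior-drawn starts by
default). `hierarchical_fit()` estimates the full hierarchy: each
subject's parameter is drawn from a normal with a group-specific mean
and a group-shared, parameter-specific SD, truncated to the parameter's
support ($[0,1]$ for rates, $[0,\infty)$ for maxima; the truncation is
handled in the density, not by clipping, which would bias means). Group
mean rates have a Beta(1.1, 1.1) prior, maxima a Gamma(shape 1.2, rate
0.2) prior, SDs a positive half-Cauchy(0, 5).

The sampler is a random-walk Metropolis-within-Gibbs written in C++:
per-parameter subject updates (the only moves that touch the trial
likelihood), several likelihood-free sweeps over group means and SDs per
iteration, and a joint scale move that rescales an SD together with its
subject-level deviations. The scale move matters: without it the
hierarchical "funnel" (small SD locking the subject parameters in place)
inflates split-chain R-hat on the SDs well above 1.05 at the default
draw counts. Proposal scales adapt during warmup only, by Robbins–Monro
on the acceptance probability (target 0.44). Defaults are 4 chains ×
1000 warmup + 1000 kept draws; fits are flagged when any split-chain
R-hat exceeds 1.05. A `prior_only` mode drops the likelihood term so the
prior implementation can be checked against its closed forms.

Posterior summaries use highest-density intervals: the narrowest
contiguous window containing $\lceil m n \rceil$ sorted draws, ties
broken toward the lowest left endpoint. Group differences are computed
draw-wise, and `p_nz()` reports the largest HDI mass that excludes zero
(bisection to 0.001, floored/capped at 0.001/0.999). One estimator
caveat: for samples essentially symmetric about zero, tiny-mass windows
can sit a noise-width away from zero, so the index bottoms out near its
floor rather than exactly at it — irrelevant at the effect sizes where
the index is informative.

## Model comparison

`compare_models()` scores every family member by
$\mathrm{BIC} = -2\,\mathrm{LL} + k \ln n$ with $k = z s$ ($z$
parameters per subject, $s$ subjects, $n$ total trials), with
$\mathrm{AICc} = 2k - 2\,\mathrm{LL} + 2k(k+1)/(n-k-1)$ as a
cross-check. LL is the posterior mean of the per-draw total
log-likelihood in hierarchical mode, or the data log-likelihood at the
MAP point in MAP mode; both modes exist because screening by MAP and
refining hierarchically is the usual workflow at this model-family size.
A practical fact worth knowing: with $k = zs$ the BIC penalty is stiff.
At 12 subjects × 1200 trials, adding side stickiness costs
$24\ln(14{,}400) \approx 230$ BIC points, so the full model is only
selected when the generating side-stickiness maximum is substantial
($d_l$ near 1); at $d_l \approx 0.4$ BIC prefers the stimulus-stickiness
model even on data generated with side stickiness. The model-recovery
test and the acceptance script therefore use generating values in the
identifiable regime — which is also the regime implied by a study whose
data did select the full model.

## Behavioural measures and the obey analysis

`errors_to_criterion()` sums incorrect choices over sessions strictly
before the first criterion session (the criterion day is excluded;
square-root transform via `sqrt_errors()`, the usual choice for counts
whose variance grows with the mean). `obey_analysis()` matches every
trial with its immediately preceding trial within a session and asks
whether the subject *obeyed* the feedback — stayed after reward, shifted
after punishment — tabulated by the previous trial's valence and
veracity, with discrimination and reversal stages kept separate (the
headline analysis uses discriminations only). The model-side
counterpart, `model_obey_probabilities()`, evaluates the fitted model's
probability of the obeying choice at each trial pair and averages over
posterior draws; on model-generated data the two tables agree cell-wise,
which is the package's self-consistency check between behaviour and
model.

## The virtual necessity/sufficiency experiment

`necessity_sufficiency()` simulates large virtual cohorts (default
protocol: $p = 0.8$, 30 trials/session, criterion 90%, capped at 100
sessions; $n = 1000$ identical subjects per group) under *constraint
schemes*: each scheme lets a subset of the winning model's parameters
take group-specific values while the rest are pinned to the pooled
value. Groups are compared with Welch tests (the safe two-sample default
at these sizes) on square-root errors and obey-true/obey-false
probabilities; a scheme is *sufficient* for an effect if it reproduces
it in the expected direction at level $\alpha$, and a parameter is
*necessary* if no scheme excluding it is sufficient. Expected directions
can be supplied or inferred from the all-varying scheme; because the
tests have arbitrarily high power at $n = 1000$, effect sizes are
reported alongside the verdicts.

Choosing the generating group values deserves transparency, because the
joint behavioural signature — a lower reinforcement rate producing
*both* more errors to criterion *and* a higher probability of obeying
false feedback — only exists in part of the parameter space. Regime
exploration with this package shows: with weak stimulus stickiness the
90% criterion is reachable only by binomial luck (the value gap alone
caps single-trial accuracy near 0.77), washing out the errors effect;
with very strong stickiness, perseveration dominates and the obey-false
difference reverses sign. With moderate contrast such as $\tau$ 0.45
vs. 0.25 both groups reach the value asymptote within a session and
neither effect is reliable. The regime that reproduces the studied
phenomenon — and lands square-root errors per discrimination near the
magnitudes such studies report — is a genuinely low depleted-group rate
against substantial stimulus stickiness: control $\tau = 0.20$ vs.
depleted $\tau = 0.05$ over shared $\tau_c = 0.3$, $d_c = 1.0$,
$\tau_l = 0.3$, $d_l = 0.3$. Those are the package's documented
virtual-experiment conditions; under them the $\tau$-only scheme is
sufficient for both effects and stickiness-only schemes for neither, so
$\tau$ is necessary.

## The variable-interval punishment-sensitivity engine

`simulate_vi_session()` is a discrete-event simulator of the concurrent
schedule used to measure punishment-induced response suppression: per
side, a VI reward schedule with intervals drawn uniformly from 0–40 s in
5-s steps (mean 20 s) and, in the punishment phase, an independent VI
punishment schedule on 20–60 s in 5-s steps (mean 40 s). The first
response at or after an interval's elapse collects the armed outcome
(a 0-s draw arms instantly, so the next response can collect
immediately); the next interval starts only once that response is made.
If both schedules on a side have elapsed before the next response, the
earlier-elapsed outcome is delivered first and the other on the
subsequent response; no single response ever carries two outcomes, and
simultaneous elapses (probability zero under continuous responding)
break in favour of reward. `suppression_metrics()` reports per-session
response counts and the punishment-phase minus reward-only-phase change,
the suppression/facilitation index. No model is fitted to VI data; the
engine exists to generate and score schedule behaviour.

## Numerical and testing notes

The per-trial loops (likelihood, simulation, sampler) are compiled; a
plain-R reference implementation of the likelihood is kept and tested to
agree with the compiled path to 1e-12, and both are checked against an
independently coded oracle on hand-built logs. All randomness flows
through R's RNG, so a single seed fixes cohorts, fits and virtual
experiments; per-subject streams are derived from the plan seed so
cohorts are reproducible regardless of subject order.

Test problem sizes are the package's chosen study conditions: parameter
recovery uses 12 subjects × 1200 trials with 10 replicate cohorts
(the 95% HDI of the group-mean rate covers the generating value in at
least 9), model recovery uses the same size with the identifiable
generating values above (the generating specification wins BIC in at
least 7 of 10), and the virtual experiment runs the full $n = 1000$
protocol. What passing these tests shows — and what it does not — should
be read against the generator: synthetic agents *are* the fitted model
class, so recovery results certify the inference machinery, not the
model's adequacy for any real animal; veracity-balanced feedback,
perfectly balanced sides and stationary parameters are idealisations;
and session-level stopping makes trial counts random, which the
likelihood handles but which means cohort sizes vary across seeds.

Known limitations: the sampler is a random-walk method — adequate at
this model size but needing its draw budget; the BIC penalty's $k = zs$
convention makes selection conservative at small cohorts (see above);
obey cells with no pairs are absent rather than zero, so subjects who
learn very fast can lack false-feedback cells and drop out of the
corresponding comparisons; and the VI engine models schedule mechanics
only, not response latencies of real animals.
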