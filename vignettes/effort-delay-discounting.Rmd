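---
title: "Effort and delay discounting: models, Bayesian fitting, and staircase analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effort and delay discounting: models, Bayesian fitting, and staircase analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(effdisc)
```

## The scientific problem

Decision costs devalue rewards. For temporal delay the discount curve is
convex (hyperbolic): adding delay to a short wait hurts much more than adding
it to a long one. Whether physical effort discounts reward the same way is a
different question: perceived exertion grows slowly at low forces and steeply
near one's maximum, which predicts an *initially concave* discount curve —
small devaluation for easy grips, accelerating devaluation as the required
force approaches the maximum voluntary contraction (MVC).

`effdisc` implements the full analysis pipeline needed to adjudicate between
these hypotheses from two-alternative choice data: candidate value functions
with a softmax choice rule, per-subject Bayesian model fitting with a
free-energy approximation to the log model evidence, random-effects group
Bayesian model selection, and the model-free complement — PEST staircases
that titrate offers to indifference, psychometric indifference-point
estimation, and a concavity classification of the resulting curve. Because
no human dataset ships with the package, a first-class synthetic-cohort
module generates choice data with the same statistical structure from agents
with known parameters, which is what every test and the recovery studies run
on.

## Models

An offer is a reward magnitude $M$ (display units, 0–75) at a normalized
cost $C \in [0,1]$ ($C = 1$ is 75 weeks for delay, or 100% of the
participant-scaled maximum 12-s grip force for effort). The candidate
subjective-value functions are

* hyperbolic: $V = M/(1+kC)$,
* linear: $V = M - kC$,
* quadratic: $V = M - kC^2$,
* two-parameter power: $V = M - kC^p$,
* sigmoidal: $V = M\left(1 - \left(\sigma(k(C-p)) - \sigma(-kp)\right)\left(1 + e^{-kp}\right)\right)$,

with $\sigma$ the logistic function. The sigmoidal form subtracts its value
at $C=0$ so the curve passes exactly through $(0, M)$, and rescales so it
converges to 0 (not to a positive floor) as $C \to \infty$; $k$ is the slope
and $p$ the turning point between the initial concave and the later convex
regime. Internally the expression is evaluated in the algebraically
identical form $V = M\,\sigma(-k(C-p))/\sigma(kp)$, computed in log space:
the printed form cancels catastrophically once $k|p|$ is large, whereas the
log-space form is stable for arbitrary optimizer probes (e.g.
$k|C-p| > 700$). Choices follow a softmax,
$P(\text{choose }1) = \sigma(\beta(V_1 - V_2))$, and the optional utility
variant replaces $M$ by $M^{\alpha}$ (default $\alpha = 0.8$ when enabled)
before discounting — never the cost.

```{r}
subjective_value("hyperbolic", list(k = 4.86), M = 75, C = 1)
subjective_value("sigmoidal", list(k = 10.49, p = 0.70), M = 75, C = c(0, 0.5, 1))
```

## Bayesian fitting and model evidence

Each subject × model fit maximizes the log joint (Bernoulli choice
likelihood + Gaussian prior) in an unconstrained estimation space
($\ln k$, $\ln\beta$, sigmoidal $p$ on the identity scale, power exponent
$\ln p$), then forms a Laplace Gaussian posterior at the optimum. The
reported free energy is

$$F = \underbrace{\mathbb{E}_q[\log p(y\mid\theta)]}_{\text{accuracy}}
  - \underbrace{\mathrm{KL}(q \,\|\, \text{prior})}_{\text{complexity}},$$

with the accuracy term evaluated to second order around the posterior mean
(`accuracy_order = "second"` in the fit metadata). $F$ approximates the log
model evidence; the decomposition identity $F = \text{accuracy} -
\text{complexity}$ holds exactly for every returned fit, and complexity is a
KL divergence, hence non-negative — a model is only penalized to the extent
the data actually move its posterior away from the prior.

Design choices worth knowing:

* **Priors.** $\ln k \sim N(0, 10)$, $\ln\beta \sim N(0, 10)$, sigmoidal
  $p \sim N(0.5, 1)$, power $\ln p \sim N(0, 1)$. These are weakly
  informative over several orders of magnitude in native space; the
  `prior_sensitivity()` contract (refit with covariances ×0.1 and ×10)
  is the robustness check that conclusions do not hinge on them. The
  identity scale is kept for the sigmoidal turning point — deliberately not
  clipped at 1, since turning points beyond 100% MVC are conceptually
  possible — but the power exponent is log-transformed: an identity-scale
  exponent admits $p < 0$, where $V = M - kC^p$ diverges at $C = 0$ and the
  evidence integrand becomes pathological.
* **Multi-start.** Eight initializations per parameter, arranged as a
  deterministic staggered (cyclic Latin) set of eight starts spanning all
  parameter ranges jointly rather than a full $8^d$ Cartesian product: with
  three free parameters the full grid would cost 512 optimizations per
  subject × model with no measurable benefit on these smooth likelihoods.
  The fit kept is the start with maximal $F$, and the returned object
  records all starts' free energies.
* **Optimization.** Quasi-Newton (BFGS) ascent with convergence on relative
  objective change; the normative surface is the free-energy decomposition
  contract, not a specific update rule.
* **Validation.** `evidence_oracle()` integrates the marginal likelihood by
  brute-force quadrature: an iteratively zooming coarse scan locates the
  posterior mass inside the diffuse prior, the integrand's moments are
  estimated from the weighted grid, and the final grid is laid out in the
  whitened eigenbasis so that thin correlated ridges (the sigmoidal $k$–$p$
  ridge has posterior standard deviations of order $10^{-2}$ inside a prior
  box of width $\sim 12$) are resolved. Doubling the grid density must move
  the result by less than 0.05 nats or the oracle refuses to answer. On
  simulated subjects, $|F - \text{oracle}| < 1$ nat throughout the test
  suite; the conjugate-Gaussian toy is reproduced to machine precision.

A known limitation: the Laplace posterior's symmetric 95% interval for $k$
undercovers mildly (measured ≈ 0.91 over 200 replicate fits spanning
$\beta \in [0.2, 1]$) because the $\ln k$ likelihood is skewed for
near-deterministic subjects. Rank-based recovery is unaffected (Spearman
correlations > 0.9 in the acceptance suite).

## Group model selection

`rfx_bms()` treats model identity as a random effect: subject
responsibilities $u_{nk} \propto \exp(F_{nk} + \psi(\alpha_k) -
\psi(\sum_j \alpha_j))$ update a Dirichlet posterior $\alpha_k = \alpha_0 +
\sum_n u_{nk}$ over population model frequencies, iterated to
$\max|\Delta\alpha| < 10^{-4}$. Reported are the posterior mean frequency
`mp` and the exceedance probability `xp` (probability a model is the most
frequent), computed exactly via the regularized incomplete Beta function for
two models and by $10^6$ seeded Dirichlet draws otherwise; `xp` is printed
at four decimals. Responsibilities are log-sum-exp stabilized, so only
within-subject evidence differences matter and arbitrary spreads cannot
overflow. $\alpha_0 = 1$ (uniform over frequencies). One consequence worth
internalizing: a single subject, however decisive ($\Delta F = 20$), yields
$\alpha = (2, 1)$ and hence $xp = P(\mathrm{Beta}(2,1) > 0.5) = 0.75$ —
near-certain exceedance requires agreement across subjects, which is the
point of a random-effects analysis.

## The staircase task and indifference points

The model-free arm emulates a two-block session (96 trials each): a
no-effort default (40 then 200 display units) against a variable option at
one of six effort levels, 16 choices per level, level order randomized, with
six interleaved PEST staircases driving the variable magnitude. PEST rules
as implemented: rejection raises the next offer by the current step,
acceptance lowers it; the step halves on each direction reversal and doubles
after the third consecutive same-direction step (capped at the initial step,
as classic PEST implementations bound the maximum step); when a halving
brings the step to a quarter of its initial size, the staircase
re-initializes — magnitude re-jittered uniformly around the initial value
(60 ± 6 and 260 ± 20 display units per block; initial steps 8 and 24), step
restored, and run history restarted (whether history survives
re-initialization is unspecified in the source procedure; restarting is the
simpler invariant). Effort levels default to
$[0.15, 0.25, 0.4, 0.55, 0.75, 1]$; the alternative printed set
$[0.15, 0.25, 0.35, 0.5, 0.75, 1]$ can be configured — the two appear
inconsistently in the source material, and the figure-caption values are
the default here.

Per level, all choices (pooled across re-initializations) feed a Bernoulli
maximum-likelihood psychometric fit $P(\text{accept}) =
\sigma(\beta_{\text{psy}}(x - x_{50}))$; the indifference point $x_{50}$ is
where the curve crosses 0.5. Complete separation — a threshold-deterministic
chooser — is resolved by the midpoint between the highest rejected and
lowest accepted magnitude, with the slope flagged unbounded. Indifference
points have three representations: raw $x_{50}$, multiplicative
$D/x_{50}$ (relative residual value; 1 = no devaluation), and additive
$D - (x_{50} - D)$ (absolute decrease; negative once $x_{50} > 2D$).
A multiplicative profile is classified concave when at least three of the
five interior points lie *strictly* above the chord from $(0, 1)$ to the
sixth point (points exactly on the chord do not count; the strict reading
is the conservative one for an unspecified boundary).

```{r}
ag <- agent("sigmoidal", list(k = 4, p = 1), beta = 0.3, id = "demo")
ses <- simulate_exp2_session(ag, seed = 42)
curve <- estimate_indifference_points(ses$traces[[1]])
curve
```

The two blocks also form a diagnostic for the *nature* of discounting: a
multiplicative agent ($V = M f(C)$, e.g. sigmoidal) produces identical
multiplicative curves in both blocks, while an additive agent
($V = M + f(C)$, e.g. quadratic) produces identical premiums
$x_{50} - D$. The magnitude effect — shallower relative discounting for
larger stakes — appears as a multiplicative curve that differs between
blocks.

## The synthetic cohort: what it emulates and what it does not

`design_exp1_stimuli()` reproduces the discriminative-design logic of the
fixed-stimulus experiment: 2 × 100 integer-magnitude pairs (0–75) with
costs on a 0.05 grid, retained only if, for at least two of nine agents per
family, at least two of the three families {hyperbolic, linear, concave}
deterministically prefer different options. The concave family is
represented by sigmoidal agents ($k$ log-spaced on $[3, 30]$ ×
$p \in \{0.3, 0.5, 0.7\}$); hyperbolic $k$ spans $[0.5, 30]$ and linear $k$
spans $[5, 75]$, shallow to steep, all log-spaced — the source names the
procedure but not the grids, so these are fixed package defaults. Trivial
pairs (cost difference < 0.1 with magnitude difference > 40) are excluded
and pairs with both costs > 0.4 are capped at 15% of the set. Agents choose
by Bernoulli draws from the softmax; realized-effort flags hit their target
fraction exactly (30% for the fixed-design task, 15% for the staircase
task) and never influence simulated choices. Default agent temperature is
$\beta = 0.2$ in display-unit value space, which puts predicted-choice
accuracy of fitted models in the empirically typical 0.75–0.9 band.

What a green test on this cohort does *not* establish: agents are
stationary (no fatigue, no drift, no lapses), choices are exchangeable
across trials, magnitudes are exact integers, and the generating model is
always one of the five candidates. Model-recovery results certify the
pipeline's statistical machinery, not the behavioral claims themselves.

## Auxiliary statistics

`choice_logistic_regression()` regresses choice of option 1 on both options'
magnitudes and costs (IRLS; separation is detected as a diverging per-SD
slope and re-estimated under a small ridge whose weight scales with $n$, so
duplicating trials changes nothing). `fatigue_tests()` runs three
permutation tests on the fraction of higher-reward/higher-cost (HRHC)
choices: post-effort vs matched post-no-effort trials, post-hard vs
post-easy (median split on the previous trial's cost), and first vs second
half. P-values use the add-one convention $(b+1)/(n_{\text{perm}}+1)$ with
ties between permuted and observed statistics counted one half: HRHC
outcomes are binary, ties are common, and counting them fully makes null
p-values conservative rather than uniform. `parameter_correlations()`
reports the uncorrected Pearson table across tasks, as is conventional for
this table.

## Numerical and degenerate-input conventions

Choice probabilities are clipped at $10^{-300}$ before logs; value
functions accept costs outside $[0, 1]$ without error (optimizers probe
there; domain checks live in the I/O layer); `predicted_choice_accuracy()`
scores exact-tie probabilities as 0.5; staircase offers are floored at 0;
an evidence spread of hundreds of nats within a subject is handled by
log-sum-exp; permutation tests with no realized trials return an
"inapplicable" report rather than an error. All randomness flows from
explicit seeds through an RNG-state-preserving wrapper, so identical
configurations give byte-identical outputs and no function perturbs the
caller's RNG stream.
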