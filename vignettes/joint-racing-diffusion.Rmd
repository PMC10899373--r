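---
title: "Joint hierarchical modelling with racing diffusion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint hierarchical modelling with racing diffusion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`rdmjoint` implements joint hierarchical Bayesian estimation of racing
diffusion models (RDMs) of choice and response time across several
decision-making tasks, together with the model-comparison machinery needed to
ask whether latent decision processes are shared across tasks and stable
across sessions.

## The racing diffusion model

Each response option has one accumulator: a Wiener diffusion with drift $v$
and within-trial noise $s = 1$ (a scaling constraint, not an estimable
quantity) racing from a start point toward an absorbing boundary at distance
$b$. The first accumulator to hit its boundary determines the choice; the
response time is the hitting time plus a non-decision time $t_0$ covering
encoding and motor execution. The hitting time of a single accumulator has
the shifted-Wald (inverse Gaussian) density

$$f(t \mid v, b) = \frac{b}{\sqrt{2\pi t^3}}
  \exp\!\left(-\frac{(b - v t)^2}{2t}\right),$$

which is *defective* when $v \le 0$: it integrates to $e^{2vb} \le 1$, the
probability that the accumulator ever finishes. The likelihood of observing
choice $c$ at time $t$ is the winner's density at $t - t_0$ times every
loser's survival probability, and survival terms are computed in log space
(floored at $e^{-700}$) so extreme drift-boundary products neither overflow
nor underflow. A response at or before $t_0$ has zero likelihood and returns
`-Inf` rather than raising an error, so samplers reject such proposals
gracefully.

Drift rates are parameterised throughout as an evidence-independent *urgency*
($V_0$) plus an evidence-dependent *difference* term ($\delta$, the
information-processing ability). Start-point adjustments are represented as
reductions of the effective boundary distance, which is mathematically
identical to moving the start point toward the boundary. There is no
between-trial start-point variability: the parameter sets are exactly
$\{B, V_0, \delta, t_0, \dots\}$ per task, matching the reported counts.

## The four task models

* **Reversal learning (`rl_rev`, 6 parameters)** — two-alternative
  instrumental learning with mid-block reward reversals. Expected values
  follow the delta rule $Q_{t+1} = Q_t + \alpha (r - Q_t)$, updated only for
  the chosen stimulus, reset to $Q_0 = 0.5$ at block starts (rewards are
  0/1, so the midpoint is the uninformative initial value). Drifts follow
  the advantage framework:
  $v_i = V_0 + \delta (Q_i - Q_j) + \Sigma (Q_i + Q_j)$, where the sum
  weight $\Sigma$ (named `sigma_sum` in code) captures reward sensitivity.
* **Speed-accuracy trade-off learning (`rl_sat`, 8 parameters)** — the same
  learning architecture with interleaved speed- and accuracy-emphasis
  mini-blocks; emphasis selects between two urgencies ($V_{0,spd},
  V_{0,acc}$) and two thresholds ($B_{spd}, B_{acc}$), while the learning
  rate, difference and sum weights and $t_0$ are shared (that is what the
  8-parameter count enforces). Responses slower than the emphasis deadline
  are flagged but retained in the likelihood; whether the deadline censors
  the likelihood is not specified by the task description, so the likelihood
  is uncensored and the flag lets users drop those trials instead.
* **Reference-back working memory (`rb`, 9 parameters)** — a sensitivity
  parameterisation: the correct response's accumulator gets $V_0 + \delta$,
  the error accumulator $V_0 - \delta$. The urgency depends on the
  trial-type transition (repeat/switch), $\delta$ on trial type
  (reference/comparison) crossed with the correct response
  (same/different), and the threshold on the stimulus-identity transition.
  The $\pm\delta$ form (not $\pm\delta/2$) is the governing equation; the
  two differ only by a factor-2 rescaling of $\delta$, and the choice is
  documented so reported $\delta$ scales are unambiguous.
* **Multi-source interference (`msit`, 8 parameters)** — three response
  accumulators; each drift is $V_0$ plus flanker support ($v_{Flank}$ if
  the flanking digit matches that response), Simon support ($v_{Simon}$ if
  the target's spatial position primes it), and target support ($\delta$
  for the correct response). The target accumulator's start point moves
  toward the boundary by a position-dependent modifier; position 3 is the
  reference with modifier fixed at 0.

Concatenated, the four models give $6 + 8 + 9 + 8 = 31$ parameters per
participant.

## Hierarchy, joint models and sampling scale

Per-subject parameter vectors ("random effects") are modelled as draws from
a group-level multivariate normal on an unconstrained sampling scale:
thresholds and non-decision times are log-transformed, learning rates
logit-transformed, drift-type parameters untouched. Group means have
independent unit-variance normal priors whose locations are set on the
natural scale by parameter kind (2 for thresholds and difference
parameters, 1 for urgencies, 0.2 for non-decision times, 0 otherwise) and
mapped through the transforms.

Two group-level covariance structures are available:

* **Full multivariate normal** (between-session joint models): the group
  covariance has the marginally noninformative hierarchical inverse-Wishart
  prior ($\nu = 2$, unit half-t scales), giving conjugate Gibbs updates for
  the mean, covariance and auxiliary scales. Covariances are translated to
  correlations for reporting; in a two-session joint model the matched-
  parameter correlations quantify test-retest stability of the constructs.
* **Factor decomposition** (between-task joint models):
  $\Sigma = \Lambda\Lambda^\top + \mathrm{diag}(\epsilon)$ with $k$ latent
  factors. Identification uses fixed zeros above the diagonal of $\Lambda$
  plus *nonnegative diagonal loadings*. The sign constraint (rather than
  post-hoc alignment alone) removes the reflection modes from the
  posterior; a sign-multimodal loading posterior cannot be approximated by
  the moment-matched proposals that the evidence estimator relies on.
  Diagonal loadings therefore carry half-normal priors and are drawn by
  single-site truncated Gibbs steps. The parameter ordering puts the
  reversal task's $\delta$ first, so the constrained (1,2) entry is that
  parameter's loading on factor 2.

Two prior defaults deliberately differ from the commonly cited unit-scale
choices, because the sampling scale here has subject-level variances around
0.04–0.1: free loadings are $N(0, 0.5^2)$ (a unit normal would put
essentially all its prior mass on loadings larger than any attainable value
and inflate the Occam penalty of every additional factor by ~2.5 log units
per loading, distorting factor-count comparison), and uniquenesses are
IG(2, 0.3) (an IG(2, 1) prior, mean 1, inflates desk-scale uniquenesses
several-fold and shrinks every implied correlation). Both are arguments to
`group_prior()` and can be restored to other values.

## Particle Metropolis-within-Gibbs

Estimation alternates conjugate Gibbs updates of the group level with
conditional-importance-sampling ("particle") updates of each subject's
vector, in three stages: burn-in, adaptation, and sampling. A particle
update draws fresh candidates from a mixture of (i) the group-level
distribution, (ii) a local Gaussian centred on the subject's current value,
and — in the sampling stage — (iii) a conditional proposal fitted during
adaptation; the current value is always retained as one particle, and one
particle is selected with probability proportional to
likelihood × group density / mixture density.

Two structural choices matter for mixing and were adopted after the naive
alternatives failed on joint models:

* **Blocked subject updates.** For joint models the subject vector is
  updated one component (task or session) at a time. Under the factor group
  the components are conditionally independent given the factor scores,
  with diagonal conditional covariance; under the multivariate normal group
  the conditional prior of a block given the others is the Schur-complement
  normal. Updating 6–9 dimensional blocks with a few dozen particles mixes
  well; updating a 31-dimensional vector directly does not (subjects stall
  near their initial values and group correlations never accumulate).
* **Dimension-free local proposal.** The local mixture component has
  covariance $0.5^2\,\Sigma$ (not divided by dimension). A random-walk-style
  $1/p$ scaling makes the local kernel's peak density so high that the
  retained particle is penalised by tens of log units in the importance
  weights, and chains then drift through low-likelihood states.

Defaults (`sampler_config()`): burn-in 500, adaptation 500, sampling 1000
iterations; 100/100/50 particles; mixture weights 0.5/0.5 before the
sampling stage and 0.1/0.3/0.6 once conditional proposals exist. Validation
studies in the test suite use documented reduced settings (stage lengths
60–250, 12–40 particles), chosen as the smallest sizes at which the
conjugate-toy diagnostics stay calibrated.

Initialisation draws a cloud of candidates around the prior means (with
non-decision times capped below each subject's fastest response) and starts
each subject at the highest-likelihood candidate, so burn-in polishes rather
than travels.

## Evidence: importance sampling squared

`is2_marglik()` estimates the log marginal likelihood of a fitted model.
The outer level samples group parameters on an unconstrained vector
(means; log-Cholesky covariance for the multivariate normal group; free
loadings and log uniquenesses for the factor group, with the appropriate
Jacobians, and the hierarchical inverse-Wishart prior marginalised over its
auxiliary scales in closed form). The outer proposal is a defensive mixture:
a moment-matched multivariate t (df 5, inflated 1.2×) plus, with weight
`kernel_weight`, a Gaussian kernel mixture over the stored posterior draws —
in high-dimensional group spaces a moment fit alone cannot track the
posterior and the kernel component keeps the proposal anchored to it.

The inner level estimates each subject's likelihood contribution
$p(y_s \mid \theta)$ by importance sampling. For factor-group joint models
this uses a factorised estimator: conditional on the factor scores the
components are independent, so factor scores are drawn from a fitted
proposal and each component integral is estimated in its own 6–9
dimensions. All inner proposals are independent of $\theta$, so particles
and their (expensive) likelihoods are drawn once per subject and reused by
every outer draw; each outer draw then costs only Gaussian algebra. This
reduced the inner-estimator noise on a 31-parameter joint model from tens
of log units to a few, at a fraction of the cost of the naive scheme.

Bayes factors are ratios of marginal likelihoods; their standard errors come
from bootstrap resampling of each estimate's importance weights, and
evidence objects carry a data fingerprint so estimates computed on different
data refuse to form a Bayes factor.

# The synthetic-cohort generator

`simulate_cohort()` generates complete cohorts: group structure (multivariate
normal or factor), subject vectors on the sampling scale, per-subject design
realisations, and trial data simulated through the task models with exact
inverse-Gaussian first-passage draws (no time discretisation). Learning
tasks thread the value state online, so simulated choices determine realised
feedback. A master seed spawns per-subject/task/session child seeds
deterministically, making any slice reproducible on its own.

Default generating group means are the natural-scale medians reported for
these four paradigms (e.g. reversal learning: $\delta = 1.50$, $B = 1.63$,
$t_0 = 0.13$, $V_0 = 2.08$, $\alpha = 0.18$, $\Sigma = 0.48$); between-
subject standard deviations on the sampling scale default to 0.3 (identity-
scale parameters), 0.2 (log) and 0.5 (logit). Two-session multivariate
cohorts draw the two session vectors jointly with per-parameter
cross-session correlation `session_rho` (default 0.6). Factor cohorts use a
two-factor loading pattern that mirrors the structure the between-task
analysis targets: factor 1 on the difference/interference parameters of all
tasks, factor 2 on the learning tasks' thresholds and urgencies, with the
constrained first-row loading at zero.

What the generator does *not* emulate: contaminant/omission processes, slow
drifts in attention, post-error adjustments, stimulus-specific learning
biases, or deadline-induced censoring. Passing recovery tests on these
cohorts therefore demonstrates internal consistency of model, simulator and
sampler — not robustness of the model to the violations real data contain.

# Validation studies and the problem sizes they use

The test suite validates each layer against an independent oracle: the Wald
mathematics against closed forms, quadrature and a Euler–Maruyama race
simulator with Brownian-bridge crossing corrections; the Gibbs kernels
against conjugate posteriors and a hand-coded one-dimensional chain; the
sampler and IS² against a hierarchical normal toy with analytic posterior
and analytic evidence; and the full pipelines against parameter- and
model-recovery on synthetic cohorts.

Recovery studies run at desk scale, sized so the whole suite completes on a
single CPU: 10-subject single-task cohorts (reversal 2×60 trials with
reversal at 30, speed-accuracy 4×60, reference-back 320, interference 240)
with reduced sampler settings for group-mean coverage; a 30-subject
two-session reference-back cohort (256 trials per session) for test-retest
correlation recovery; and 20-subject four-task cohorts (two pooled sessions
of 48/48/48/36 trials) generated from a two-factor structure with strong
loadings (0.7 on the sampling scale, implying construct correlations near
0.95 among loaded parameters) for factor-count recovery by IS² Bayes
factors. Desk-scale caveats worth stating plainly: with ten subjects and a
few hundred trials, weakly identified parameters (urgency and learning-rate
means in the speed-accuracy task) are prior-influenced, and latent
test-retest correlations of parameters with modest single-session
reliability are posterior-shrunk toward zero; both effects shrink as trials
and subjects grow and neither reflects a defect of the estimator on
well-identified quantities.

# Numerical choices

* Quadrature for choice probabilities: adaptive, absolute tolerance 1e-6,
  horizon where total finishing probability exceeds $1 - 10^{-8}$.
* Survival log-probabilities floored at $-700$; all weight arithmetic in
  log space with max-shift stabilisation.
* Fitted proposal covariances are symmetrised and ridged ($10^{-6}$);
  conditional-proposal fits that remain rank-deficient extend the
  adaptation stage (up to a configured cap) before failing.
* Ties in race simulation (probability zero) resolve to the lowest index.
* Posterior summaries use type-7 (linear interpolation) quantiles; credible
  intervals that exclude zero are flagged, mirroring the bold-marking
  convention of the tables this output format follows.

# Known limitations

* No censoring model for deadline-bound responses; flagged, not modelled.
* The evidence estimator's effective sample size degrades in very
  high-dimensional group spaces (three-factor joint models at 31
  parameters); estimates remain usable for ranking well-separated models
  but their bootstrap SEs are then optimistic.
* Single-chain defaults; the suite runs replicate chains for its
  convergence checks but no within-fit R-hat gate is enforced.
* The reference-back state machine assumes an error-free reference update
  (the memorised item is the stimulus shown on the last reference trial).
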