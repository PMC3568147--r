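---
title: "Modeling structural credit assignment in reward-based trajectory learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling structural credit assignment in reward-based trajectory learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3)
library(trajlearn)
```

## The scientific problem

When a single scalar reward follows a movement, the learner faces a
*structural* credit-assignment problem: which property of the movement —
not which movement in a sequence — earned or lost the money? `trajlearn`
models a reaching task built around exactly this question. Participants
repeatedly draw 7-cm reach trajectories toward an invisible target shape,
receiving only a monetary score after each attempt. Every trajectory is
summarized by two dimensionless parameters: a **direction** component
$\alpha$ (linear lateral drift) and a **curvature** component $\beta$
(midpoint-peaked lateral bow). The score weights the two error dimensions
unequally (0.8 vs 0.2), and the weighting is flipped between two groups, so
the task dissociates how strongly each movement property is penalized from
how quickly it is learned.

The package provides the full loop as tested code: the trajectory family
and its inversion, the reward rule, a grid-based Bayesian learner that can
generate behavior, a synthetic-cohort generator with the experiment's
design, a 4-parameter model fitter, and the behavioral analyses
(exponential learning curves, quiver summaries of trial-to-trial changes,
session-wise meta-learning tables).

## Trajectory family and workspace geometry

A reach lives in a table-top workspace 21.7 cm wide and 7 cm deep, starting
at the origin and ending on the line $y = Y = 7$ cm. With $u = y/Y$, the
two-parameter family is

$$x(y) = \alpha\,\tfrac{W}{2}\,u \;+\; \beta\,C\,4u(1-u),
\qquad W = 21.7\ \mathrm{cm},$$

a linear direction term plus a curvature bump that vanishes at both ends
and peaks at mid-reach. The curvature scale is fixed at $C = W/8$: this is
the largest value for which the lateral extremum of every member of the
enumerated target family stays at the reach endpoints, which makes the
tight bounding box of all $21 \times 21$ grid targets *exactly* the printed
workspace — `family_bounding_box()` verifies 21.7 cm × 7 cm, and the test
suite asserts it without tolerance. Targets take $\alpha, \beta$ values on
the 0.1-spaced grid covering $[-1, 1]$; executed movements may leave that
range.

Because the family is linear in $(\alpha, \beta)$, `estimate_params()`
recovers the parameters of a sampled path by closed-form least squares on
the two basis shapes; a noiseless round trip is exact to numerical
precision. Generated paths default to 250 samples per reach, echoing one
second of movement at the task's approximately 250 Hz cursor sampling.

```{r traj-example}
p <- traj_params(0.6, -0.4)
tr <- generate_trajectory(p)
estimate_params(tr)
```

## Reward model

Normalized absolute errors divide by 2, the full width of the target range,
the unique constant for which any in-range executed/target pair gives
errors in $[0, 1]$:

$$\Delta_\alpha = \tfrac{|\hat\alpha - \alpha^\ast|}{2}, \qquad
\Delta_\beta = \tfrac{|\hat\beta - \beta^\ast|}{2}.$$

The score fraction is the weighted linear penalty
$1 - (W\Delta_\mathrm{weighted} + w\Delta_\mathrm{unweighted})$ with
$W = 0.8$, $w = 0.2$, scaled by 50 cents. Out-of-range movements can push
the fraction negative; participants are nevertheless shown a clipped,
non-negative amount, and the simulated learner likewise observes only the
displayed reward (rescaled to $[0,1]$) — that is all a participant ever
sees. The raw fraction is logged for analysis. Sessions pay the best
attempt per target, summed over the 50 targets, so a flawless session is
worth exactly 25 dollars.

## The Bayesian learner

The learner maintains a normalized probability map over candidate targets
on a $G \times G$ cell-centered grid spanning $[-1,1]^2$ (cell $i$ center
$-1 + (2i-1)/G$; $G = 200$ canonically). Each trial iterates four steps:

1. **Memory decay.** $P \leftarrow \lambda P + (1-\lambda)\,U$ with $U$
   uniform. This convex-combination forgetting is the unique linear scheme
   for which $\lambda = 1$ is perfect recall and $\lambda = 0$ a flat
   prior, and it contracts the map to uniform geometrically.
2. **Action selection.** The maximum-a-posteriori cell center, plus
   simulation-only Gaussian exploration noise (`explore_sd`). Ties break
   deterministically to the first maximal cell in storage (column-major)
   order. On a still-uniform map the default is a uniform random draw over
   $[-1,1]^2$ — simulated cohorts must start by exploring, as people do;
   a configuration switch restores the bare tie-break.
3. **Reward observation.** The displayed, clipped reward as a fraction
   $r_t \in [0,1]$.
4. **Update.** The learner's subjective reward prediction at each candidate
   cell uses *squared* normalized errors with internal weights
   $(w_\alpha, w_\beta)$:
   $\hat r(pos) = 1 - (w_\alpha \Delta_\alpha^2 + w_\beta \Delta_\beta^2)$.
   The prediction error $e(pos) = \hat r(pos) - r_t$ defines a likelihood
   kernel, and the posterior is $P(pos) \propto P(pos)\,
   e^{-\kappa\,e(pos)^2}$, renormalized.

The multiplicative exponential kernel was chosen over an additive
prediction-error step because it preserves positivity and normalization by
construction and composes as Bayes' rule — prior times likelihood — with
the learning rate $\kappa$ setting how sharply a single observation
reshapes belief. A numerically underflowed posterior (possible at extreme
$\kappa$) falls back to the prior with a warning. Note the learner's
internal quadratic approximation deliberately differs from the task's
linear reward: subjects are assumed to approximate, not know, the rule.

After one informative reward the posterior concentrates on a curved band
of hypotheses that would have predicted the observed reward; learning
proceeds by intersecting such bands across trials, at a speed governed
jointly by $\lambda$ (how much of the previous band survives) and
$\kappa$ (how sharp each band is).

## Synthetic cohorts

`generate_cohort()` reproduces the experimental design: 2 reward conditions
× 8 participants × 50 targets × 25 trials (1250 reaches per participant),
targets drawn without replacement from the 441-cell grid, all randomness
derived from one master seed through per-participant sub-seeds. Each
synthetic participant draws individual learner parameters from
`default_learner_distribution()`:

* **memory decay** centered on the per-condition group estimates (0.32
  direction-weighted, 0.54 curvature-weighted) with the reported 0.1
  spread;
* **internal weights** centered on the condition's true reward weights
  (sd 0.05) — the assumption that subjects, on average, discover the true
  weighting;
* **learning rate** $\kappa = 50 \pm 10$ and **exploration noise** 0.05:
  fixed assumptions, chosen once so that simulated reward curves rise
  early and plateau around the 20th trial with per-target best rewards in
  the mid-40-cent range, the regime the group curves describe. With
  $\kappa = 50$ a reward prediction error of 0.1 scales a cell's
  probability by $e^{-0.5} \approx 0.61$, i.e. single observations are
  informative but not dogmatic.

Draws are truncated to each parameter's valid range. The generator does
*not* emulate arm biomechanics, reaction times, within-trial kinematic
noise, drop-out, or meta-learning (parameters are constant across a
simulated session), so passing tests demonstrate correctness of the
machinery and recoverability of parameters under the model's own
assumptions — not that human data were reproduced. The human numbers this
design echoes (decay constants, asymptotes, variance explained) are
qualitative anchors only, since the original behavioral data are not
public.

## Fitting the 4-parameter model

`fit_learner()` estimates $(\lambda, w_\alpha, w_\beta, \kappa)$ per
participant. The replay is *teacher-forced*: within each sequence the map
is conditioned on the participant's actual actions and rewards for trials
$1 \ldots t-1$, and the MAP of the decayed map is the deterministic
prediction for trial $t$ (first trials have none; a still-uniform map
predicts the grid center). Teacher forcing matches how the model is
evaluated against trial-to-trial decisions: predictions must condition on
the realized history, not on the model's own trajectory.

The loss is the summed squared Euclidean distance between predicted and
observed actions from trial 2 on. The fitted model is scored by the pooled
two-dimensional $R^2$ between predicted and observed *trial-to-trial
change* vectors, the natural companion of a squared-error loss.
Exploration noise is excluded from the fitted set — the model has exactly
four free parameters — and residual action noise is absorbed by the loss.

Optimization is multi-start Nelder-Mead on transformed coordinates (logit
for $\lambda$, log for weights and $\kappa$): a coarse 24-point grid is
scored, local searches run from the best points, and the incumbent is
polished by a simplex restart. The objective is piecewise constant in the
parameters (predictions are discrete cell centers), which rules out
gradient-based methods; with 1250 trials the steps are fine enough for a
simplex to track. Fitting uses $G = 100$ by default — replay cost scales
with $G^2$, and halving the canonical resolution changes predictions by at
most one cell width (0.02), well under the exploration noise. The hot
replay loop is compiled (C++), and the test suite pins it to a
step-by-step R composition of the exported map operations at $10^{-12}$.

Two identifiability facts, established empirically in the test suite:

* With moderate exploration noise, 15–50 sequences identify $\lambda$ to a
  median absolute error of a few hundredths and the dominant weight to
  about 0.01–0.02; cohort medians sit well inside the ±0.1 and ±0.15
  acceptance bands used in the recovery tests.
* On *noiseless* self-generated data the loss is exactly zero on a plateau
  of $(\lambda, \kappa)$ values producing identical MAP sequences, so
  point recovery is only guaranteed up to that plateau; the fixed-point
  test therefore regenerates data with the original noise level.

## Behavioral analyses

`learning_curves()` averages $|\hat\theta - \theta^\ast|$ (raw parameter
units) or displayed reward per trial index over all sequences.
`fit_exponential()` fits $y(t) = A e^{-t/\tau} + c$, so $\tau$ is directly
in trials; for fixed $\tau$ the other two parameters are a linear fit, so
$\tau$ is profiled on a log grid and refined with Brent's method — no
random starts, deterministic, and exact to $10^{-6}$ on noiseless curves.
Near-constant series are flagged `unidentifiable` (amplitude ≈ 0, $\tau$
meaningless) rather than reported as fits. Group-average curves are fitted
(per-participant fitting is available by subsetting), and the headline
qualitative effect — the reward-weighted property has the smaller $\tau$
in both conditions — is asserted on synthetic cohorts in the tests.

`quiver_summary()` works in absolute normalized-error coordinates: trials
are binned by $(|\Delta_\alpha|, |\Delta_\beta|)$ (bin width 0.1), and the
mean change in those errors to the next trial is averaged per bin,
observed next to model-predicted; a negative component means the error
shrank. Bins below `min_n` trials are omitted, not zero-filled, and the
$n$-weighted bin means reconstruct the overall mean change exactly.
`meta_learning_summary()` groups the 50 targets into 5 sessions of 10 (in
presentation order) and summarizes each sequence by its last 5 trials
(21–25); non-canonical designs must state their session size explicitly.
Inferential statistics between groups are out of scope throughout — the
summaries are descriptive means ± sem.

## Problem sizes and reproducibility

The test suite exercises reduced but structurally faithful problems:
belief grids of 25–100 cells per dimension, 10–50 sequences per
participant, recovery studies of 10 participants per condition at the full
protocol (50 × 25, $G = 100$) and 20 per condition at a lighter one
(15 × 25, $G = 60$). The pipeline (`run_simulate()` → `run_fit()` →
`run_analyze()`, or the `inst/cli/trajlearn.R` wrapper) is deterministic
from a config and seed: rerunning a stage reproduces its CSVs byte for
byte.

## Known limitations

* The learner is stationary: constant $\lambda$ and $\kappa$ within a
  session, hence no meta-learning in generated cohorts; the session-wise
  summary exists to *detect* such trends, and is flat by construction on
  the generator.
* The additive variant of the map update (prediction error scaled into the
  map directly) is a documented alternative that is not implemented; the
  multiplicative kernel was preferred on the grounds above.
* MAP action selection with a deterministic tie-break is a modeling
  choice; posterior-sampling policies are not provided.
* Fitted $\kappa$ is the least identified of the four parameters (it
  trades off against the weights' scale in sharpening the likelihood);
  recovery tests therefore gate only $\lambda$ and the dominant weight.
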