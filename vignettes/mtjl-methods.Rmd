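---
title: "Multi-trial joint learning: model, solver and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trial joint learning: model, solver and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtjl)
```

## The problem

Reading ability is usually assessed with long question batteries.
Eye-tracking offers a faster route: while a participant reads a battery of
single-sentence trials, the tracker summarizes each trial into a vector of
indicators -- pupil diameter, blink count and rate, fixation count / rate /
duration / position, saccade count / rate / duration / amplitude, regression
count / rate / path length -- optionally augmented with entrance-exam
scores.  The estimation problem is then: given $m$ per-trial feature tables
$X_i \in \mathbb{R}^{N \times D}$ over the same $N$ participants and one
reading-score vector $Y \in \mathbb{R}^N$ on the 0--100 scale, learn
per-trial predictors that pool their strength across trials.

## Model

Each trial $i$ carries a weight vector $w_i \in \mathbb{R}^D$ and bias
$b_i$.  `mtjl` minimizes

$$
J(W, b) \;=\; \sum_{i=1}^m \lVert X_i w_i + \mathbf{1}_N b_i - Y \rVert_2^2
\;+\; \lambda \sum_{i=1}^m \lVert w_i \rVert_2^2
\;+\; \gamma\, \lVert W \rVert_* ,
$$

where $W = [w_1, \dots, w_m] \in \mathbb{R}^{D \times m}$ and
$\lVert W \rVert_*$ is the nuclear (trace) norm, the sum of singular
values and the standard convex surrogate of $\mathrm{rank}(W)$.  The
low-rank term encodes the belief that the $m$ trials measure the same
underlying construct, so their weight vectors should span a low-dimensional
subspace; the ridge term controls per-trial complexity.  Both penalty
weights default to 1 and are exposed through `mtjl_control()`.

The nuclear norm is handled through the identity
$\lVert W\rVert_* = \mathrm{Trace}\!\left(W^\top (WW^\top)^{-1/2} W\right)$,
which yields closed-form stationarity conditions:

$$
w_i = (X_i^\top X_i + \lambda I + \gamma D_r)^{-1}
      (X_i^\top Y - X_i^\top \mathbf{1}_N b_i), \qquad
b_i = \tfrac{1}{N}\big(\mathbf{1}_N^\top Y - \mathbf{1}_N^\top X_i w_i\big),
$$

with the reweighting matrix $D_r = \tfrac{1}{2}(WW^\top)^{-1/2}$.  The
solver iterates: update every $w_i$ (with $D_r$ fixed from the previous
iterate), then every $b_i$, then recompute $D_r$ and the objective.  This
is a majorize--minimize scheme -- the quadratic form
$\mathrm{Trace}(W^\top D_r W)$ with $D_r$ frozen at the previous iterate
upper-bounds the (smoothed) nuclear norm up to a constant -- so the
objective trace is non-increasing; the tests assert this on every fit.

## Numerical choices

* **Smoothing.** $(WW^\top)^{-1/2}$ is undefined for rank-deficient $W$
  (including a zero start), so the implementation uses
  $(WW^\top + \delta I)^{-1/2}$ with $\delta = 10^{-8}$, the standard
  smoothing of iteratively-reweighted trace-norm schemes.  The smoothed
  surrogate $\sum_k \sigma_k^2/\sqrt{\sigma_k^2+\delta}$ converges to the
  nuclear norm as $\delta \to 0$; `trace_surrogate()` at
  $\delta = 10^{-10}$ matches the SVD nuclear norm to $10^{-4}$.
  All symmetric decompositions clip eigenvalues at $\delta$; linear
  systems are solved by factorization, never by forming an inverse.
* **Initialization.** By default every trial is warm-started at its
  decoupled ridge-with-intercept solution (the exact $\gamma = 0$
  optimum), which is well-posed and close to the joint fixed point; fits
  then typically converge in one to three reweighting iterations.  A
  `"zeros"` start is available and converges to the same objective value,
  only more slowly.
* **Convergence.** The stopping rule is relative:
  $|J_t - J_{t-1}| / \max(1, |J_{t-1}|) \le 10^{-6}$, capped at 100
  iterations (reaching the cap yields a warning and `converged = FALSE`,
  not an error).
* **Biases.** One bias per trial, as the stationarity equations dictate
  (the per-trial bias is the residual mean).
* **Prediction.** The model yields $m$ per-trial scores for a new
  participant; the paper-level method does not define how they combine,
  so the package uses their unweighted mean by default (`"median"`
  optional, plus optional clipping to $[0, 100]$).
* **Degenerate inputs.** With $\lambda = \gamma = 0$ and rank-deficient
  features, the weight solve fails with an error naming the trial;
  constant columns are centered but not scaled (with a warning); an
  entirely missing column cannot be imputed and errors by name.

Against an independent first-order solver of the same convex objective
(FISTA with singular-value thresholding, biases eliminated by centering),
the closed-form scheme agrees in final objective to better than $10^{-6}$
relative on random problems; the acceptance suite re-checks this at the
$10^{-4}$ level on twenty instances.

## Indicator screening

`screen_indicators()` runs a one-way ANOVA per indicator between the
high- and low-ability groups and flags `p < alpha` (default
$\alpha = 0.05$).  Because each participant contributes $m$ correlated
trial observations, the default unit of analysis is the participant's
across-trial mean -- testing single-trial observations as if independent
would inflate the effective sample size (pseudo-replication); a
`per_trial` mode is provided for comparison.  No multiple-testing
correction is applied, matching the reference protocol.  Screening is a
report, not a filter: all features still enter the model, since weakly
contributing indicators can still carry weight.

The package ships the published screening table of the motivating
74-participant cohort (`screening_reference()`).  A printed significance
of 0 is read as "below display precision", not literal zero.  At
$\alpha = 0.05$ exactly 13 of its 15 indicators are sensitive -- fixation
position Y ($p = 0.83$) and regression length ($p = 0.19$) are not.  The
study's own prose also quotes a count of fourteen that includes
regression length; the tabled p-values support thirteen, which is what
the package reports, and both counts are noted here deliberately.

## The synthetic cohort generator

No public release of the original cohort exists, so the generator
emulates its *structure*: $N = 74$ participants, $m = 42$ sentence
trials, $D = 19$ features (16 eye-tracking indicators + Chinese, math and
English exam scores), scores mapped into the observed 48.8--90.83 range,
plausible per-family raw units, a rank-2 ground-truth weight matrix, and
sporadic missingness in the blink columns (blinks are rare, so real
trials often record none).

Construction, per trial: a standardized latent reading ability $a$, a
group-shift direction $h$, and feature noise are combined as
$\tilde X_i = a\, w_i^{*\top} + h\, c^\top + P_i$, where

* the ground truth $W^* = AB^\top$ has exact rank $r$ (default 2) with
  unit-norm columns, its first trial factor shifted so trials share a
  dominant direction (real trial profiles are consistent, not
  sign-alternating);
* $c$ holds per-indicator group shifts (default 1.0 SD on the thirteen
  sensitive indicators, 0 elsewhere) and is projected orthogonal to the
  columns of $W^*$, so group differences never leak into the scores;
* $P_i$ is noise projected orthogonal to $w_i^*$, the constant, $a$
  and $h$.

This makes every trial exactly consistent,
$\tilde X_i w_i^* = a$, so $W^*$ is identifiable and recovery is a sharp
test: with the default cohort and small penalties the fitted matrix is
within a few percent relative Frobenius error of $W^*$.  Scores are the
across-trial mean prediction affinely mapped into the score range, plus
Normal(0, `noise_sd`) noise *in score points* (default 0.5), clipped to
the range.  Columns of the normalized representation are exactly
mean-zero and approximately unit-variance; the exact-consistency
construction precludes forcing unit variance per column, which is why
recovery checks fit on `simulate_cohort(raw = FALSE)` output with
`normalize = "none"` and compare $\hat W / \beta$ (score-map slope
$\beta$) against $W^*$.

Two deliberate departures from the recruited cohort: group labels are
drawn balanced (37/37) and *independent* of the latent ability, with
group differences entering only through the shift coefficients.  This
keeps the screening ground truth exact -- an indicator differs between
groups if and only if it was given a shift -- which is what the
screening-power checks need; with a median-split-by-ability grouping,
every ability-loaded indicator would separate the groups and "null"
would be ill-defined.  (The original study recruited 36 high / 38 low
readers; the generator's invariant is balance within one.)  A side
effect of the exact orthogonalization is that noise carries no realized
group contrast at all, so the false-flag rate on null indicators sits
*below* the nominal $\alpha$; the calibration of the ANOVA itself is
checked separately on i.i.d. draws.

What the generator does **not** emulate: realistic marginal shapes
(indicators are Gaussian on their family scales; real counts are
discrete and skewed), correlations between indicator families beyond the
shared ability factor, trial-order effects such as fatigue, and any
dependence of missingness on the signal (cells are masked completely at
random).  Passing tests therefore certify the estimator and pipeline
mechanics, not performance on real recordings, and no synthetic result
is presented as reproducing the published F statistics or the published
error of 4.91 (SD 0.94) over 100 runs, which would require the
undeposited data.

## Evaluation protocol

`repeated_evaluation()` mirrors the reference protocol: repeatedly split
the participants in half (37/37 at $N = 74$; trials never straddle a
split), z-score each feature per trial with *training-fold* statistics
(population SD), impute missing cells with the training mean (zero on
the z-score scale), fit, and score the held-out half.  The published
protocol never names its error metric beyond "average error out of
100"; the package reads that as mean absolute error on the centesimal
scale and offers RMSE as an alternative.  Runs that fail are excluded
from the mean/SD summaries (conservative) and abort the evaluation if
they exceed 20%.  Contribution summaries use conventions of this
package, chosen for interpretability rather than to reproduce plotted
values: indicator contribution is the normalized mean absolute weight
across trials, trial contribution the absolute column sum (raw and
max-scaled).

Determinism: every stochastic step (generation, masking, splitting)
flows from an explicit seed, run $k$ of an evaluation uses
`base_seed + k - 1`, and output documents embed the settings and seed
that produced them.

## Problem sizes used in the test suite

The suite exercises the solver at $N = 20$--$40$, $D \le 6$, $m \le 5$
for oracle comparisons (20 instances against the convex oracle, 100 for
convergence properties), the full default cohort ($74 \times 19 \times
42$) for recovery, shrinkage and screening-power checks (10--50 seeds),
and 100-run repeated evaluations -- sizes at which every check completes
in seconds while leaving the asserted tolerances sharp
($10^{-8}$ for analytic limits, $10^{-4}$ against the convex oracle,
5% relative Frobenius error for recovery).

## Known limitations

* The mean rule for aggregating per-trial predictions is a convention;
  trial-weighted aggregation could use the trial contributions.
* The nuclear-norm smoothing parameter trades accuracy for conditioning;
  $\delta$ far above $10^{-6}$ visibly biases the rank term.
* `anova_f` assumes equal group variances (the classical one-way form);
  no nonparametric fallback is provided.
* With $\lambda = \gamma = 0$ the model is ordinary least squares per
  trial and requires full-rank features; the solver will not silently
  regularize.
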