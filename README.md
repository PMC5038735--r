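# mtjl

Multi-trial joint learning for eye-tracking based reading-ability
assessment.

## What problem this solves

Assessing a reader's ability with question batteries takes hours and the
result drifts with fatigue, mood and prior knowledge of the material.
Eye-tracking during a short battery of sentence-reading trials offers a
faster, more objective signal: pupil diameter, blink, fixation, saccade
and regression indicators all separate strong from weak readers.  The
statistical difficulty is that every participant contributes *m* trials
(42 in the motivating design), each yielding its own feature table over
the same participants, with one shared score vector — too correlated to
pool naively, too small to fit independently.

`mtjl` implements the multi-trial joint learning model for this setting:
one linear predictor per trial, coupled through a low-rank penalty on the
stacked weight matrix

$$
\min_{w_i,\,b_i}\;
\sum_{i=1}^{m} \lVert X_i w_i + \mathbf{1}_N b_i - Y\rVert_2^2
+ \lambda \sum_{i=1}^{m} \lVert w_i\rVert_2^2
+ \gamma\,\lVert W \rVert_* ,
\qquad W = [w_1,\dots,w_m] \in \mathbb{R}^{D\times m},
$$

where $\lVert W\rVert_*$ (nuclear norm, sum of singular values) is the
convex surrogate of $\mathrm{rank}(W)$.  The solver alternates exact
closed-form updates of $w_i$ and $b_i$ with a reweighting matrix
$D_r = \tfrac12 (WW^\top + \delta I)^{-1/2}$, giving a monotonically
decreasing objective that typically converges in a handful of
iterations.  Around the solver the package provides the full pipeline:
one-way ANOVA screening of indicators between ability groups,
training-fold z-score normalization, missing-value handling for the
sporadically empty blink cells, repeated half-split evaluation,
indicator/trial contribution summaries, a synthetic cohort generator
with known low-rank ground truth, JSON/CSV round-tripping and a small
CLI.  It is aimed at researchers in educational measurement and
eye-movement analysis who want the method, a reproducible evaluation
harness, or a test bed for extensions.

See `vignette("mtjl-methods")` for the model, the solver and every
design decision.

## Worked example

Simulate a cohort with the default structure (74 participants, 42
trials, 19 features, rank-2 truth, 0.5 score-point noise), mask 10% of
the blink cells, screen the indicators, fit, and evaluate:

```r
library(mtjl)

sim    <- simulate_cohort(cohort_config(), seed = 42)
cohort <- inject_missing(sim$data, fraction = 0.1, families = "blink",
                         seed = 43)
cohort
#> <multitrial_dataset> 74 participants x 19 features x 42 trials
#>   scores: 49.0-90.8; missing cells: 623

scr <- screen_indicators(cohort, sim$truth$group_labels, alpha = 0.05)
sum(scr$sensitive)
#> [1] 13
```

Thirteen indicators separate the two ability groups — exactly the ones
the generator shifted by 1 SD.  Each row carries the F statistic, its
p-value and degrees of freedom (e.g. saccade amplitude: F = 1160 on
(1, 72) df).

```r
fit <- mtjl_fit(cohort, mtjl_control(lambda = 1, gamma = 1))
fit
#> <mtjl_model> 19 features x 42 trials (lambda = 1, gamma = 1)
#>   converged after 2 iteration(s); objective 7698.85; nuclear norm 92.72

ev <- repeated_evaluation(cohort, mtjl_control(lambda = 1, gamma = 1),
                          n_runs = 100, base_seed = 1)
ev
#> <mtjl_evaluation> 100 run(s): MAE = 0.669 (sd 0.118); median iterations 2
```

Over 100 random 37/37 splits the model predicts held-out reading scores
to within 0.67 points (on the 0–100 scale) on average — close to the
generator's 0.5-point noise floor, i.e. the model recovers nearly all
recoverable signal.  `ev$indicator_contributions` and
`ev$trial_contributions` summarize which indicators and trials carry the
weight; `autoplot(fit)`, `autoplot(ev)`, `plot_screening(scr)` and
`plot_indicator_contributions(ev)` visualize the results, and `tidy()` /
`glance()` give tibble summaries of every fitted object.

The same pipeline runs from a shell:

```sh
inst/cli/mtjl simulate --out cohort/ --seed 42
inst/cli/mtjl screen   --features cohort/features.csv --scores cohort/scores.csv --out screening.csv
inst/cli/mtjl fit      --features cohort/features.csv --scores cohort/scores.csv --out model.json
inst/cli/mtjl evaluate --features cohort/features.csv --scores cohort/scores.csv --n-runs 100 --out report.json
```

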