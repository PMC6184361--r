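---
title: "Methods: adaptive psychophysics with task switching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive psychophysics with task switching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psyswitch)
```

This vignette documents the models and algorithmic choices behind
`psyswitch` at the level of detail needed to audit or re-implement them.

## 1. The psychometric model

The probability of the `r1` response (clockwise tilt / yellowish hue) at
signed stimulus strength $s$ is the lapse-extended cumulative Gaussian

$$p(r_1 \mid s) \;=\; \frac{\lambda}{2} \;+\; (1 - \lambda)\,
  \Phi\!\left(\frac{s - \mu}{\sigma}\right),$$

with bias $\mu$, perceptual noise $\sigma > 0$ and lapse rate
$\lambda \in [0, 1]$. The lapse term is split evenly between the two
responses, so $p$ is confined to $[\lambda/2,\, 1 - \lambda/2]$.
`psychometric_prob()` evaluates this directly.

Stimulus strength lives on an abstract unit scale $w$. For orientation
the default conversion to degrees of tilt is $\theta = 180 w / \pi$
(`w_to_orientation()`, so $w = 0.5$ maps to $28.6479^\circ$); a
`"linear60"` alternative maps $w \in [-0.5, 0.5]$ linearly onto
$[-30^\circ, 30^\circ]$. Which scaling the original apparatus used is
genuinely underdetermined by the available description, so both are
exposed and the choice is an explicit argument. For colour, $w$
interpolates linearly in CIELAB at fixed lightness $L^\ast = 78$ between
a blue endpoint $(a^\ast, b^\ast) = (-30, -40)$ and a yellow endpoint
$(0, 80)$ (`w_to_lab()`, `color_endpoints()`).

## 2. The adaptive staircase

The engine (`psi_engine()`) maintains a discrete posterior over
$(\mu, \sigma, \lambda)$ on a fixed grid: by default 51 linear $\mu$
points on $[-0.5, 0.5]$, 25 log-spaced $\sigma$ points on
$[0.002, 0.8]$, and 25 linear $\lambda$ points on $[0, 0.3]$ — 31,875
cells — with a uniform prior. The likelihood table
$P_{js} = p(r_1 \mid s;\, \theta_j)$ over the 101 candidate stimuli is
precomputed once per engine and shared across participants.

After a relevant-key response $r \in \{0, 1\}$ at stimulus $s$ the
posterior update is exact Bayes on the grid
(`update_posterior()`). Trials answered with a task-irrelevant key do
not update the posterior: they carry no information about the
psychometric parameters of the cued task.

### Stimulus selection by expected entropy

`select_stimulus()` picks the candidate minimizing the expected Shannon
entropy of the next posterior. Writing $q$ for the current posterior,
$x \log x$ elementwise, and $P_{\cdot s}$ for the likelihood column of
candidate $s$:

$$\mathrm{EE}(s) = -\sum_j q_j \log q_j
  \;-\; \sum_j q_j \big[ x\log x(P_{js}) + x\log x(1 - P_{js}) \big]
  \;+\; x\log x(\pi_1) + x\log x(\pi_0),$$

where $\pi_1 = \sum_j q_j P_{js}$ is the predictive probability of
$r_1$ and $\pi_0 = 1 - \pi_1$. This identity turns the naive
"update-then-measure" double loop into two dot products per candidate;
the implementation caches $x\log x(P) + x\log x(1-P)$ at engine
construction and evaluates the sweep in C++, restricted to the posterior
support ($q_j > 10^{-15}$, which bounds the truncation error near
machine precision). A pure-R per-candidate slow path
(`expected_entropy(state, s = ...)`) computes the same quantity by
explicit Bayes updates and is used as the oracle in the tests.

Ties within a relative tolerance of $10^{-9}$ resolve to the smallest
$|s|$ and then to the negative member; $|s|$ itself is compared with a
tolerance so floating-point asymmetries in the candidate grid cannot
flip the sign preference. An optional `entropy_scope =
"sigma_marginal"` minimizes the entropy of the $\sigma$ marginal
instead of the joint.

Staircase state serializes to JSON (`psi_state_json()` /
`psi_state_restore()`) with the posterior flattened row-major,
$\lambda$ fastest, so sessions can be interrupted and resumed.

## 3. The session design and key map

A session is a sequence of blocks, by default
`O C S S S S C O` with 100 trials each: 800 trials, exactly 200
single-task orientation and 200 single-task colour trials, and 400
switch trials whose cued feature is a fair coin per trial. Within switch
blocks each feature runs its own staircase per participant, so noise
estimates under load are identified separately.

Eight response keys factor into side × feature × response. Given the
cued feature and stimulus side, exactly two keys are task-relevant; the
remaining six are task-irrelevant motor output (TIMO), subclassified as
*spatial* (wrong side), *feature* (wrong feature) or *both*
(`classify_key()`, `timo_keys()`). Correctness is defined only for
relevant presses; TIMO trials carry `NA` correctness by construction and
the trial validator enforces this.

## 4. Synthetic observers

`observer_params()` fixes a generative participant: per-condition
psychometric parameters $(\mu, \sigma_\text{cond}, \lambda)$,
ex-Gaussian reaction-time parameters per condition, and TIMO
propensities by subtype. `simulate_participant()` runs the observer
through the same staircase loop a real session would use: on each trial
the engine proposes $w$, the observer either emits a TIMO press (with
its configured probability, subtype by its weights) or a relevant press
drawn from its psychometric function, and only relevant presses update
the staircase. Distractor strengths are drawn from a von Mises centred
at zero ($\kappa = 30$, halved to the half-angle scale, SD about
$5.2^\circ$) for orientation and uniformly for colour.

Cohorts (`cohort_spec()`) draw each observer's parameters from
group-level distributions; the defaults give the case group larger
switch-cost noise and higher TIMO rates, calibrated so that staircase
placement holds non-TIMO accuracy near the 75–85 % range that
entropy-optimal placement targets. Every sampled ground-truth parameter
is returned in a `truth` table alongside the trials, which is what makes
full-pipeline recovery tests possible.

## 5. Grid maximum likelihood

Fits use fixed parameter grids (`mle_grid(n)`; the canonical analysis
uses $n = 201$ points per dimension: $\mu$ linear on $[-0.2, 0.2]$,
$\lambda$ log-spaced on $[10^{-4}, 0.3]$, $\sigma$ log-spaced on
$[0.002, 0.6]$). The *main* model shares $\mu$ and $\lambda$ across load
conditions within a feature and lets $\sigma$ differ by load
($\sigma_\text{noswitch}, \sigma_\text{switch}$); the *full* model fits
$(\mu, \sigma, \lambda)$ per condition.

Because trials partition by load and the likelihood factorizes, for
fixed $(\mu, \lambda)$ the best $\sigma$ per load can be found
independently — the 4-D search is exactly separable into per-load 1-D
searches inside a 2-D $(\mu, \lambda)$ sweep. The C++ kernel
additionally exploits that $\Phi$ is monotone in $s$: within a
$(\mu, \sigma)$ cell the stimulus bins whose $\Phi$ value saturates to
exactly 0 or 1 contribute closed-form terms via prefix-sum counts, which
collapses most of the inner loop at large grids. Ties in the likelihood
resolve to the lowest grid index in $(\mu, \lambda, \sigma)$ order.
Probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ before taking
logs. Note the prefix-sum grouping changes floating-point summation
order relative to a naive loop, so oracle comparisons should be made on
log-likelihoods with tolerance rather than on grid indices.

Fits are S3 objects with `coef()`, `logLik()` (4 or 6 df), `predict()`
and `plot()` methods; `compare_models()` gives the likelihood-ratio
test and AIC/BIC for the nested pair on identical trial sets.

## 6. Reaction-time models

The ex-Gaussian density (Gaussian $\mathcal N(\mu, \sigma^2)$ plus an
independent exponential with mean $\tau$) is evaluated on the log scale
for numerical stability. `fit_exgauss()` maximizes the likelihood with
bounded L-BFGS-B from six starts: the moment-based start
($\mu = m - 0.8 s$, $\tau = 0.8 s$, $\sigma = 0.6 s$), two
deterministic alternatives, and three jittered restarts from a fixed
seed; the RNG state is saved and restored so fitting never perturbs the
caller's random stream. `fit_rt_family()` adds closed-form log-normal
and `MASS::fitdistr()` gamma alternatives. Cells with fewer than 10
reaction times keep their nonparametric summaries (median, IQR) but
report `NA` parameters rather than an unstable fit.

## 7. Metrics and statistics

`build_metric_table()` produces one row per participant: TIMO rates
overall and by subtype, per-condition $\sigma$, RT medians and $\tau$,
and their logs. A participant with zero TIMO presses in $n$ trials gets
the offset rate $0.5 / n$ before the log, the standard continuity
correction for log-transformed zero counts.

Group statistics avoid heavy dependencies by construction:

- `mixed_anova()` handles balanced two-group designs with 2-level
  within factors via per-participant $\pm 1$ contrast scores, which for
  this design class is algebraically identical to the classical
  mixed-model ANOVA (the tests verify agreement with
  `aov(... Error(participant/(load*feature)))` to $10^{-6}$), and
  reports partial eta squared.
- `posthoc_tests()` runs the 12-comparison (three-way) or 4-comparison
  (two-way) plan: rank-sum tests between groups, signed-rank tests
  within, each at the Sidak-corrected level.
- `spearman_matrix()` computes pairwise-complete Spearman correlations
  with $t$-approximation p values.
- `meff_sidak()` applies the Nyholt correction: with $M$ measures and
  eigenvalues $\lambda_i$ of their correlation matrix,
  $$M_\mathrm{eff} = 1 + (M - 1)\left(1 -
    \frac{\operatorname{Var}(\lambda)}{M}\right),$$
  with $\operatorname{Var}$ the sample variance (denominator $M - 1$),
  and the per-test level $\alpha_\mathrm{Sid} = 1 -
  (1-\alpha)^{1/M_\mathrm{eff}}$. For the built-in 7×7 reference matrix
  (`reference_correlations()`) this gives $M_\mathrm{eff} = 5.73$ and
  $\alpha_\mathrm{Sid} = 0.0089$.
- `bootstrap_median_ci()` gives seeded percentile intervals.

## 8. Classification

`fit_logistic()` is plain maximum-likelihood logistic regression with
explicit detection of complete separation. `stratified_cv()` repeats
stratified k-fold cross-validation over many random fold assignments
(with 20 cases, 20 controls and $k = 10$, every fold holds exactly two
of each); accuracy uses a $\geq$ threshold rule, ties predicting the
positive class. `roc_curve()` sweeps 201 thresholds with the same rule
(exclusive at threshold 1) and integrates by trapezoid, which for
continuous scores equals the Mann–Whitney statistic.
`classification_report()` runs the four regressor sets: $\log\sigma$
alone, $\log$ TIMO alone, both, and all metrics.

## 9. Problem sizes and costs

On a single CPU core: one 800-trial simulated session costs about 7 s
(dominated by the entropy sweep over 31,875 grid cells × 101 candidates
per trial); a main-model fit at the canonical $201^3$ grid about 11 s
(0.3 s at $61^3$); an ex-Gaussian fit milliseconds. The full default
pipeline is minutes for a 20 + 20 cohort.

## 10. Limitations

- The ANOVA implementation covers exactly the balanced, equal-group,
  2-level-within designs used here; it refuses anything else rather
  than approximating.
- Grid ML inherits grid resolution: estimates are grid points, and
  credible/confidence statements should respect the grid spacing.
- The orientation unit conversion is exposed as an explicit choice
  (`"deg_per_rad"` vs `"linear60"`) because the upstream description
  underdetermines it; downstream analyses operate on the abstract $w$
  scale and are unaffected.
- Synthetic observers are stationary: no learning, fatigue or sequential
  dependencies beyond the staircase itself.

```{r session}
sessionInfo()
```
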