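---
title: "Intra-cage correlation: models, estimators, and trial design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intra-cage correlation: models, estimators, and trial design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagecor)
```

## Why cage-mates are not independent

Murine aging studies deliver interventions — restricted diets, compounds in
food or water — to whole housing units. The cage is therefore the randomized
unit, and the outcomes of cage-mates share whatever the cage shares:
micro-environment, social stress, barbering, competition for food. The
standard toolbox (two-sample tests, ordinary regression, Cox models on
individual animals) assumes independence. `cagecor` quantifies the departure
from independence as an intra-class correlation (ICC) at the cage level,
tests it, and propagates it into design calculations.

Two features of this setting drive the package's choices. First, typical
colonies have *many small cages* (hundreds to thousands of cages of 3–8
animals), so asymptotics in the number of cages are appropriate, and even
small ICCs shift type-I error noticeably. Second, the ICC can plausibly be
*negative* — animals competing for a shared resource become anti-correlated
— which breaks the usual variance-components intuition and, as shown below,
the usual variance-components estimator.

## The models

**One level (lifespan).** For animal $i$ in cage $j$,
$y_{ij} = x_{ij}'\beta + b_j + e_{ij}$ with $b_j \sim N(0, \sigma_b^2)$,
$e_{ij} \sim N(0, \sigma_e^2)$, and
$\mathrm{ICC} = \sigma_b^2 / (\sigma_b^2 + \sigma_e^2)$.

**Two levels (longitudinal phenotypes).** Repeated measurements add an
animal intercept: $y_{tij} = x_{tij}'\beta + c_j + a_{ij} + e_{tij}$. The
cage-attributable share is
$\sigma_c^2 / (\sigma_c^2 + \sigma_a^2 + \sigma_e^2)$ (the
proportion-of-variance ICC, bounded below by 0).

**Marginal (GEE) view.** Instead of conditioning on random effects, the
exchangeable working-correlation GEE models
$\mathrm{corr}(y_{ij}, y_{i'j}) = \alpha$ directly. $\alpha$ is a genuine
correlation, so it may be negative down to the positive-semidefiniteness
bound $-1/(k_{\max}-1)$ for the largest cage size $k_{\max}$.

## The estimators and their numerical choices

### ANOVA (moment) estimator

After optionally regressing covariates out by OLS, the one-way mean squares
over cages give $(MSB - MSW) / (MSB + (k_0 - 1) MSW)$ with
$k_0 = (N - \sum_j k_j^2/N)/(m-1)$ for $m$ cages of sizes $k_j$. It is
unbiased to first order, can be negative, and is the fast statistic used in
permutation loops.

### Random-intercept REML

The restricted likelihood is maximized over the variance ratio
$\lambda = \sigma_b^2/\sigma_e^2$, with $\beta$ and $\sigma_e^2$ profiled
out in closed form. Because cage blocks are exchangeable,
$W_j^{-1} = I - \tfrac{\lambda}{1+\lambda k_j} J$ and
$\log|W_j| = \log(1 + \lambda k_j)$, so one likelihood evaluation costs
$O(N p^2)$ — no dense matrix is ever formed. The scalar search is Brent's
method on $\log\lambda \in [\log 10^{-8}, \log 10^{3}]$ (bracket expanded
up to three times if the optimum sits at the upper edge) with x-tolerance
$10^{-6}$; the profiled likelihood is flat at its optimum, so the attained
log-likelihood is accurate to machine-level precision, and the test suite
verifies agreement with a dense brute-force REML evaluation to $10^{-6}$
and with an independent implementation (lme4). The boundary
$\sigma_b^2 = 0$ is decided by comparing the interior optimum with the
profiled likelihood at $\lambda = 0$ and is flagged on the fit object.

The zero bound is not a technicality: on anti-correlated data REML *always*
returns $\hat\sigma_b^2 = 0$, i.e. the mixed model silently reverts to an
independence fit. This truncation also biases the estimator upward near
zero truth: $E[\max(0, Z)] > 0$ even when the truth is 0. The package
therefore treats the LMM ICC as a one-sided instrument and recommends
pairing it with the GEE estimate; the summary method prints a note whenever
the boundary fires.

### Exchangeable GEE

Coefficients are updated by GLS under the current working correlation
$\alpha$ (the same closed-form block inverses as above, valid for negative
$\alpha$ because $1 + \alpha(k_j - 1) > 0$ above the PSD bound), and
$\alpha$ by the moment update
$\hat\alpha = \sum_j \sum_{i<i'} e_{ij} e_{i'j} / (\phi \sum_j k_j(k_j-1)/2)$
with $\phi = \mathrm{RSS}/(N-p)$ recomputed each iteration. During
iteration $\hat\alpha$ is clamped to
$[-1/(k_{\max}-1) + 10^{-6},\, 1 - 10^{-6}]$; the reported value is the
unclamped fixed point when interior. On balanced data with no covariates
the fixed point *equals* the brute-force pairwise moment correlation, which
the tests assert to $10^{-6}$. Coefficient variances are always the robust
(sandwich) cluster estimator. Iteration stops when both $\alpha$ and
$\beta$ move less than $10^{-10}$; failure to converge within 100
iterations raises an error carrying the $\alpha$ trace. Below 20 cages the
fit warns: both the moment update and the sandwich variance assume many
clusters.

Confidence intervals for $\alpha$: a cage-level nonparametric bootstrap
percentile interval (default, B = 1000), robust at the parameter boundary;
or a leave-one-cage-out jackknife normal interval. The jackknife replaces a
delta-method variance of the moment $\hat\alpha$, which has no clean closed
form under unbalanced cages; the jackknife is the standard cluster-level
robust alternative.

### Parametric bootstrap for the LMM ICC

B datasets are simulated from the fitted model (GLS fixed effects + normal
cage intercepts + normal noise on the observed design), refitted by REML,
and the percentile interval of the bootstrap ICCs is returned. With a
boundary fit the lower limit piles up at exactly 0. For balanced
intercept-only refits the REML solution is computed in closed form from the
between/within mean squares (identical to the optimizer output, verified in
tests), which vectorizes the whole bootstrap; other designs go through the
profiled optimizer with a relaxed x-tolerance of $10^{-4}$ — three orders
of magnitude finer than the Monte Carlo noise a 500-replicate percentile
carries.

### Permutation test

Cages, not animals, receive treatments, so the permutation null shuffles
animals across cages *within* treatment strata, preserving every cage's
size, and recomputes the ICC statistic (moment estimator by default; GEE
$\alpha$ optionally). The p-value uses the add-one convention
$(1 + \#\{\hat\rho^* \ge \hat\rho\}) / (1 + n_{perm})$ and is one-sided
against clustering by default — the alternative of scientific interest —
with a two-sided option. The default 1000 permutations is comfortable:
p-values stabilize by a few hundred shuffles at colony scale.

### Joint fixed-effect tests

`joint_fixed_effect_test()` computes a Wald F for a (multi-level) term
under OLS (residual df) or under the REML GLS covariance with a
*between-cage* denominator df, $m - \mathrm{rank}$(cage-level design). The
between-cage df is an approximation chosen over Satterthwaite-type df; it
is slightly conservative in small designs (empirical size ~0.046 at 100
cages in the package's own simulations), which we accept as the safer
direction for a validity-protecting method.

## The synthetic-cohort generator

The generator is the package's ground-truth instrument, and its defaults
mirror the structure of large colony databases: cages of 3–8 animals
(default 4), hundreds of cages, treatment assigned to whole cages, ICC
magnitudes in roughly $-0.05$ to $+0.10$, optional additive batch shifts,
and a right-censoring rate below 4% (censoring times drawn uniformly below
the event time; lifespan analyses drop censored rows).

Non-negative ICC is realized as a shared cage intercept. Negative ICC
cannot be produced that way, so the generator uses the spectral
factorization of the exchangeable covariance: with $z \sim N(0, I_k)$,
$y = \sqrt{1-\rho}\,(z - \bar z \mathbf 1) + \sqrt{1 + (k-1)\rho}\,\bar z
\mathbf 1$ has exactly unit variances and pairwise correlation $\rho$, for
any $\rho \ge -1/(k-1)$. At the bound with $k = 2$, cage pairs sum to a
constant — a property the tests exploit.

The `gaussian-copula-weibull` family transforms exchangeable latent normal
scores through the probability-integral transform onto a Weibull marginal
with the requested mean and SD (shape solved from the coefficient of
variation by Brent's method). The stated ICC then lives on the *latent*
scale; the induced outcome-scale correlation is attenuated, which the
cohort's attributes record. Calibration and acceptance checks use the
gaussian family, where truth is on the outcome scale.

For longitudinal traits, `residual_sd` is the *total* random SD; cage,
animal, and noise components receive variance shares `icc_cage`,
`icc_animal`, and the remainder. A linear age trend (default 0.1 trait
units per age unit, the shape of a slowly drifting aging biomarker) and
per-diet shifts form the fixed part.

What the generator does *not* emulate: frailty dynamics, non-exchangeable
within-cage structure (e.g. dominance hierarchies), informative censoring,
cage changes mid-study, or heavy-tailed measurement error. Passing tests
demonstrate correct behavior under exchangeable correlation with the
stated marginals — not robustness to those departures.

One global integer seed expands into per-operation substreams through a
counter-based integer hash (`substream_seed`), so pipeline stages can be
added, removed, or reordered without perturbing each other's draws, and
replicate $r$ of a simulation depends only on (seed, $r$).

## Batch adjustment

Colony lifespan databases arrive with batch structure (generation, cohort,
group). `remove_batch_effects()` fits the outcome on sum-to-zero-coded
batch plus user covariates with a cage random intercept, on rows with *far
outliers* removed, then subtracts each row's batch coefficient from the raw
outcome; rows with non-positive adjusted lifespans are dropped and counted.
Two underdetermined choices are fixed as package policy: "far outlier"
means beyond median ± 3 IQR (trimming only the fitting subset, never the
adjusted rows), and sum-to-zero coding keeps the adjusted grand mean at the
raw grand mean. Strain effects in multi-strain inbred designs can be
removed in the same stage (pass them as `fixed_terms`) to keep a strict
two-level hierarchy for the GEE, which handles one clustering level at a
time. Aliasing of batch with a design factor is a hard error naming the
confounded columns. The adjustment subtracts a per-batch constant, so
within-batch rank order is preserved, and a second application moves the
outcome by less than $10^{-6}$ of its SD.

## Trial simulation and sample size

`run_power_grid()` simulates two-arm cage-randomized trials over ICC ×
size grids and analyzes each replicate with methods that do (LMM, GEE) or
do not (LM, log-rank) account for clustering. Empirical rejection rates
carry the Monte Carlo SE $\sqrt{r(1-r)/n_{reps}}$. The log-rank test
stands in for proportional-hazards fits of censored data (they share the
score test in the two-group case); frailty models are out of scope. A
partial last cage is allowed when the arm size is not divisible by the
cage size.

The qualitative results these simulations reproduce: under a null
treatment effect, the independence tests are anti-conservative for
positive ICC (null p-values skewed toward 0) and conservative for negative
ICC (skewed toward 1), while LMM and GEE hold near-nominal size — except
that LMM under *negative* ICC truncates and inherits the conservatism of
the independence fit, the one regime where only GEE remains calibrated.

Sample sizes use the normal-approximation two-sample formula
$n = 2 (z_{1-\alpha/2} + z_{power})^2 \sigma^2 / \Delta^2$ inflated by the
design effect $1 + (k-1)\,\mathrm{ICC}$, with the ceiling applied once,
after inflation. Normal (z) quantiles are the default because they
reproduce the canonical worked example (mean 912 days, SD 143, 10% effect,
power 0.8, cages of 4 → 39/40/45/51 mice per group at ICC = 0/0.01/0.05/0.1)
exactly under ceiling rounding; a t-quantile variant and unequal allocation
are available as options. Strain- and sex-specific means and SDs for grid
tables are user inputs — the package ships only the worked example's values.

## Monte Carlo problem sizes used by the test suite

All empirical claims in the package's documentation are computed by the
test suite at these sizes, chosen as the package's own accuracy/runtime
trade-off:

* Estimator calibration: 200 replicates × 1000 cages of 4 per ICC truth in
  $\{0, 0.01, 0.05, 0.1, -0.1\}$; agreement asserted within 3 Monte Carlo
  SE for the unbiased routes (ANOVA, GEE) at every truth and for the LMM at
  the interior truths 0.05 and 0.1 — near zero the LMM's truncation bias
  (~0.006 at this scale, several times the 3-SE band) is itself the
  asserted behavior, not a recovery failure.
* Type-I-error distortion: 50 cages of 4 per arm; 5000 replicates per size
  scenario (a design-stage power analysis showed the LM-inflation check at
  ICC = +0.05 — true size ≈ 0.067 vs a ≈ 0.065 cutoff — is a coin flip at
  2000 replicates; 5000 narrows every band and makes all checks
  simultaneously well-powered), 2000 replicates for the two p-value-skew
  scenarios, whose effects are large.
* Permutation-null uniformity: 200 replicates × 500 permutations, 100
  cages of 4.
* Bootstrap CI coverage: 200 outer replicates × B = 500 at 1000 cages of 4.
* Two-level recovery: one cohort of 500 cages × 8 animals × 6 ages with a
  cage share of 0.0674 (a realistic frailty-domain magnitude), recovered
  within ±0.02.

## Known limitations

* Exactly exchangeable within-cage correlation; no serial correlation
  across ages beyond the animal intercept.
* The GEE route handles a single clustering level; repeated measures go
  through the two-level LMM only.
* Between-cage denominator df for mixed-model Wald tests (no
  Satterthwaite); slightly conservative in small designs.
* No shared-frailty survival models; censored-data trials are analyzed by
  the cluster-naive log-rank test, so censored-data size/power statements
  inherit its independence assumption.
* Sample-size formulas are normal-approximation, census-observed (no
  censoring correction).
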