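---
title: "Methods: SBM efficiency, global Malmquist productivity, and spatial panel models for provincial health-resource panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SBM efficiency, global Malmquist productivity, and spatial panel models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thcdea)
```

This vignette is the package's own account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
establish about real data.

## The analysis pipeline

The package targets a four-stage analysis of a balanced province-by-year
panel of township health centre (THC) resources: (1) score each
province-year's allocative efficiency with a super-efficiency slacks-based
DEA model; (2) decompose productivity change over time with a
global-frontier Malmquist index; (3) test and localise spatial clustering
of the scores with Moran statistics on a rook contiguity matrix; (4)
explain the scores with a spatial Durbin panel regression, selected by a
battery of specification tests, and translate its coefficients into
direct and spillover effects. `run_pipeline()` chains the stages and
writes one CSV artifact per published-table analog plus a machine-readable
decision report.

## Slacks-based efficiency and super-efficiency

The non-oriented SBM score of unit 0 against reference technology
$(X, Y)$ under variable returns to scale (VRS) is

$$\rho \;=\; \min_{\lambda, s^-, s^+}
\frac{1 - \tfrac1m \sum_i s^-_i / x_{i0}}
     {1 + \tfrac1s \sum_k s^+_k / y_{k0}}
\quad \text{s.t.} \quad
x_0 = X\lambda + s^-,\;
y_0 = Y\lambda - s^+,\;
\textstyle\sum_j \lambda_j = 1,\; \lambda, s^\pm \ge 0 .$$

The measure penalises *all* input and output slacks simultaneously
(non-radial, non-oriented), lies in $(0, 1]$, and equals 1 exactly when no
convex combination of the reference units weakly dominates the evaluated
point. Because every term divides by the unit's own $x_{i0}$ or $y_{k0}$,
the data must be strictly positive; the constructors reject zeros rather
than imputing them. Efficient units are re-scored by the super-efficiency
variant, which removes the unit from its reference set and asks how far
its inputs could grow (and outputs shrink) before a reference combination
matches it; scores are then $\ge 1$ and rank the efficient units.
`two_stage_score()` glues the two: units scoring below $1 - \text{tol}$
(tol $= 10^{-6}$, the scale of LP solver tolerances) keep their SBM score.

Both programs are linearised by the Charnes–Cooper device (all variables
scaled by $t$, the fractional objective's denominator pinned to 1) and
solved by a dense two-phase primal simplex with Bland's rule
(`R/lp.R`). Two numerical choices matter:

* **Row normalisation.** Every input/output row is divided by the
  evaluated unit's own level before the tableau is formed. The score is
  invariant to this (units-invariance is an SBM property, and is tested),
  but raw health-resource data span five orders of magnitude and an
  unnormalised tableau mixes coefficients of order $10^{-8}$ and $10^7$,
  which defeats fixed pivot tolerances.
* **Anti-cycling.** The optimum of an efficient unit's program is heavily
  degenerate; Bland's rule guarantees termination.

VRS super-efficiency programs can be infeasible in oriented models; in
this non-oriented form the output targets may fall to zero, so with
strictly positive data a feasible point always exists. The infeasibility
flag is still propagated, and `score_panel()` records such cells (score
kept at the SBM value of 1) so the panel table stays complete.

The implementation is validated against an LP-free oracle: the SBM
objective has a closed form for each fixed $\lambda$, so exhaustive
enumeration over a $1/200$-resolution grid on the $\lambda$-simplex
(locally refined around the incumbent) brackets the optimum. On random
small instances ($n \le 4$, $m = s \le 2$) the LP and the oracle agree to
$10^{-3}$.

## Global Malmquist productivity

Productivity change between adjacent years is measured against a single
pooled reference set $S^g = S^1 \cup \dots \cup S^T$:

$$MI_{t,t+1} = \frac{E^g(x^{t+1}, y^{t+1})}{E^g(x^t, y^t)},
\qquad
EC_{t,t+1} = \frac{E^{t+1}(x^{t+1}, y^{t+1})}{E^{t}(x^{t}, y^{t})},
\qquad
TC = MI / EC .$$

$E^g$ is the standard (non-super) SBM score against the pooled set and
$E^t$ against the contemporaneous set. Using the plain SBM inside the
index is deliberate: every evaluated point belongs to the pooled set, so
$E^g$ is always feasible, avoiding the cross-period infeasibilities that
super-efficiency scores would introduce. The single fixed reference set
makes the index circular —
$MI_{t,t+2} = MI_{t,t+1} \cdot MI_{t+1,t+2}$ holds to $10^{-9}$ in the
tests — and $MI = EC \times TC$ is an algebraic identity, exact by
construction.

Averaging conventions: per-unit averages over the $T-1$ year pairs use
the geometric mean (the only mean that preserves the multiplicative
identity, and the standard choice for index numbers); cross-unit
"national" means are arithmetic, matching how the published summary rows
aggregate. The packaged per-province reference table is itself
inconsistent with the multiplicative identity on 13 of its 29 rows (up to
0.028, far beyond 3-decimal rounding), a pattern consistent with
arithmetic averaging of its yearly components at the source; the package
does not inherit that choice.

## Moran autocorrelation and clusters

The global statistic on values $x$ with weights $w_{ij}$ is

$$I = \frac{\sum_i \sum_j w_{ij} (x_i - \bar x)(x_j - \bar x)}
           {S^2 \sum_i \sum_j w_{ij}},
\qquad S^2 = \tfrac1n \sum_i (x_i - \bar x)^2 ,$$

with expectation $-1/(n-1)$ under the null. Inference defaults to the
randomization (permutation-moment) variance with a two-sided normal
p-value; the normality variance and a Monte-Carlo permutation p-value are
options. The statistic is location-scale invariant, which the suite
checks, and the analytic randomization variance is cross-checked against
$10^4$ random permutations.

Weights are first-order rook contiguity, row-standardized by default:
row-standardization is the common econometric-software default and is
what the admissible interval of the spatial models assumes; the raw
binary mode is exposed for sensitivity. The packaged 29-province edge
list joins Hainan (an island) to Guangdong so no unit is isolated. The
Moran scatter classifies each unit by the signs of its deviation
$d_i = x_i - \bar x$ and the row-standardized lag
$l_i = \sum_j \tilde w_{ij} d_j$ into HH/LH/LL/HL; exact zeros (never
observed in 3-decimal data) are assigned to the positive side. The
agglomeration share is $(|HH| + |LL|)/n$.

## Spatial panel models

The maintained model is the spatial Durbin specification with two-way
fixed effects,

$$Y_t = \rho W Y_t + X_t \beta + W X_t \theta + \mu + \gamma_t \iota
  + \varepsilon_t ,$$

with SAR ($\theta = 0$) and SEM (spatially autocorrelated error) as
restrictions. Estimation is quasi-ML: effects are absorbed by the within
transformation, the likelihood is concentrated in the spatial parameter,
and $T \ln|I_n - \rho W|$ is evaluated from the eigenvalues of $W$. The
search is a bounded scalar maximisation over
$(1/\omega_{\min} + 10^{-6},\, 1 - 10^{-6})$ at tolerance $10^{-8}$, and
the suite verifies the returned optimum against an independent
profile-likelihood grid. The covariance matrix is the analytic
information matrix; $R^2$ is the squared correlation of fitted and
observed transformed responses (the literature has no single convention
here, so the definition is stated rather than compared).

Three implementation details are worth recording:

* **Lag-then-demean.** The within projector does not commute with a
  row-standardized $W$ (its column sums are not 1), so $Wy$ and $WX$ are
  computed on the raw data and then demeaned. Applying $W$ to demeaned
  data mis-states the profile likelihood of the dummy-variable model —
  detectably: it can rank a two-way fit below its own one-way restriction.
* **Transformed likelihood (`lee_yu = TRUE`).** The default likelihood is
  the dummy-model profile, which carries the usual incidental-parameter
  bias in $\sigma^2$. The option evaluates the exact likelihood of the
  orthogonally transformed model instead: effective dimensions
  $(n-1)(T-1)$, and — because cross-unit demeaning removes the unit
  eigenvector of the row-stochastic $W$ — one $\ln(1-\rho)$ term leaves
  the log-determinant. It is off by default so the default estimator
  matches the common software behaviour.
* **Bartlett-adjusted LR.** Thirteen Durbin restrictions on a
  $29 \times 10$ panel put the chi-square-referenced LR visibly above its
  nominal size (its null mean matches the classical second-order
  regression prediction $N[q/(m-2) - q(q+2)/(2(m-2)(m-4))]$ almost
  exactly). `lr_test()` therefore rescales the statistic by $q/E[LR]$
  using that analytic formula — no fitted constants — restoring
  near-nominal size without touching first-order asymptotics.

The LM battery (lag, error, and robust variants) is computed from pooled
OLS residuals on the transformed data. Demeaning across units gives the
error quadratic form $e'(I_T \otimes W)e$ a nonzero null mean, so the
statistics are centred and scaled by the exact post-projection moments
$\mathrm{tr}(QAQ)$ and $\mathrm{tr}((QAQ)^2 + QAQ(QAQ)')$, which factor
into $n \times n$ computations for balanced panels.

The Hausman comparison keeps time effects fixed and treats individual
effects as random via two-step Swamy–Arora quasi-demeaning whose
auxiliary regressions include the spatial terms. A two-step RE estimator
is not fully efficient, so $V_{FE} - V_{RE}$ can be indefinite; the
quadratic form is then taken on its positive eigenspace with df equal to
its rank, and the fallback is noted in the result object. (This also
offers a mechanical reading of published Hausman tests whose df falls
short of the regressor count.)

Effects are decomposed per regressor through
$S_k(W) = (I - \rho W)^{-1} (\beta_k I + \theta_k W)$: the direct effect
is the average diagonal, the total the average row sum, the indirect
their difference — an identity the code preserves exactly. Inference
simulates parameter vectors from the fit's covariance (defaults: 1000
draws, seed 20240816), discarding draws outside the admissible
$\rho$-interval.

Model selection (`decision_report()`) follows the standard flowchart: LM
and robust-LM admit spatial dependence (none significant → non-spatial
panel); LR and Wald degradation tests on the Durbin model decide
SDM/SAR/SEM; Hausman decides fixed versus random effects; LR tests on the
effect structure decide the fixed-effect layout. All decisions use a
single configurable threshold, 5% by default (published work mixes
1/5/10% stars; one explicit default keeps the report reproducible).

## Synthetic study designs

The generators define the conditions under which the package's
statistical guarantees are demonstrated.

* `generate_dea_panel()` — 29 units × 10 years × 5 inputs × 4 outputs by
  default. A latent scale $z_j$ (log-normal, sd 0.5) fixes each unit's
  size; frontier inputs are proportional to $z_j$ with the published
  input-mix magnitudes (facilities, beds, physicians, nurses,
  pharmacists), frontier outputs proportional to $z_j^{\gamma}$
  ($\gamma = 0.8$, concave ⇒ VRS) with the published output mix, shifted
  by $e^{-0.03(t-1)}$ per period (a slowly regressing frontier, matching
  the direction of the published productivity trend). Observed inputs are
  inflated by $e^u$, $u \sim |N(0, 0.3)|$, so true inefficiency is known
  per cell. All units share the mix vectors; this guarantees that
  zero-inefficiency panels lie exactly on the frontier (a tested
  invariant) at the cost of mix heterogeneity.
* `generate_covariates()` — 13 independent series targeting the published
  means and dispersions: log-normal for positive scale variables, normal
  for percentages and indices, percentages clipped to $[0, 100]$. The
  published urban-population percentage prints an impossible dispersion
  (sd 292.9, max 5042 for a percentage); the generator substitutes a
  plausible spread (sd 15) under the same clip. Each series carries a
  persistent unit component (70% of variance): real provincial series are
  strongly persistent, and without between-unit information a
  random-effects estimator is vacuous. No cross-covariate correlation is
  imposed (none is published).
* `generate_sdm_panel()` — the spatial outcome process
  $y_t = (I - \rho W)^{-1}(X_t\beta + WX_t\theta + \mu + \gamma_t +
  \varepsilon_t)$ with defaults set to the published study conditions:
  the 29-province rook matrix, $T = 10$, $\rho = -0.1555$, the 13
  published response and spatial-lag coefficients, and
  $\sigma^2 = 0.0058$; unit and period effects are $N(0, 0.1^2)$.

Under these defaults the test suite demonstrates: mean $\hat\rho$ within
0.03 of truth and 90–99% coverage of 95% Wald intervals for $\beta$ over
200 replications; LM and (Bartlett-adjusted, transformed-likelihood) LR
sizes within $[0.03, 0.07]$ at nominal 5% over 500 replications; and
Spearman correlation $\le -0.8$ between true inefficiency and SBM scores.

What passing these tests does *not* show: the generators draw covariates
independently of the unit effects (so the random-effects null is true by
construction), impose no measurement error, no missingness, no
cross-covariate correlation, and a single common input/output mix. Real
yearbook panels violate all of these; the guarantees transfer only to the
extent that the stated structure approximates them.

## Problem sizes and budgets

The test suite runs the full 100-instance oracle sweep, the 200-replication
recovery study and the two 500-replication size studies at the sizes named
above; the whole suite completes in well under a minute of CPU plus about
half a minute for the LP-heavy DEA property tests. `scripts/acceptance.R`
is deterministic and instantaneous: it recomputes the Moran statistics and
the agglomeration share from the packaged printed tables.

## Known limitations

* No undesirable-output (bad-output) SBM extension, no radial CCR/BCC
  pipeline scores, no biennial or Malmquist–Luenberger variants.
* The random-effects spatial estimator is two-step quasi-demeaning, not
  full ML in the variance components; it exists to power the Hausman
  battery, not as a production RE estimator.
* No GMM/IV or dynamic spatial panels; no general nesting model.
* Weight matrices are binary contiguity (row-standardized or raw) only —
  no distance or k-nearest-neighbour weights.
* The published per-province Malmquist table cannot be reproduced from
  deposited data (none exists); it ships only as a fixture, and one of its
  internal-consistency checks fails on the printed numbers themselves, as
  discussed above.
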