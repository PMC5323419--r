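---
title: "Multilevel models for intensive longitudinal data with heterogeneous AR(1) errors"
author: "mlmct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel models for intensive longitudinal data with heterogeneous AR(1) errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ecological momentary assessment (EMA) and other intensive longitudinal
designs produce many repeated observations per person (tens to hundreds of
occasions). The workhorse analysis is a two-level linear mixed model,

$$ y_{ti} = \gamma_{00} + \gamma_{10} z_{ti} + \gamma_{01} c_i
  + \gamma_{11} c_i z_{ti} + u_{0i} + u_{1i} z_{ti} + e_{ti}, $$

with occasions $t$ nested in persons $i$, a time-varying covariate
$z_{ti}$, a time-invariant covariate $c_i$, random intercept and slope
$(u_{0i}, u_{1i}) \sim N(0, G)$, and level-1 residuals $e_{ti}$. Standard
software fits this model under the assumption that the within-person
residual covariance $R_i$ is *identical across persons* — usually
independent homoscedastic ("ID", $R_i = \sigma^2 I$) or a single shared
AR(1) structure. Empirically, however, people differ markedly in how
strongly their momentary states carry over from one occasion to the next:
each person has their own autocorrelation $\rho_i$.

This package implements and evaluates a two-step estimator for that
situation, the multilevel model with Cholesky transformation (MLM-CT):

1. **Per-person whitening.** For each person, fit the subject-level
   regression $y_i = Z_i \beta_i + e_i$ (intercept and $z$) with AR($p$)
   errors by exact Gaussian maximum likelihood, and form the whitening
   operator $A_i = L_i^{-1}$, the inverse Cholesky factor of the fitted
   residual correlation structure, so that $A_i R_i A_i' = \sigma^2_{wi} I$.
   Transform $y_i^\ast = A_i y_i$, $X_i^\ast = A_i X_i$,
   $Z_i^\ast = A_i Z_i$ — *all* columns, including the ones column.
2. **Standard MLM on transformed data.** Fit the two-level model to
   $(y^\ast, X^\ast, Z^\ast)$ by REML with ID residuals, taking the
   transformed design columns verbatim (injecting a fresh intercept column
   would undo the transformation).

For a stationary AR(1) with parameter $\rho$, the operator has first row
$(\sqrt{1-\rho^2}, 0, \ldots)$ and subsequent rows $(-\rho, 1)$ on the two
relevant bands; the autocovariance is
$\gamma(h) = \sigma^2_w \rho^h / (1-\rho^2)$ and the precision matrix is
tridiagonal. These closed forms are implemented in `ar1_autocovariance()`,
`ar1_covariance()`, `ar1_precision()` and `ar1_whitening()`; general
AR($p$) operators (`arp_whitening()`) use the Yule–Walker stationary
covariance for the leading $p \times p$ block and the AR filter below it.
Operators are stored banded, so applying one costs $O(Lp)$.

## Estimators compared

`mlm_reml()` fits the two-level model by REML with either residual
structure:

* **MLM-ID**: $R_i = \sigma^2 I$ (what most applied analyses assume);
* **MLM-AR**: $R_i[t,s] = \sigma^2 \rho^{|t-s|}$ with one shared $\rho$;
* **MLM-CT**: `mlm_ct_fit()`, the two-step estimator above.

The REML criterion is evaluated per subject through the Woodbury identity:
with $\Sigma_i = Z_i G Z_i' + R_i$ and tridiagonal $R_i^{-1}$, every
subject contributes only through lag cross-products of $[X_i, Z_i, y_i]$,
so one evaluation costs $O(N q^3)$ with $q = 7$, independent of $L$ after a
single $O(NL)$ pass. The full $NL \times NL$ covariance is never formed and
fitting cost is linear in $N$. The criterion itself is exposed as
`reml_criterion()` so it can be verified against a direct dense evaluation.

Numerical choices:

* $G$ is parameterized by its log-Cholesky factor (positive definite by
  construction, boundary reachable in the limit), $\sigma^2$ by its log,
  and $\rho$ as $0.98\tanh\theta$, keeping the whitening operator defined.
* Optimization is BFGS with numerical gradients, relative tolerance
  $10^{-12}$, with up to three jittered restarts; starting values are
  method-of-moments (pooled OLS residual variance split 50/50 between the
  intercept variance and the residual variance; $\rho$ started at the
  pooled lag-1 residual autocorrelation).
* Model-based standard errors are
  $\sqrt{\mathrm{diag}\,[\sum_i X_i'\hat\Sigma_i^{-1}X_i]^{-1}}$. No
  degrees-of-freedom machinery (Satterthwaite, Kenward–Roger) is provided:
  the package evaluates bias of estimates and of these SEs, not coverage.

The first-step AR fit (`fit_ar_regression()`) maximizes the *exact*
likelihood — the first $p$ observations enter through the stationary
distribution — with $\beta$ and $\sigma^2_w$ profiled out in closed form
through the whitening operator, leaving a 1-dimensional search over $\rho$
for $p = 1$ (partial autocorrelations, mapped through Levinson–Durbin, for
$p > 1$). Exact rather than conditional likelihood makes short-series
behaviour well defined and matches how the whitening operator treats the
initial observations. $|\hat\rho_i|$ is capped at $0.98$; cap hits are
flagged per subject. The analysis order defaults to $p = 1$; AIC/BIC
selection up to a maximum order is available (`select_ar_order()`) for real
data, where the order is not known a priori.

Two design points were genuinely open and decided as follows. First, the
two-step procedure can be described as OLS-then-transform, but the
estimator implemented (and evaluated in the simulation) uses joint exact ML
of $(\beta_i, \rho_i, \sigma^2_{wi})$ per subject; the OLS-based two-stage
variant remains available as `method = "two_stage"` for diagnostics.
Second, all columns of $X_i$ — including the level-2 columns $c_i$ and
$c_i z_{ti}$, which are constant multiples of the within-person columns —
are premultiplied by $A_i$.

## What the simulation emulates

`generate_dataset()` draws balanced $N \times L$ panels from the model
above with: $z_{ti}, c_i \sim N(0,1)$; all fixed effects equal to 1;
$\sigma^2_{u0} = \sigma^2_{u1} = 0.5$, $\sigma_{u0u1} = 0.15$ (random-effect
correlation 0.3); unit innovation variance; and crucially *heterogeneous*
autocorrelations $\rho_i \sim U(\bar\rho - 0.3, \bar\rho + 0.3)$ with
$\bar\rho \in \{0, 0.3, 0.6\}$. The AR(1) errors are initialized from their
stationary distribution $N(0, \sigma^2_w/(1-\rho_i^2))$, so no burn-in is
needed and the error covariance is exactly the stationary one at every
occasion. At $\bar\rho = 0$ half the people have *negative*
autocorrelation; the estimators must handle $\hat\rho < 0$.

The default grid (`default_grid()`) crosses
$N, L \in \{20, 50, 100, 200\}$ with the three $\bar\rho$ values — 48
conditions, 500 replications each: 24,000 datasets and 72,000 fits, every
replicate reproducible in isolation from (base seed, condition,
replicate) through a deterministic seed hash. `run_condition()` fits all
requested estimators to the *same* datasets; `summarize_condition()`
computes relative bias, $\mathrm{mean}[(\hat\theta - \theta)/\theta] \times
100$, over converged fits. For standard errors the true value is known in
the simulation: it is
$\sqrt{\mathrm{diag}\,[\sum_i X_i'\Sigma_i^{-1}X_i]^{-1}}$ evaluated at the
generating parameters with each subject's own $\rho_i$
(`true_fixed_se()`) — the sampling SE of the GLS fixed effects under the
heterogeneous model. Judged against this yardstick, a model that inflates
$\hat\sigma^2_{u0}$ also inflates its reported SEs. (When the generating
covariance is unknown, `se_relative_bias()` falls back to the empirical SD
of the estimates across replicates.) Convergence failures are excluded
from the averages and reported; fits at a variance boundary count as
converged but are flagged.

What this generator does *not* emulate about real EMA data: missing and
unequally spaced occasions (random prompts), non-normal or skewed momentary
states, heterogeneous innovation *variances* (the generator uses
$\sigma^2_w = 1$ for everyone — which is why the pipeline's per-subject
rescaling, `rescale_to_unit_variance()`, defaults to off; turn it on for
real data), person-varying AR *order*, and measurement reactivity. Passing
tests therefore show correctness of the estimators under the stated
stationary-AR(1) conditions, not robustness to those complications.

## Problem sizes used by the test suite

The package's checks run the bias study at the scales where the published
pattern is identifiable: the headline misspecification cells
($N{=}20, L{=}20$ and $N{=}20, L{=}200$ at $\bar\rho = 0.6$; $N{=}200,
L{=}20$ for SE bias) at the full 500 replications, unbiasedness checks at
$N{=}50, L{=}50$ with 100 replications, SE calibration with 1500
replications, and a reduced (R = 50) two-cell grid for the method-ordering
property. The full 48-condition grid reproduces the study's overall
averages and can be run as a long job via the CLI:
`mlmct bias-report --grid default --reps 500 --seed 1 --out results/`.

Tolerances follow Monte Carlo logic: exact linear-algebra identities at
$10^{-8}$–$10^{-10}$; stochastic quantities within the larger of 3 Monte
Carlo standard errors and 15% of the reference value.

## Known limitations

* Equal within-person spacing is assumed; continuous-time (exponential
  decay) covariance for random prompts is out of scope.
* The two steps are not iterated; with very short series ($L \approx 20$)
  the first-step $\hat\rho_i$ are noisy and MLM-CT can be *more* biased for
  the random-intercept variance than the homogeneous-AR model — the method
  earns its keep at $L \gtrsim 50$.
* No ARMA or moving-average error structures; no crossed or >2-level
  random effects; no heteroscedastic-by-covariate residual models.
* `relative_bias()` is undefined for true value 0 by construction.
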