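# mlmct

Two-level mixed models for intensive longitudinal data (EMA diaries,
experience sampling) whose within-person residuals are **individually
heterogeneous AR(1) processes** — each person has their own autocorrelation
$\rho_i$. The package implements the **multilevel model with Cholesky
transformation (MLM-CT)**, the comparison estimators that assume a
homogeneous residual structure, and a reproducible Monte Carlo study of the
bias that misspecification produces.

## The model and the estimator

The data model is

$$ y_{ti} = \gamma_{00} + \gamma_{10} z_{ti} + \gamma_{01} c_i
  + \gamma_{11} c_i z_{ti} + u_{0i} + u_{1i} z_{ti} + e_{ti},
  \qquad (u_{0i}, u_{1i}) \sim N(0, G), $$

with $e_{ti} = \rho_i e_{(t-1)i} + w_{ti}$ and person-specific $\rho_i$.
MLM-CT proceeds in two steps:

1. for each person, estimate a regression with AR($p$) errors by exact
   maximum likelihood and build the whitening operator $A_i = L_i^{-1}$
   (inverse Cholesky factor of the fitted residual correlation), so
   $A_i R_i A_i' = \sigma^2_{wi} I$;
2. fit the intended multilevel model by REML to the transformed variables
   $A_i y_i$, $A_i X_i$, $A_i Z_i$ with independent residuals.

Misspecifying the heterogeneous AR structure as homogeneous-independent
inflates the random-intercept variance estimate dramatically (about +98%
at $\bar\rho = 0.6$ with short series) and the standard errors of the
level-2 fixed effects; MLM-CT removes most of that bias once series are
moderately long ($L \ge 50$).

## Worked example

```r
library(mlmct)

cond  <- simulation_condition(N = 30, L = 50, rho_bar = 0.6, reps = 1, seed = 7)
panel <- generate_dataset(cond)       # columns subject, occasion, y, z, c

mlm_reml(panel, residual = "ID")      # what a naive analysis assumes
mlm_ct_fit(panel)                     # the two-step transformation estimator
```

The ID fit prints (abridged):

```
Two-level REML fit (ID residuals): 30 subjects, 1500 observations
        Estimate Std.Error
gamma00   1.1376    0.1779
...
Random effects:  var_u0 = 0.8809  var_u1 = 0.7038  cov_u0u1 = 0.3061
Residual: sigma2 = 1.628
```

and the CT fit:

```
Two-level REML fit (ID residuals): 30 subjects, 1500 observations
         Estimate Std.Error
x_star_1   1.1380    0.1663
...
Random effects:  var_u0 = 0.6705  var_u1 = 0.6353  cov_u0u1 = 0.2595
Residual: sigma2 = 0.9721
```

The generating values are $\gamma = (1,1,1,1)$ and
$\sigma^2_{u0} = 0.5$: on this single panel the ID fit inflates the
random-intercept variance to 0.88, while whitening brings it down to 0.67
(one replicate; the bias tables below average 500). The CT fit's residual
variance is near 1 because the whitened innovations have unit variance by
construction.

The simulation study scales from one cell to the full published grid:

```r
est <- run_condition(simulation_condition(N = 20, L = 20, rho_bar = 0.6,
                                          reps = 500, seed = 1))
summarize_condition(est)      # relative bias (%) per parameter and method
plan_grid(default_grid())     # 48 conditions, 24000 datasets, 72000 fits
```

A thin CLI wraps the same functions: see `exec/mlmct`
(`simulate`, `transform`, `fit`, `bias-report` subcommands).

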