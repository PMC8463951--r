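---
title: "Methods: spatial modelling of day-of-surgery cancellation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial modelling of day-of-surgery cancellation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialdosc)
```

## The problem

Day-of-surgery cancellation (DoSC) wastes operating-room capacity and
burdens families, and its frequency varies sharply across neighbourhoods.
`spatialdosc` models the *tract-level* cancellation rate: cases are
aggregated to census tracts, the crude rate `k/n` per tract is stabilised
by empirical Bayes shrinkage, and the resulting rate surface is regressed
on tract covariates with a family of spatial autoregressive models. The
package covers the full workflow — preprocessing, spatial weights,
autocorrelation screening, estimation, nested cross-validated evaluation,
permutation importance, and local observed-vs-predicted correlation — and
ships a synthetic-data generator with known ground truth so that every
stage can be validated end to end.

## Model families

With `W` a row-standardised spatial weight matrix, `X` the tract
covariates and `y` the (shrunk) rate vector, `spreg()` fits by maximum
likelihood:

| family      | model                                                |
|-------------|------------------------------------------------------|
| `glm`       | `y = Xb + e`                                          |
| `ridge_glm` | OLS with an L2 penalty on the slopes                  |
| `sar`       | `y = rho W y + Xb + e` (spatial lag)                  |
| `sdm`       | `y = rho W y + Xb + WX theta + e` (spatial Durbin)    |
| `sem`       | `y = Xb + u`, `u = lambda W u + e` (spatial error)    |
| `sdem`      | `sem` plus `WX theta` (Durbin error)                  |
| `sma`       | `y = Xb + (I + lambda W) e` (moving average)          |
| `sac`       | lag and error dependence together (SARAR)             |
| `ridge_sar` | `sar` with the penalised beta step                    |

All families assume Gaussian innovations on the modelling scale and one
common `W` for every spatial process (the lag and error filters of the
SARAR model share it). Estimation concentrates the likelihood: at each
candidate `rho`/`lambda`, `beta` and `sigma^2` have closed forms, and the
Jacobian term `ln|I - rho W|` is evaluated as `sum(ln(1 - rho w_i))` from
the eigenvalues of `W`, computed once per weights object and cached.
Because `W` is a row-standardised version of a symmetric nonnegative
matrix it is similar to a symmetric matrix; its spectrum is real (an
imaginary residue above `1e-8` raises an error) and lies in `[-1, 1]`,
giving the admissible interval `(1/w_min + 1e-6, 1 - 1e-6)` used by the
bounded Brent searches (parameter tolerance `1e-8`). The moving-average
likelihood requires dense solves against `(I + lambda W)` at each
candidate `lambda`; at the lattice sizes used here (up to 400 tracts) that
is a few milliseconds per evaluation.

The SARAR surface is maximised by a nested bounded search — an outer
scalar search over `rho` whose objective maximises `lambda` by an inner
scalar search — backed by a 3x3 multistart grid at
`{-0.5, 0, 0.5}^2` polished with box-constrained quasi-Newton steps; the
best candidate wins. A near-flat profile (log-likelihood range below
`1e-6` across multistarts that disagree on the optimum) triggers a
warning, since SARAR models on small lattices can be weakly identified.

### The L2-penalised variants

The penalised beta step standardises the predictors on the data at hand
(training folds only, inside cross-validation), solves
`(Z'Z + cI) b = Z'y_c` with the intercept unpenalised and recovered from
the means, and reports coefficients on the original scale. For
`ridge_sar` this step simply replaces the OLS step inside the
concentrated likelihood — the log-determinant and variance terms are
unchanged, which is the minimal penalised extension of the lag model. On
spatially filtered designs (`sem`/`sdem`/`sac` with a penalty) the
filtered intercept column is no longer constant, so there the penalty is
applied on the raw scale instead of through standardisation.

### Prediction

Held-out tracts are predicted from the *signal* reduced form using the
full weight structure and the fitted parameters only — e.g.
`(I - rho W)^-1 X b` for lag families — never from observed outcomes.
The alternative (conditional best linear prediction given training
outcomes) would use more information but blurs the train/test boundary;
signal-only prediction keeps the cross-validated comparison honest, and
the test suite verifies that perturbing a held-out tract's outcome cannot
change its prediction.

## Empirical Bayes rate shrinkage

Crude rates from small tracts are noisy. `estimate_beta_prior()` fits a
beta prior by global method of moments: prior mean `m = sum(k)/sum(n)`,
between-tract variance `s2 = sum(n_i (r_i - m)^2)/sum(n)` (case-weighted,
so large tracts dominate), and prior strength `a + b = m(1-m)/s2 - 1`.
The posterior mean `(k_i + a)/(n_i + a + b)` then pulls small tracts
toward `m` while leaving large tracts nearly untouched. When the implied
strength is nonpositive (observed dispersion at or beyond the binomial
limit) or `s2 = 0`, the prior is flagged degenerate and crude rates pass
through unchanged. A Marshall-type *local* (neighbourhood) moment
estimator is the main alternative; the global estimator was chosen
because it is fully determined by the counts, easy to verify by hand, and
standard in small-area disease mapping. Shrunk rates always lie weakly
between the crude rate and `m`, and their variance never exceeds the
crude-rate variance — both are enforced by tests.

Driving-time profiles reuse the same machinery: each 6-minute category
(1–10, with `>60` minutes as category 11; exactly 60 minutes is *not*
"farther than one hour" and stays in category 10) is shrunk as its own
binomial against its own beta prior, and the globally most common
category is dropped as the base (ties to the lower index) to avoid the
induced linear dependence.

## Spatial weights

"Sharing at least one boundary edge" is read literally as rook-style
contiguity: two tracts are neighbours iff their boundaries overlap in a
collinear segment longer than `1e-9` length units, so corner-touching
tracts are not neighbours. Weights are inverse Euclidean distances
between polygon area centroids (boundary-to-boundary distance is the
alternative; centroids were chosen as the conventional reading), then
each row is divided by its sum. Islands keep all-zero rows rather than
being dropped — they receive no spatial signal but remain in every table,
keeping tract sets stable across stages; all estimators accept such rows
(their filters act as the identity there).

## Diagnostics

`global_moran()` computes `I = (n/S0) z'Wz / z'z` and tests it by random
permutation of the values over tracts (999 draws by default, two-sided
around `E[I] = -1/(n-1)`). Permutation inference was preferred to the
closed-form randomisation variance because it is assumption-free and
directly testable; the permutation SD also supplies the `I ± 1.96 sd`
interval used for CI-style plots. Covariates are screened out when they
show no significant clustering (`p >= alpha`) or when their VIF
(`1/(1 - R^2)` against the other covariates) reaches 10.

`gw_pearson()` computes a locally weighted Pearson correlation around
each tract with a bisquare kernel and an adaptive bandwidth equal to the
distance of the `k`-th nearest tract (default `k = 50`) — standard
geographically weighted practice, robust to uneven tract density; the
kernel and `k` are configurable. Significance comes from globally
permuting the predicted vector, with no multiplicity correction (the
flag count and `alpha` are recorded so users can post-correct).

## Cross-validated evaluation

`nested_cv()` follows a nested 10x10 design: the outer folds measure
RMSE (reported in percentage-rate units), the inner folds grid-search the
penalty over integer powers of ten from `1e-6` to `1e6` (ties to the
smallest penalty, preferring parsimony). Fold assignment is plain random
with sizes differing by at most one; spatial blocking is deliberately out
of scope. Training-fold weights are re-row-standardised on the training
subset. The 95% interval is the normal approximation
`mean ± 1.96 sd/sqrt(10)` over outer-fold RMSEs — a pragmatic, clearly
labelled choice, since fold RMSEs are not independent. Families without
hyperparameters skip the inner loop and use the same outer folds.

Permutation importance shuffles one preprocessed modelling column at a
time (20 repeats), re-predicts without refitting, and reports the mean
RMSE increment. The IPA baseline fits a case-level logistic regression (a
deliberately plain stand-in for richer case-level learners), grouped by
tract so that no case of a held-out tract enters training, and averages
predicted probabilities within tracts.

## The synthetic generator

`simulate_tract_data()` emulates a hospital service area as a square
lattice (default 20x20, 400 tracts — a regular lattice exercises
contiguity, IDW and every estimator; irregular polygons add no
statistical content). Covariates are SAR-filtered Gaussian fields
`(I - phi W)^-1 e` with a common `phi = 0.6`, the simplest mechanism
reproducing the spatially clustered covariates seen in real tract data.
Outcomes are either a Gaussian surface from any family's reduced form or
binomial counts: tract volumes are lognormal (`exp(N(log 150, 0.6))`,
floored at one case — real volume distributions are only known through
medians, so the lognormal is an explicit assumption with configurable
parameters), the linear predictor follows the family's reduced form on
the logit scale, and probabilities are clipped to `(1e-6, 1 - 1e-6)`
before the binomial draw to avoid degenerate tracts. The default
intercept is `qlogis(0.05) * (1 - rho)`, so that after the spatial
filter's amplification (`(I - rho W)^-1` multiplies a constant by roughly
`1/(1 - rho)`) the generated rates centre near 5% with a realistic 1–12%
spread, matching the scale of observed cancellation rates. One master
seed expands into independent substreams (covariates, noise, counts), so
enlarging one stage never perturbs another.

What the generator does *not* emulate: irregular tract geometry and area
heterogeneity, drive-time road networks, measurement error in covariates,
and case-level feature structure (IPA fixtures attach pure-noise case
features). Passing tests therefore demonstrate correctness of the
estimators and the pipeline logic under known ground truth, not fidelity
to any particular city's data.

## Validation problem sizes

The shipped tests validate likelihoods against dense multivariate-normal
evaluations on 25–49-tract lattices over 21-point parameter grids (at
`1e-8`), Moran's I against a literal double sum on 50 random graphs (at
`1e-12`), and parameter recovery with 100 simulated data sets per family
at 400 tracts (mean absolute error below 0.1 with full sign coverage —
observed errors are 0.006–0.05). Cross-validated comparisons use 140–196
tract fixtures. These sizes were chosen to keep the full validation run
in the low tens of seconds while leaving Monte-Carlo margins wide.

## Known limitations

- No analytic standard errors or impact decompositions for the spatial
  fits; the package's focus is predictive evaluation.
- The SARAR profile can be weakly identified on small lattices; the flat
  multistart warning should be taken seriously.
- Signal-only prediction ignores information in neighbouring observed
  outcomes at prediction time; it is a lower bound on spatial models'
  out-of-sample accuracy.
- Grand-mean/mode imputation and divide-by-IQR rescaling (without
  median-centering; the IQR-only reading of the preprocessing convention)
  are simple by design and learn only from retained tracts.
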