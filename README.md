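# spatialdosc

Small-area spatial analysis of day-of-surgery cancellation (DoSC) rates.

Scheduled surgeries are cancelled on the day of the procedure far more
often in some neighbourhoods than in others, and the drivers — prior
no-show behaviour, travel burden, socioeconomic context — cluster in
space. `spatialdosc` is for health-services and epidemiology researchers
who want to model an outcome rate observed per census tract while taking
that spatial structure seriously:

- **Preprocessing.** Case records are aggregated to tracts; tracts with
  no inhabitants or fewer than 20 cases are excluded a priori; crude
  rates k/n are stabilised by empirical Bayes shrinkage toward a beta
  prior fit by method of moments; driving times are binned into 6-minute
  categories with EB-shrunk per-tract profiles; missing covariates get
  grand-mean/mode imputation; monetary columns are categorised and
  percentage columns rescaled by their IQR.
- **Spatial weights.** Rook contiguity (shared boundary edges, not
  corners), inverse centroid-distance weights, row standardisation:
  `w_ij = (1/d_ij) / Σ_j (1/d_ij)` for neighbours, so `Wy` is a
  neighbour average.
- **Diagnostics.** Global Moran's *I* = (n/S₀)·z′Wz/z′z with Monte-Carlo
  permutation inference, VIF collinearity screening, and geographically
  weighted local Pearson correlation of observed vs predicted rates
  (adaptive bisquare kernel).
- **Models.** One fitting function, `spreg()`, estimates by maximum
  likelihood: OLS (`glm`), ridge (`ridge_glm`), spatial lag
  `y = ρWy + Xβ + ε` (`sar`), spatial Durbin (`sdm`), spatial error
  `y = Xβ + u, u = λWu + ε` (`sem`), Durbin error (`sdem`), spatial
  moving average `y = Xβ + (I+λW)ε` (`sma`), SARAR (`sac`), and an
  L2-penalised lag model (`ridge_sar`). Spatial parameters are profiled
  out with eigenvalue-based log-determinants; fits expose
  `print`/`summary`/`coef`/`predict`/`residuals`/`fitted`/`logLik`/
  `simulate` methods.
- **Evaluation.** Nested 10×10 cross-validation with penalty grid search
  (10⁻⁶…10⁶), RMSE in percentage-rate units with a 95% CI over outer
  folds, residual Moran tests, permutation feature importance, and an
  individual-prediction-aggregation (IPA) baseline that averages
  case-level predicted probabilities within tracts.
- **Synthetic data.** A lattice generator with spatially autocorrelated
  covariates and outcomes drawn from any of the model families — counts
  or Gaussian surfaces — so every stage is testable against known ground
  truth.

## Worked example

```r
library(spatialdosc)

cfg <- synth_config(rows = 12, cols = 12, n_covariates = 3,
                    dgp_family = "sar", true_rho = 0.5, seed = 2024)
sim    <- simulate_tract_data(cfg)
tracts <- add_eb_rate(filter_tracts(sim$tracts, min_cases = 20))
keep   <- which(!tracts$excluded_flag)
d      <- tracts[keep, ]
w      <- subset_weights(sim$weights, keep)

attr(tracts, "eb_prior")
#> Beta prior: a = 1.412, b = 21.817 (mean 0.0608, strength 23.2)

global_moran(d$eb_rate, w, n_perm = 999, seed = 1)
#> Global Moran's I = 0.4479 (E[I] = -0.0070), permutation p = 0.001 [999 perms] *

fit <- spreg(eb_rate ~ x1 + x2 + x3, d, w, family = "sar")
fit
#> Spatial regression fit: family 'sar' (n = 144)
#> Coefficients:
#> (Intercept)          x1          x2          x3
#>    0.036223    0.016453   -0.008884    0.008675
#> rho (spatial lag):    0.420635
#> sigma^2 = 0.000565093, log-likelihood = 330.3963

nested_cv(d, eb_rate ~ x1 + x2 + x3, w, family = "sar", seed = 9)
#> Cross-validated sar: RMSE 2.6628% (95% CI 2.2871-3.0386), 10 folds
nested_cv(d, eb_rate ~ x1 + x2 + x3, w, family = "glm", seed = 9)
#> Cross-validated glm: RMSE 2.7559% (95% CI 2.3595-3.1522), 10 folds

permutation_importance(fit, d, w, seed = 10)
#> Permutation importance (baseline RMSE 2.5494, 20 repeats)
#>   variable delta_rmse  sd_delta rank
#> 1       x1  1.5411878 0.1405404    1
#> 2       x2  0.5972281 0.1047474    2
#> 3       x3  0.5846321 0.1036584    3
```

Reading the output: the tract rates are strongly spatially clustered
(Moran's *I* ≈ 0.45, permutation p = 0.001), the lag model recovers
ρ̂ ≈ 0.42 close to the generator's 0.5 on a shrunk binomial outcome, its
cross-validated RMSE of 2.66 percentage points edges out the nonspatial
OLS at 2.76, and shuffling `x1` (generator coefficient 0.3, the largest)
degrades RMSE most.

`run_dosc_pipeline(config)` drives the whole chain (simulate/read →
preprocess → weights → screen → cross-validate → importance → GeoJSON
map export) from one configuration list and writes CSV/GeoJSON/JSON
artifacts plus a manifest; `export_map()` attaches quantile bins and
significance flags for choropleth rendering.

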