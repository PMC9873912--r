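# carntrend

Population trends of large terrestrial carnivores (Canidae, Felidae,
Hyaenidae, Ursidae) are reported in wildly heterogeneous ways: abundance
time series, finite rates of change, total percent changes, per-year change
multipliers, or nothing more than "the population decreased". `carntrend`
is an R package for ecologists and conservation modellers who want to pool
all of those records and ask what drives them — land-use change, climate
extremes, governance, species traits, or socioeconomic development — and
what trajectories carnivore abundance could follow under different
human-development futures.

## The model

Every record is first standardised to an annual instantaneous rate of
change *r* (the slope of log<sub>e</sub> abundance on year) and its
percentage equivalent 100(e^r − 1). Time series are fitted by generalized
least squares with an Ornstein–Uhlenbeck residual covariance
σ² exp(−θ|tᵢ−tⱼ|) to absorb temporal autocorrelation; the other datatypes
have closed-form conversions (r = ln λ, r = ln(1 + P/100)/T, r = mean ln
multiplier).

The rates then enter a hierarchical Bayesian linear model:

- **Quantitative records**: yᵢ ~ Normal(μᵢ, σ²/wᵢ + seᵢ²), where the
  quality weight wᵢ ∈ (0, 1] inflates the uncertainty of trends derived
  from short monitoring periods, few observations, or less robust methods.
- **Qualitative records** are interval-censored: the latent rate is only
  known to lie in (−50, 0), (−5, 5) or (0, 50) %/yr for Decrease, Stable,
  Increase. The intervals overlap by design — a 2 %/yr trend may be called
  stable by one source and increasing by another.
- **Linear predictor**: μᵢ = α + Σⱼ βⱼ xᵢⱼ + u_genus + u_species +
  u_subregion + u_country, with 16 z-transformed covariates and 7
  interactions (23 slope terms). Imputed covariate cells enter as latent
  Normal(m, s²) values, so imputation uncertainty propagates.
- **Kuo–Mallick selection**: optional and interaction terms carry Bernoulli
  inclusion indicators γⱼ with βⱼ = γⱼ bⱼ; seven core terms are always in
  the model.

Posterior sampling is a blocked Gibbs sampler written in C++ (conjugate
joint updates for the slopes, marginalized indicator updates,
truncated-normal draws for censored records, latent draws for
measurement-error covariates, half-Cauchy scales via inverse-gamma
augmentation). An independently written JAGS implementation of the same
posterior serves as a cross-check in the test suite.

Downstream of the fit: convergence and residual diagnostics
(rank-normalized split R̂, Moran's I with great-circle weights, Pagel's λ,
posterior predictive checks, conditional/marginal R²), counterfactual
scenarios (no habitat loss / no climate change / no human-development
growth), and decelerating human-development pathway projections with
turning-point detection.

## Worked example

Simulate a 600-population study with a known standardized effect of change
in human development (−0.44 %/yr per sd), fit the full model, and
interrogate it:

```r
library(carntrend)
cfg  <- synthetic_config(n_populations = 600, seed = 7)
ds   <- generate_dataset(cfg)
covs <- standardize_covariates(impute_covariates(ds$covariates, seed = 7))
design <- build_design(ds$trends, covs)
design
#> Model design: 600 records (527 quantitative, 73 censored), 23 slope terms, 509 latent covariate cells

fit <- sample_posterior(design, prior_spec(),
                        mcmc_config(n_chains = 3, n_iterations = 5000,
                                    n_burnin = 1000, thin = 5, seed = 7))

round(inclusion_probabilities(fit)[c("change_human_development",
                                     "change_drought")], 3)
#> change_human_development           change_drought
#>                    0.995                    0.011
```

Selection keeps the real effect (posterior inclusion 0.995) and drops the
pure-noise term (0.011). The recovered coefficient covers the truth:

```r
quantile(coef_draws(fit, "change_human_development", conditional = TRUE),
         c(0.025, 0.5, 0.975))
#>       2.5%        50%      97.5%
#> -0.6921723 -0.4806109 -0.2633390
```

A counterfactual world without human-development growth, and a projection
of a hypothetical carnivore population under the Moderate development
pathway (mean pace 1.5 %/yr, deceleration −0.02 %/yr², HDI 0.2 in 1960):

```r
counterfactual_diff(fit, scenario_spec("no_hd_growth"))
#> Counterfactual 'no_hd_growth' (zeroed: change_human_development)
#>   pooled difference in annual rate of change: -0.010 [-1.013, 1.005] %/yr

project_abundance(coef_draws(fit, "change_human_development",
                             conditional = TRUE),
                  standardization = c(mean = 1.2, sd = 0.5),
                  pathway = hd_pathway("Moderate"))
#> Abundance projection (Moderate pathway): baseline 100 in 1960 -> median 83.6 [77.2, 90.7] in 2020
#>   turning point: 2005 (dHD = 1.20 %/yr)
```

In this synthetic world the pressure is centred on zero, so the pooled
counterfactual difference is ~0 with spread across populations; the
projection declines while development change is fast and turns around in
2005, the year the pathway's change in human development falls below the
1.2 %/yr zero-growth threshold.

The whole pipeline (simulate → covariates → fit → diagnostics →
counterfactuals → projections, with all artifacts and a manifest) runs as

```r
run_pipeline(list(seed = 1, output_dir = "demo-run"))
```

or from a shell via `Rscript inst/scripts/carntrends.R run-all --config
config.yaml`.

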