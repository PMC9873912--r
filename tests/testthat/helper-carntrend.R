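# shared fixtures: everything is generated in code, no data files

# a small synthetic study ready for fitting
quick_design <- function(n = 200, seed = 1, frac_qualitative = 0.15,
                         missing_rate = 0.05, ...) {
  cfg <- synthetic_config(n_populations = n,
                          frac_qualitative = frac_qualitative,
                          missing_rate = missing_rate, seed = seed, ...)
  ds <- generate_dataset(cfg)
  covs <- if (missing_rate > 0)
    impute_covariates(ds$covariates, seed = seed) else ds$covariates
  std <- standardize_covariates(covs)
  list(design = build_design(ds$trends, std), data = ds, covariates = std)
}

# short chains for structural tests (not for inference quality)
quick_mcmc <- function(seed = 1, n_chains = 2, n_iterations = 1200,
                       n_burnin = 300, thin = 3) {
  mcmc_config(n_chains, n_iterations, n_burnin, thin, seed = seed)
}

quick_fit <- function(qd = quick_design(), seed = 1, ...) {
  suppressWarnings(sample_posterior(qd$design, prior_spec(),
                                    quick_mcmc(seed = seed), ...))
}
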