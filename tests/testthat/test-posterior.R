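test_that("identical seeds and inputs give identical draws", {
  qd <- quick_design(n = 120, seed = 6)
  f1 <- quick_fit(qd, seed = 9)
  f2 <- quick_fit(qd, seed = 9)
  expect_identical(f1$chains[[1]]$b, f2$chains[[1]]$b)
  expect_identical(f1$chains[[2]]$u, f2$chains[[2]]$u)
  expect_identical(f1$chains[[1]]$xmis, f2$chains[[1]]$xmis)
  f3 <- quick_fit(qd, seed = 10)
  expect_false(identical(f1$chains[[1]]$b, f3$chains[[1]]$b))
})

test_that("posterior medians match a weighted-least-squares oracle when variance components vanish", {
  cfg <- synthetic_config(
    n_populations = 300, frac_qualitative = 0, missing_rate = 0,
    true_betas = c(change_human_development = -0.44,
                   primary_land_loss = 0.8),
    sd_random = c(genus = 0, species = 0, subregion = 0, country = 0),
    seed = 21)
  ds <- generate_dataset(cfg)
  std <- standardize_covariates(ds$covariates)
  design <- build_design(ds$trends, std)
  fit <- suppressWarnings(sample_posterior(
    design, prior_spec(), mcmc_config(2, 3000, 800, 2, seed = 2),
    select = FALSE))
  X <- carntrend:::design_matrix(design)
  wls <- lm(design$y ~ X, weights = design$w)
  B <- carntrend:::beta_draws(fit)
  for (term in c("change_human_development", "primary_land_loss",
                 "governance")) {
    post <- B[, term]
    expect_lt(abs(median(post) - coef(wls)[[paste0("X", term)]]),
              2 * sd(post))
  }
  alpha <- carntrend:::combined(fit, "alpha")
  expect_lt(abs(median(alpha) - coef(wls)[[1]]), 2 * sd(alpha))
})

test_that("the Gibbs sampler agrees with an independent JAGS fit of the same model", {
  cfg <- synthetic_config(n_populations = 250, frac_qualitative = 0.15,
                          missing_rate = 0.04, seed = 31)
  ds <- generate_dataset(cfg)
  imp <- impute_covariates(ds$covariates, seed = 31)
  std <- standardize_covariates(imp)
  design <- build_design(ds$trends, std)
  fit <- suppressWarnings(sample_posterior(
    design, prior_spec(), mcmc_config(2, 4000, 1000, 2, seed = 3),
    select = FALSE))

  # same posterior, written independently in BUGS language
  model_str <- "
  model {
    for (k in 1:Nmis) { xm[k] ~ dnorm(Mm[k], pm[k]) }
    for (i in 1:N) {
      for (j in 1:Ncov) { x[i,j] <- xdat[i,j] + ismis[i,j]*xm[idmat[i,j]] }
      for (k in 1:Nint) { xi[i,k] <- x[i,pa[k]] * x[i,pb[k]] }
      mu[i] <- alpha + inprod(x[i,1:Ncov], beta[1:Ncov]) +
        inprod(xi[i,1:Nint], beta[(Ncov+1):(Ncov+Nint)]) +
        u_gen[genus[i]] + u_sp[species[i]] + u_sub[subreg[i]] +
        u_cty[country[i]]
      prec[i] <- w[i] / pow(sigma, 2)
    }
    for (i in 1:Nq) { y[i] ~ dnorm(mu[iq[i]], prec[iq[i]]) }
    for (c in 1:Nc) {
      cint[c] ~ dinterval(ylat[c], lim[c,1:2])
      ylat[c] ~ dnorm(mu[ic[c]], prec[ic[c]])
    }
    alpha ~ dnorm(0, 0.01)
    for (j in 1:(Ncov+Nint)) { beta[j] ~ dnorm(0, 0.01) }
    sigma ~ dt(0, 0.04, 1) T(0,)
    for (k in 1:Kg) { u_gen[k] ~ dnorm(0, pow(sdg, -2)) }
    for (k in 1:Ks) { u_sp[k] ~ dnorm(0, pow(sds, -2)) }
    for (k in 1:Kb) { u_sub[k] ~ dnorm(0, pow(sdb, -2)) }
    for (k in 1:Kc) { u_cty[k] ~ dnorm(0, pow(sdc, -2)) }
    sdg ~ dt(0, 0.04, 1) T(0,)
    sds ~ dt(0, 0.04, 1) T(0,)
    sdb ~ dt(0, 0.04, 1) T(0,)
    sdc ~ dt(0, 0.04, 1) T(0,)
  }"
  n <- length(design$y)
  quant <- design$is_cens == 0
  Xd <- design$Xmain
  ismis <- matrix(0, n, ncol(Xd))
  idmat <- matrix(1L, n, ncol(Xd))
  if (length(design$mis_row)) {
    cells <- cbind(design$mis_row + 1L, design$mis_col + 1L)
    ismis[cells] <- 1
    idmat[cells] <- seq_len(nrow(cells))
    Xd[cells] <- 0
  }
  dat <- list(N = n, Ncov = ncol(Xd), Nint = nrow(design$int_pairs),
              Nq = sum(quant), Nc = sum(!quant),
              Nmis = length(design$mis_row),
              y = design$y[quant], xdat = Xd, ismis = ismis, idmat = idmat,
              Mm = design$mis_mean, pm = 1 / design$mis_sd^2,
              pa = design$int_pairs[, 1], pb = design$int_pairs[, 2],
              genus = design$groups$genus + 1L,
              species = design$groups$species + 1L,
              subreg = design$groups$subregion + 1L,
              country = design$groups$country + 1L,
              Kg = design$n_levels[["genus"]],
              Ks = design$n_levels[["species"]],
              Kb = design$n_levels[["subregion"]],
              Kc = design$n_levels[["country"]],
              w = design$w, cint = rep(1L, sum(!quant)),
              lim = design$lim[!quant, , drop = FALSE],
              iq = which(quant), ic = which(!quant))
  inits <- lapply(1:2, function(ch)
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = ch,
         ylat = rowMeans(design$lim[!quant, , drop = FALSE])))
  m <- rjags::jags.model(textConnection(model_str), data = dat,
                         inits = inits, n.chains = 2, quiet = TRUE)
  update(m, 1000, progress.bar = "none")
  s <- rjags::coda.samples(m, c("alpha", "beta", "sigma"), n.iter = 3000,
                           progress.bar = "none")
  jags_mean <- summary(s)$statistics[, "Mean"]
  B <- carntrend:::beta_draws(fit)
  for (j in seq_along(design$term_names)) {
    expect_lt(abs(mean(B[, j]) - jags_mean[[paste0("beta[", j, "]")]]),
              0.08)
  }
  expect_lt(abs(mean(carntrend:::combined(fit, "alpha")) -
                  jags_mean[["alpha"]]), 0.25)
  expect_lt(abs(mean(carntrend:::combined(fit, "sigma")) -
                  jags_mean[["sigma"]]), 0.15)
})

test_that("record order does not change posterior summaries beyond Monte-Carlo error", {
  qd <- quick_design(n = 150, seed = 8, missing_rate = 0)
  fit1 <- suppressWarnings(sample_posterior(
    qd$design, prior_spec(), mcmc_config(2, 2500, 600, 2, seed = 4)))
  perm <- with(qd$data, {
    set.seed(99)
    trends[sample(nrow(trends)), ]
  })
  design2 <- build_design(perm, qd$covariates)
  fit2 <- suppressWarnings(sample_posterior(
    design2, prior_spec(), mcmc_config(2, 2500, 600, 2, seed = 4)))
  b1 <- carntrend:::beta_draws(fit1)[, "change_human_development"]
  b2 <- carntrend:::beta_draws(fit2)[, "change_human_development"]
  expect_lt(abs(median(b1) - median(b2)),
            4 * sqrt(var(b1) + var(b2)) / sqrt(200))
  expect_lt(abs(median(carntrend:::combined(fit1, "sigma")) -
                  median(carntrend:::combined(fit2, "sigma"))), 0.1)
})

test_that("predictions are linear in the covariates and intervals nest", {
  qd <- quick_design(n = 150, seed = 12)
  fit <- quick_fit(qd, seed = 2)
  base <- predict_rate(fit)
  expect_identical(base$draws, carntrend:::combined(fit, "alpha"))
  shifted <- predict_rate(fit, c(change_human_development = 1))
  expect_equal(
    shifted$draws - base$draws,
    unname(carntrend:::beta_draws(fit)[, "change_human_development"]))
  iv <- shifted$intervals
  expect_true(iv$lower[1] >= iv$lower[2], iv$lower[2] >= iv$lower[3])
  expect_true(iv$upper[1] <= iv$upper[2], iv$upper[2] <= iv$upper[3])
  expect_error(predict_rate(fit, c(not_a_covariate = 1)), "unknown")
  expect_error(predict_rate(fit, groups = c(genus = "not_a_genus")),
               "unknown group")
  withgrp <- predict_rate(fit, groups = c(genus = qd$data$trends$genus[1]))
  expect_false(identical(withgrp$median, base$median))
})

test_that("pinned indicators have inclusion probability exactly one", {
  qd <- quick_design(n = 100, seed = 13, missing_rate = 0)
  fit <- quick_fit(qd, seed = 5, pin_terms = "human_development")
  ip <- inclusion_probabilities(fit)
  expect_identical(ip[["human_development"]], 1)
  expect_error(inclusion_probabilities(fit, "governance"),
               "not under selection")
  expect_error(sample_posterior(qd$design, prior_spec(), quick_mcmc(),
                                pin_terms = "governance"), "selectable")
})
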