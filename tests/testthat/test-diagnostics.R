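test_that("split R-hat separates converged from divergent chains", {
  set.seed(1)
  stationary <- rnorm(4000)
  expect_equal(rhat(cbind(stationary, stationary)), 1, tolerance = 0.01)
  # disjoint chains: between-chain variance dominates
  expect_gt(rhat(cbind(rnorm(500, -10), rnorm(500, 10))), 1.5)
  # independent draws from the same distribution
  expect_lt(rhat(matrix(rnorm(40000), ncol = 4)), 1.01)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(rhat(matrix(rnorm(8), ncol = 2)), "10 draws")
})

test_that("Moran's I has the analytic expectation and detects spatial signal", {
  set.seed(7)
  lat <- runif(11, -40, 60); lon <- runif(11, -150, 150)
  m <- morans_i(rnorm(11), lat, lon, n_permutations = 199, seed = 1)
  expect_equal(m$expected, -1 / 10)
  expect_gt(m$p, 0.01)   # i.i.d. residuals inside the permutation null
  # a smooth function of latitude is strongly autocorrelated
  n <- 40
  lat2 <- seq(-40, 60, length.out = n); lon2 <- runif(n, -150, 150)
  sig <- morans_i(lat2 / 20, lat2, lon2, n_permutations = 999, seed = 2)
  expect_gt(sig$I, sig$expected)
  expect_lte(sig$p, 0.01)
  # permutation p is seed-stable
  sig2 <- morans_i(lat2 / 20, lat2, lon2, n_permutations = 999, seed = 2)
  expect_identical(sig$p, sig2$p)
  expect_error(morans_i(rep(1, 11), lat, lon), "constant")
  expect_error(morans_i(rnorm(11), rep(1, 11), rep(2, 11)), "duplicate")
  expect_silent(morans_i(rnorm(11), rep(1, 11), rep(2, 11), jitter = TRUE,
                         n_permutations = 19))
})

test_that("the analytic Moran expectation holds for any row-standardized weights", {
  # permutation mean of I equals -1/(n-1) (symbolic identity checked by
  # brute force on a small instance)
  set.seed(3)
  n <- 7
  lat <- runif(n, 0, 50); lon <- runif(n, 0, 50); res <- rnorm(n)
  perms <- t(vapply(seq_len(2000), function(k)
    sample(res), numeric(n)))
  Is <- apply(perms, 1, function(z)
    morans_i(z, lat, lon, n_permutations = 1, seed = 1)$I)
  expect_lt(abs(mean(Is) - (-1 / (n - 1))),
            4 * sd(Is) / sqrt(length(Is)))
})

test_that("Pagel's lambda is near zero for i.i.d. tips and high for Brownian traits", {
  species <- sprintf("sp%02d", 1:40)
  genus <- rep(sprintf("gen%02d", 1:8), each = 5)
  tree <- taxonomy_tree(species, genus)
  set.seed(11)
  null_ps <- vapply(1:50, function(r) {
    x <- setNames(rnorm(40), species)
    pagels_lambda(x, tree = tree)$p
  }, 0)
  expect_gte(mean(null_ps > 0.05), 0.9)
  bm_lambda <- vapply(1:50, function(r) {
    x <- ape::rTraitCont(tree, sigma = 1)
    pagels_lambda(x, tree = tree)$lambda
  }, 0)
  expect_gt(median(bm_lambda), 0.8)
})

test_that("lambda is invariant to branch-length rescaling and zero on a star", {
  species <- sprintf("sp%02d", 1:30)
  genus <- rep(sprintf("gen%02d", 1:6), each = 5)
  tree <- taxonomy_tree(species, genus)
  set.seed(21)
  x <- ape::rTraitCont(tree, sigma = 1)
  l1 <- pagels_lambda(x, tree = tree)$lambda
  tree3 <- tree; tree3$edge.length <- tree3$edge.length * 3
  l3 <- pagels_lambda(x, tree = tree3)$lambda
  expect_equal(l1, l3, tolerance = 1e-4)
  expect_true(l1 >= 0 && l1 <= 1)
  star <- ape::read.tree(text = paste0("(",
    paste0(species, ":1", collapse = ","), ");"))
  ls <- pagels_lambda(setNames(rnorm(30), species), tree = star)
  expect_identical(ls$lambda, 0)
  expect_error(pagels_lambda(setNames(rnorm(3), c("a", "b", "zz")),
                             tree = tree), "missing from the tree")
})

test_that("posterior predictive checks pass on self-simulated data and flag gross misfit", {
  qd <- quick_design(n = 150, seed = 17)
  fit <- quick_fit(qd, seed = 3)
  ppc <- posterior_predictive_check(fit, seed = 1)
  med <- ppc[ppc$statistic == "q50", ]
  expect_gte(med$observed, med$rep_lo)
  expect_lte(med$observed, med$rep_hi)
  expect_true(all(ppc$ppp > 0 & ppc$ppp < 1))
  # shift the observations after fitting: the check must flag it
  broken <- fit
  broken$design$y <- broken$design$y + 50
  ppc2 <- posterior_predictive_check(broken, seed = 1)
  med2 <- ppc2[ppc2$statistic == "q50", ]
  expect_gt(med2$observed, med2$rep_hi)
  expect_lte(med2$ppp, 0.01)
  empty <- fit
  empty$design$y <- numeric(0)
  expect_error(posterior_predictive_check(empty), "no records")
})

test_that("variance partition is recovered by conditional and marginal R2", {
  # fixed 0.4 / random 0.3 / residual 0.3 at unit total variance
  cfg <- synthetic_config(
    n_populations = 500, frac_qualitative = 0, missing_rate = 0,
    true_betas = c(change_human_development = sqrt(0.4)),
    sd_random = c(genus = sqrt(0.15), species = sqrt(0.15),
                  subregion = 0, country = 0),
    sd_residual = sqrt(0.3), seed = 23)
  ds <- generate_dataset(cfg)
  std <- standardize_covariates(ds$covariates)
  design <- build_design(ds$trends, std)
  fit <- suppressWarnings(sample_posterior(
    design, prior_spec(), mcmc_config(2, 3000, 800, 2, seed = 6),
    select = FALSE))
  r2 <- conditional_r2(fit)
  # quality weighting inflates the realised residual variance; the oracle
  # uses the generator's own weights
  var_e <- 0.3 * mean(1 / design$w)
  cond_true <- (0.4 + 0.3) / (0.4 + 0.3 + var_e)
  marg_true <- 0.4 / (0.4 + 0.3 + var_e)
  expect_lt(abs(r2$conditional - cond_true), 0.1)
  expect_lt(abs(r2$marginal - marg_true), 0.1)
  expect_true(all(r2$draws$conditional >= r2$draws$marginal))
})

test_that("R2 reaches its noiseless and null limits", {
  base <- list(n_populations = 250, frac_qualitative = 0, missing_rate = 0,
               sd_random = c(genus = 0, species = 0, subregion = 0,
                             country = 0))
  noiseless <- do.call(synthetic_config, c(base, list(
    true_betas = c(change_human_development = 2), sd_residual = 0.02,
    seed = 24)))
  ds <- generate_dataset(noiseless)
  fit <- suppressWarnings(sample_posterior(
    build_design(ds$trends, standardize_covariates(ds$covariates)),
    prior_spec(), quick_mcmc(seed = 7), select = FALSE))
  r2 <- conditional_r2(fit)
  expect_gt(r2$conditional, 0.95)
  expect_gt(r2$marginal, 0.95)
  null <- do.call(synthetic_config, c(base, list(
    true_betas = c(change_human_development = 0), seed = 25)))
  ds0 <- generate_dataset(null)
  fit0 <- suppressWarnings(sample_posterior(
    build_design(ds0$trends, standardize_covariates(ds0$covariates)),
    prior_spec(), quick_mcmc(seed = 8), select = FALSE))
  r20 <- conditional_r2(fit0)
  # finite-sample estimation noise counts as "explained" variance, so the
  # null limit is approached from above
  expect_lt(r20$conditional, 0.2)
  expect_lt(r20$marginal, 0.2)
})

test_that("the assembled diagnostics report carries every component", {
  qd <- quick_design(n = 120, seed = 27)
  fit <- quick_fit(qd, seed = 4)
  rep <- diagnostics_report(fit, n_permutations = 49, seed = 1)
  expect_s3_class(rep, "carn_diagnostics")
  expect_true(all(rep$rhat > 0.9))
  expect_true(rep$lambda$lambda >= 0 && rep$lambda$lambda <= 1)
  expect_true(rep$conditional_r2 >= rep$marginal_r2)
  expect_output(print(rep), "Moran")
})
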