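test_that("counterfactual differences vanish where observed pressure is already zero", {
  qd <- quick_design(n = 120, seed = 31, missing_rate = 0)
  # force one population's scenario covariate to raw zero
  covs <- qd$data$covariates
  covs$primary_land_loss[1] <- 0
  std <- standardize_covariates(covs)
  design <- build_design(qd$data$trends, std)
  fit <- suppressWarnings(sample_posterior(design, prior_spec(),
                                           quick_mcmc(seed = 11)))
  cf <- counterfactual_diff(fit, scenario_spec("no_habitat_loss"))
  expect_true(all(cf$draws[, 1] == 0))
  expect_identical(cf$per_population$median[1], 0)
})

test_that("counterfactuals are additive over disjoint zeroed sets", {
  qd <- quick_design(n = 100, seed = 32, missing_rate = 0.05)
  fit <- quick_fit(qd, seed = 12)
  a <- counterfactual_diff(fit, scenario_spec(
    "custom", zeroed_covariates = "primary_land_loss"))
  b <- counterfactual_diff(fit, scenario_spec(
    "custom", zeroed_covariates = "change_human_development"))
  ab <- counterfactual_diff(fit, scenario_spec(
    "custom",
    zeroed_covariates = c("primary_land_loss", "change_human_development")))
  # no interaction pairs these two covariates, so zeroing both equals the
  # sum of zeroing each (draw-wise identity)
  expect_lt(max(abs(ab$draws - a$draws - b$draws)), 1e-10)
})

test_that("the sign of the counterfactual follows the sign of the effect", {
  qd <- quick_design(n = 400, seed = 33, frac_qualitative = 0,
                     missing_rate = 0)
  fit <- quick_fit(qd, seed = 13, select = FALSE)
  # the generator's true effect of change in human development is negative;
  # populations that experienced above-average growth must be better off
  # without it
  cf <- counterfactual_diff(fit, scenario_spec("no_hd_growth"))
  x <- qd$covariates$change_human_development
  hi <- x > 0.5
  expect_gt(median(cf$per_population$median[hi]), 0)
  expect_lt(median(cf$per_population$median[x < -0.5]), 0)
})

test_that("zeroing a covariate with no true effect yields a null pooled difference", {
  qd <- quick_design(n = 300, seed = 34, frac_qualitative = 0,
                     missing_rate = 0)
  fit <- quick_fit(qd, seed = 14)
  cf <- counterfactual_diff(fit, scenario_spec(
    "custom", zeroed_covariates = "change_crop_cover"))
  expect_lt(abs(cf$pooled[["median"]]), 0.05)
})

test_that("scenario specifications validate their covariates", {
  qd <- quick_design(n = 60, seed = 35, missing_rate = 0)
  fit <- quick_fit(qd, seed = 15)
  expect_error(counterfactual_diff(fit, scenario_spec(
    "custom", zeroed_covariates = "not_a_covariate")), "not in the model")
  expect_error(scenario_spec("custom"), "zeroed_covariates")
})

test_that("pathway arithmetic matches the printed constants exactly", {
  p <- hd_pathway("Moderate")
  expect_equal(p$delta_hd[p$year == 1960], 2.1, tolerance = 1e-12)
  expect_equal(p$delta_hd[p$year == 2020], 0.9, tolerance = 1e-12)
  expect_equal(mean(p$delta_hd), 1.5, tolerance = 1e-12)
  expect_equal(p$hdi[p$year == 1961], 0.2 * 1.021, tolerance = 1e-12)
  expect_equal(p$hdi[p$year == 1960], 0.2)
  # the change series is linear with slope equal to the deceleration
  expect_equal(unique(round(diff(p$delta_hd), 12)), -0.02)
  expect_equal(attr(hd_pathway("Slow"), "pace"), 1.25)
  expect_equal(attr(hd_pathway("Fast"), "pace"), 1.75)
  # no deceleration: constant change, geometric index growth
  flat <- hd_pathway("custom", pace = 1, deceleration = 0, end_year = 1970)
  expect_true(all(flat$delta_hd == 1))
  expect_equal(flat$hdi, 0.2 * 1.01^(0:10), tolerance = 1e-12)
  expect_error(hd_pathway("custom", pace = 30), "above 1")
})

test_that("projections respond to the effect size as the model implies", {
  path <- hd_pathway("Moderate")
  std <- c(mean = 1.2, sd = 0.5)
  flat <- project_abundance(rep(0, 100), std, path)
  expect_true(all(flat$trajectory$median == 100))
  expect_true(all(flat$trajectory$lo95 == 100))
  # doubling the baseline doubles the whole trajectory
  p1 <- project_abundance(rep(-0.44, 50), std, path, 100)
  p2 <- project_abundance(rep(-0.44, 50), std, path, 200)
  expect_equal(p2$trajectory$median, 2 * p1$trajectory$median,
               tolerance = 1e-12)
  # a more negative effect is pointwise dominated
  p3 <- project_abundance(rep(-0.8, 50), std, path, 100)
  expect_true(all(p3$trajectory$median <= p1$trajectory$median))
  # extinction clips at zero and stays there
  crash <- project_abundance(rep(-300, 10), std,
                             hd_pathway("custom", pace = 3,
                                        deceleration = 0,
                                        end_year = 1990))
  m <- crash$trajectory$median
  expect_true(all(m >= 0))
  first0 <- which(m == 0)[1]
  expect_true(all(m[first0:length(m)] == 0))
  expect_error(project_abundance(numeric(0), std, path), "empty")
})

test_that("a negative effect with a decelerating pathway gives a U-shaped trajectory", {
  path <- hd_pathway("Moderate")
  pr <- project_abundance(rep(-0.44, 200), c(mean = 1.2, sd = 0.5), path)
  med <- pr$trajectory$median
  tp <- turning_point(pr)
  # the growth rate crosses zero where delta HD hits the standardization
  # mean (1.2%), which under the Moderate pathway is 1990 + 0.3/0.02 = 2005
  expect_equal(tp$year, 2005)
  expect_equal(tp$delta_hd, 1.2, tolerance = 1e-9)
  imin <- which.min(med)
  expect_true(pr$trajectory$year[imin] %in% c(2005, 2006))
  expect_true(all(diff(med[seq_len(imin - 1)]) < 0))
  expect_true(all(diff(med[(imin + 1):length(med)]) > 0))
})

test_that("turning points are absent for monotone trajectories and ordered by pace", {
  std <- c(mean = 1.2, sd = 0.5)
  # positive effect: abundance grows throughout, no flip
  up <- project_abundance(rep(0.3, 20), std, hd_pathway("Moderate"))
  expect_null(turning_point(up))
  slow <- turning_point(project_abundance(rep(-0.44, 20), std,
                                          hd_pathway("Slow")))
  fast <- turning_point(project_abundance(rep(-0.44, 20), std,
                                          hd_pathway("Fast")))
  expect_lt(slow$year, fast$year)
  # both flips happen where the pathway crosses the same threshold
  expect_equal(slow$delta_hd, fast$delta_hd, tolerance = 0.02)
})
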