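test_that("z-transform centres and scales with the sample sd", {
  zt <- z_transform(c(1, 2, 3))
  expect_equal(zt$x, c(-1, 0, 1))
  expect_equal(zt$mean, 2)
  expect_equal(zt$sd, 1)
  # idempotence on an already standardized column
  x <- scale(rnorm(50))[, 1]
  zt2 <- z_transform(x)
  expect_equal(zt2$x, x, tolerance = 1e-12)
  expect_lt(abs(zt2$mean), 1e-12)
  expect_equal(zt2$sd, 1, tolerance = 1e-12)
  expect_error(z_transform(c(5, 5, 5)), "constant")
  # missing entries stay missing, moments use the rest
  zt3 <- z_transform(c(1, NA, 3))
  expect_true(is.na(zt3$x[2]))
  expect_equal(abs(zt3$x[c(1, 3)]), c(1, 1) / sqrt(2))
  # output moments on the non-missing entries
  z <- z_transform(rnorm(100, 5, 3))$x
  expect_lt(abs(mean(z)), 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
})

test_that("lag windows extend the monitoring start backwards", {
  expect_equal(apply_lag_window(list(start_year = 1990, end_year = 2000), 10),
               list(start_year = 1980, end_year = 2000))
  expect_equal(apply_lag_window(c(1990, 2000), 0), c(1990, 2000))
  expect_equal(apply_lag_window(c(1970, 1975), 5), c(1965, 1975))
  expect_error(apply_lag_window(c(1990, 2000), -1), "non-negative")
})

test_that("exceedance months count strictly-above-threshold window months per year", {
  # baseline 1901-1920 with mean 0 and sd ~1: threshold ~2
  baseline <- expand.grid(year = 1901:1920, month = 1:12)
  baseline$value <- rep(c(-1, 1), length.out = nrow(baseline))
  window <- expand.grid(year = 1991:2000, month = 1:12)
  window$value <- ifelse(window$month <= 3, 3, 0)  # 3 months/yr above
  series <- rbind(baseline, window)
  expect_equal(exceedance_months(series, c(1901, 1920), c(1991, 2000)), 3)
  # no exceedance when all window values sit at or below the threshold
  window0 <- window; window0$value <- 0
  expect_equal(exceedance_months(rbind(baseline, window0),
                                 c(1901, 1920), c(1991, 2000)), 0)
  # saturation: every month above
  window12 <- window; window12$value <- 10
  expect_equal(exceedance_months(rbind(baseline, window12),
                                 c(1901, 1920), c(1991, 2000)), 12)
  # invariance to adding a constant to the whole series
  shifted <- series; shifted$value <- shifted$value + 7.3
  expect_equal(exceedance_months(shifted, c(1901, 1920), c(1991, 2000)), 3)
  expect_error(exceedance_months(baseline, c(1901, 1920), c(1991, 2000)),
               "window")
})

test_that("sampling-point counts interpolate 13-295 on the log-area scale", {
  expect_identical(buffer_sampling_points(10, 10, 1e6), 13L)
  expect_identical(buffer_sampling_points(1e6, 10, 1e6), 295L)
  expect_identical(buffer_sampling_points(sqrt(10 * 1e6), 10, 1e6), 154L)
  areas <- 10^seq(1, 6, length.out = 50)
  n <- buffer_sampling_points(areas, 10, 1e6)
  expect_true(all(diff(n) >= 0))
  expect_true(all(n >= 13 & n <= 295))
  expect_error(buffer_sampling_points(-1), "positive")
})

test_that("imputation honours the (mean, sd) contract and is reproducible", {
  cov <- data.frame(population_id = sprintf("p%03d", 1:200),
                    a = rnorm(200), b = rnorm(200))
  cov$c <- cov$a + rnorm(200, 0, 0.3)       # imputable from a
  expect_identical(impute_covariates(cov, seed = 1)[names(cov)], cov)
  full_c <- cov$c
  mis <- sample(200, 40)
  cov$c[mis] <- NA
  i1 <- impute_covariates(cov, seed = 2)
  i2 <- impute_covariates(cov, seed = 2)
  expect_identical(i1, i2)
  expect_true(all(i1$c__sd[mis] > 0))
  expect_true(all(i1$c__sd[-mis] == 0))
  expect_identical(i1$a, cov$a)
  # imputation error beats the marginal sd under MCAR (generator oracle)
  rmse <- sqrt(mean((i1$c[mis] - full_c[mis])^2))
  expect_lt(rmse, sd(full_c))
  cov$c <- NA
  expect_error(impute_covariates(cov), "missing")
})

test_that("standardize_covariates stores back-transformation constants", {
  cov <- data.frame(population_id = c("a", "b", "c", "d"),
                    x = c(2, 4, 6, 8), y = c(0, 1, 0, 1),
                    y__sd = c(0, 0.5, 0, 0))
  std <- standardize_covariates(cov)
  expect_equal(attr(std, "center")[["x"]], 5)
  expect_equal(attr(std, "scale")[["x"]], sd(c(2, 4, 6, 8)))
  expect_equal(std$y__sd[2], 0.5 / sd(c(0, 1, 0, 1)))
  expect_lt(abs(mean(std$x)), 1e-12)
})
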