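#' Abundance time series for one population
#'
#' @param population_id identifier.
#' @param years integer years, strictly increasing.
#' @param abundances positive abundance (or density) estimates, one per year.
#' @param unit free-text unit label.
#' @return An object of class `abundance_series`.
#' @export
abundance_series <- function(population_id, years, abundances,
                             unit = "abundance") {
  if (length(years) != length(abundances))
    stop_input("years and abundances must have the same length")
  if (length(years) < 2) stop_input("a series needs at least 2 observations")
  if (any(diff(years) <= 0)) stop_input("years must be strictly increasing")
  if (any(!is.finite(abundances)) || any(abundances <= 0))
    stop_input("abundances must be positive (zeros are rejected; log is undefined)")
  structure(list(population_id = population_id, years = as.numeric(years),
                 abundances = as.numeric(abundances), unit = unit),
            class = "abundance_series")
}

# common container for a standardized trend
trend_estimate <- function(r, se_r, n_obs, duration_years, ou_theta_hat,
                           method) {
  structure(list(r = r, se_r = se_r, pct = pct_from_instantaneous(r),
                 n_obs = n_obs, duration_years = duration_years,
                 ou_theta_hat = ou_theta_hat, method = method),
            class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("Trend (%s): r = %.4f /yr (%.2f %%/yr)", x$method, x$r, x$pct))
  if (is.finite(x$se_r %||% NA)) cat(sprintf(", se_r = %.4f", x$se_r))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.trend_estimate <- function(x, ...) {
  data.frame(r = x$r, se_r = x$se_r %||% NA_real_, pct = x$pct,
             n_obs = x$n_obs %||% NA_real_,
             duration_years = x$duration_years %||% NA_real_,
             ou_theta_hat = x$ou_theta_hat %||% NA_real_, method = x$method)
}

# GLS machinery for one fixed OU range parameter theta.
# Correlation R_ij = exp(-theta |t_i - t_j|); profile log-likelihood over
# the regression coefficients and sigma^2.
ou_gls_at_theta <- function(tt, l, theta) {
  n <- length(l)
  R <- exp(-theta * abs(outer(tt, tt, "-")))
  ch <- chol(R)
  Xd <- cbind(1, tt)
  Xs <- backsolve(ch, Xd, transpose = TRUE)
  ls <- backsolve(ch, l, transpose = TRUE)
  XtX <- crossprod(Xs)
  bet <- solve(XtX, crossprod(Xs, ls))
  res <- ls - Xs %*% bet
  rss <- sum(res^2)
  s2 <- max(rss / n, .Machine$double.xmin)
  ll <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
  list(beta = drop(bet), rss = rss, XtXinv = solve(XtX), loglik = ll, n = n)
}

#' Fit a log-linear trend with Ornstein-Uhlenbeck autocorrelation
#'
#' Regresses log abundance on year by generalized least squares under an OU
#' residual covariance `sigma^2 * exp(-theta |t_i - t_j|)`, the continuous
#' analogue of an AR(1) error that accounts for non-independence within a
#' time series. The range parameter `theta` is profiled by maximum
#' likelihood over a log-spaced grid refined by golden-section search on
#' `[1e-3, 1e3]` per year. As `theta` grows the correlation vanishes and the
#' estimate reduces to ordinary least squares. The slope is the annual
#' instantaneous rate of change r.
#'
#' A two-observation series is unidentifiable under the OU model and falls
#' back to the two-point rate `diff(log(abundance)) / diff(year)` with an
#' undefined standard error.
#'
#' @param series an [abundance_series()].
#' @param fixed_theta optional fixed OU rate (skips profiling).
#' @param theta_bounds search bounds for theta (1/years).
#' @return A `trend_estimate` with slope `r`, its GLS standard error,
#'   the percentage rate, and the profiled `ou_theta_hat`.
#' @export
fit_loglinear_ou <- function(series, fixed_theta = NULL,
                             theta_bounds = c(1e-3, 1e3)) {
  stopifnot(inherits(series, "abundance_series"))
  yrs <- series$years
  l <- log(series$abundances)
  n <- length(l)
  dur <- yrs[n] - yrs[1]
  if (dur <= 0) stop_input("degenerate series: all years equal")
  if (n == 2) {
    return(trend_estimate(r = diff(l) / diff(yrs), se_r = NA_real_,
                          n_obs = 2, duration_years = dur,
                          ou_theta_hat = NA_real_, method = "two_point"))
  }
  tt <- yrs - mean(yrs)
  if (!is.null(fixed_theta)) {
    fit <- ou_gls_at_theta(tt, l, fixed_theta)
    theta_hat <- fixed_theta
  } else {
    lb <- log(theta_bounds)
    grid <- exp(seq(lb[1], lb[2], length.out = 41))
    lls <- vapply(grid, function(th) ou_gls_at_theta(tt, l, th)$loglik, 0)
    k <- which.max(lls)
    lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
    opt <- optimize(function(lth) ou_gls_at_theta(tt, l, exp(lth))$loglik,
                    lower = log(lo), upper = log(hi), maximum = TRUE,
                    tol = 1e-8)
    theta_hat <- exp(opt$maximum)
    if (opt$objective < lls[k]) theta_hat <- grid[k]
    fit <- ou_gls_at_theta(tt, l, theta_hat)
  }
  se_r <- if (fit$rss < 1e-12) 0 else
    sqrt(fit$rss / (n - 2) * fit$XtXinv[2, 2])
  trend_estimate(r = fit$beta[2], se_r = se_r, n_obs = n,
                 duration_years = dur, ou_theta_hat = theta_hat,
                 method = "time_series")
}

#' Annual instantaneous rate from a finite rate of change
#'
#' A finite rate lambda is the year-over-year multiplicative change in
#' abundance; the instantaneous rate is `r = ln(lambda)`.
#'
#' @param lambda finite annual rate of change (> 0).
#' @return A `trend_estimate`.
#' @export
rate_from_finite_rate <- function(lambda) {
  if (!is.finite(lambda) || lambda <= 0)
    stop_input("finite rate of change must be positive")
  trend_estimate(r = log(lambda), se_r = NA_real_, n_obs = NA_real_,
                 duration_years = NA_real_, ou_theta_hat = NA_real_,
                 method = "finite_rate")
}

#' Annual instantaneous rate from a total percent change
#'
#' A total change of P percent over T years implies
#' `r = ln(1 + P/100) / T` per year.
#'
#' @param P total percent change over the period (> -100).
#' @param T period length in years (> 0).
#' @return A `trend_estimate`.
#' @export
rate_from_percent_change <- function(P, T) {
  if (!is.finite(P) || P <= -100)
    stop_input("percent change must exceed -100 (total loss has no finite rate)")
  if (!is.finite(T) || T <= 0) stop_input("period length must be positive")
  trend_estimate(r = log1p(P / 100) / T, se_r = NA_real_, n_obs = NA_real_,
                 duration_years = T, ou_theta_hat = NA_real_,
                 method = "percent_change")
}

#' Annual instantaneous rate from a series of per-year changes
#'
#' For per-year finite multipliers (e.g. the population doubled in year 1
#' and halved in year 2: `c(2, 0.5)`), the mean log multiplier is the annual
#' instantaneous rate; doubling then halving gives exactly 0.
#'
#' @param multipliers positive per-year finite changes.
#' @return A `trend_estimate`.
#' @export
rate_from_change_series <- function(multipliers) {
  if (length(multipliers) < 1) stop_input("need at least one multiplier")
  if (any(!is.finite(multipliers)) || any(multipliers <= 0))
    stop_input("all multipliers must be positive")
  trend_estimate(r = mean(log(multipliers)), se_r = NA_real_,
                 n_obs = length(multipliers),
                 duration_years = length(multipliers),
                 ou_theta_hat = NA_real_, method = "change_series")
}

#' Percentage rate from an instantaneous rate
#'
#' `pct = 100 (e^r - 1)`; strictly increasing in r and bounded below
#' by -100.
#'
#' @param r annual instantaneous rate(s) of change.
#' @return Annual percent rate(s) of change.
#' @export
pct_from_instantaneous <- function(r) {
  if (any(!is.finite(r))) stop_input("rate must be finite")
  100 * expm1(r)
}

#' Fit trends for every population in a long abundance table
#'
#' @param abundance a data.frame with columns `population_id`, `year`,
#'   `abundance`.
#' @param ... passed to [fit_loglinear_ou()].
#' @return A data.frame with one row per population: `r`, `se_r`, `pct`,
#'   `n_obs`, `duration_years`, `ou_theta_hat`, `method`.
#' @export
estimate_trends <- function(abundance, ...) {
  need <- c("population_id", "year", "abundance")
  if (!all(need %in% names(abundance)))
    stop_input("abundance table needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(abundance, abundance$population_id), function(d) {
    d <- d[order(d$year), ]
    est <- fit_loglinear_ou(
      abundance_series(d$population_id[1], d$year, d$abundance), ...)
    cbind(population_id = d$population_id[1], as.data.frame(est))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
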