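#' Default covariate and interaction structure
#'
#' The model distinguishes three parameter groups. Core terms enter every
#' model; optional and interaction terms are screened by Kuo-Mallick
#' indicator variable selection. Sixteen main covariates (land-use, climate,
#' governance/socioeconomic, and trait groups) and seven trait/governance/
#' environment interactions give 23 slope terms in total.
#'
#' @return A list with character vectors `core`, `optional`, and a list of
#'   length-2 character vectors `interactions`.
#' @export
default_model_terms <- function() {
  list(
    core = c("change_human_density", "primary_land_loss", "population_area",
             "body_mass", "change_extreme_heat", "governance",
             "protected_area"),
    optional = c("human_development", "change_human_development",
                 "change_drought", "niche_breadth", "max_longevity",
                 "seminatural_conversion", "reproductive_output",
                 "change_crop_cover", "change_pasture_cover"),
    interactions = list(
      c("primary_land_loss", "change_human_density"),
      c("primary_land_loss", "seminatural_conversion"),
      c("primary_land_loss", "niche_breadth"),
      c("change_extreme_heat", "protected_area"),
      c("change_drought", "protected_area"),
      c("change_extreme_heat", "niche_breadth"),
      c("primary_land_loss", "governance")
    )
  )
}

#' Model specification
#'
#' Defines the fixed-effect structure (core terms always included; optional
#' and interaction terms under Kuo-Mallick selection), the censoring
#' intervals that map qualitative categories onto partially known annual
#' rates of change, the covariate lag window, and the priors.
#'
#' The default censoring intervals are Decrease (-50, 0), Stable (-5, 5) and
#' Increase (0, 50) percent per year. Their overlap is deliberate: different
#' sources may call the same modest change "stable" or "increasing", and the
#' overlap encodes that grey area in the observation model.
#'
#' @param core_terms character vector of always-included main effects.
#' @param optional_terms character vector of main effects under selection.
#' @param interaction_terms list of length-2 character vectors; each parent
#'   must be a core or optional term.
#' @param censor_intervals named list mapping category to `c(lower, upper)`
#'   in percent per year.
#' @param lag_years covariate lag window in years (0, 5 or 10).
#' @param priors a [prior_spec()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(core_terms = default_model_terms()$core,
                       optional_terms = default_model_terms()$optional,
                       interaction_terms = default_model_terms()$interactions,
                       censor_intervals = list(Decrease = c(-50, 0),
                                               Stable = c(-5, 5),
                                               Increase = c(0, 50)),
                       lag_years = 10,
                       priors = prior_spec()) {
  core_terms <- as.character(core_terms)
  optional_terms <- as.character(optional_terms)
  if (anyDuplicated(c(core_terms, optional_terms)))
    stop_input("core and optional term names must be disjoint and unique")
  main <- c(core_terms, optional_terms)
  for (pair in interaction_terms) {
    if (length(pair) != 2)
      stop_input("each interaction must name exactly two parent terms")
    bad <- setdiff(pair, main)
    if (length(bad))
      stop_input("interaction parent(s) not in core or optional terms: ",
                 paste(bad, collapse = ", "))
  }
  for (nm in names(censor_intervals)) {
    iv <- censor_intervals[[nm]]
    if (length(iv) != 2 || !(iv[1] < iv[2]))
      stop_input("censor interval for ", nm, " must satisfy lower < upper")
  }
  if (!lag_years %in% c(0, 5, 10))
    stop_input("lag_years must be 0, 5 or 10")
  stopifnot(inherits(priors, "prior_spec"))
  structure(list(core_terms = core_terms, optional_terms = optional_terms,
                 interaction_terms = interaction_terms,
                 censor_intervals = censor_intervals,
                 lag_years = lag_years, priors = priors),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model specification:\n")
  cat("  core terms      :", length(x$core_terms), "\n")
  cat("  optional terms  :", length(x$optional_terms), "(under selection)\n")
  cat("  interactions    :", length(x$interaction_terms), "(under selection)\n")
  cat("  censor intervals:",
      paste(sprintf("%s (%g, %g)", names(x$censor_intervals),
                    sapply(x$censor_intervals, `[`, 1),
                    sapply(x$censor_intervals, `[`, 2)), collapse = "; "), "\n")
  cat("  covariate lag   :", x$lag_years, "years\n")
  invisible(x)
}

# full ordered term vector: main effects then interactions ("a:b")
term_names <- function(spec) {
  c(spec$core_terms, spec$optional_terms,
    vapply(spec$interaction_terms, paste, "", collapse = ":"))
}

#' Prior specification
#'
#' Weakly informative priors on the percent-per-year scale of z-transformed
#' covariates: normal slopes and intercept, half-Cauchy scales for the
#' residual and random-intercept standard deviations, and a Bernoulli
#' inclusion prior for terms under selection.
#'
#' @param slope_sd prior sd of slope coefficients (default 10).
#' @param intercept_sd prior sd of the intercept (default 10).
#' @param inclusion_prob prior inclusion probability for selectable terms.
#' @param sigma_scale half-Cauchy scale of the residual sd (default 5).
#' @param re_sd_scale half-Cauchy scale of random-intercept sds (default 5).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(slope_sd = 10, intercept_sd = 10, inclusion_prob = 0.5,
                       sigma_scale = 5, re_sd_scale = 5) {
  if (!(slope_sd > 0 && intercept_sd > 0 && sigma_scale > 0 && re_sd_scale > 0))
    stop_input("all prior scales must be positive")
  if (!(inclusion_prob > 0 && inclusion_prob < 1))
    stop_input("inclusion_prob must lie in (0, 1)")
  structure(list(slope_sd = slope_sd, intercept_sd = intercept_sd,
                 inclusion_prob = inclusion_prob, sigma_scale = sigma_scale,
                 re_sd_scale = re_sd_scale),
            class = "prior_spec")
}

#' MCMC configuration
#'
#' Defaults mirror a long production run (3 chains of 150,000 iterations,
#' 50,000 burn-in, thinning 10). Tests and examples use much shorter chains.
#'
#' @param n_chains,n_iterations,n_burnin,thin chain geometry.
#' @param seed integer; all chain randomness derives from it.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iterations = 150000,
                        n_burnin = 50000, thin = 10, seed = 1) {
  if (!is_count(n_chains) || n_chains < 1) stop_input("n_chains must be >= 1")
  if (!(n_burnin < n_iterations)) stop_input("n_burnin must be < n_iterations")
  if (!is_count(thin) || thin < 1) stop_input("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Quality weight for a trend record
#'
#' Converts record quality metadata into a precision weight `w` in (0, 1].
#' The record-level residual sd is `sigma / sqrt(w)`, so low-quality records
#' (short monitoring period, few observations, less robust derivation
#' method) carry inflated uncertainty rather than being discarded. The
#' weight is the product of a duration component, an observation-count
#' component (each capped and raised to an exponent), and `method_class / 3`
#' where class 3 is the most robust derivation (e.g. a full time-series fit)
#' and class 1 the least (e.g. a qualitative report).
#'
#' @param duration_years monitored timespan in years (> 0).
#' @param n_observations number of abundance observations (>= 1).
#' @param method_class ordinal robustness class in {1, 2, 3}.
#' @param caps saturation points for duration and observation count.
#' @param exponents exponents for the duration and count components.
#' @return Numeric weights in (0, 1], monotone non-decreasing in every
#'   quality component.
#' @examples
#' weight_precision(10, 10, 3)   # best-quality anchor: 1
#' weight_precision(2.5, 10, 3)  # 0.5
#' @export
weight_precision <- function(duration_years, n_observations, method_class,
                             caps = c(duration = 10, n_observations = 10),
                             exponents = c(duration = 0.5,
                                           n_observations = 0.5)) {
  if (any(!is.finite(duration_years)) || any(duration_years <= 0))
    stop_input("duration_years must be positive")
  if (any(!is.finite(n_observations)) || any(n_observations < 1))
    stop_input("n_observations must be >= 1")
  if (!all(method_class %in% 1:3))
    stop_input("method_class must be 1, 2 or 3")
  (pmin(duration_years, caps[[1]]) / caps[[1]])^exponents[[1]] *
    (pmin(n_observations, caps[[2]]) / caps[[2]])^exponents[[2]] *
    (method_class / 3)
}

#' Log-likelihood of an interval-censored normal observation
#'
#' Returns `log(Phi((upper - mu) / sigma) - Phi((lower - mu) / sigma))`, the
#' normal probability mass on the censoring interval, computed on the log
#' scale so that extreme tails (|z| well beyond 8) do not underflow.
#'
#' @param mu,sigma mean and sd of the latent normal (percent per year).
#' @param lower,upper censoring interval, `lower < upper`.
#' @return Log-probabilities, vectorised over all four arguments.
#' @export
censored_loglik <- function(mu, sigma, lower, upper) {
  n <- max(length(mu), length(sigma), length(lower), length(upper))
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(!is.finite(mu)) || any(!is.finite(sigma)))
    stop_input("mu and sigma must be finite")
  if (any(sigma <= 0)) stop_input("sigma must be positive")
  if (any(lower >= upper)) stop_input("interval must satisfy lower < upper")
  zl <- (lower - mu) / sigma
  zu <- (upper - mu) / sigma
  out <- numeric(n)
  hi <- zl > 0                      # both bounds in the upper tail
  lo <- zu < 0                      # both bounds in the lower tail
  mid <- !hi & !lo
  if (any(hi)) {
    a <- pnorm(zl[hi], lower.tail = FALSE, log.p = TRUE)
    b <- pnorm(zu[hi], lower.tail = FALSE, log.p = TRUE)
    out[hi] <- a + log1p(-exp(b - a))
  }
  if (any(lo)) {
    a <- pnorm(zu[lo], log.p = TRUE)
    b <- pnorm(zl[lo], log.p = TRUE)
    out[lo] <- a + log1p(-exp(b - a))
  }
  if (any(mid)) out[mid] <- log(pnorm(zu[mid]) - pnorm(zl[mid]))
  out
}

# censoring interval for one qualitative category
censor_interval <- function(category, spec) {
  iv <- spec$censor_intervals[[category]]
  if (is.null(iv)) stop_input("unknown qualitative category: ", category)
  iv
}
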