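#' Configuration for the synthetic study generator
#'
#' Defines a complete synthetic study: taxonomic and geographic hierarchy
#' sizes, the mix of quantitative and qualitative records, the true linear
#' predictor (intercept, standardized effects, random-intercept sds,
#' residual sd), the OU parameters used for raw abundance series, and the
#' covariate missingness rate. Defaults emulate the assembled study data:
#' 1123 populations of 50 species (nested in genera) across countries nested
#' in UN sub-regions, roughly 12% qualitative records, annual rates of
#' change mostly within -10 to 10 percent, and a single true standardized
#' effect of -0.44 percent per year per sd on change in human development.
#'
#' @param n_populations,n_species,n_genera,n_countries,n_subregions counts;
#'   `n_genera <= n_species`, `n_subregions <= n_countries`.
#' @param frac_qualitative proportion of records observed only as
#'   Increase/Stable/Decrease.
#' @param true_intercept mean annual rate of change (percent per year).
#' @param true_betas named standardized effects (percent per year per sd);
#'   main-effect names from [default_model_terms()], interactions as "a:b".
#' @param sd_residual residual sd of annual rates at best quality (w = 1).
#' @param sd_random named sds of the genus, species, subregion and country
#'   random intercepts.
#' @param ou_theta,ou_sigma OU autocorrelation rate (1/years) and stationary
#'   sd (log-abundance units) for simulated abundance series.
#' @param missing_rate probability that a covariate cell is missing.
#' @param covariate_correlation optional equicorrelation among covariates.
#' @param seed integer seed; identical seeds give byte-identical datasets.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_populations = 1123, n_species = 50,
                             n_genera = 20, n_countries = 75,
                             n_subregions = 18,
                             frac_qualitative = 138 / 1123,
                             true_intercept = -1,
                             true_betas = c(change_human_development = -0.44),
                             sd_residual = 2,
                             sd_random = c(genus = 1, species = 0.7,
                                           subregion = 0.7, country = 0.5),
                             ou_theta = 0.5, ou_sigma = 0.1,
                             missing_rate = 0.05,
                             covariate_correlation = 0,
                             seed = 1) {
  if (n_genera > n_species) stop_input("n_genera must be <= n_species")
  if (n_subregions > n_countries)
    stop_input("n_subregions must be <= n_countries")
  if (!(frac_qualitative >= 0 && frac_qualitative <= 1))
    stop_input("frac_qualitative must lie in [0, 1]")
  if (!(missing_rate >= 0 && missing_rate < 1))
    stop_input("missing_rate must lie in [0, 1)")
  if (sd_residual <= 0) stop_input("sd_residual must be positive")
  need <- c("genus", "species", "subregion", "country")
  if (!all(need %in% names(sd_random)) || any(sd_random[need] < 0))
    stop_input("sd_random must name non-negative sds for ",
               paste(need, collapse = ", "))
  if (ou_theta <= 0 || ou_sigma < 0)
    stop_input("ou_theta must be > 0 and ou_sigma >= 0")
  structure(list(n_populations = n_populations, n_species = n_species,
                 n_genera = n_genera, n_countries = n_countries,
                 n_subregions = n_subregions,
                 frac_qualitative = frac_qualitative,
                 true_intercept = true_intercept, true_betas = true_betas,
                 sd_residual = sd_residual, sd_random = sd_random[need],
                 ou_theta = ou_theta, ou_sigma = ou_sigma,
                 missing_rate = missing_rate,
                 covariate_correlation = covariate_correlation,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a complete synthetic study dataset with known ground truth
#'
#' Draws the hierarchy (species in genera, countries in sub-regions),
#' standard-normal covariates, quality metadata, and per-population true
#' annual rates of change from the same generative structure the model
#' assumes: `rate = intercept + sum(beta * z) + random intercepts +
#' Normal(0, sd_residual / sqrt(w))`, where `w` is the record's quality
#' weight. A fraction of records is reduced to a qualitative category via
#' the non-overlapping partition at +-5 percent per year (the overlap of the
#' model's censoring intervals is a property of the observation model, not
#' of the truth), and covariate cells are then removed completely at random.
#'
#' @param config a [synthetic_config()].
#' @return A list with `trends` (trend-record table), `covariates` (wide
#'   covariate table, possibly with missing cells), and `truth` (a
#'   `synthetic_truth` list holding the per-population true rates, the
#'   complete covariates, group assignments, random-intercept values and the
#'   generating parameters).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  terms <- default_model_terms()
  cov_names <- c(terms$core, terms$optional)
  all_terms <- c(cov_names,
                 vapply(terms$interactions, paste, "", collapse = ":"))
  bad <- setdiff(names(cfg$true_betas), all_terms)
  if (length(bad))
    stop_input("unknown true_betas name(s): ", paste(bad, collapse = ", "))
  beta <- setNames(numeric(length(all_terms)), all_terms)
  beta[names(cfg$true_betas)] <- cfg$true_betas

  out <- with_seed(substream_seed(cfg$seed, "generator"), {
    n <- cfg$n_populations
    # grouping maps are functions: each species has one genus, each country
    # one subregion; the first assignments guarantee every level is used
    genus_of_species <- c(seq_len(cfg$n_genera),
                          sample(cfg$n_genera, cfg$n_species - cfg$n_genera,
                                 replace = TRUE))
    subregion_of_country <- c(seq_len(cfg$n_subregions),
                              sample(cfg$n_subregions,
                                     cfg$n_countries - cfg$n_subregions,
                                     replace = TRUE))
    species <- sample(cfg$n_species, n, replace = TRUE)
    country <- sample(cfg$n_countries, n, replace = TRUE)
    genus <- genus_of_species[species]
    subregion <- subregion_of_country[country]

    latitude <- runif(n, -55, 70)
    longitude <- runif(n, -180, 180)
    area_km2 <- 10^runif(n, 1.5, 5.5)
    start_year <- sample(1970:2000, n, replace = TRUE)
    duration <- sample(3:30, n, replace = TRUE)
    end_year <- pmin(start_year + duration, 2015)
    duration_years <- end_year - start_year

    m_qual <- floor(cfg$frac_qualitative * n)
    qual <- rep(FALSE, n)
    if (m_qual > 0) qual[sample(n, m_qual)] <- TRUE
    n_observations <- ifelse(qual, sample(1:5, n, replace = TRUE),
                             sample(3:40, n, replace = TRUE))
    method_class <- ifelse(qual, 1L,
                           sample(1:3, n, replace = TRUE,
                                  prob = c(0.1, 0.2, 0.7)))
    w <- weight_precision(duration_years, n_observations, method_class)

    X <- matrix(rnorm(n * length(cov_names)), n, length(cov_names),
                dimnames = list(NULL, cov_names))
    if (cfg$covariate_correlation > 0) {
      rho <- cfg$covariate_correlation
      X <- sqrt(rho) * rnorm(n) + sqrt(1 - rho) * X
    }
    XI <- cbind(X, interaction_columns(X, terms$interactions))

    u <- list(genus = rnorm(cfg$n_genera, 0, cfg$sd_random[["genus"]]),
              species = rnorm(cfg$n_species, 0, cfg$sd_random[["species"]]),
              subregion = rnorm(cfg$n_subregions, 0,
                                cfg$sd_random[["subregion"]]),
              country = rnorm(cfg$n_countries, 0, cfg$sd_random[["country"]]))
    mu <- cfg$true_intercept + drop(XI %*% beta) + u$genus[genus] +
      u$species[species] + u$subregion[subregion] + u$country[country]
    true_rate <- mu + rnorm(n, 0, cfg$sd_residual / sqrt(w))

    trends <- data.frame(
      population_id = sprintf("pop%04d", seq_len(n)),
      species = sprintf("sp%02d", species),
      genus = sprintf("gen%02d", genus),
      country = sprintf("country%02d", country),
      subregion = sprintf("subreg%02d", subregion),
      latitude = latitude, longitude = longitude, area_km2 = area_km2,
      start_year = start_year, end_year = end_year,
      response_kind = ifelse(qual, "qualitative", "quantitative"),
      pct = ifelse(qual, NA_real_, true_rate),
      category = ifelse(qual, categorize_trend(true_rate), NA_character_),
      duration_years = duration_years, n_observations = n_observations,
      method_class = method_class,
      stringsAsFactors = FALSE)

    covariates <- data.frame(population_id = trends$population_id, X,
                             stringsAsFactors = FALSE)
    truth <- structure(list(
      config = cfg, true_rate = true_rate,
      covariates_full = covariates,
      assignments = trends[, c("population_id", "species", "genus",
                               "country", "subregion")],
      random_intercepts = u,
      betas = beta, intercept = cfg$true_intercept,
      sd_residual = cfg$sd_residual, weights = w),
      class = "synthetic_truth")
    list(trends = trends, covariates = covariates, truth = truth)
  })
  if (cfg$missing_rate > 0)
    out$covariates <- inject_missingness(out$covariates, cfg$missing_rate,
                                         substream_seed(cfg$seed,
                                                        "missingness"))
  out
}

# products of main-effect columns for a list of parent pairs
interaction_columns <- function(X, pairs) {
  if (!length(pairs)) return(matrix(0, nrow(X), 0))
  out <- sapply(pairs, function(p) X[, p[1]] * X[, p[2]])
  colnames(out) <- vapply(pairs, paste, "", collapse = ":")
  out
}

#' Simulate an abundance time series with OU noise around a log-linear trend
#'
#' Log abundance follows `log(start) + r_true * (year - year0)` plus a
#' stationary Gaussian process with sd `ou_sigma` and correlation
#' `exp(-ou_theta * dt)` — the inverse of the model fitted by
#' [fit_loglinear_ou()]. Simulating on the log scale keeps abundances
#' strictly positive.
#'
#' @param r_true annual instantaneous rate of change.
#' @param n_years series length (>= 2), one observation per year.
#' @param ou_theta OU rate (1/years, > 0).
#' @param ou_sigma stationary sd of the OU noise (log units, >= 0).
#' @param start_abundance abundance in the first year (> 0).
#' @param seed optional integer seed.
#' @param start_year calendar year of the first observation.
#' @return An [abundance_series()].
#' @export
generate_abundance_series <- function(r_true, n_years, ou_theta = 0.5,
                                      ou_sigma = 0.1, start_abundance = 100,
                                      seed = NULL, start_year = 1990) {
  if (!is_count(n_years) || n_years < 2) stop_input("n_years must be >= 2")
  if (ou_theta <= 0) stop_input("ou_theta must be positive")
  if (ou_sigma < 0) stop_input("ou_sigma must be non-negative")
  if (start_abundance <= 0) stop_input("start_abundance must be positive")
  tt <- seq_len(n_years) - 1
  eps <- if (ou_sigma > 0) {
    Sig <- ou_sigma^2 * exp(-ou_theta * abs(outer(tt, tt, "-")))
    with_seed(seed, drop(crossprod(chol(Sig), rnorm(n_years))))
  } else rep(0, n_years)
  abundance_series(population_id = "synthetic",
                   years = start_year + tt,
                   abundances = exp(log(start_abundance) + r_true * tt + eps))
}

#' Qualitative category implied by a latent annual rate
#'
#' Generator-side partition: rates at or below -5 percent per year are a
#' Decrease, at or above +5 an Increase, otherwise Stable. Unlike the
#' model's overlapping censoring intervals this partition is disjoint: the
#' overlap belongs to the observation model, not to the truth.
#'
#' @param rate_pct annual rate(s) of change in percent per year.
#' @return Character vector of categories.
#' @export
categorize_trend <- function(rate_pct) {
  if (any(!is.finite(rate_pct))) stop_input("rate must be finite")
  ifelse(rate_pct <= -5, "Decrease", ifelse(rate_pct >= 5, "Increase",
                                            "Stable"))
}

#' Remove covariate cells completely at random
#'
#' Each covariate cell is set to missing independently with probability
#' `missing_rate`; at least one observed value is always retained per
#' column so downstream imputation stays defined.
#'
#' @param covariates wide covariate table (first column `population_id`).
#' @param missing_rate probability in `[0, 1)`.
#' @param seed integer seed; the missingness mask is reproducible.
#' @return The table with `NA` cells.
#' @export
inject_missingness <- function(covariates, missing_rate, seed = 1) {
  if (!(missing_rate >= 0 && missing_rate < 1))
    stop_input("missing_rate must lie in [0, 1)")
  if (missing_rate == 0) return(covariates)
  cols <- setdiff(names(covariates), "population_id")
  with_seed(seed, {
    for (cl in cols) {
      mis <- runif(nrow(covariates)) < missing_rate
      if (all(mis)) mis[sample(length(mis), 1)] <- FALSE
      covariates[[cl]][mis] <- NA_real_
    }
    covariates
  })
}
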