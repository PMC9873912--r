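#' z-transform a covariate column
#'
#' Centres and scales by the mean and sample sd (n - 1 denominator) of the
#' non-missing entries; missing entries stay missing. The returned mean and
#' sd allow back-transformation, which the counterfactual scenarios rely on
#' to express "raw zero" on the standardized scale.
#'
#' @param values raw covariate column (may contain `NA`).
#' @return A list with `x` (standardized column), `mean`, and `sd`.
#' @export
z_transform <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2) stop_input("need at least 2 non-missing values")
  m <- mean(obs)
  s <- sd(obs)
  if (!(s > 0)) stop_input("cannot standardize a constant column")
  list(x = (values - m) / s, mean = m, sd = s)
}

# window helpers: a monitoring window is list(start_year, end_year)
as_window <- function(w) {
  if (is.numeric(w) && length(w) == 2) w <- list(start_year = w[1],
                                                 end_year = w[2])
  if (!all(c("start_year", "end_year") %in% names(w)))
    stop_input("a window needs start_year and end_year")
  if (w$start_year > w$end_year)
    stop_input("window start_year must be <= end_year")
  w
}

#' Extend a monitoring window backwards by a covariate lag
#'
#' Time-varying covariates are summarised over the population monitoring
#' period; a lag of L years extends the start of that period backwards by L
#' (a 1990-2000 window with a 10-year lag captures covariates over
#' 1980-2000), reflecting delayed population responses to environmental
#' change.
#'
#' @param window `list(start_year, end_year)` or `c(start, end)`.
#' @param lag_years non-negative lag in years.
#' @return The lagged window, same shape as the input.
#' @export
apply_lag_window <- function(window, lag_years) {
  if (!is.finite(lag_years) || lag_years < 0)
    stop_input("lag_years must be non-negative")
  w <- as_window(window)
  w$start_year <- w$start_year - lag_years
  if (is.numeric(window) && length(window) == 2)
    return(c(w$start_year, w$end_year))
  w
}

#' Mean months per year exceeding a pre-industrial baseline threshold
#'
#' The climate-extremes metric: the threshold is the mean plus two standard
#' deviations of the monthly values over the baseline period (by default the
#' pre-industrial 1901-1920 window), and the statistic is the number of
#' window months strictly above that threshold divided by the number of
#' window years. Applies identically to extreme-heat and drought series.
#' Adding a constant to the whole series leaves the result unchanged, since
#' the threshold shifts with it.
#'
#' @param monthly_series data.frame with columns `year`, `month`, `value`.
#' @param baseline,window monitoring windows (`list(start_year, end_year)`
#'   or `c(start, end)`).
#' @return Mean exceedance months per year over the window.
#' @export
exceedance_months <- function(monthly_series, baseline, window) {
  need <- c("year", "month", "value")
  if (!all(need %in% names(monthly_series)))
    stop_input("monthly series needs columns: ", paste(need, collapse = ", "))
  b <- as_window(baseline); w <- as_window(window)
  base <- monthly_series$value[monthly_series$year >= b$start_year &
                                 monthly_series$year <= b$end_year]
  if (!length(base)) stop_input("series does not cover the baseline period")
  win <- monthly_series$value[monthly_series$year >= w$start_year &
                                monthly_series$year <= w$end_year]
  if (!length(win)) stop_input("series does not cover the window period")
  threshold <- mean(base) + 2 * sd(base)
  n_years <- w$end_year - w$start_year + 1
  sum(win > threshold) / n_years
}

#' Number of covariate sampling points for a population area
#'
#' Covariates are sampled within a circular zone around each population's
#' centroid, with more points in larger areas: between 13 and 295 points,
#' interpolated linearly in log10 area between the smallest and largest
#' areas (population areas span orders of magnitude, so the log scale is the
#' natural interpolation axis). Monotone non-decreasing in area and always
#' clamped to [13, 295].
#'
#' @param area population area(s), km^2.
#' @param area_min,area_max areas mapped to the 13- and 295-point endpoints.
#' @return Integer count(s) of sampling points.
#' @export
buffer_sampling_points <- function(area, area_min = 10, area_max = 1e6) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop_input("area must be positive")
  if (!(area_min > 0 && area_max > area_min))
    stop_input("need 0 < area_min < area_max")
  frac <- (log10(area) - log10(area_min)) /
    (log10(area_max) - log10(area_min))
  n <- round(13 + (295 - 13) * frac)
  as.integer(pmin(pmax(n, 13), 295))
}

#' Impute missing covariate cells with uncertainty
#'
#' Iterative chained regression: each incomplete column is regressed on the
#' other covariates (current working values), cycling a few sweeps; the
#' final fit supplies the predictive mean for each missing cell, and its
#' uncertainty combines the spread of predictions across bootstrap refits
#' with the residual sd, so every imputed cell gets a strictly positive sd.
#' The (mean, sd) pair is the contract the model consumes: imputed cells
#' enter the likelihood as latent `Normal(mean, sd^2)` covariate values
#' rather than plug-in points. Any imputation method honouring that contract
#' can replace this one.
#'
#' @param covariates wide covariate table (first column `population_id`),
#'   `NA` at missing cells; every column needs >= 2 observed values.
#' @param seed integer seed (bootstrap resampling is reproducible).
#' @param n_boot bootstrap refits used for the imputation sd.
#' @param n_sweeps chained-regression sweeps.
#' @return The table with missing cells filled by their predictive means and
#'   one `<name>__sd` column per covariate (0 at observed cells).
#' @export
impute_covariates <- function(covariates, seed = 1, n_boot = 20,
                              n_sweeps = 3) {
  cols <- setdiff(names(covariates), "population_id")
  X <- as.matrix(covariates[cols])
  if (!is.numeric(X)) stop_input("covariate columns must be numeric")
  n_obs_col <- colSums(!is.na(X))
  if (any(n_obs_col == 0))
    stop_input("column(s) entirely missing: ",
               paste(cols[n_obs_col == 0], collapse = ", "))
  if (any(n_obs_col < 2))
    stop_input("every column needs at least 2 observed values")
  mis <- is.na(X)
  sd_mat <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  if (any(mis)) {
    incomplete <- which(colSums(mis) > 0)
    filled <- X
    for (j in seq_len(ncol(X)))
      filled[mis[, j], j] <- mean(X[, j], na.rm = TRUE)
    with_seed(substream_seed(seed, "imputation"), {
      for (sweep in seq_len(n_sweeps)) {
        for (j in incomplete) {
          obs <- !mis[, j]
          fit <- lm.fit(cbind(1, filled[obs, -j, drop = FALSE]), X[obs, j])
          filled[mis[, j], j] <-
            drop(cbind(1, filled[mis[, j], -j, drop = FALSE]) %*% fit$coefficients)
        }
      }
      for (j in incomplete) {
        obs_i <- which(!mis[, j]); mis_i <- which(mis[, j])
        A_mis <- cbind(1, filled[mis_i, -j, drop = FALSE])
        boot_pred <- matrix(NA_real_, n_boot, length(mis_i))
        resid_sd <- rep(NA_real_, n_boot)
        for (bi in seq_len(n_boot)) {
          take <- sample(obs_i, length(obs_i), replace = TRUE)
          fb <- lm.fit(cbind(1, filled[take, -j, drop = FALSE]), X[take, j])
          boot_pred[bi, ] <- drop(A_mis %*% fb$coefficients)
          dfree <- max(length(take) - length(fb$coefficients), 1)
          resid_sd[bi] <- sqrt(sum(fb$residuals^2) / dfree)
        }
        spread <- apply(boot_pred, 2, sd)
        sd_mat[mis_i, j] <- pmax(sqrt(spread^2 + mean(resid_sd)^2), 1e-6)
      }
      invisible(NULL)
    })
    X <- filled
  }
  out <- data.frame(population_id = covariates$population_id, X,
                    stringsAsFactors = FALSE, check.names = FALSE)
  sd_df <- as.data.frame(sd_mat)
  names(sd_df) <- paste0(cols, "__sd")
  cbind(out, sd_df)
}

#' Standardize a covariate table, keeping the back-transformation constants
#'
#' Applies [z_transform()] to every covariate column and rescales any paired
#' `<name>__sd` imputation-uncertainty columns by the same sd. The centring
#' means and scaling sds are stored as attributes `center` and `scale` and
#' travel with the design into the fitted model, where the counterfactual
#' engine uses them to map raw zero onto the z scale.
#'
#' @param covariates wide covariate table (first column `population_id`).
#' @return The standardized table with `center` and `scale` attributes.
#' @export
standardize_covariates <- function(covariates) {
  cols <- setdiff(names(covariates), "population_id")
  value_cols <- cols[!grepl("__sd$", cols)]
  center <- setNames(numeric(length(value_cols)), value_cols)
  scale <- setNames(numeric(length(value_cols)), value_cols)
  out <- covariates
  for (cl in value_cols) {
    zt <- z_transform(covariates[[cl]])
    out[[cl]] <- zt$x
    center[cl] <- zt$mean
    scale[cl] <- zt$sd
    sd_col <- paste0(cl, "__sd")
    if (sd_col %in% names(covariates)) out[[sd_col]] <- out[[sd_col]] / zt$sd
  }
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}
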