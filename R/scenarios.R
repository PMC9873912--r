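#' Counterfactual scenario specification
#'
#' A scenario names the covariates whose observed values are replaced by
#' their no-change (raw zero) value: no loss in primary habitat, no climate
#' change (extreme heat and drought changes both zeroed), or no growth in
#' human development. Zeroing happens on the raw covariate scale and is
#' re-expressed on the z scale with the stored standardization constants.
#'
#' @param name one of `"no_habitat_loss"`, `"no_climate_change"`,
#'   `"no_hd_growth"`, or `"custom"`.
#' @param zeroed_covariates covariate names to zero (required for
#'   `"custom"`, defaulted otherwise).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("no_habitat_loss", "no_climate_change",
                                   "no_hd_growth", "custom"),
                          zeroed_covariates = NULL) {
  name <- match.arg(name)
  defaults <- list(
    no_habitat_loss = "primary_land_loss",
    no_climate_change = c("change_extreme_heat", "change_drought"),
    no_hd_growth = "change_human_development")
  if (is.null(zeroed_covariates)) {
    if (name == "custom")
      stop_input("custom scenarios must name zeroed_covariates")
    zeroed_covariates <- defaults[[name]]
  }
  structure(list(name = name, zeroed_covariates = zeroed_covariates),
            class = "scenario_spec")
}

#' Counterfactual difference in annual rate of change
#'
#' For every retained draw and population, predicts the annual rate of
#' change with the observed covariates and again with the scenario
#' covariates set to raw zero (interactions involving a zeroed parent are
#' recomputed), keeping the population's random intercepts in both. The
#' reported quantity is the difference counterfactual minus observed: a
#' positive value means the population would have been better off had the
#' zeroed pressure not occurred. Latent (imputed) covariate cells use their
#' posterior draws.
#'
#' @param fit a `carn_fit`.
#' @param scenario a [scenario_spec()].
#' @return An object of class `carn_counterfactual`: `per_population`
#'   (median and 50/95 percent quantiles of the difference per population)
#'   and `pooled` (the same summaries across all populations and draws).
#' @export
counterfactual_diff <- function(fit, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  design <- fit$design
  main <- colnames(design$Xmain)
  zc <- scenario$zeroed_covariates
  bad <- setdiff(zc, main)
  if (length(bad))
    stop_input("scenario covariate(s) not in the model: ",
               paste(bad, collapse = ", "))
  center <- design$center %||% setNames(rep(0, length(main)), main)
  scale <- design$scale %||% setNames(rep(1, length(main)), main)
  if (anyNA(center[zc]) || anyNA(scale[zc]))
    stop_input("missing standardization constants for: ",
               paste(zc[is.na(center[zc])], collapse = ", "))
  z0 <- (0 - center[zc]) / scale[zc]

  B <- beta_draws(fit)
  S <- nrow(B); n <- nrow(design$Xmain)
  zcols <- match(zc, main)
  Pm <- ncol(design$Xmain)

  XM <- if (length(design$mis_row))
    do.call(rbind, lapply(fit$chains, `[[`, "xmis")) else NULL
  # per-draw observed main-effect values (latent cells from their draws)
  Xobs <- lapply(zcols, function(j)
    matrix(design$Xmain[, j], S, n, byrow = TRUE))
  names(Xobs) <- zc
  for (m in seq_along(design$mis_row)) {
    j <- design$mis_col[m] + 1L
    k <- match(j, zcols)
    if (!is.na(k)) Xobs[[k]][, design$mis_row[m] + 1L] <- XM[, m]
  }
  # latent draws are also needed for unzeroed interaction parents
  parent_value <- function(i, j) {
    m <- which(design$mis_row + 1L == i & design$mis_col + 1L == j)
    if (length(m)) XM[, m] else rep(design$Xmain[i, j], S)
  }

  DIFF <- matrix(0, S, n)
  for (k in seq_along(zcols)) {
    j <- zcols[k]
    DIFF <- DIFF + B[, j] * (z0[k] - Xobs[[k]])
  }
  # interactions with at least one zeroed parent
  if (nrow(design$int_pairs)) {
    for (q in seq_len(nrow(design$int_pairs))) {
      a <- design$int_pairs[q, 1]; bcol <- design$int_pairs[q, 2]
      za <- a %in% zcols; zb <- bcol %in% zcols
      if (!za && !zb) next
      for (i in seq_len(n)) {
        xa <- if (za) Xobs[[match(a, zcols)]][, i] else parent_value(i, a)
        xb <- if (zb) Xobs[[match(bcol, zcols)]][, i] else
          parent_value(i, bcol)
        xa_cf <- if (za) z0[match(a, zcols)] else xa
        xb_cf <- if (zb) z0[match(bcol, zcols)] else xb
        DIFF[, i] <- DIFF[, i] + B[, Pm + q] * (xa_cf * xb_cf - xa * xb)
      }
    }
  }
  per_pop <- data.frame(
    population_id = design$population_id,
    median = apply(DIFF, 2, median),
    q25 = apply(DIFF, 2, quantile, 0.25),
    q75 = apply(DIFF, 2, quantile, 0.75),
    q2.5 = apply(DIFF, 2, quantile, 0.025),
    q97.5 = apply(DIFF, 2, quantile, 0.975))
  pooled <- c(median = median(DIFF), q25 = quantile(DIFF, 0.25,
                                                    names = FALSE),
              q75 = quantile(DIFF, 0.75, names = FALSE),
              q2.5 = quantile(DIFF, 0.025, names = FALSE),
              q97.5 = quantile(DIFF, 0.975, names = FALSE))
  structure(list(scenario = scenario, per_population = per_pop,
                 pooled = pooled, draws = DIFF),
            class = "carn_counterfactual")
}

#' @export
print.carn_counterfactual <- function(x, ...) {
  cat(sprintf(
    "Counterfactual '%s' (zeroed: %s)\n  pooled difference in annual rate of change: %.3f [%.3f, %.3f] %%/yr\n",
    x$scenario$name, paste(x$scenario$zeroed_covariates, collapse = ", "),
    x$pooled["median"], x$pooled["q2.5"], x$pooled["q97.5"]))
  invisible(x)
}

#' Human-development pathway
#'
#' An idealised within-country trajectory of the instantaneous change in
#' human development: linear deceleration
#' `dHD(t) = pace + deceleration * (t - midpoint)`, anchored at the period
#' midpoint so the mean over the projection years equals the stated pace,
#' and the implied human development index compounding as
#' `HDI(t+1) = HDI(t) * (1 + dHD(t)/100)` from the initial value. Standard
#' labels: Slow (1.25), Moderate (1.5) and Fast (1.75) percent per year
#' mean pace, shared deceleration -0.02 percent per year per year, initial
#' index 0.2 in 1960, projected to 2020.
#'
#' @param label `"Slow"`, `"Moderate"`, `"Fast"` (sets the default pace) or
#'   any custom label.
#' @param pace mean percent change in human development per year.
#' @param deceleration change in `dHD` per year (negative = slowing).
#' @param hd0 initial human development index in `(0, 1]`.
#' @param start_year,end_year projection period.
#' @return A data.frame (class `hd_pathway`) with columns `year`,
#'   `delta_hd` (percent per year) and `hdi`, plus the parameters as
#'   attributes.
#' @export
hd_pathway <- function(label = "Moderate", pace = NULL, deceleration = -0.02,
                       hd0 = 0.2, start_year = 1960, end_year = 2020) {
  paces <- c(Slow = 1.25, Moderate = 1.5, Fast = 1.75)
  if (is.null(pace)) {
    if (!label %in% names(paces))
      stop_input("pace is required for custom pathway labels")
    pace <- paces[[label]]
  }
  if (pace <= 0) stop_input("pace must be positive")
  if (!(start_year < end_year)) stop_input("start_year must precede end_year")
  if (!(hd0 > 0 && hd0 <= 1)) stop_input("hd0 must lie in (0, 1]")
  years <- start_year:end_year
  midpoint <- (start_year + end_year) / 2
  delta_hd <- pace + deceleration * (years - midpoint)
  hdi <- numeric(length(years))
  hdi[1] <- hd0
  for (t in seq_along(years)[-1]) {
    hdi[t] <- hdi[t - 1] * (1 + delta_hd[t - 1] / 100)
    if (hdi[t] > 1)
      stop_input("pathway drives the human development index above 1 in ",
                 years[t])
  }
  structure(data.frame(year = years, delta_hd = delta_hd, hdi = hdi),
            label = label, pace = pace, deceleration = deceleration,
            hd0 = hd0, midpoint = midpoint,
            class = c("hd_pathway", "data.frame"))
}

#' Project abundance under a human-development pathway
#'
#' Uses the posterior draws of the change-in-human-development effect to
#' project a hypothetical carnivore abundance: per draw, the annual rate is
#' `g(t) = other_terms + beta * z(dHD(t))` with the pathway's change value
#' standardized by the stored covariate constants (all other covariates sit
#' at their mean, i.e. z = 0), and abundance compounds annually as
#' `N(t+1) = N(t) * (1 + g(t)/100)` from the baseline. Trajectories are
#' clipped at 0 (local extinction) and stay there. The band across draws
#' captures the credible interval of the coefficient.
#'
#' @param beta_draws posterior draws of the standardized effect (percent
#'   per year per sd), e.g. `beta_draws(fit)[, "change_human_development"]`
#'   from a fitted model.
#' @param standardization `c(mean, sd)` of the raw change-in-human-
#'   development covariate (percent per year units).
#' @param pathway an [hd_pathway()].
#' @param baseline_abundance abundance at the pathway start (> 0).
#' @param other_terms fixed additional contribution to the annual rate
#'   (percent per year), default 0.
#' @return An object of class `projection_result`: data.frame `trajectory`
#'   with `year`, `median`, `lo95`, `hi95`, plus the pathway.
#' @export
project_abundance <- function(beta_draws, standardization = c(mean = 1.2,
                                                              sd = 0.5),
                              pathway = hd_pathway("Moderate"),
                              baseline_abundance = 100, other_terms = 0) {
  if (!length(beta_draws)) stop_input("empty draw set")
  if (baseline_abundance <= 0)
    stop_input("baseline_abundance must be positive")
  stopifnot(inherits(pathway, "hd_pathway"))
  z <- (pathway$delta_hd - standardization[[1]]) / standardization[[2]]
  n_yr <- nrow(pathway)
  S <- length(beta_draws)
  N <- matrix(0, S, n_yr)
  N[, 1] <- baseline_abundance
  for (t in seq_len(n_yr - 1)) {
    g <- other_terms + beta_draws * z[t]
    N[, t + 1] <- pmax(N[, t] * (1 + g / 100), 0)
  }
  traj <- data.frame(year = pathway$year,
                     median = apply(N, 2, median),
                     lo95 = apply(N, 2, quantile, 0.025),
                     hi95 = apply(N, 2, quantile, 0.975))
  structure(list(trajectory = traj, pathway = pathway,
                 baseline = baseline_abundance, draws = N),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  last <- x$trajectory[nrow(x$trajectory), ]
  cat(sprintf(
    "Abundance projection (%s pathway): baseline %.0f in %d -> median %.1f [%.1f, %.1f] in %d\n",
    attr(x$pathway, "label"), x$baseline, x$trajectory$year[1],
    last$median, last$lo95, last$hi95, last$year))
  tp <- turning_point(x)
  if (!is.null(tp))
    cat(sprintf("  turning point: %d (dHD = %.2f %%/yr)\n", tp$year,
                tp$delta_hd))
  invisible(x)
}

#' Turning point of a projected trajectory
#'
#' The year the median trajectory flips from decline to recovery: the last
#' year of the declining phase once year-over-year changes turn positive
#' (equivalently the interior minimum of the trajectory, with a small
#' relative tolerance so that a rate numerically indistinguishable from
#' zero counts as flat). Absent when the trajectory never flips.
#'
#' @param result a [project_abundance()] result.
#' @param pathway pathway to read `delta_hd` from (defaults to the one
#'   stored in `result`).
#' @return `list(year, delta_hd)`, or `NULL` when no decline-to-recovery
#'   flip occurs.
#' @export
turning_point <- function(result, pathway = NULL) {
  stopifnot(inherits(result, "projection_result"))
  pathway <- pathway %||% result$pathway
  med <- result$trajectory$median
  years <- result$trajectory$year
  ch <- diff(med)
  tol <- 1e-8 * max(abs(med), 1)
  sign_ch <- ifelse(ch > tol, 1L, ifelse(ch < -tol, -1L, 0L))
  neg <- which(sign_ch == -1L)
  pos <- which(sign_ch == 1L)
  if (!length(neg) || !length(pos)) return(NULL)
  first_pos_after <- pos[pos > min(neg)]
  if (!length(first_pos_after)) return(NULL)
  last_neg <- max(neg[neg < min(first_pos_after)])
  year <- years[last_neg + 1L]   # first year after the decline ends
  list(year = year,
       delta_hd = pathway$delta_hd[match(year, pathway$year)])
}
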