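#' Draw from the posterior of the hierarchical trend model
#'
#' Runs the blocked Gibbs sampler over the full model: quantitative records
#' `y_i ~ Normal(mu_i, sigma^2 / w_i + se_i^2)`, censored records through
#' latent responses restricted to their category interval,
#' `mu_i = alpha + sum_j beta_j x_ij + u_genus + u_species + u_subregion +
#' u_country`, latent `Normal(m, s^2)` values for imputed covariate cells,
#' and Kuo-Mallick inclusion indicators `gamma_j ~ Bernoulli(pi)` with
#' `beta_j = gamma_j b_j` on optional and interaction terms. Chains are
#' exactly reproducible given the seed.
#'
#' @param design a [build_design()] result.
#' @param priors a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @param select enable Kuo-Mallick selection (if `FALSE` every term is
#'   always included).
#' @param pin_terms optional character vector of selectable terms whose
#'   indicator is pinned at 1 (they remain in the selection bookkeeping).
#' @return An object of class `carn_fit` holding per-chain draws of the
#'   intercept, slopes `b`, indicators `gamma`, `sigma`, random-intercept
#'   sds and levels, latent censored responses and latent covariate cells,
#'   along with the design and configuration. Use [summary.carn_fit()],
#'   [inclusion_probabilities()], [predict_rate()].
#' @export
sample_posterior <- function(design, priors = prior_spec(),
                             mcmc = mcmc_config(), select = TRUE,
                             pin_terms = NULL) {
  stopifnot(inherits(design, "carn_design"), inherits(priors, "prior_spec"),
            inherits(mcmc, "mcmc_config"))
  if (any(design$n_levels < 2))
    warning("grouping factor(s) with a single level: ",
            paste(names(design$n_levels)[design$n_levels < 2],
                  collapse = ", "))
  pinned <- design$pinned
  if (!is.null(pin_terms)) {
    bad <- setdiff(pin_terms, design$term_names[design$selectable])
    if (length(bad))
      stop_input("pin_terms must name selectable terms; unknown: ",
                 paste(bad, collapse = ", "))
    pinned[design$term_names %in% pin_terms] <- TRUE
  }
  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    chains[[ch]] <- with_seed(
      as.integer((as.numeric(mcmc$seed) + 104729 * ch) %% 2147483647),
      gibbs_chain_cpp(
        y0 = design$y, is_cens = design$is_cens, lim = design$lim,
        Xmain0 = design$Xmain,
        mis_row = design$mis_row, mis_col = design$mis_col,
        mis_mean = design$mis_mean, mis_sd = design$mis_sd,
        int_pairs = matrix(as.integer(design$int_pairs - 1L),
                           ncol = 2),
        selectable = as.integer(design$selectable & select),
        pinned = as.integer(pinned),
        group_idx = design$groups, n_levels = design$n_levels,
        w = design$w, se2 = design$se2,
        slope_sd = priors$slope_sd, intercept_sd = priors$intercept_sd,
        incl_prob = priors$inclusion_prob,
        sigma_scale = priors$sigma_scale, re_scale = priors$re_sd_scale,
        n_iter = mcmc$n_iterations, n_burn = mcmc$n_burnin,
        thin = mcmc$thin, do_select = select))
    colnames(chains[[ch]]$b) <- design$term_names
    colnames(chains[[ch]]$gamma) <- design$term_names
    colnames(chains[[ch]]$sd_re) <- names(design$n_levels)
    colnames(chains[[ch]]$u) <- unlist(lapply(names(design$group_labels),
      function(g) paste0(g, ":", design$group_labels[[g]])))
    if (length(design$mis_row))
      colnames(chains[[ch]]$xmis) <-
        paste0(design$population_id[design$mis_row + 1L], ":",
               colnames(design$Xmain)[design$mis_col + 1L])
    if (sum(design$is_cens))
      colnames(chains[[ch]]$ylat) <-
        design$population_id[design$is_cens == 1]
  }
  fit <- structure(list(chains = chains, design = design, priors = priors,
                        mcmc = mcmc, select = select, pinned = pinned),
                   class = "carn_fit")
  fit$rhat <- fit_rhat(fit)
  fit$converged <- all(fit$rhat < 1.1, na.rm = TRUE)
  if (!fit$converged)
    warning("R-hat above 1.1 for: ",
            paste(names(fit$rhat)[fit$rhat >= 1.1], collapse = ", "))
  fit
}

# stack one scalar/column parameter across chains: iterations x chains
chain_matrix <- function(fit, what, column = NULL) {
  sapply(fit$chains, function(ch) {
    m <- ch[[what]]
    if (is.null(column)) m[, 1] else m[, column]
  })
}

# combined draws (all chains appended) of a named quantity
combined <- function(fit, what, column = NULL) {
  as.vector(chain_matrix(fit, what, column))
}

# model-averaged coefficient draws: beta_j = gamma_j * b_j
beta_draws <- function(fit, term = NULL) {
  b <- do.call(rbind, lapply(fit$chains, `[[`, "b"))
  g <- do.call(rbind, lapply(fit$chains, `[[`, "gamma"))
  out <- b * g
  if (!is.null(term)) {
    if (!all(term %in% colnames(out)))
      stop_input("unknown term(s): ",
                 paste(setdiff(term, colnames(out)), collapse = ", "))
    out <- out[, term, drop = FALSE]
  }
  out
}

fit_rhat <- function(fit) {
  pars <- c("alpha", "sigma")
  out <- c(alpha = rhat(chain_matrix(fit, "alpha")),
           sigma = rhat(chain_matrix(fit, "sigma")))
  for (term in fit$design$term_names) {
    g <- chain_matrix(fit, "gamma", term)
    # beta = gamma * b is the monitored effect
    out[paste0("b:", term)] <- rhat(chain_matrix(fit, "b", term) * g)
  }
  for (g in colnames(fit$chains[[1]]$sd_re))
    out[paste0("sd_", g)] <- rhat(chain_matrix(fit, "sd_re", g))
  out
}

#' Posterior draws of one coefficient
#'
#' Returns either the model-averaged draws `gamma_j * b_j` (the default
#' reporting convention: excluded draws contribute exactly 0) or the
#' conditional-on-inclusion draws (the slope given the term is in the
#' model, which is the natural scale for effect-recovery checks). For terms
#' not under selection the two conventions coincide. When a term was
#' included in fewer than `min_draws` retained draws the conditional set is
#' too small to summarise and the model-averaged draws are returned
#' instead.
#'
#' @param fit a [sample_posterior()] result.
#' @param term one term name.
#' @param conditional return conditional-on-inclusion draws.
#' @param min_draws minimum conditional sample size (default 20).
#' @return Numeric vector of draws (percent per year per sd).
#' @export
coef_draws <- function(fit, term, conditional = FALSE, min_draws = 20) {
  B <- beta_draws(fit, term)[, 1]
  j <- match(term, fit$design$term_names)
  if (is.na(j)) stop_input("unknown term: ", term)
  if (!conditional || !fit$design$selectable[j]) return(B)
  g <- do.call(rbind, lapply(fit$chains, `[[`, "gamma"))[, term]
  if (sum(g == 1) < min_draws) return(B)
  B[g == 1]
}

#' Posterior inclusion probabilities of the selectable terms
#'
#' The mean of each Kuo-Mallick indicator over retained draws: the posterior
#' probability that the optional or interaction term improves fit enough to
#' be kept in the model.
#'
#' @param fit a [sample_posterior()] result.
#' @param terms terms to report (default: all selectable terms). Asking for
#'   a term not under selection is an error.
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
inclusion_probabilities <- function(fit, terms = NULL) {
  sel <- fit$design$term_names[fit$design$selectable]
  if (is.null(terms)) terms <- sel
  bad <- setdiff(terms, sel)
  if (length(bad))
    stop_input("term(s) not under selection: ", paste(bad, collapse = ", "))
  g <- do.call(rbind, lapply(fit$chains, `[[`, "gamma"))
  colMeans(g[, terms, drop = FALSE])
}

#' @describeIn sample_posterior posterior summary table: model-averaged
#'   (`gamma * b`) medians and 50/80/95 percent intervals per term, plus
#'   conditional-on-inclusion medians, inclusion probabilities and R-hat.
#' @param object,x,... method arguments.
#' @export
summary.carn_fit <- function(object, ...) {
  fit <- object
  B <- beta_draws(fit)
  G <- do.call(rbind, lapply(fit$chains, `[[`, "gamma"))
  rows <- lapply(colnames(B), function(term) {
    bb <- B[, term]; gg <- G[, term]
    cond <- if (any(gg == 1)) median(B[gg == 1, term]) else NA_real_
    iv50 <- central_interval(bb, 0.5)
    iv80 <- central_interval(bb, 0.8)
    iv95 <- central_interval(bb, 0.95)
    data.frame(term = term, median = median(bb),
               lo50 = iv50[1], hi50 = iv50[2], lo80 = iv80[1],
               hi80 = iv80[2], lo95 = iv95[1], hi95 = iv95[2],
               conditional_median = cond,
               inclusion = mean(gg),
               selectable = fit$design$selectable[
                 match(term, fit$design$term_names)],
               rhat = fit$rhat[[paste0("b:", term)]])
  })
  coef_table <- do.call(rbind, rows)
  alpha <- combined(fit, "alpha")
  sigma <- combined(fit, "sigma")
  sds <- do.call(rbind, lapply(fit$chains, `[[`, "sd_re"))
  structure(list(
    coefficients = coef_table,
    intercept = c(median = median(alpha), central_interval(alpha, 0.95)),
    sigma = c(median = median(sigma), central_interval(sigma, 0.95)),
    random_sd = apply(sds, 2, median),
    n_draws = length(alpha), converged = fit$converged),
    class = "summary.carn_fit")
}

#' @export
print.summary.carn_fit <- function(x, ...) {
  cat(sprintf("Posterior summary (%d draws%s)\n", x$n_draws,
              if (x$converged) "" else "; CONVERGENCE WARNING"))
  cat(sprintf("  intercept: %.3f [%.3f, %.3f]  sigma: %.3f\n",
              x$intercept[1], x$intercept[2], x$intercept[3], x$sigma[1]))
  df <- x$coefficients[, c("term", "median", "lo95", "hi95", "inclusion")]
  df[-1] <- lapply(df[-1], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.carn_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical trend model fit: %d records, %d terms, %d chains x %d draws%s\n",
    length(x$design$y), length(x$design$term_names), length(x$chains),
    nrow(x$chains[[1]]$b),
    if (x$converged) "" else " (R-hat warning)"))
  invisible(x)
}

#' Posterior predictive rate of change for a covariate profile
#'
#' Computes the linear predictor per retained draw for a supplied set of
#' standardized covariate values; unspecified covariates sit at 0, the mean
#' of a z-transformed covariate, so the default is the marginal prediction
#' at average conditions. Random intercepts are added when group labels are
#' supplied, otherwise predictions are population-level (random effects 0).
#'
#' @param fit a [sample_posterior()] result.
#' @param covariates named numeric vector of standardized main-effect
#'   values; interactions are formed from their parents automatically.
#' @param include optional subset of terms contributing to the prediction
#'   (default all); excluded terms contribute 0.
#' @param groups optional named character vector, e.g.
#'   `c(genus = "gen01", country = "country03")`; unknown labels error.
#' @return A list with `draws`, `median` and central `intervals`
#'   (50/80/95 percent), in percent per year.
#' @export
predict_rate <- function(fit, covariates = NULL, include = NULL,
                         groups = NULL) {
  design <- fit$design
  main <- colnames(design$Xmain)
  xv <- setNames(numeric(length(main)), main)
  if (!is.null(covariates)) {
    bad <- setdiff(names(covariates), main)
    if (length(bad))
      stop_input("unknown covariate name(s): ", paste(bad, collapse = ", "))
    xv[names(covariates)] <- covariates
  }
  xfull <- c(xv, vapply(seq_len(nrow(design$int_pairs)), function(k)
    xv[design$int_pairs[k, 1]] * xv[design$int_pairs[k, 2]], 0))
  names(xfull) <- design$term_names
  if (is.null(include)) include <- design$term_names
  bad <- setdiff(include, design$term_names)
  if (length(bad)) stop_input("unknown term(s): ", paste(bad, collapse = ", "))
  keep <- design$term_names %in% include
  B <- beta_draws(fit)
  draws <- combined(fit, "alpha") + drop(B[, keep, drop = FALSE] %*%
                                           xfull[keep])
  if (!is.null(groups)) {
    U <- do.call(rbind, lapply(fit$chains, `[[`, "u"))
    for (g in names(groups)) {
      lab <- paste0(g, ":", groups[[g]])
      if (!lab %in% colnames(U))
        stop_input("unknown group label: ", g, " = ", groups[[g]])
      draws <- draws + U[, lab]
    }
  }
  list(draws = draws, median = median(draws),
       intervals = data.frame(
         level = c(0.5, 0.8, 0.95),
         lower = c(central_interval(draws, 0.5)[1],
                   central_interval(draws, 0.8)[1],
                   central_interval(draws, 0.95)[1]),
         upper = c(central_interval(draws, 0.5)[2],
                   central_interval(draws, 0.8)[2],
                   central_interval(draws, 0.95)[2])))
}

# per-draw, per-record linear predictor mu (fixed + random effects),
# reconstructed exactly from the stored draws, including latent covariate
# cells and the interactions they feed
fitted_draws <- function(fit, include_random = TRUE) {
  design <- fit$design
  Xbase <- design_matrix(design)
  B <- beta_draws(fit)
  MU <- B %*% t(Xbase) + combined(fit, "alpha")
  if (include_random) {
    U <- do.call(rbind, lapply(fit$chains, `[[`, "u"))
    off <- 0
    for (g in names(design$n_levels)) {
      idx <- design$groups[[g]] + 1L + off
      MU <- MU + U[, idx, drop = FALSE]
      off <- off + design$n_levels[[g]]
    }
  }
  # corrections where the base matrix used imputation means instead of the
  # latent covariate draws
  if (length(design$mis_row)) {
    XM <- do.call(rbind, lapply(fit$chains, `[[`, "xmis"))
    Pm <- ncol(design$Xmain)
    # main-effect corrections
    for (m in seq_along(design$mis_row)) {
      i <- design$mis_row[m] + 1L
      j <- design$mis_col[m] + 1L
      MU[, i] <- MU[, i] + B[, j] * (XM[, m] - design$mis_mean[m])
    }
    # interaction corrections: recompute products with latent parents
    if (nrow(design$int_pairs)) {
      rows_mis <- unique(design$mis_row + 1L)
      for (i in rows_mis) {
        for (k in seq_len(nrow(design$int_pairs))) {
          a <- design$int_pairs[k, 1]; bcol <- design$int_pairs[k, 2]
          ma <- which(design$mis_row + 1L == i & design$mis_col + 1L == a)
          mb <- which(design$mis_row + 1L == i & design$mis_col + 1L == bcol)
          if (!length(ma) && !length(mb)) next
          xa <- if (length(ma)) XM[, ma] else design$Xmain[i, a]
          xb <- if (length(mb)) XM[, mb] else design$Xmain[i, bcol]
          MU[, i] <- MU[, i] + B[, Pm + k] * (xa * xb - Xbase[i, Pm + k])
        }
      }
    }
  }
  MU
}

#' Posterior-mean residuals of the quantitative records
#'
#' @param object a `carn_fit`.
#' @param ... unused.
#' @return Named numeric vector (one element per quantitative record) of
#'   observed minus posterior-mean fitted rates.
#' @export
residuals.carn_fit <- function(object, ...) {
  mu_bar <- colMeans(fitted_draws(object))
  keep <- object$design$is_cens == 0
  setNames(object$design$y[keep] - mu_bar[keep],
           object$design$population_id[keep])
}
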