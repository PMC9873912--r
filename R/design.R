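#' Assemble model inputs from trend records and covariates
#'
#' Matches every trend record to its covariate vector, expands the 23-term
#' design (main effects then interactions), flags qualitative records with
#' their censoring interval, attaches quality weights and optional trend-fit
#' standard errors, marks imputed covariate cells as latent normal
#' measurement-error entries, and builds the nested grouping indices (genus,
#' species-in-genus, subregion, country-in-subregion).
#'
#' @param records trend-record table (see [load_trend_table()] for the
#'   schema); one row per population.
#' @param covariates standardized covariate table from
#'   [standardize_covariates()] (optionally with `<name>__sd` columns from
#'   [impute_covariates()]).
#' @param spec a [model_spec()].
#' @param use_trend_se if `TRUE` and the records carry an `se_pct` column,
#'   each record's trend-fit standard error is folded into its residual sd
#'   in quadrature (`sd_i^2 = sigma^2 / w_i + se_i^2`).
#' @return An object of class `carn_design`.
#' @export
build_design <- function(records, covariates, spec = model_spec(),
                         use_trend_se = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  idx <- match(records$population_id, covariates$population_id)
  if (anyNA(idx))
    stop_input("no covariate vector for population(s): ",
               paste(head(records$population_id[is.na(idx)], 5),
                     collapse = ", "))
  covariates <- covariates[idx, , drop = FALSE]
  main <- c(spec$core_terms, spec$optional_terms)
  missing_cov <- setdiff(main, names(covariates))
  if (length(missing_cov))
    stop_input("unknown covariate name(s): ",
               paste(missing_cov, collapse = ", "))
  n <- nrow(records)
  Xmain <- as.matrix(covariates[main])
  if (anyNA(Xmain))
    stop_input("covariates contain NA; impute before building the design")

  # latent measurement-error cells: wherever an imputation sd is present
  sd_cols <- paste0(main, "__sd")
  Smat <- matrix(0, n, length(main))
  for (j in seq_along(main))
    if (sd_cols[j] %in% names(covariates))
      Smat[, j] <- ifelse(is.na(covariates[[sd_cols[j]]]), 0,
                          covariates[[sd_cols[j]]])
  mis <- which(Smat > 0, arr.ind = TRUE)

  int_pairs <- t(vapply(spec$interaction_terms,
                        function(p) match(p, main), integer(2)))
  if (nrow(int_pairs) == 0) int_pairs <- matrix(integer(0), 0, 2)

  qual <- records$response_kind == "qualitative"
  lim <- matrix(0, n, 2)
  y <- rep(NA_real_, n)
  y[!qual] <- records$pct[!qual]
  for (i in which(qual)) {
    iv <- censor_interval(records$category[i], spec)
    lim[i, ] <- iv
    y[i] <- mean(iv)   # latent initial value
  }
  if (anyNA(y)) stop_input("quantitative record(s) with missing pct")

  w <- weight_precision(records$duration_years, records$n_observations,
                        records$method_class)
  se2 <- rep(0, n)
  if (use_trend_se && "se_pct" %in% names(records)) {
    se <- records$se_pct
    se2 <- ifelse(is.na(se) | qual, 0, se^2)
  }

  groups <- list(genus = factor(records$genus),
                 species = factor(records$species),
                 subregion = factor(records$subregion),
                 country = factor(records$country))
  structure(list(
    y = y, is_cens = as.integer(qual), lim = lim,
    Xmain = Xmain,
    mis_row = if (nrow(mis)) as.integer(mis[, 1] - 1L) else integer(0),
    mis_col = if (nrow(mis)) as.integer(mis[, 2] - 1L) else integer(0),
    mis_mean = if (nrow(mis)) Xmain[mis] else numeric(0),
    mis_sd = if (nrow(mis)) Smat[mis] else numeric(0),
    int_pairs = int_pairs,
    w = w, se2 = se2,
    groups = lapply(groups, function(f) as.integer(f) - 1L),
    group_labels = lapply(groups, levels),
    n_levels = vapply(groups, nlevels, 0L),
    term_names = term_names(spec),
    selectable = c(rep(FALSE, length(spec$core_terms)),
                   rep(TRUE, length(spec$optional_terms)),
                   rep(TRUE, nrow(int_pairs))),
    pinned = rep(FALSE, length(term_names(spec))),
    population_id = records$population_id,
    latitude = records$latitude, longitude = records$longitude,
    species = records$species, genus = records$genus,
    center = attr(covariates, "center"),
    scale = attr(covariates, "scale"),
    spec = spec), class = "carn_design")
}

#' @export
print.carn_design <- function(x, ...) {
  cat(sprintf(
    "Model design: %d records (%d quantitative, %d censored), %d slope terms, %d latent covariate cells\n",
    length(x$y), sum(x$is_cens == 0), sum(x$is_cens == 1),
    length(x$term_names), length(x$mis_row)))
  invisible(x)
}

# point design matrix (latent cells at their imputation means)
design_matrix <- function(design) {
  X <- design$Xmain
  XI <- if (nrow(design$int_pairs))
    sapply(seq_len(nrow(design$int_pairs)), function(k)
      X[, design$int_pairs[k, 1]] * X[, design$int_pairs[k, 2]])
  else matrix(0, nrow(X), 0)
  out <- cbind(X, XI)
  colnames(out) <- design$term_names
  out
}
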