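# trend-record CSV schema (UTF-8, comma-separated, "." decimal, NA missing)
TREND_COLUMNS <- c("population_id", "species", "genus", "country",
                   "subregion", "latitude", "longitude", "area_km2",
                   "start_year", "end_year", "response_kind", "pct",
                   "category", "duration_years", "n_observations",
                   "method_class")

#' Read and validate a trend-record table
#'
#' Validates every row (exactly one of `pct`/`category`, coordinates in
#' range, period ordering, positive duration, method class in 1-3) and
#' reports all offending rows at once rather than failing on the first.
#'
#' @param path CSV file path.
#' @return A validated data.frame of trend records.
#' @export
load_trend_table <- function(path) {
  if (!file.exists(path)) stop_input("trend table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("NA", ""))
  validate_trend_table(df)
}

#' @rdname load_trend_table
#' @param records a trend-record data.frame (e.g. from
#'   [generate_dataset()]).
#' @export
validate_trend_table <- function(records) {
  missing_cols <- setdiff(TREND_COLUMNS, names(records))
  if (length(missing_cols))
    stop_input("trend table lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  errs <- character(0)
  bad <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows))
      errs <<- c(errs, paste0(msg, " (rows ",
                              paste(head(rows, 10), collapse = ", "),
                              if (length(rows) > 10) ", ..." else "", ")"))
  }
  has_pct <- !is.na(records$pct)
  has_cat <- !is.na(records$category) & records$category != ""
  bad(has_pct & has_cat, "both pct and category present")
  bad(!has_pct & !has_cat, "neither pct nor category present")
  bad(records$response_kind == "quantitative" & !has_pct,
      "quantitative record without pct")
  bad(records$response_kind == "qualitative" & !has_cat,
      "qualitative record without category")
  bad(has_cat & !records$category %in%
        c("Increase", "Stable", "Decrease", NA),
      "unknown category")
  bad(records$latitude < -90 | records$latitude > 90, "latitude out of range")
  bad(records$longitude < -180 | records$longitude > 180,
      "longitude out of range")
  bad(records$start_year > records$end_year, "start_year after end_year")
  bad(records$duration_years <= 0, "non-positive duration")
  bad(records$n_observations < 1, "n_observations below 1")
  bad(!records$method_class %in% 1:3, "method_class outside 1-3")
  if (length(errs))
    stop_input("invalid trend table:\n  ", paste(errs, collapse = "\n  "))
  records
}

#' @rdname load_trend_table
#' @export
write_trend_table <- function(records, path) {
  write.csv(records[TREND_COLUMNS], path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a wide covariate table
#'
#' @param path CSV with `population_id` plus one numeric column per
#'   covariate (and optional `<name>__sd` columns).
#' @return data.frame.
#' @export
load_covariate_table <- function(path) {
  if (!file.exists(path)) stop_input("covariate table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"population_id" %in% names(df))
    stop_input("covariate table needs a population_id column")
  num <- setdiff(names(df), "population_id")
  notnum <- num[!vapply(df[num], is.numeric, TRUE)]
  if (length(notnum))
    stop_input("non-numeric covariate column(s): ",
               paste(notnum, collapse = ", "))
  df
}

#' Load a pipeline run configuration
#'
#' Reads a YAML file (or accepts a list) and merges it over the defaults:
#' a seeded synthetic dataset, the default model specification and priors,
#' a short demonstration MCMC, the three standard counterfactual scenarios
#' and the three standard development pathways.
#'
#' @param config path to a YAML file, or a list of overrides.
#' @return A fully populated configuration list (class `run_config`).
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    seed = 1,
    output_dir = "carntrend-run",
    trend_file = NULL, covariate_file = NULL,
    synthetic = list(n_populations = 400, missing_rate = 0.05),
    mcmc = list(n_chains = 3, n_iterations = 4000, n_burnin = 1000,
                thin = 5),
    priors = list(),
    select = TRUE,
    scenarios = c("no_habitat_loss", "no_climate_change", "no_hd_growth"),
    pathways = c("Slow", "Moderate", "Fast"),
    hd_standardization = c(mean = 1.2, sd = 0.5),
    write_draws = FALSE,
    n_permutations = 99)
  merged <- utils::modifyList(defaults, config)
  class(merged) <- "run_config"
  merged
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

# lightweight stamp so artifacts can be traced to a configuration
config_hash <- function(config) {
  txt <- paste(deparse(config[sort(names(unclass(config)))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1))
          %% 4294967291)
}

#' Run the full analysis pipeline
#'
#' Executes the stages data (simulate, or load the configured CSVs) ->
#' covariates (impute + standardize) -> fit -> diagnostics ->
#' counterfactuals -> projections, writing every artifact under
#' `output_dir` along with a manifest recording the configuration hash,
#' seed, and per-stage status. A failing stage stops the run but leaves the
#' artifacts of completed stages and the manifest in place. Reruns with an
#' identical configuration reproduce identical outputs.
#'
#' @param config a [run_config()], YAML path, or list of overrides.
#' @return Invisibly, a list with `status` (0 on success), `stages`, and
#'   `artifacts`; on failure `status` is 1 and `failed_stage` names the
#'   stage.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list())
  art <- function(...) file.path(config$output_dir, ...)
  state <- new.env(parent = emptyenv())
  stages <- list(
    data = function() {
      if (!is.null(config$trend_file)) {
        state$trends <- load_trend_table(config$trend_file)
        state$covariates <- load_covariate_table(config$covariate_file)
        state$truth <- NULL
      } else {
        syn <- do.call(synthetic_config,
                       c(config$synthetic, list(seed = config$seed)))
        ds <- generate_dataset(syn)
        state$trends <- ds$trends
        state$covariates <- ds$covariates
        state$truth <- ds$truth
        write_json(list(true_rate = ds$truth$true_rate,
                        betas = as.list(ds$truth$betas),
                        intercept = ds$truth$intercept),
                   art("truth.json"))
      }
      write_trend_table(state$trends, art("trends.csv"))
      write.csv(state$covariates, art("covariates.csv"), row.names = FALSE)
      validate_trend_table(state$trends)
      invisible(NULL)
    },
    covariates = function() {
      imp <- impute_covariates(state$covariates, seed = config$seed)
      state$cov_std <- standardize_covariates(imp)
      write.csv(state$cov_std, art("covariates_imputed.csv"),
                row.names = FALSE)
      invisible(NULL)
    },
    fit = function() {
      spec <- model_spec(priors = do.call(prior_spec, config$priors))
      design <- build_design(state$trends, state$cov_std, spec)
      mc <- do.call(mcmc_config, c(config$mcmc, list(seed = config$seed)))
      state$fit <- sample_posterior(design, spec$priors, mc,
                                    select = config$select)
      sm <- summary(state$fit)
      write_json(list(intercept = as.list(sm$intercept),
                      sigma = as.list(sm$sigma),
                      random_sd = as.list(sm$random_sd),
                      coefficients = sm$coefficients,
                      inclusion =
                        as.list(inclusion_probabilities(state$fit))),
                 art("fit_summary.json"))
      if (isTRUE(config$write_draws)) {
        B <- beta_draws(state$fit)
        long <- data.frame(
          draw = rep(seq_len(nrow(B)), ncol(B)),
          parameter = rep(colnames(B), each = nrow(B)),
          value = as.vector(B))
        write.csv(long, art("draws.csv"), row.names = FALSE)
      }
      invisible(NULL)
    },
    diagnostics = function() {
      rep <- diagnostics_report(state$fit,
                                n_permutations = config$n_permutations,
                                seed = config$seed)
      write_json(list(max_rhat = max(rep$rhat, na.rm = TRUE),
                      min_ess = min(rep$ess, na.rm = TRUE),
                      morans = rep$morans[c("I", "expected", "p")],
                      lambda = rep$lambda[c("lambda", "p")],
                      conditional_r2 = rep$conditional_r2,
                      marginal_r2 = rep$marginal_r2,
                      ppc = rep$ppc),
                 art("diagnostics.json"))
      invisible(NULL)
    },
    counterfactuals = function() {
      for (sc in config$scenarios) {
        cf <- counterfactual_diff(state$fit, scenario_spec(sc))
        write.csv(cf$per_population,
                  art(paste0("counterfactual_", sc, ".csv")),
                  row.names = FALSE)
      }
      invisible(NULL)
    },
    projections = function() {
      bd <- beta_draws(state$fit)[, "change_human_development"]
      tps <- list()
      for (pw in config$pathways) {
        path <- hd_pathway(pw)
        pr <- project_abundance(bd, config$hd_standardization, path)
        write.csv(pr$trajectory, art(paste0("projection_", pw, ".csv")),
                  row.names = FALSE)
        tp <- turning_point(pr)
        tps[[pw]] <- if (is.null(tp)) "none" else tp
      }
      write_json(tps, art("turning_points.json"))
      invisible(NULL)
    })
  for (nm in names(stages)) {
    res <- tryCatch({ stages[[nm]](); "ok" },
                    error = function(e) conditionMessage(e))
    manifest$stages[[nm]] <- res
    write_json(manifest, art("manifest.json"))
    if (!identical(res, "ok")) {
      warning("pipeline stage '", nm, "' failed: ", res)
      return(invisible(list(status = 1L, failed_stage = nm, error = res,
                            stages = manifest$stages,
                            output_dir = config$output_dir)))
    }
  }
  invisible(list(status = 0L, stages = manifest$stages,
                 output_dir = config$output_dir, fit = state$fit))
}
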