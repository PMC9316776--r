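# End-to-end workflow: describe -> fit the requested families -> compare ->
# report effects for the selected model, writing a reproducible artifact
# bundle (JSON/CSV) to an output directory.

# FNV-1a 32-bit hash of a string, for the manifest's config fingerprint
.fnv1a <- function(s) {
  h <- 0x811c9dc5
  for (b in utf8ToInt(s)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime, split to stay exact in doubles
    hi <- h %/% 65536; lo2 <- h %% 65536
    h <- (lo2 * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  path
}

#' Configure a pipeline run
#'
#' Exactly one of `input` (a CSV path plus `schema`) or `truth` (a
#' [truth_config()] for simulate-first mode) must be given.
#'
#' @param input CSV path of an existing dataset.
#' @param schema Schema for `input` (path or list, see [read_schema()]).
#' @param truth A [truth_config()] to simulate from instead.
#' @param families Families to fit (default all six).
#' @param count_covariates,zero_covariates,random_intercept,random_slopes,
#'   random_zero_intercept Model structure shared by every family (zero-part
#'   settings apply only to the zi/hurdle families); defaults are taken from
#'   `truth` when simulating.
#' @param seed Seed for the stochastic stages.
#' @param out_dir Output directory for the bundle.
#' @param control A [fit_control()].
#' @param verbose Print stage progress.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, schema = NULL, truth = NULL,
                       families = MLCOUNT_FAMILIES,
                       count_covariates = NULL, zero_covariates = NULL,
                       random_intercept = TRUE, random_slopes = character(),
                       random_zero_intercept = FALSE,
                       seed = 1L, out_dir = tempfile("mlcount_run_"),
                       control = fit_control(), verbose = TRUE) {
  if (is.null(input) == is.null(truth)) {
    stop("exactly one of `input` or `truth` must be set", call. = FALSE)
  }
  if (!is.null(input) && is.null(schema)) {
    stop("`input` mode needs a `schema`", call. = FALSE)
  }
  families <- match.arg(families, MLCOUNT_FAMILIES, several.ok = TRUE)
  if (!is.null(truth)) {
    if (is.null(count_covariates)) count_covariates <- truth$count_covariates
    if (is.null(zero_covariates)) zero_covariates <- truth$zero_covariates
  }
  structure(
    list(input = input, schema = schema, truth = truth, families = families,
         count_covariates = count_covariates %||% character(),
         zero_covariates = zero_covariates %||% character(),
         random_intercept = random_intercept,
         random_slopes = random_slopes,
         random_zero_intercept = random_zero_intercept,
         seed = as.integer(seed), out_dir = out_dir, control = control,
         verbose = verbose),
    class = "run_config"
  )
}

#' Run the full describe/fit/compare/report pipeline
#'
#' Emits, in order: a validation report, the outcome frequency table, group
#' summaries for every categorical covariate (and the grouping column), one
#' fit JSON per family, a comparison CSV (deviance/AIC/BIC per family), an
#' effect report for the AIC-best model, and a manifest recording package
#' version, seed and the full configuration (so the bundle can be rerun
#' exactly). A stage failure aborts with a stage-named error; outputs from
#' completed stages are retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the dataset, fits, comparison, effect
#'   report and output file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  say <- function(...) if (config$verbose) message("[mlcount] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
    say(sprintf("stage %-12s %6.1fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  data <- stage("load", {
    if (!is.null(config$truth)) {
      sim <- simulate_counts(config$truth, seed = config$seed)
      sim$data
    } else {
      load_dataset(config$input, config$schema, quiet = !config$verbose)
    }
  })
  paths$validation <- .write_json(data$validation,
                                  file.path(config$out_dir, "validation.json"))

  freq <- stage("describe", frequency_table(data))
  paths$frequency <- .write_json(
    list(counts = as.list(freq$counts),
         percentages = as.list(round(freq$percentages, 1)),
         n = freq$n, mean = freq$mean, variance = freq$variance,
         dispersion_ratio = freq$dispersion_ratio,
         skewness = freq$skewness, kurtosis = freq$kurtosis),
    file.path(config$out_dir, "frequency.json"))

  cat_covs <- names(Filter(function(cv) cv$type == "categorical",
                           data$covariates))
  summaries <- lapply(c(data$group, cat_covs),
                      function(nm) group_summary(data, nm))
  names(summaries) <- c(data$group, cat_covs)
  paths$group_summaries <- .write_json(
    lapply(summaries, function(s) s$rows),
    file.path(config$out_dir, "group_summaries.json"))

  fits <- list()
  for (fam in config$families) {
    has_zero <- fam %in% c("zip", "zinb", "hp", "hnb")
    spec <- model_spec(
      fam,
      count_covariates = config$count_covariates,
      zero_covariates = if (has_zero) config$zero_covariates else character(),
      random_intercept = config$random_intercept,
      random_slopes = config$random_slopes,
      random_zero_intercept = has_zero && config$random_zero_intercept)
    fit <- stage(paste0("fit:", fam),
                 fit_count_model(data, spec, control = config$control))
    fits[[fam]] <- fit
    paths[[paste0("fit_", fam)]] <- .write_json(
      list(family = fam, seed = config$seed,
           loglik = fit$loglik, deviance = fit$deviance,
           aic = fit$aic, bic = fit$bic, n_params = fit$n_params,
           n_obs = fit$n_obs, n_groups = fit$n_groups,
           converged = fit$converged, grad_norm = fit$optimizer$grad_norm,
           coefficients = wald_table(fit)),
      file.path(config$out_dir, paste0("fit_", fam, ".json")))
  }

  if (length(fits) >= 2) {
    comp <- stage("compare", compare_models(fits))
    best <- comp$best_by_aic
  } else {
    f <- fits[[1]]
    comp <- list(rows = data.frame(family = f$spec$family,
                                   deviance = f$deviance, aic = f$aic,
                                   bic = f$bic, n_params = f$n_params,
                                   converged = f$converged),
                 best_by_aic = f$spec$family,
                 best_by_bic = f$spec$family,
                 best_by_deviance = f$spec$family, ties = character())
    best <- f$spec$family
  }
  comp_csv <- file.path(config$out_dir, "comparison.csv")
  utils::write.csv(comp$rows, comp_csv, row.names = FALSE, quote = FALSE)
  paths$comparison <- comp_csv

  eff <- stage("report", effect_report(fits[[best]]))
  paths$effects <- .write_json(
    list(family = best, seed = config$seed, effects = eff),
    file.path(config$out_dir, "effect_report.json"))

  cfg_json <- as.character(jsonlite::toJSON(
    list(mode = if (is.null(config$truth)) "input" else "simulate",
         input = config$input, truth = config$truth,
         families = config$families,
         count_covariates = config$count_covariates,
         zero_covariates = config$zero_covariates,
         random_intercept = config$random_intercept,
         random_slopes = config$random_slopes,
         random_zero_intercept = config$random_zero_intercept,
         seed = config$seed, n_quad = config$control$n_quad),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE))
  paths$manifest <- .write_json(
    list(package = "mlcount",
         version = as.character(utils::packageVersion("mlcount")),
         seed = config$seed, config_hash = .fnv1a(cfg_json),
         config = jsonlite::fromJSON(cfg_json, simplifyVector = FALSE),
         best_by_aic = best),
    file.path(config$out_dir, "manifest.json"))

  invisible(list(data = data, frequency = freq, summaries = summaries,
                 fits = fits, comparison = comp, effects = eff,
                 best = best, paths = paths, out_dir = config$out_dir))
}
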