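# Reading and validating mother-level survey tables, and building the design
# matrices the model equations consume. Covariates are declared up front in a
# schema (YAML/JSON or an R list): categorical covariates carry an explicit
# level list and reference level; continuous covariates are used on their raw
# scale unless standardisation is requested in the model spec.

#' Read a covariate schema
#'
#' A schema declares the outcome column, the group (cluster) column, and each
#' covariate as either categorical (with `levels` and a `reference`) or
#' continuous. Accepted as a YAML or JSON file path, or an already-parsed
#' list with the same shape.
#'
#' @param schema File path or list with fields `outcome`, `group`,
#'   `covariates` (list of `{name, type, levels, reference}`).
#' @return Validated schema list of class `"mlcount_schema"`.
#' @export
read_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1) {
    if (!file.exists(schema)) {
      stop("schema file not found: ", schema, call. = FALSE)
    }
    schema <- if (grepl("\\.json$", schema, ignore.case = TRUE)) {
      jsonlite::fromJSON(schema, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(schema)
    }
  }
  if (!is.list(schema) || is.null(schema$outcome) || is.null(schema$group)) {
    stop("schema must declare `outcome` and `group` columns", call. = FALSE)
  }
  covs <- schema$covariates %||% list()
  for (cv in covs) {
    if (is.null(cv$name) || is.null(cv$type)) {
      stop("each covariate needs `name` and `type`", call. = FALSE)
    }
    if (!cv$type %in% c("categorical", "continuous")) {
      stop("covariate `", cv$name, "`: type must be categorical or continuous",
           call. = FALSE)
    }
    if (cv$type == "categorical") {
      if (is.null(cv$levels) || is.null(cv$reference)) {
        stop("categorical covariate `", cv$name,
             "` needs `levels` and `reference`", call. = FALSE)
      }
      if (!cv$reference %in% cv$levels) {
        stop("covariate `", cv$name, "`: reference level `", cv$reference,
             "` is not among its levels", call. = FALSE)
      }
    }
  }
  names(covs) <- vapply(covs, `[[`, "", "name")
  schema$covariates <- covs
  class(schema) <- "mlcount_schema"
  schema
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a mother-level survey dataset
#'
#' Reads a CSV (header row, RFC-4180) against a declared schema, enforcing
#' that the outcome is a non-negative integer count, that categorical values
#' are among their declared levels, and dropping (and counting) rows with
#' missing values in any modelled column.
#'
#' @param path CSV file path, or a `data.frame` already in memory.
#' @param schema Schema as accepted by [read_schema()].
#' @param quiet Suppress the dropped-rows message.
#' @return A `survey_dataset`: list with `records` (validated data.frame),
#'   `outcome`, `group`, `covariates` (schema declarations), `n`, `m`,
#'   `group_levels`, and a `validation` report (rows read/dropped, level
#'   tables) serialisable with [validation_report()].
#' @export
load_dataset <- function(path, schema, quiet = FALSE) {
  schema <- read_schema(schema)
  df <- if (is.data.frame(path)) {
    path
  } else {
    if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  needed <- c(schema$outcome, schema$group, names(schema$covariates))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("schema error: declared column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rows_read <- nrow(df)

  # complete-case filter over modelled columns only
  used <- df[needed]
  empty <- vapply(used, function(x) is.na(x) | (is.character(x) & !is.na(x) & x == ""),
                  logical(rows_read))
  keep <- if (rows_read == 1) !any(empty) else rowSums(empty) == 0
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  if (!nrow(df)) stop("data error: no complete rows remain", call. = FALSE)

  y <- df[[schema$outcome]]
  if (!is.numeric(y) || any(y < 0) || any(y != floor(y))) {
    stop("data error: outcome `", schema$outcome,
         "` must be a non-negative integer count", call. = FALSE)
  }
  df[[schema$outcome]] <- as.integer(y)
  df[[schema$group]] <- as.character(df[[schema$group]])

  level_tables <- list()
  for (cv in schema$covariates) {
    x <- df[[cv$name]]
    if (cv$type == "categorical") {
      x <- as.character(x)
      bad <- which(!x %in% cv$levels)
      if (length(bad)) {
        stop("data error: column `", cv$name, "`, row ", bad[1],
             ": unknown level `", x[bad[1]], "`", call. = FALSE)
      }
      df[[cv$name]] <- x
      level_tables[[cv$name]] <- table(factor(x, levels = cv$levels))
    } else {
      if (!is.numeric(x)) {
        stop("data error: continuous covariate `", cv$name,
             "` is not numeric", call. = FALSE)
      }
    }
  }

  group_levels <- sort(unique(df[[schema$group]]))
  if (!quiet && n_dropped > 0) {
    message("load_dataset: dropped ", n_dropped,
            " row(s) with missing modelled values")
  }
  structure(
    list(
      records = df,
      outcome = schema$outcome,
      group = schema$group,
      covariates = schema$covariates,
      n = nrow(df),
      m = length(group_levels),
      group_levels = group_levels,
      validation = list(
        rows_read = rows_read,
        rows_kept = nrow(df),
        rows_dropped = n_dropped,
        groups = as.list(table(df[[schema$group]])),
        level_tables = lapply(level_tables, as.list)
      )
    ),
    class = "survey_dataset"
  )
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset> n =", x$n, "rows in m =", x$m, "groups\n")
  cat("  outcome:", x$outcome, " group:", x$group, "\n")
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param data A `survey_dataset`.
#' @param path Output file; omit to return the JSON string.
#' @export
validation_report <- function(data, path = NULL) {
  js <- jsonlite::toJSON(data$validation, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else {
    js
  }
}

#' Write a survey dataset back to CSV
#'
#' Round-trips through [load_dataset()]: reloading the written file with the
#' same schema reproduces outcome, group, and covariate values exactly.
#'
#' @param data A `survey_dataset`.
#' @param path Output CSV path.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specify a two-level count model
#'
#' @param family One of `"poisson"`, `"nb"`, `"zip"`, `"zinb"`, `"hp"`
#'   (hurdle Poisson), `"hnb"` (hurdle negative binomial).
#' @param count_covariates Covariate names entering the count-part (log rate)
#'   linear predictor.
#' @param zero_covariates Covariate names entering the zero-part (logit)
#'   predictor; must be empty unless the family has a zero/hurdle part. The
#'   two sets need not coincide.
#' @param random_intercept Give each group a count-part random intercept.
#' @param random_slopes Covariate names whose count-part coefficients vary by
#'   group. Each must contribute a single design column (continuous, or
#'   categorical with two levels).
#' @param random_zero_intercept Give each group a zero-part random intercept
#'   (zero-inflated / hurdle families only).
#' @param standardize Centre and scale continuous covariates before fitting;
#'   default keeps the raw scale so coefficients read per natural unit.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family,
                       count_covariates = character(),
                       zero_covariates = character(),
                       random_intercept = TRUE,
                       random_slopes = character(),
                       random_zero_intercept = FALSE,
                       standardize = FALSE) {
  family <- match.arg(family, MLCOUNT_FAMILIES)
  has_zero <- family %in% c("zip", "zinb", "hp", "hnb")
  if (!has_zero && length(zero_covariates)) {
    stop("family `", family, "` has no zero part; `zero_covariates` must be empty",
         call. = FALSE)
  }
  if (!has_zero && random_zero_intercept) {
    stop("family `", family, "` has no zero part; no zero-part random intercept",
         call. = FALSE)
  }
  if (length(random_slopes) && !all(random_slopes %in% count_covariates)) {
    stop("random slopes must be among `count_covariates`", call. = FALSE)
  }
  structure(
    list(family = family,
         count_covariates = count_covariates,
         zero_covariates = zero_covariates,
         random_intercept = random_intercept,
         random_slopes = random_slopes,
         random_zero_intercept = random_zero_intercept,
         standardize = standardize),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$family, "\n")
  cat("  count part: ~", paste(c("1", x$count_covariates), collapse = " + "), "\n")
  if (x$family %in% c("zip", "zinb", "hp", "hnb")) {
    cat("  zero part:  ~", paste(c("1", x$zero_covariates), collapse = " + "), "\n")
  }
  re <- c(if (x$random_intercept) "intercept", x$random_slopes,
          if (x$random_zero_intercept) "zero intercept")
  cat("  random (by group):", paste(re, collapse = ", "), "\n")
  invisible(x)
}

# Expand one declared covariate into design columns (treatment coding
# against its declared reference level).
.covariate_columns <- function(data, name, standardize = FALSE) {
  cv <- data$covariates[[name]]
  if (is.null(cv)) {
    stop("spec error: covariate `", name, "` is not declared in the dataset",
         call. = FALSE)
  }
  x <- data$records[[name]]
  if (cv$type == "continuous") {
    if (standardize) x <- as.numeric(scale(x))
    m <- matrix(x, ncol = 1, dimnames = list(NULL, name))
  } else {
    others <- setdiff(cv$levels, cv$reference)
    m <- vapply(others, function(l) as.numeric(x == l), numeric(length(x)))
    m <- matrix(m, ncol = length(others),
                dimnames = list(NULL, paste0(name, ":", others)))
  }
  m
}

.design_part <- function(data, covariates, standardize) {
  cols <- lapply(covariates, .covariate_columns, data = data,
                 standardize = standardize)
  X <- cbind(`(Intercept)` = rep(1, data$n))
  for (m in cols) X <- cbind(X, m)
  X
}

#' Build design matrices for a model specification
#'
#' Constructs the count-part matrix `X`, the zero-part matrix `Z` (families
#' with a zero/hurdle part), and the random-effects designs `R_count` /
#' `R_zero`. All matrices start with an all-ones intercept column; a
#' categorical covariate with L levels contributes L-1 indicators against its
#' declared reference. Column order follows the spec's covariate order, so
#' the construction is deterministic.
#'
#' @param data A `survey_dataset`.
#' @param spec A [model_spec()].
#' @return List of class `design_matrices`: `X`, `Z` (or `NULL`), `R_count`
#'   (n x d matrix of random-effect covariate values; first column ones when
#'   a random intercept is present), `R_zero`, `group_index` (1..m per row),
#'   `group_levels`, `y`, and `column_names`.
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(data, "survey_dataset"), inherits(spec, "model_spec"))
  X <- .design_part(data, spec$count_covariates, spec$standardize)
  has_zero <- spec$family %in% c("zip", "zinb", "hp", "hnb")
  Z <- if (has_zero) .design_part(data, spec$zero_covariates, spec$standardize)
       else NULL

  re_cols <- list()
  if (spec$random_intercept) {
    re_cols[["(Intercept)"]] <- rep(1, data$n)
  }
  for (nm in spec$random_slopes) {
    cm <- .covariate_columns(data, nm, spec$standardize)
    if (ncol(cm) != 1) {
      stop("random slope `", nm, "` must contribute exactly one design column",
           call. = FALSE)
    }
    re_cols[[colnames(cm)]] <- cm[, 1]
  }
  R_count <- if (length(re_cols)) do.call(cbind, re_cols) else NULL
  R_zero <- if (has_zero && spec$random_zero_intercept) {
    matrix(1, data$n, 1, dimnames = list(NULL, "(Intercept)"))
  } else NULL

  group_index <- match(data$records[[data$group]], data$group_levels)
  structure(
    list(X = X, Z = Z, R_count = R_count, R_zero = R_zero,
         group_index = group_index, group_levels = data$group_levels,
         y = data$records[[data$outcome]],
         column_names = list(count = colnames(X), zero = colnames(Z),
                             random_count = colnames(R_count),
                             random_zero = colnames(R_zero))),
    class = "design_matrices"
  )
}
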