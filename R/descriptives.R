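# Descriptive stage: outcome frequency distribution with moments,
# overdispersion diagnosis (variance vs mean, observed vs Poisson-implied
# zeros), and per-category outcome summaries.

.outcome_vector <- function(data) {
  if (inherits(data, "survey_dataset")) {
    data$records[[data$outcome]]
  } else if (is.numeric(data)) {
    .check_counts(data)
    as.integer(data)
  } else {
    stop("expected a survey_dataset or an integer outcome vector",
         call. = FALSE)
  }
}

#' Frequency distribution and moments of the count outcome
#'
#' Tabulates every outcome value from 0 to the observed maximum with
#' percentages, and reports mean, variance (sample, n-1 denominator),
#' skewness and kurtosis. Because conventions differ, skewness and excess
#' kurtosis are given in both the population (`m3/m2^1.5`, `m4/m2^2 - 3`)
#' and adjusted-sample forms.
#'
#' @param data A `survey_dataset` or a bare non-negative integer vector.
#' @return A `frequency_table`: `counts`, `percentages`, `n`, `mean`,
#'   `variance`, `skewness`/`kurtosis` (each a list with `population` and
#'   `sample`), and `dispersion_ratio` (variance/mean).
#' @export
frequency_table <- function(data) {
  y <- .outcome_vector(data)
  n <- length(y)
  if (n < 1) stop("data error: empty outcome", call. = FALSE)
  counts <- tabulate(y + 1L, nbins = max(y) + 1L)
  names(counts) <- 0:max(y)
  mu <- mean(y)
  m2 <- mean((y - mu)^2)
  m3 <- mean((y - mu)^3)
  m4 <- mean((y - mu)^4)
  v <- if (n > 1) stats::var(y) else 0
  skew_pop <- if (m2 > 0) m3 / m2^1.5 else NA_real_
  kurt_pop <- if (m2 > 0) m4 / m2^2 - 3 else NA_real_
  skew_smp <- if (n > 2 && m2 > 0) skew_pop * sqrt(n * (n - 1)) / (n - 2)
              else NA_real_
  kurt_smp <- if (n > 3 && m2 > 0) {
    ((n + 1) * kurt_pop + 6) * (n - 1) / ((n - 2) * (n - 3))
  } else NA_real_
  structure(
    list(counts = counts, percentages = 100 * counts / n, n = n,
         mean = mu, variance = v,
         skewness = list(population = skew_pop, sample = skew_smp),
         kurtosis = list(population = kurt_pop, sample = kurt_smp),
         dispersion_ratio = if (mu > 0) v / mu else NA_real_),
    class = "frequency_table"
  )
}

#' @export
print.frequency_table <- function(x, digits = 3, ...) {
  cat("Outcome frequency distribution (n =", x$n, ")\n")
  tab <- data.frame(value = names(x$counts), frequency = as.integer(x$counts),
                    percent = sprintf("%.1f", x$percentages))
  print(tab, row.names = FALSE)
  cat(sprintf("mean %.4g  variance %.4g  variance/mean %.4g\n",
              x$mean, x$variance, x$dispersion_ratio))
  cat(sprintf("skewness %.4g (population) / %.4g (sample)\n",
              x$skewness$population, x$skewness$sample))
  cat(sprintf("excess kurtosis %.4g (population) / %.4g (sample)\n",
              x$kurtosis$population, x$kurtosis$sample))
  invisible(x)
}

#' Per-level outcome summaries for a categorical covariate
#'
#' One row per declared level with its count, outcome mean and sample
#' variance. The grouping (region) column itself may also be summarised.
#'
#' @param data A `survey_dataset`.
#' @param covariate Name of a declared categorical covariate, or the group
#'   column.
#' @return A `group_summary`: `by` and a data.frame `rows` with columns
#'   `level`, `n`, `mean`, `variance`.
#' @export
group_summary <- function(data, covariate) {
  stopifnot(inherits(data, "survey_dataset"))
  y <- data$records[[data$outcome]]
  if (identical(covariate, data$group)) {
    lev <- data$group_levels
    x <- data$records[[data$group]]
  } else {
    cv <- data$covariates[[covariate]]
    if (is.null(cv)) {
      stop("spec error: covariate `", covariate, "` is not declared",
           call. = FALSE)
    }
    if (cv$type != "categorical") {
      stop("spec error: `", covariate,
           "` is continuous; bin it before summarising", call. = FALSE)
    }
    lev <- cv$levels
    x <- data$records[[covariate]]
  }
  rows <- do.call(rbind, lapply(lev, function(l) {
    yi <- y[x == l]
    data.frame(level = l, n = length(yi),
               mean = if (length(yi)) mean(yi) else NA_real_,
               variance = if (length(yi) > 1) stats::var(yi) else NA_real_)
  }))
  structure(list(by = covariate, rows = rows), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Outcome by", x$by, "\n")
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Overdispersion and excess-zero diagnosis
#'
#' Compares the outcome variance with its mean (equidispersion holds under
#' the Poisson law) and the observed zero fraction with the Poisson-implied
#' `exp(-mean)`.
#'
#' @param data A `survey_dataset` or integer outcome vector.
#' @return List with `mean`, `variance`, `dispersion_ratio`, `overdispersed`
#'   (ratio > 1), `zero_fraction`, `poisson_zero_fraction`, `excess_zeros`.
#' @export
overdispersion_report <- function(data) {
  y <- .outcome_vector(data)
  if (length(y) < 2) stop("need at least two observations", call. = FALSE)
  mu <- mean(y)
  v <- stats::var(y)
  zf <- mean(y == 0)
  pz <- exp(-mu)
  structure(
    list(mean = mu, variance = v,
         dispersion_ratio = if (mu > 0) v / mu else NA_real_,
         overdispersed = isTRUE(v > mu),
         zero_fraction = zf, poisson_zero_fraction = pz,
         excess_zeros = zf - pz),
    class = "overdispersion_report"
  )
}

#' @export
print.overdispersion_report <- function(x, ...) {
  cat(sprintf("mean %.4g, variance %.4g, ratio %.3g -> %s\n",
              x$mean, x$variance, x$dispersion_ratio,
              if (x$overdispersed) "overdispersed" else "not overdispersed"))
  cat(sprintf("zeros %.1f%% observed vs %.1f%% Poisson-implied (excess %+.1f pp)\n",
              100 * x$zero_fraction, 100 * x$poisson_zero_fraction,
              100 * x$excess_zeros))
  invisible(x)
}
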