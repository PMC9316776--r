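# Model comparison by deviance/AIC/BIC and translation of coefficients into
# incidence-rate ratios (count part) and odds ratios of a structural zero
# (zero part).

#' Deviance, AIC and BIC from a log-likelihood
#'
#' `deviance = -2 logLik`, `AIC = deviance + 2k`, `BIC = deviance +
#' k log(n)` with `n` the number of observations (not groups).
#'
#' @param loglik Maximised log-likelihood.
#' @param n_params Number of free parameters `k` (>= 1).
#' @param n_obs Number of observations `n` (>= 1).
#' @return List with `deviance`, `aic`, `bic`.
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  if (n_params < 1) stop("`n_params` must be >= 1", call. = FALSE)
  if (n_obs < 1) stop("`n_obs` must be >= 1", call. = FALSE)
  dev <- -2 * loglik
  list(deviance = dev, aic = dev + 2 * n_params,
       bic = dev + n_params * log(n_obs))
}

#' Compare fitted models by information criteria
#'
#' Builds a comparison table across model families fitted to the same
#' dataset, sorted by AIC. Non-converged fits stay in the table but are
#' flagged and cannot be "best". Exact ties on a criterion are broken by
#' family name order and both rows flagged as tied.
#'
#' @param fits List of `mlcount_fit` objects (>= 2) on the same data, or a
#'   pre-computed data.frame with columns `family`, `deviance`, `aic`,
#'   `bic` (and optionally `n_params`, `converged`) such as a published
#'   criteria table.
#' @return A `comparison_table`: `rows` (data.frame sorted by AIC) plus
#'   `best_by_aic`, `best_by_bic`, `best_by_deviance` and `ties`.
#' @export
compare_models <- function(fits) {
  if (is.data.frame(fits)) {
    rows <- fits
    if (is.null(rows$converged)) rows$converged <- TRUE
    if (is.null(rows$n_params)) rows$n_params <- NA_integer_
  } else {
    if (length(fits) < 2) stop("need at least two fits", call. = FALSE)
    n_obs <- vapply(fits, `[[`, 0, "n_obs")
    if (length(unique(n_obs)) != 1) {
      stop("comparison error: fits use different numbers of observations",
           call. = FALSE)
    }
    rows <- do.call(rbind, lapply(fits, function(f) {
      data.frame(family = f$spec$family, deviance = f$deviance,
                 aic = f$aic, bic = f$bic, n_params = f$n_params,
                 converged = f$converged)
    }))
  }
  rows <- rows[order(rows$aic, rows$family), , drop = FALSE]
  rownames(rows) <- NULL
  ok <- rows[rows$converged, , drop = FALSE]
  if (!nrow(ok)) stop("no converged fits to compare", call. = FALSE)
  pick <- function(col) {
    v <- ok[[col]]
    winners <- ok$family[v == min(v)]
    sort(winners)[1]
  }
  ties <- unique(unlist(lapply(c("deviance", "aic", "bic"), function(col) {
    v <- ok[[col]]
    if (sum(v == min(v)) > 1) ok$family[v == min(v)] else character()
  })))
  structure(
    list(rows = rows,
         best_by_aic = pick("aic"),
         best_by_bic = pick("bic"),
         best_by_deviance = pick("deviance"),
         ties = ties),
    class = "comparison_table"
  )
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("Model comparison (lower is better)\n")
  print(x$rows, row.names = FALSE, digits = 6)
  cat("best by deviance:", x$best_by_deviance,
      "| AIC:", x$best_by_aic, "| BIC:", x$best_by_bic, "\n")
  if (length(x$ties)) cat("tied families:", paste(x$ties, collapse = ", "), "\n")
  invisible(x)
}

#' Rate-ratio / odds-ratio effect report
#'
#' Exponentiates the fixed coefficients: count-part rows become incidence
#' rate ratios (multiplicative effects on the expected count), zero-part
#' rows become odds ratios of a structural zero. Wald 95% intervals are
#' formed on the coefficient scale (`estimate +/- 1.96 SE`) and then
#' exponentiated; ratios are also given rounded to 3 significant figures
#' for reporting.
#'
#' @param fit An `mlcount_fit`.
#' @return Data.frame with `part`, `term`, `estimate`, `ratio`,
#'   `ratio_rounded`, `ci_low`, `ci_high`, `p_value`.
#' @export
effect_report <- function(fit) {
  wt <- wald_table(fit)
  wt <- wt[wt$part %in% c("count", "zero"), , drop = FALSE]
  zc <- stats::qnorm(0.975)
  out <- data.frame(
    part = wt$part, term = wt$term, estimate = wt$estimate,
    ratio = exp(wt$estimate),
    ratio_rounded = signif(exp(wt$estimate), 3),
    ci_low = exp(wt$estimate - zc * wt$std_error),
    ci_high = exp(wt$estimate + zc * wt$std_error),
    p_value = wt$p_value
  )
  out
}
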