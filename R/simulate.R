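# Synthetic two-level survey generator. Emulates the structure of a DHS-style
# mother-level extract: ~11 regions of unequal size, a zero-heavy overdispersed
# count outcome, categorical and continuous covariates, an optional
# Bernoulli zero (structural or hurdle) component with its own covariates,
# and independent normal region-level random intercepts/slopes.
#
# RNG: R's Mersenne-Twister with inversion for normals (the R >= 3.6 default),
# driven by a single integer seed; identical (config, seed) pairs reproduce
# the dataset exactly.

#' Describe the generating truth for a synthetic two-level count dataset
#'
#' @param family Outcome family, one of `"poisson"`, `"nb"`, `"zip"`,
#'   `"zinb"`, `"hp"`, `"hnb"`.
#' @param group_sizes Integer vector of per-group sample sizes (its length is
#'   the number of groups `m`).
#' @param covariates Named list of generating laws: either
#'   `list(type = "categorical", levels =, probs =, reference =)` or
#'   `list(type = "continuous", mean =, sd =)`.
#' @param count_covariates,zero_covariates Covariate names entering each
#'   linear predictor (zero part only for zi/hurdle families).
#' @param beta Named true count-part coefficients; names must match the
#'   design columns (`"(Intercept)"`, continuous names, `"cov:level"`).
#' @param gamma Named true zero-part coefficients (logit scale).
#' @param alpha True NB2 dispersion (`alpha = 1/nu`); ignored by the Poisson
#'   families.
#' @param re_variances Named true random-effect variances `delta^2`: names
#'   among `"(Intercept)"`, count-part design columns (random slopes), and
#'   `"zero:(Intercept)"`.
#' @param group_labels Optional group names (defaults `g01`, `g02`, ...).
#' @param seed Default seed used when [simulate_counts()] is not given one.
#' @return A `truth_config` object.
#' @export
truth_config <- function(family, group_sizes, covariates = list(),
                         count_covariates = names(covariates),
                         zero_covariates = character(),
                         beta, gamma = NULL, alpha = 0,
                         re_variances = c("(Intercept)" = 0),
                         group_labels = NULL, seed = 1L) {
  family <- match.arg(family, MLCOUNT_FAMILIES)
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 1)) stop("group sizes must be >= 1", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (any(re_variances < 0)) stop("random-effect variances must be >= 0",
                                  call. = FALSE)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (identical(cv$type, "categorical")) {
      if (abs(sum(cv$probs) - 1) > 1e-8) {
        stop("covariate `", nm, "`: level probabilities must sum to 1",
             call. = FALSE)
      }
      if (is.null(cv$reference)) covariates[[nm]]$reference <- cv$levels[1]
    }
  }
  has_zero <- family %in% c("zip", "zinb", "hp", "hnb")
  if (has_zero && is.null(gamma)) {
    stop("family `", family, "` needs zero-part coefficients `gamma`",
         call. = FALSE)
  }
  if (is.null(group_labels)) {
    group_labels <- sprintf("g%02d", seq_along(group_sizes))
  }
  structure(
    list(family = family, group_sizes = group_sizes, m = length(group_sizes),
         covariates = covariates, count_covariates = count_covariates,
         zero_covariates = zero_covariates, beta = beta, gamma = gamma,
         alpha = alpha, re_variances = re_variances,
         group_labels = group_labels, seed = as.integer(seed)),
    class = "truth_config"
  )
}

# model_spec implied by a truth config (random structure read off the
# variance names)
.truth_spec <- function(config) {
  re <- names(config$re_variances)
  slopes <- setdiff(re, c("(Intercept)", "zero:(Intercept)"))
  # map design-column names back to covariate names for the spec
  slope_covs <- vapply(slopes, function(s) sub(":.*$", "", s), "")
  model_spec(config$family,
             count_covariates = config$count_covariates,
             zero_covariates = config$zero_covariates,
             random_intercept = "(Intercept)" %in% re,
             random_slopes = unname(slope_covs),
             random_zero_intercept = "zero:(Intercept)" %in% re)
}

# draw one covariate column for n rows
.draw_covariate <- function(cv, n) {
  if (identical(cv$type, "categorical")) {
    sample(cv$levels, n, replace = TRUE, prob = cv$probs)
  } else {
    stats::rnorm(n, cv$mean, cv$sd)
  }
}

.rztrunc <- function(n, family, mu, alpha) {
  # zero-truncated draw by inverse cdf conditional on Y > 0
  if (family == "hp") {
    p0 <- stats::dpois(0, mu)
    u <- p0 + stats::runif(n) * (1 - p0)
    stats::qpois(pmin(u, 1 - 1e-16), mu)
  } else {
    size <- 1 / max(alpha, .ALPHA_POISSON_LIMIT / 10)
    if (alpha < .ALPHA_POISSON_LIMIT) {
      p0 <- stats::dpois(0, mu)
      u <- p0 + stats::runif(n) * (1 - p0)
      stats::qpois(pmin(u, 1 - 1e-16), mu)
    } else {
      p0 <- stats::dnbinom(0, mu = mu, size = size)
      u <- p0 + stats::runif(n) * (1 - p0)
      stats::qnbinom(pmin(u, 1 - 1e-16), mu = mu, size = size)
    }
  }
}

#' Simulate a two-level count dataset from a known truth
#'
#' For each group, independent normal random effects are drawn with the
#' configured variances; each row's linear predictors are built from the true
#' coefficients plus its group's effects; the outcome is then drawn from the
#' configured family. For zero-inflated families a structural zero is first
#' drawn with probability `phi = plogis(eta_zero)`; for hurdle families a
#' zero is drawn with probability `p0 = plogis(eta_zero)` and positives come
#' from the zero-truncated count law.
#'
#' @param config A [truth_config()].
#' @param seed Integer seed; defaults to the config's.
#' @return A `simulated_dataset`: `data` (a `survey_dataset`), `truth`
#'   (the config), `latent` (per-group drawn effects, columns named like the
#'   variance names), and `component_labels` (per-row logical: structural
#'   zero for zi families, hurdle zero for hurdle families, NA otherwise).
#' @export
simulate_counts <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "truth_config"))
  set.seed(as.integer(seed))
  n <- sum(config$group_sizes)
  group <- rep(config$group_labels, config$group_sizes)

  rec <- list()
  for (nm in names(config$covariates)) {
    rec[[nm]] <- .draw_covariate(config$covariates[[nm]], n)
  }
  rec <- as.data.frame(rec, optional = TRUE)
  if (!ncol(rec)) rec <- data.frame(row.names = seq_len(n))
  rec$region <- group
  rec$deaths <- 0L

  schema <- list(
    outcome = "deaths", group = "region",
    covariates = lapply(names(config$covariates), function(nm) {
      cv <- config$covariates[[nm]]
      if (identical(cv$type, "categorical")) {
        list(name = nm, type = "categorical", levels = cv$levels,
             reference = cv$reference)
      } else {
        list(name = nm, type = "continuous")
      }
    })
  )
  data <- load_dataset(rec, schema, quiet = TRUE)
  spec <- .truth_spec(config)
  dm <- build_design(data, spec)

  # random effects: one column per variance term, one row per group
  re_names <- names(config$re_variances)
  u <- matrix(0, config$m, length(re_names),
              dimnames = list(config$group_labels, re_names))
  for (k in seq_along(re_names)) {
    u[, k] <- stats::rnorm(config$m, 0, sqrt(config$re_variances[k]))
  }
  count_re <- setdiff(re_names, "zero:(Intercept)")
  gi <- dm$group_index
  eta_count <- drop(dm$X %*% config$beta[colnames(dm$X)])
  if (length(count_re)) {
    eta_count <- eta_count +
      rowSums(dm$R_count[, count_re, drop = FALSE] *
                u[gi, count_re, drop = FALSE])
  }
  has_zero <- config$family %in% c("zip", "zinb", "hp", "hnb")
  eta_zero <- NULL
  if (has_zero) {
    eta_zero <- drop(dm$Z %*% config$gamma[colnames(dm$Z)])
    if ("zero:(Intercept)" %in% re_names) {
      eta_zero <- eta_zero + u[gi, "zero:(Intercept)"]
    }
  }

  lam <- exp(eta_count)
  alpha <- config$alpha
  size <- if (alpha >= .ALPHA_POISSON_LIMIT) 1 / alpha else Inf
  draw_count <- function(k, mu) {
    if (config$family %in% c("poisson", "zip", "hp") ||
        alpha < .ALPHA_POISSON_LIMIT) {
      stats::rpois(k, mu)
    } else {
      stats::rnbinom(k, mu = mu, size = size)
    }
  }

  labels <- rep(NA, n)
  if (config$family %in% c("poisson", "nb")) {
    y <- draw_count(n, lam)
  } else if (config$family %in% c("zip", "zinb")) {
    pz <- stats::plogis(eta_zero)
    z <- stats::runif(n) < pz
    y <- integer(n)
    y[!z] <- draw_count(sum(!z), lam[!z])
    labels <- z
  } else {
    pz <- stats::plogis(eta_zero)
    z <- stats::runif(n) < pz
    y <- integer(n)
    if (any(!z)) y[!z] <- .rztrunc(sum(!z), config$family, lam[!z], alpha)
    labels <- z
  }
  data$records$deaths <- as.integer(y)

  structure(
    list(data = data, truth = config, latent = u, component_labels = labels,
         seed = as.integer(seed)),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  y <- x$data$records[[x$data$outcome]]
  cat("<simulated_dataset>", x$truth$family, "family, n =", x$data$n,
      "rows, m =", x$data$m, "groups\n")
  cat(sprintf("  zeros %.1f%%, mean %.3f, var %.3f (seed %d)\n",
              100 * mean(y == 0), mean(y), stats::var(y), x$seed))
  invisible(x)
}

#' Default truth emulating a national survey of infant deaths per mother
#'
#' Eleven regions with the unequal sizes of a 2016 national demographic and
#' health survey (10,547 mothers in total), a zero-inflated negative binomial
#' outcome whose zero fraction falls around 70% with variance well above the
#' mean, covariates (residence, mother's age, age at first birth, birth
#' weight, breastfeeding, birth order, household size) with effects near the
#' signs and magnitudes reported for such surveys, and a region-level random
#' intercept. The count-part and zero-part intercepts are calibrated so the
#' marginal outcome matches that survey's shape (~70% zeros, variance/mean
#' close to 1.9).
#'
#' @param seed Seed stored in the config.
#' @return A [truth_config()].
#' @export
edhs_like_default <- function(seed = 1L) {
  sizes <- c(Tigray = 1023, Afar = 1043, Amhara = 972, Oromia = 1569,
             Somali = 1496, `Benishangul Gumuz` = 867, SNNPR = 1269,
             Gambela = 703, Harari = 603, `Addis Ababa` = 460,
             `Dire Dawa` = 542)
  covs <- list(
    residence = list(type = "categorical", levels = c("rural", "urban"),
                     probs = c(0.8134, 0.1866), reference = "rural"),
    mother_age = list(type = "continuous", mean = 28, sd = 7),
    age_first_birth = list(type = "continuous", mean = 19, sd = 3.5),
    birth_weight = list(type = "continuous", mean = 3200, sd = 300),
    breastfeeding = list(type = "categorical", levels = c("yes", "no"),
                         probs = c(0.9, 0.1), reference = "yes"),
    birth_order = list(type = "categorical",
                       levels = c("first", "2-4", "5+"),
                       probs = c(0.204, 0.438, 0.358), reference = "first"),
    household_size = list(type = "continuous", mean = 5, sd = 2)
  )
  beta <- c(`(Intercept)` = 3.28, `residence:urban` = 0.2,
            mother_age = -0.022, age_first_birth = -0.026,
            birth_weight = -0.0013, `breastfeeding:no` = 0.36,
            `birth_order:2-4` = 0.9, `birth_order:5+` = 1.641,
            household_size = 0.063)
  gamma <- c(`(Intercept)` = -1.345, `residence:urban` = 0.46,
             `breastfeeding:no` = 1.368)
  truth_config(
    family = "zinb", group_sizes = sizes, covariates = covs,
    count_covariates = names(covs),
    zero_covariates = c("residence", "breastfeeding"),
    beta = beta, gamma = gamma, alpha = 1.0,
    re_variances = c("(Intercept)" = 0.15),
    group_labels = names(sizes), seed = seed
  )
}
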