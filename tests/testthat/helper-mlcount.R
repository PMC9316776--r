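# Shared fixtures, all built in code at test time.

# printed frequency distribution of infant deaths per mother in the survey
# the package's defaults emulate (counts of mothers with k = 0..6 deaths)
table1_counts <- c(`0` = 7570, `1` = 1346, `2` = 992, `3` = 435,
                   `4` = 134, `5` = 52, `6` = 18)

table1_outcome <- function() {
  rep(0:6, times = table1_counts)
}

# minimal schema used by the toy CSV fixtures
toy_schema <- function() {
  list(
    outcome = "deaths",
    group = "region",
    covariates = list(
      list(name = "residence", type = "categorical",
           levels = c("rural", "urban"), reference = "rural"),
      list(name = "age", type = "continuous")
    )
  )
}

toy_csv <- function(path = tempfile(fileext = ".csv"),
                    deaths = c(0, 0, 1, 2, 0),
                    region = c("A", "A", "B", "B", "A"),
                    residence = c("rural", "urban", "rural", "rural", "urban"),
                    age = c(25, 30, 35, 28, 22)) {
  utils::write.csv(
    data.frame(deaths = deaths, region = region,
               residence = residence, age = age),
    path, row.names = FALSE, quote = FALSE)
  path
}

# small one-covariate truth configs per family for fitting tests
small_truth <- function(family, m = 20, nj = 50, beta0 = 0.3, beta1 = 0.5,
                        gamma0 = -1, gamma1 = 0.6, alpha = 0.7,
                        re_var = 0.3, seed = 1) {
  has_zero <- family %in% c("zip", "zinb", "hp", "hnb")
  truth_config(
    family = family, group_sizes = rep(nj, m),
    covariates = list(x = list(type = "continuous", mean = 0, sd = 1)),
    count_covariates = "x",
    zero_covariates = if (has_zero) "x" else character(),
    beta = c(`(Intercept)` = beta0, x = beta1),
    gamma = if (has_zero) c(`(Intercept)` = gamma0, x = gamma1) else NULL,
    alpha = alpha,
    re_variances = c(`(Intercept)` = re_var),
    seed = seed
  )
}

small_spec <- function(family, ...) {
  has_zero <- family %in% c("zip", "zinb", "hp", "hnb")
  model_spec(family, count_covariates = "x",
             zero_covariates = if (has_zero) "x" else character(), ...)
}

# brute-force 1-D integration oracle for the marginal likelihood of a small
# dataset with a single random intercept: trapezoid rule on a wide fine grid
# in log space, independent of the quadrature code path
grid_marginal_loglik <- function(y, eta_fix, eta_zero, family, alpha, delta,
                                 group, n_grid = 20001, width = 12) {
  m <- max(group)
  total <- 0
  b <- seq(-width * max(delta, 0.3), width * max(delta, 0.3),
           length.out = n_grid)
  h <- b[2] - b[1]
  for (j in seq_len(m)) {
    rows <- which(group == j)
    nr <- length(rows)
    # evaluate all (grid point, observation) pairs in one vectorised call
    eta <- rep(eta_fix[rows], each = n_grid) + b
    yv <- rep(y[rows], each = n_grid)
    ez <- if (!is.null(eta_zero)) rep(eta_zero[rows], each = n_grid)
    ll <- switch(family,
      poisson = poisson_logpmf(yv, exp(eta)),
      nb = nb_logpmf(yv, exp(eta), alpha),
      zip = zip_logpmf(yv, exp(eta), plogis(ez)),
      zinb = zinb_logpmf(yv, exp(eta), alpha, plogis(ez)),
      hp = hurdle_poisson_logpmf(yv, exp(eta), plogis(ez)),
      hnb = hurdle_nb_logpmf(yv, exp(eta), alpha, plogis(ez)))
    lg <- rowSums(matrix(ll, n_grid, nr)) + dnorm(b, 0, delta, log = TRUE)
    mx <- max(lg)
    w <- rep(1, n_grid); w[c(1, n_grid)] <- 0.5
    total <- total + mx + log(sum(w * exp(lg - mx)) * h)
  }
  total
}

# a minimal fit-shaped object so coefficient-report arithmetic can be
# exercised on published coefficient values without refitting
stub_fit <- function(beta, se_beta, gamma = NULL, se_gamma = NULL) {
  structure(
    list(estimates = list(beta = beta, gamma = gamma, alpha = NULL,
                          re_variances = NULL),
         std_errors = list(beta = se_beta, gamma = se_gamma,
                           alpha = NULL, re_variances = NULL)),
    class = "mlcount_fit")
}
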