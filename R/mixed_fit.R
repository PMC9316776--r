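# Maximum marginal likelihood for two-level count models: the group-level
# normal random effects are integrated out of each family's likelihood by
# adaptive Gauss-Hermite quadrature (a single random term) or a group-wise
# Laplace approximation (several terms), and the resulting marginal
# log-likelihood is maximised by BFGS over an unconstrained parameter vector.
#
# Parameter packing (theta), in order:
#   beta        count-part fixed coefficients (one per column of X)
#   gamma       zero-part fixed coefficients (zi/hurdle families only)
#   log(alpha)  NB2 dispersion (nb/zinb/hnb only)
#   log(delta)  one per random-effect term (count intercept, slopes, then
#               the zero-part intercept), delta = random-effect SD
# Variances/dispersion live on the log scale so the optimiser is box-free;
# log(delta) = -Inf is admitted as the exact delta = 0 boundary.

.RE_ACTIVE_MIN <- 1e-6  # SD below which a random term is treated as zero

.layout <- function(dm, spec) {
  fam <- spec$family
  has_zero <- fam %in% c("zip", "zinb", "hp", "hnb")
  has_alpha <- fam %in% c("nb", "zinb", "hnb")
  p <- ncol(dm$X)
  q <- if (has_zero) ncol(dm$Z) else 0L
  count_re <- if (!is.null(dm$R_count)) colnames(dm$R_count) else character()
  zero_re <- if (!is.null(dm$R_zero)) "zero:(Intercept)" else character()
  re_names <- c(count_re, zero_re)
  d <- length(re_names)
  idx_beta <- seq_len(p)
  idx_gamma <- if (q) p + seq_len(q) else integer()
  idx_alpha <- if (has_alpha) p + q + 1L else integer()
  idx_delta <- if (d) p + q + length(idx_alpha) + seq_len(d) else integer()
  list(family = fam, has_zero = has_zero, has_alpha = has_alpha,
       p = p, q = q, d = d, re_names = re_names,
       n_count_re = length(count_re), has_zero_re = length(zero_re) > 0,
       idx_beta = idx_beta, idx_gamma = idx_gamma,
       idx_alpha = idx_alpha, idx_delta = idx_delta,
       n_params = p + q + length(idx_alpha) + d,
       par_names = c(paste0("count:", colnames(dm$X)),
                     if (q) paste0("zero:", colnames(dm$Z)),
                     if (has_alpha) "log_alpha",
                     if (d) paste0("log_delta:", re_names)))
}

.theta_unpack <- function(theta, lay) {
  ld <- theta[lay$idx_delta]
  list(beta = theta[lay$idx_beta],
       gamma = if (lay$q) theta[lay$idx_gamma] else NULL,
       alpha = if (lay$has_alpha) exp(unname(theta[lay$idx_alpha])) else 0,
       log_delta = ld,
       delta = exp(ld))
}

.check_theta <- function(theta, lay) {
  if (length(theta) != lay$n_params) {
    stop("theta must have length ", lay$n_params, " (",
         paste(lay$par_names, collapse = ", "), ")", call. = FALSE)
  }
  fixed <- setdiff(seq_along(theta), lay$idx_delta)
  if (any(!is.finite(theta[fixed]))) {
    stop("non-finite value in theta", call. = FALSE)
  }
  ld <- theta[lay$idx_delta]
  if (any(is.nan(ld) | ld == Inf)) {
    stop("non-finite value in theta (log delta may only be -Inf)",
         call. = FALSE)
  }
}

# evaluation environment shared by every likelihood call of a fit
.fit_env <- function(dm) {
  list(y = dm$y, lgyp1 = lgamma(dm$y + 1), gi = dm$group_index,
       m = length(dm$group_levels), n = length(dm$y),
       X = dm$X, Z = dm$Z, Rc = dm$R_count,
       group_levels = dm$group_levels,
       rows_by_group = split(seq_along(dm$y), dm$group_index))
}

# per-group sums of observation log-likelihoods at count-part random-effect
# values bmat (m x n_active_count), using a prebuilt pass over active rows
.group_loglik_pass <- function(env, pass, Ra, gia, eta_a, bmat) {
  eta <- eta_a
  if (!is.null(Ra)) {
    eta <- eta + rowSums(Ra * bmat[gia, , drop = FALSE])
  }
  out <- pass$const_group
  gs <- rowsum(pass$f(eta), gia, reorder = TRUE)
  out[as.integer(rownames(gs))] <- out[as.integer(rownames(gs))] + drop(gs)
  out
}

# Laplace approximation, one group at a time, for several active terms.
# Inner modes found by nlminb; curvature by numeric Hessian at the mode.
.laplace_groups <- function(env, lay, eta_fc, eta_fz, alpha, delta_a, active,
                            start = NULL, return_modes = FALSE) {
  da <- length(active)
  ca <- active[active <= lay$n_count_re]
  zero_act <- lay$has_zero_re && (lay$d %in% active)
  total <- 0
  modes <- matrix(0, env$m, da)
  for (j in seq_len(env$m)) {
    rows <- env$rows_by_group[[j]]
    yj <- env$y[rows]; lgj <- env$lgyp1[rows]
    efc <- eta_fc[rows]
    efz <- if (!is.null(eta_fz)) eta_fz[rows] else NULL
    Rj <- if (length(ca)) env$Rc[rows, ca, drop = FALSE] else NULL
    gj <- function(b) {
      ec <- efc
      if (length(ca)) ec <- ec + drop(Rj %*% b[seq_along(ca)])
      ez <- efz
      if (zero_act) ez <- ez + b[da]
      sum(.obs_loglik(lay$family, yj, lgj, ec, ez, alpha)) +
        sum(stats::dnorm(b, 0, delta_a, log = TRUE))
    }
    neg <- function(b) -gj(b)
    b0 <- if (is.null(start)) numeric(da) else start[j, ]
    opt <- stats::nlminb(b0, neg, control = list(rel.tol = 1e-10))
    H <- stats::optimHess(opt$par, neg)
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) H <- H + diag(abs(min(ev)) + 1e-8, da)
    ld <- determinant(H, logarithm = TRUE)$modulus
    total <- total + (-opt$objective) + 0.5 * da * log(2 * pi) - 0.5 * ld
    modes[j, ] <- opt$par
  }
  if (return_modes) list(loglik = total, modes = modes) else total
}

# the marginal log-likelihood core; cache (an environment) carries
# warm-start posterior modes between successive calls of one optimisation
.marginal_core <- function(theta, env, lay, control, cache = NULL,
                           return_modes = FALSE) {
  up <- .theta_unpack(theta, lay)
  eta_fc <- drop(env$X %*% up$beta)
  eta_fz <- if (lay$has_zero) drop(env$Z %*% up$gamma) else NULL
  active <- which(up$delta > .RE_ACTIVE_MIN)
  zero_act <- lay$has_zero_re && (lay$d %in% active)
  pass <- .make_pass(lay$family, env$y, env$lgyp1, env$gi, env$m,
                     eta_fz, up$alpha)

  if (!length(active)) {
    ll <- sum(pass$const_group) + sum(pass$f(eta_fc[pass$active]))
    if (return_modes) return(list(loglik = ll, modes = matrix(0, env$m, lay$d)))
    return(ll)
  }

  if (length(active) == 1 && !zero_act) {
    # one count-part random term: adaptive Gauss-Hermite quadrature
    dlt <- up$delta[active]
    act <- pass$active
    gia <- env$gi[act]
    eta_a <- eta_fc[act]
    Ra <- env$Rc[act, active, drop = FALSE]
    g <- function(b) {
      .group_loglik_pass(env, pass, Ra, gia, eta_a, matrix(b, ncol = 1)) +
        stats::dnorm(b, 0, dlt, log = TRUE)
    }
    ll_modes <- .aghq_1d(g, env$m, control,
                         start = if (!is.null(cache)) cache$modes else NULL)
    if (!is.null(cache)) cache$modes <- ll_modes$mode
    if (return_modes) {
      modes <- matrix(0, env$m, lay$d)
      modes[, active] <- ll_modes$mode
      return(list(loglik = ll_modes$loglik, modes = modes))
    }
    return(ll_modes$loglik)
  }

  if (length(active) == 1 && zero_act) {
    # zero-part random intercept only: quadrature over the logit scale
    dlt <- up$delta[active]
    g <- function(b) {
      l <- .obs_loglik(lay$family, env$y, env$lgyp1, eta_fc,
                       eta_fz + b[env$gi], up$alpha)
      drop(rowsum(l, env$gi, reorder = TRUE)) +
        stats::dnorm(b, 0, dlt, log = TRUE)
    }
    ll_modes <- .aghq_1d(g, env$m, control,
                         start = if (!is.null(cache)) cache$modes else NULL)
    if (!is.null(cache)) cache$modes <- ll_modes$mode
    if (return_modes) {
      modes <- matrix(0, env$m, lay$d)
      modes[, active] <- ll_modes$mode
      return(list(loglik = ll_modes$loglik, modes = modes))
    }
    return(ll_modes$loglik)
  }

  start <- if (!is.null(cache) && is.matrix(cache$modes) &&
               all(dim(cache$modes) == c(env$m, length(active))))
    cache$modes else NULL
  lp <- .laplace_groups(env, lay, eta_fc, eta_fz, up$alpha,
                        up$delta[active], active, start = start,
                        return_modes = TRUE)
  if (!is.null(cache)) cache$modes <- lp$modes
  if (return_modes) {
    modes <- matrix(0, env$m, lay$d)
    modes[, active] <- lp$modes
    return(list(loglik = lp$loglik, modes = modes))
  }
  lp$loglik
}

# adaptive Gauss-Hermite integration of exp(g) for a scalar random effect,
# vectorised over groups: recentre at the posterior mode, rescale by the
# curvature there, then apply the Hermite rule
.aghq_1d <- function(g, m, control, start = NULL) {
  nm <- .newton_modes_1d(g, m, start = start)
  s <- 1 / sqrt(nm$hess)
  gh <- control$gh
  K <- length(gh$nodes)
  L <- matrix(0, m, K)
  for (k in seq_len(K)) {
    L[, k] <- g(nm$mode + sqrt(2) * s * gh$nodes[k]) + gh$logw[k]
  }
  list(loglik = sum(.row_logsumexp(L) + 0.5 * log(2) + log(s)),
       mode = nm$mode)
}

#' Control settings for the marginal-likelihood machinery
#'
#' @param n_quad Number of adaptive Gauss-Hermite nodes for a
#'   one-dimensional random effect (models with several random terms use a
#'   Laplace approximation instead; raise `n_quad` only to sharpen the 1-D
#'   integral).
#' @param max_iter Maximum BFGS iterations.
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @param grad_eps Relative step for the central-difference gradient.
#' @return A `fit_control` list.
#' @export
fit_control <- function(n_quad = 15, max_iter = 300, reltol = 1e-10,
                        grad_eps = 1e-5) {
  gh <- gauss_hermite(n_quad)
  list(n_quad = n_quad, max_iter = max_iter, reltol = reltol,
       grad_eps = grad_eps,
       gh = list(nodes = gh$nodes, logw = log(gh$weights) + gh$nodes^2))
}

#' Two-level marginal log-likelihood
#'
#' For parameter vector `theta` (see Details) returns
#' `sum_j log Int prod_i f(y_ij | fixed + b) N(b; 0, diag(delta^2)) db`,
#' the random effects integrated out by adaptive Gauss-Hermite quadrature
#' (one random term) or a Laplace approximation (several). With all
#' `delta = 0` this reduces exactly to the fixed-effects log-likelihood.
#'
#' @details `theta` packs, in order: the count-part coefficients (columns of
#' `X`), the zero-part coefficients (zi/hurdle families), `log(alpha)` for
#' the NB families, and one `log(delta)` per random term (`-Inf` allowed,
#' meaning that term's variance is zero).
#'
#' @param data A `survey_dataset`.
#' @param spec A [model_spec()].
#' @param theta Unconstrained parameter vector.
#' @param control A [fit_control()].
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(data, spec, theta, control = fit_control()) {
  dm <- build_design(data, spec)
  lay <- .layout(dm, spec)
  .check_theta(theta, lay)
  env <- .fit_env(dm)
  .marginal_core(theta, env, lay, control)
}

# symmetric central-difference Hessian (step ~ eps^(1/4) scaled per
# coordinate, the usual optimum for second differences)
.num_hess <- function(f, x, h = 1e-4) {
  p <- length(x)
  hh <- h * pmax(1, abs(x))
  f0 <- f(x)
  H <- matrix(0, p, p)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + hh[i]
    xm <- x; xm[i] <- x[i] - hh[i]
    fp[i] <- f(xp); fm[i] <- f(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / hh[i]^2
  }
  if (p > 1) {
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      xpp <- x; xpp[i] <- x[i] + hh[i]; xpp[j] <- x[j] + hh[j]
      xmm <- x; xmm[i] <- x[i] - hh[i]; xmm[j] <- x[j] - hh[j]
      H[i, j] <- H[j, i] <-
        (f(xpp) - fp[i] - fp[j] + 2 * f0 - fm[i] - fm[j] + f(xmm)) /
        (2 * hh[i] * hh[j])
    }
  }
  H
}

.num_grad <- function(f, x, eps) {
  vapply(seq_along(x), function(i) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# documented starting values: count part from a Poisson fixed-effects GLM;
# hurdle zero part from its (exact) logistic GLM; zero-inflation intercept
# from the logit of the observed zero excess; dispersion from moments;
# random-effect SDs at 0.3
.start_values <- function(env, lay, dm) {
  y <- env$y
  beta0 <- tryCatch(
    suppressWarnings(stats::glm.fit(env$X, y,
                                    family = stats::poisson())$coefficients),
    error = function(e) c(log(max(mean(y), 0.05)), numeric(lay$p - 1)))
  beta0[!is.finite(beta0)] <- 0
  th <- beta0
  if (lay$q) {
    if (lay$family %in% c("hp", "hnb")) {
      g0 <- tryCatch(
        suppressWarnings(stats::glm.fit(env$Z, as.numeric(y == 0),
                                        family = stats::binomial())$coefficients),
        error = function(e) c(stats::qlogis(max(mean(y == 0), 0.02)),
                              numeric(lay$q - 1)))
      g0[!is.finite(g0)] <- 0
    } else {
      excess <- mean(y == 0) - exp(-mean(y))
      g0 <- c(stats::qlogis(min(max(excess, 0.02), 0.95)),
              numeric(lay$q - 1))
    }
    th <- c(th, g0)
  }
  if (lay$has_alpha) {
    a0 <- max((stats::var(y) - mean(y)) / max(mean(y)^2, 1e-8), 0.05)
    th <- c(th, log(a0))
  }
  if (lay$d) th <- c(th, rep(log(0.3), lay$d))
  th
}

#' Fit a two-level count regression model
#'
#' Maximises the marginal likelihood of [marginal_loglik()] by BFGS from
#' documented starting values; standard errors come from the inverse of the
#' numerically differentiated observed information at the optimum. The
#' convergence flag reports the optimiser status together with the recorded
#' gradient norm; a singular Hessian yields `NA` standard errors rather
#' than fabricated ones.
#'
#' @param data A `survey_dataset`.
#' @param spec A [model_spec()].
#' @param control A [fit_control()].
#' @param start Optional starting theta (defaults described above).
#' @return An `mlcount_fit` with estimates, standard errors, Wald z/p for
#'   the fixed coefficients, dispersion and random-effect variance
#'   estimates, log-likelihood, deviance, AIC, BIC, and diagnostics.
#' @export
fit_count_model <- function(data, spec, control = fit_control(),
                            start = NULL) {
  stopifnot(inherits(data, "survey_dataset"), inherits(spec, "model_spec"))
  dm <- build_design(data, spec)
  if (min(table(dm$group_index)) < 1) {
    stop("every group needs at least one row", call. = FALSE)
  }
  lay <- .layout(dm, spec)
  env <- .fit_env(dm)
  cache <- new.env(parent = emptyenv())
  negll <- function(th) {
    v <- -.marginal_core(th, env, lay, control, cache)
    if (!is.finite(v)) v <- 1e10  # reject wild trial steps, keep BFGS alive
    v
  }
  gr <- function(th) .num_grad(negll, th, control$grad_eps)

  th0 <- if (is.null(start)) .start_values(env, lay, dm) else start
  .check_theta(th0, lay)
  opt <- stats::optim(th0, negll, gr = gr, method = "BFGS",
                      control = list(maxit = control$max_iter,
                                     reltol = control$reltol))
  theta <- opt$par
  grad <- gr(theta)
  grad_norm <- max(abs(grad))
  converged <- opt$convergence == 0 && is.finite(opt$value)

  H <- tryCatch(.num_hess(negll, theta), error = function(e) NULL)
  vcov_theta <- NULL
  se_theta <- rep(NA_real_, lay$n_params)
  if (!is.null(H)) {
    vcov_theta <- tryCatch(solve((H + t(H)) / 2), error = function(e) NULL)
    if (!is.null(vcov_theta)) {
      dg <- diag(vcov_theta)
      se_theta <- ifelse(is.finite(dg) & dg > 0, sqrt(pmax(dg, 0)), NA_real_)
    }
  }

  up <- .theta_unpack(theta, lay)
  names(up$beta) <- colnames(dm$X)
  if (lay$q) names(up$gamma) <- colnames(dm$Z)
  re_var <- up$delta^2
  names(re_var) <- lay$re_names
  se <- list(
    beta = se_theta[lay$idx_beta],
    gamma = if (lay$q) se_theta[lay$idx_gamma] else NULL,
    # delta method: alpha = exp(la), delta^2 = exp(2 ld)
    alpha = if (lay$has_alpha) up$alpha * se_theta[lay$idx_alpha] else NULL,
    re_variances = if (lay$d) 2 * re_var * se_theta[lay$idx_delta] else NULL
  )
  ll <- -opt$value
  ic <- information_criteria(ll, lay$n_params, env$n)

  structure(
    list(spec = spec, layout = lay,
         estimates = list(beta = up$beta, gamma = up$gamma,
                          alpha = if (lay$has_alpha) up$alpha else NULL,
                          re_variances = if (lay$d) re_var else NULL),
         std_errors = se, theta = theta, vcov_theta = vcov_theta,
         loglik = ll, deviance = ic$deviance, aic = ic$aic, bic = ic$bic,
         n_params = lay$n_params, n_obs = env$n, n_groups = env$m,
         converged = converged,
         n_quad = control$n_quad,
         optimizer = list(method = "BFGS", counts = opt$counts,
                          convergence = opt$convergence,
                          grad_norm = grad_norm, value = opt$value),
         env = env, dm = dm, control = control),
    class = "mlcount_fit"
  )
}

#' @export
print.mlcount_fit <- function(x, ...) {
  cat("<mlcount_fit>", x$spec$family, "| logLik", format(x$loglik),
      "| AIC", format(x$aic), "| BIC", format(x$bic), "\n")
  cat("  n =", x$n_obs, "obs in", x$n_groups, "groups;",
      x$n_params, "parameters;",
      if (x$converged) "converged" else "NOT converged", "\n")
  wt <- wald_table(x)
  print(wt, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Wald test arithmetic for one coefficient
#'
#' @param estimate Coefficient estimate.
#' @param se Its standard error.
#' @return List with `z` (= estimate/se), two-sided normal `p`, and the
#'   star code used at the 0.05 / 0.01 / 0.001 levels.
#' @export
wald_test <- function(estimate, se) {
  z <- estimate / se
  p <- 2 * stats::pnorm(-abs(z))
  stars <- ifelse(is.na(p), "",
           ifelse(p < 0.001, "***",
           ifelse(p < 0.01, "**",
           ifelse(p < 0.05, "*", ""))))
  list(z = z, p = p, stars = stars)
}

#' Coefficient table with Wald tests
#'
#' Per-coefficient estimate, standard error, z = estimate/SE, two-sided
#' normal p-value and significance stars for the fixed count- and zero-part
#' coefficients; the dispersion and random-effect variance estimates are
#' appended with their standard errors (no z/p, as is conventional for
#' variance components). Rows with unavailable SEs keep their estimates but
#' carry `NA` tests.
#'
#' @param fit An `mlcount_fit`.
#' @return A data.frame with columns `part`, `term`, `estimate`,
#'   `std_error`, `z`, `p_value`, `stars`.
#' @export
wald_table <- function(fit) {
  est <- fit$estimates
  se <- fit$std_errors
  rows <- data.frame(part = "count", term = names(est$beta),
                     estimate = unname(est$beta),
                     std_error = unname(se$beta))
  if (!is.null(est$gamma)) {
    rows <- rbind(rows, data.frame(part = "zero", term = names(est$gamma),
                                   estimate = unname(est$gamma),
                                   std_error = unname(se$gamma)))
  }
  wt <- wald_test(rows$estimate, rows$std_error)
  rows$z <- wt$z; rows$p_value <- wt$p; rows$stars <- wt$stars
  if (!is.null(est$alpha)) {
    rows <- rbind(rows, data.frame(part = "dispersion", term = "alpha",
                                   estimate = est$alpha,
                                   std_error = se$alpha,
                                   z = NA_real_, p_value = NA_real_,
                                   stars = ""))
  }
  if (!is.null(est$re_variances)) {
    rows <- rbind(rows, data.frame(part = "random",
                                   term = names(est$re_variances),
                                   estimate = unname(est$re_variances),
                                   std_error = unname(se$re_variances),
                                   z = NA_real_, p_value = NA_real_,
                                   stars = ""))
  }
  rows
}

#' Empirical Bayes group effects and the variance table
#'
#' Posterior modes of each group's random effects at the fitted parameters,
#' with the estimated variance (and its standard error) for each random
#' term -- one row per term declared in the model spec.
#'
#' @param fit An `mlcount_fit`.
#' @return List with `effects` (m x d matrix, one row per group) and
#'   `variances` (data.frame `term`, `variance`, `std_error`).
#' @export
predict_group_effects <- function(fit) {
  lay <- fit$layout
  if (!lay$d) stop("model has no random effects", call. = FALSE)
  res <- .marginal_core(fit$theta, fit$env, lay, fit$control,
                        return_modes = TRUE)
  effects <- res$modes
  dimnames(effects) <- list(fit$env$group_levels, lay$re_names)
  variances <- data.frame(term = lay$re_names,
                          variance = unname(fit$estimates$re_variances),
                          std_error = unname(fit$std_errors$re_variances))
  list(effects = effects, variances = variances)
}
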