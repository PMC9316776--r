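# Closed-form log-probability mass functions for the six count families.
# All six are evaluated in log space throughout: mixtures via log-sum-exp,
# zero-truncation via log(1 - exp(log P0)), so that extreme linear predictors
# (mu up to 1e6, counts up to 1e5, dispersion down to 1e-12) stay finite.

MLCOUNT_FAMILIES <- c("poisson", "nb", "zip", "zinb", "hp", "hnb")

# NB2 dispersion below this is treated as the exact Poisson limit
.ALPHA_POISSON_LIMIT <- 1e-8

.check_counts <- function(y) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    stop("`y` must contain non-negative integers", call. = FALSE)
  }
}

# log(1 - exp(x)) for x < 0, accurate near both limits
.log1mexp <- function(x) {
  out <- ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
  out[x >= 0] <- -Inf
  out
}

# log(exp(a) + exp(b)) elementwise, tolerating -Inf
.logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

#' Poisson log-probability
#'
#' Log of the Poisson probability mass `exp(-lambda) lambda^y / y!`, computed
#' through `lgamma` so that large counts do not overflow the factorial.
#'
#' @param y Non-negative integer count (vectorised).
#' @param lam Positive Poisson rate (vectorised, recycled against `y`).
#' @return Log-probability, same length as the recycled inputs.
#' @export
#' @examples
#' poisson_logpmf(0, 1)   # -1
#' exp(poisson_logpmf(2, 0.5))
poisson_logpmf <- function(y, lam) {
  .check_counts(y)
  if (any(lam <= 0)) stop("`lam` must be positive", call. = FALSE)
  -lam + y * log(lam) - lgamma(y + 1)
}

# log P(Y = 0) under NB2(mu, alpha): (nu/(nu+mu))^nu = exp(-log1p(alpha mu)/alpha)
.nb_logp0 <- function(mu, alpha) {
  ifelse(alpha < .ALPHA_POISSON_LIMIT, -mu, -log1p(alpha * mu) / alpha)
}

#' Negative binomial (NB2) log-probability
#'
#' Mean--dispersion parameterisation: `E(Y) = mu`, `Var(Y) = mu + alpha mu^2`,
#' with shape `nu = 1/alpha`. At `alpha = 0` the Poisson limit is returned
#' exactly, so the dispersion parameter can be optimised down to the boundary.
#'
#' @param y Non-negative integer count.
#' @param mu Positive mean.
#' @param alpha Dispersion, `>= 0`.
#' @return Log-probability.
#' @export
nb_logpmf <- function(y, mu, alpha) {
  .check_counts(y)
  if (any(mu <= 0)) stop("`mu` must be positive", call. = FALSE)
  if (any(alpha < 0)) stop("`alpha` must be non-negative", call. = FALSE)
  n <- max(length(y), length(mu), length(alpha))
  y <- rep_len(y, n); mu <- rep_len(mu, n); alpha <- rep_len(alpha, n)
  out <- numeric(n)
  lim <- alpha < .ALPHA_POISSON_LIMIT
  if (any(lim)) out[lim] <- -mu[lim] + y[lim] * log(mu[lim]) - lgamma(y[lim] + 1)
  if (any(!lim)) {
    nu <- 1 / alpha[!lim]; m <- mu[!lim]; k <- y[!lim]
    out[!lim] <- lgamma(k + nu) - lgamma(nu) - lgamma(k + 1) +
      nu * log(nu / (nu + m)) + k * log(m / (nu + m))
  }
  out
}

#' Zero-inflated Poisson log-probability
#'
#' Mixture of a structural zero (probability `phi`) with a Poisson count:
#' `P(0) = phi + (1-phi) e^{-lambda}`, `P(k>0) = (1-phi) Pois(k; lambda)`.
#' The zero mass is combined by log-sum-exp.
#'
#' @inheritParams poisson_logpmf
#' @param phi Structural-zero probability in `[0, 1)`.
#' @export
zip_logpmf <- function(y, lam, phi) {
  .check_counts(y)
  if (any(lam <= 0)) stop("`lam` must be positive", call. = FALSE)
  if (any(phi < 0 | phi >= 1)) stop("`phi` must lie in [0, 1)", call. = FALSE)
  n <- max(length(y), length(lam), length(phi))
  y <- rep_len(y, n); lam <- rep_len(lam, n); phi <- rep_len(phi, n)
  out <- log1p(-phi) + y * log(lam) - lam - lgamma(y + 1)
  z <- y == 0
  out[z] <- .logaddexp(log(phi[z]), log1p(-phi[z]) - lam[z])
  out
}

#' Zero-inflated negative binomial log-probability
#'
#' `P(0) = phi + (1-phi) (nu/(nu+mu))^nu`, `P(k>0) = (1-phi) NB(k; mu, alpha)`.
#' Recovers [zip_logpmf()] as `alpha -> 0` and [nb_logpmf()] at `phi = 0`.
#'
#' @inheritParams nb_logpmf
#' @param phi Structural-zero probability in `[0, 1)`.
#' @export
zinb_logpmf <- function(y, mu, alpha, phi) {
  .check_counts(y)
  if (any(phi < 0 | phi >= 1)) stop("`phi` must lie in [0, 1)", call. = FALSE)
  n <- max(length(y), length(mu), length(alpha), length(phi))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  alpha <- rep_len(alpha, n); phi <- rep_len(phi, n)
  out <- log1p(-phi) + nb_logpmf(y, mu, alpha)
  z <- y == 0
  out[z] <- .logaddexp(log(phi[z]), log1p(-phi[z]) + .nb_logp0(mu[z], alpha[z]))
  out
}

#' Hurdle Poisson log-probability
#'
#' Two-part model: a point mass `p0` at zero, and positives from a
#' zero-truncated Poisson scaled by `1 - p0`. Unlike zero inflation, all
#' zeros come from the single hurdle component.
#'
#' @inheritParams poisson_logpmf
#' @param p0 Zero probability in `[0, 1]`; the boundaries are exact limits.
#' @export
hurdle_poisson_logpmf <- function(y, lam, p0) {
  .check_counts(y)
  if (any(lam <= 0)) stop("`lam` must be positive", call. = FALSE)
  if (any(p0 < 0 | p0 > 1)) stop("`p0` must lie in [0, 1]", call. = FALSE)
  n <- max(length(y), length(lam), length(p0))
  y <- rep_len(y, n); lam <- rep_len(lam, n); p0 <- rep_len(p0, n)
  out <- log1p(-p0) + y * log(lam) - lam - lgamma(y + 1) - .log1mexp(-lam)
  z <- y == 0
  out[z] <- log(p0[z])
  out
}

#' Hurdle negative binomial log-probability
#'
#' Point mass `p0` at zero; positives from a zero-truncated NB2 scaled by
#' `1 - p0`. Recovers [hurdle_poisson_logpmf()] as `alpha -> 0`.
#'
#' @inheritParams nb_logpmf
#' @param p0 Zero probability in `[0, 1]`; the boundaries are exact limits.
#' @export
hurdle_nb_logpmf <- function(y, mu, alpha, p0) {
  .check_counts(y)
  if (any(p0 < 0 | p0 > 1)) stop("`p0` must lie in [0, 1]", call. = FALSE)
  n <- max(length(y), length(mu), length(alpha), length(p0))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  alpha <- rep_len(alpha, n); p0 <- rep_len(p0, n)
  logp0_nb <- .nb_logp0(mu, alpha)
  if (any(logp0_nb >= 0)) {
    stop("degenerate truncation: NB zero probability is 1", call. = FALSE)
  }
  out <- log1p(-p0) + nb_logpmf(y, mu, alpha) - .log1mexp(logp0_nb)
  z <- y == 0
  out[z] <- log(p0[z])
  out
}

# Builds a fast per-observation log-likelihood pass for repeated evaluation
# at varying count-part predictors but fixed zero-part predictor and
# dispersion (the case inside the quadrature/Laplace inner loops: only the
# count-part random effects move). Everything that does not depend on
# eta_count -- the logit pieces, the NB normalising constants, and for hurdle
# families the entire zero-row contribution -- is computed once. Returns
# list(active = row indices whose loglik varies with eta_count,
#      f = function(eta_count[active]) -> per-active-row loglik,
#      const_group = length-m vector of per-group constant contributions).
.make_pass <- function(family, y, lgyp1, gi, m, eta_zero, alpha) {
  n <- length(y)
  z <- y == 0L
  nbtype <- family %in% c("nb", "zinb", "hnb") && alpha >= .ALPHA_POISSON_LIMIT
  if (nbtype) {
    nu <- 1 / alpha
    cnb <- lgamma(y + nu) - lgamma(nu) - lgyp1 + nu * log(nu)
  }
  if (family %in% c("poisson", "nb")) {
    f <- if (nbtype) {
      function(eta) {
        lam <- exp(eta)
        cnb - (nu + y) * log(nu + lam) + y * eta
      }
    } else {
      function(eta) y * eta - exp(eta) - lgyp1
    }
    return(list(active = seq_len(n), f = f,
                const_group = numeric(m), zero_rows = z))
  }
  lp <- stats::plogis(eta_zero, log.p = TRUE)    # log pr(zero component)
  l1mp <- stats::plogis(-eta_zero, log.p = TRUE) # log(1 - pr)
  if (family %in% c("zip", "zinb")) {
    f <- if (nbtype) {
      function(eta) {
        lam <- exp(eta)
        out <- l1mp + cnb - (nu + y) * log(nu + lam) + y * eta
        out[z] <- .logaddexp(lp[z], l1mp[z] - log1p(alpha * lam[z]) / alpha)
        out
      }
    } else {
      function(eta) {
        lam <- exp(eta)
        out <- l1mp + y * eta - lam - lgyp1
        out[z] <- .logaddexp(lp[z], l1mp[z] - lam[z])
        out
      }
    }
    return(list(active = seq_len(n), f = f,
                const_group = numeric(m), zero_rows = z))
  }
  # hurdle: zero rows contribute log p0 regardless of the count part
  pos <- which(!z)
  const_group <- numeric(m)
  cg <- rowsum(lp[z], gi[z], reorder = TRUE)
  const_group[as.integer(rownames(cg))] <- drop(cg)
  yp <- y[pos]; lgp <- lgyp1[pos]; l1p <- l1mp[pos]
  f <- if (nbtype) {
    cnp <- cnb[pos]
    function(eta) {
      lam <- exp(eta)
      l1p + cnp - (nu + yp) * log(nu + lam) + yp * eta -
        .log1mexp(-log1p(alpha * lam) / alpha)
    }
  } else {
    function(eta) {
      lam <- exp(eta)
      l1p + yp * eta - lam - lgp - .log1mexp(-lam)
    }
  }
  list(active = pos, f = f, const_group = const_group, zero_rows = z)
}

# Per-observation log-likelihood for arbitrary (eta_count, eta_zero);
# convenience wrapper used where no repeated evaluation occurs.
# `lgyp1` caches lgamma(y + 1); eta_zero enters through the logit link for
# the zi/hurdle families and may be NULL otherwise.
.obs_loglik <- function(family, y, lgyp1, eta_count, eta_zero = NULL,
                        alpha = 0) {
  lam <- exp(eta_count)
  pois <- y * eta_count - lam - lgyp1
  if (family == "poisson") return(pois)
  if (family %in% c("nb", "zinb", "hnb") && alpha >= .ALPHA_POISSON_LIMIT) {
    nu <- 1 / alpha
    cnt <- lgamma(y + nu) - lgamma(nu) - lgyp1 +
      nu * log(nu / (nu + lam)) + y * log(lam / (nu + lam))
    logp0 <- -log1p(alpha * lam) / alpha
  } else {
    cnt <- pois
    logp0 <- -lam
  }
  if (family == "nb") return(cnt)
  z <- y == 0
  lp <- stats::plogis(eta_zero, log.p = TRUE)   # log pr(zero component)
  l1mp <- stats::plogis(-eta_zero, log.p = TRUE) # log(1 - pr)
  if (family %in% c("zip", "zinb")) {
    out <- l1mp + cnt
    out[z] <- .logaddexp(lp[z], l1mp[z] + logp0[z])
  } else {                                      # hp / hnb
    out <- l1mp + cnt - .log1mexp(logp0)
    out[z] <- lp[z]
  }
  out
}

#' Linear predictors for a two-level count model
#'
#' Combines the fixed parts `X beta` (count) and `Z gamma` (zero) with each
#' row's group-level random effects: the count-part predictor gains
#' `R_count b_j` for the row's group `j`, and (for zero-inflated or hurdle
#' families with a zero-part random intercept) the zero-part predictor gains
#' the group's zero-part effect.
#'
#' @param dm Design matrices from [build_design()].
#' @param params List with `beta` (length `ncol(dm$X)`), optionally `gamma`
#'   (length `ncol(dm$Z)`), `u` a matrix of count-part random effects with one
#'   row per group and one column per column of `dm$R_count`, and `w` a matrix
#'   of zero-part effects (columns of `dm$R_zero`). `u`/`w` may be `NULL`
#'   (treated as zero).
#' @param group_index Integer vector mapping each row to its group (1..m).
#' @return List with `eta_count` (log rate scale) and `eta_zero` (logit
#'   scale, `NULL` when the model has no zero part).
#' @export
linear_predictors <- function(dm, params, group_index) {
  n <- nrow(dm$X)
  if (length(group_index) != n) {
    stop("`group_index` length must match the design rows", call. = FALSE)
  }
  if (length(params$beta) != ncol(dm$X)) {
    stop("`beta` length does not match ncol(X)", call. = FALSE)
  }
  eta_count <- drop(dm$X %*% params$beta)
  if (!is.null(params$u) && !is.null(dm$R_count) && ncol(dm$R_count) > 0) {
    u <- as.matrix(params$u)
    if (ncol(u) != ncol(dm$R_count)) {
      stop("`u` columns do not match the count-part random design",
           call. = FALSE)
    }
    eta_count <- eta_count + rowSums(dm$R_count * u[group_index, , drop = FALSE])
  }
  eta_zero <- NULL
  if (!is.null(dm$Z)) {
    if (length(params$gamma) != ncol(dm$Z)) {
      stop("`gamma` length does not match ncol(Z)", call. = FALSE)
    }
    eta_zero <- drop(dm$Z %*% params$gamma)
    if (!is.null(params$w) && !is.null(dm$R_zero) && ncol(dm$R_zero) > 0) {
      w <- as.matrix(params$w)
      eta_zero <- eta_zero + rowSums(dm$R_zero * w[group_index, , drop = FALSE])
    }
  }
  list(eta_count = eta_count, eta_zero = eta_zero)
}
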