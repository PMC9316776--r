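# The six family log-pmfs: worked values, normalisation, nesting limits,
# numerical stability, and agreement with stats:: densities where they exist.

test_that("Poisson log-pmf matches worked values and normalises", {
  expect_equal(poisson_logpmf(0, 1.0), -1.0)
  expect_equal(poisson_logpmf(2, 0.5), -0.5 + log(0.125))
  expect_equal(poisson_logpmf(0:30, 2.7), dpois(0:30, 2.7, log = TRUE))
  expect_equal(sum(exp(poisson_logpmf(0:200, 3))), 1, tolerance = 1e-12)
  expect_error(poisson_logpmf(1, 0), "positive")
  expect_error(poisson_logpmf(-1, 1), "non-negative")
  expect_error(poisson_logpmf(1.5, 1), "integers")
})

test_that("NB2 log-pmf has the documented zero mass, moments and limits", {
  expect_equal(nb_logpmf(0, 1.0, 1.0), log(0.5))
  # alpha = 0 is exactly Poisson
  expect_equal(nb_logpmf(c(0, 1, 5), 2, 0), poisson_logpmf(c(0, 1, 5), 2))
  # brute-force moments at mu = 2, alpha = 0.5: var = mu + alpha mu^2 = 4
  k <- 0:500
  p <- exp(nb_logpmf(k, 2, 0.5))
  expect_equal(sum(k * p), 2, tolerance = 1e-8)
  expect_equal(sum(k^2 * p) - sum(k * p)^2, 4, tolerance = 1e-6)
  # agreement with dnbinom under the size = 1/alpha mapping
  expect_equal(nb_logpmf(0:40, 2.3, 0.4),
               dnbinom(0:40, mu = 2.3, size = 2.5, log = TRUE),
               tolerance = 1e-12)
  expect_error(nb_logpmf(1, 2, -0.1), "non-negative")
})

test_that("ZIP log-pmf mixes the zero mass correctly", {
  expect_equal(zip_logpmf(0, 1.0, 0.3), log(0.3 + 0.7 * exp(-1)))
  expect_equal(zip_logpmf(0:2, 1.5, 0), poisson_logpmf(0:2, 1.5))
  expect_equal(sum(exp(zip_logpmf(0:200, 2, 0.4))), 1, tolerance = 1e-12)
  expect_equal(exp(zip_logpmf(3, 2, 0.4)), 0.6 * dpois(3, 2), tolerance = 1e-14)
  expect_error(zip_logpmf(0, 1, 1), "\\[0, 1\\)")
  expect_error(zip_logpmf(0, 1, -0.1), "\\[0, 1\\)")
})

test_that("ZINB log-pmf nests ZIP and NB", {
  expect_equal(zinb_logpmf(0, 1.0, 1.0, 0.5), log(0.75))
  expect_equal(zinb_logpmf(c(0, 1, 3), 2, 1e-10, 0.3),
               zip_logpmf(c(0, 1, 3), 2, 0.3), tolerance = 1e-6)
  expect_equal(zinb_logpmf(0:10, 2, 0.7, 0), nb_logpmf(0:10, 2, 0.7))
  expect_equal(sum(exp(zinb_logpmf(0:500, 2, 0.7, 0.2))), 1, tolerance = 1e-10)
})

test_that("hurdle Poisson puts exactly p0 at zero and truncates positives", {
  expect_equal(hurdle_poisson_logpmf(0, 5.3, 0.718), log(0.718))
  expect_equal(hurdle_poisson_logpmf(1, 1.0, 0.718),
               log(0.282 * exp(-1) / (1 - exp(-1))))
  expect_equal(sum(exp(hurdle_poisson_logpmf(0:200, 2, 0.5))), 1,
               tolerance = 1e-12)
  # boundary limits
  expect_identical(hurdle_poisson_logpmf(0, 1, 1), 0)
  expect_identical(hurdle_poisson_logpmf(0, 1, 0), -Inf)
})

test_that("hurdle NB nests hurdle Poisson and normalises", {
  expect_equal(hurdle_nb_logpmf(0, 2.0, 0.5, 0.6), log(0.6))
  expect_equal(hurdle_nb_logpmf(c(1, 2, 4), 2, 1e-10, 0.4),
               hurdle_poisson_logpmf(c(1, 2, 4), 2, 0.4), tolerance = 1e-6)
  expect_equal(sum(exp(hurdle_nb_logpmf(0:500, 2, 0.5, 0.3))), 1,
               tolerance = 1e-10)
})

test_that("nesting chain holds across random parameter draws", {
  set.seed(42)
  for (i in 1:20) {
    mu <- runif(1, 0.2, 6)
    phi <- runif(1, 0.05, 0.8)
    y <- 0:8
    expect_equal(zinb_logpmf(y, mu, 1e-9, phi), zip_logpmf(y, mu, phi),
                 tolerance = 1e-6)
    expect_equal(zip_logpmf(y, mu, 0), poisson_logpmf(y, mu),
                 tolerance = 1e-12)
    expect_equal(nb_logpmf(y, mu, 1e-9), poisson_logpmf(y, mu),
                 tolerance = 1e-6)
    expect_equal(hurdle_nb_logpmf(y, mu, 1e-9, phi),
                 hurdle_poisson_logpmf(y, mu, phi), tolerance = 1e-6)
  }
})

test_that("matched zero masses make ZIP and hurdle Poisson coincide", {
  set.seed(7)
  for (i in 1:10) {
    lam <- runif(1, 0.3, 4)
    phi <- runif(1, 0.05, 0.7)
    p0 <- phi + (1 - phi) * exp(-lam)
    expect_equal(hurdle_poisson_logpmf(0:6, lam, p0),
                 zip_logpmf(0:6, lam, phi), tolerance = 1e-12)
  }
})

test_that("log-pmfs stay finite at extreme arguments", {
  expect_true(is.finite(poisson_logpmf(1e5, 1e6)))
  expect_true(is.finite(nb_logpmf(1e5, 1e6, 1e-12)))
  expect_true(is.finite(nb_logpmf(1e5, 1e6, 3)))
  expect_true(is.finite(zinb_logpmf(0, 1e6, 1e-12, 0.999)))
  expect_true(is.finite(zip_logpmf(0, 1e6, 1e-12)))
  expect_true(is.finite(hurdle_nb_logpmf(1e5, 1e6, 2, 0.5)))
  expect_true(is.finite(hurdle_poisson_logpmf(3, 1e-8, 0.5)))
})

test_that("the fast fitting pass reproduces the public pmfs", {
  set.seed(11)
  n <- 60
  y <- rpois(n, 1)
  gi <- sample(1:4, n, replace = TRUE)
  eta_c <- rnorm(n, 0, 0.8)
  eta_z <- rnorm(n, -0.5, 0.6)
  lg <- lgamma(y + 1)
  for (fam in c("poisson", "nb", "zip", "zinb", "hp", "hnb")) {
    alpha <- if (fam %in% c("nb", "zinb", "hnb")) 0.6 else 0
    pass <- mlcount:::.make_pass(fam, y, lg, gi, 4, eta_z, alpha)
    got <- pass$const_group
    gs <- rowsum(pass$f(eta_c[pass$active]), gi[pass$active])
    got[as.integer(rownames(gs))] <- got[as.integer(rownames(gs))] + gs
    ref <- switch(fam,
      poisson = poisson_logpmf(y, exp(eta_c)),
      nb = nb_logpmf(y, exp(eta_c), alpha),
      zip = zip_logpmf(y, exp(eta_c), plogis(eta_z)),
      zinb = zinb_logpmf(y, exp(eta_c), alpha, plogis(eta_z)),
      hp = hurdle_poisson_logpmf(y, exp(eta_c), plogis(eta_z)),
      hnb = hurdle_nb_logpmf(y, exp(eta_c), alpha, plogis(eta_z)))
    expect_equal(as.numeric(got), as.numeric(rowsum(ref, gi)),
                 tolerance = 1e-12, label = fam)
  }
})

test_that("linear predictors combine fixed and random parts", {
  dm <- list(X = cbind(`(Intercept)` = rep(1, 4), x = c(0, 1, 2, 3)),
             Z = cbind(`(Intercept)` = rep(1, 4)),
             R_count = cbind(`(Intercept)` = rep(1, 4)),
             R_zero = NULL)
  # all random effects zero: fixed part only
  lp <- linear_predictors(dm, list(beta = c(-1, 0.5), gamma = 0.2,
                                   u = matrix(0, 2, 1)), c(1, 1, 2, 2))
  expect_equal(lp$eta_count, c(-1, -0.5, 0, 0.5))
  expect_equal(lp$eta_zero, rep(0.2, 4))
  # intercept-only model: group effect +0.5 on a -1.154 intercept
  dm2 <- list(X = cbind(`(Intercept)` = rep(1, 3)), Z = NULL,
              R_count = cbind(`(Intercept)` = rep(1, 3)), R_zero = NULL)
  lp2 <- linear_predictors(dm2, list(beta = -1.154,
                                     u = matrix(c(0.5, 0), 2, 1)),
                           c(1, 1, 2))
  expect_equal(lp2$eta_count, c(-0.654, -0.654, -1.154))
  # opposite group effects +/- a differ by 2a
  lp3 <- linear_predictors(dm2, list(beta = 0, u = matrix(c(0.7, -0.7), 2, 1)),
                           c(1, 2, 2))
  expect_equal(lp3$eta_count[1] - lp3$eta_count[2], 1.4)
  expect_error(
    linear_predictors(dm2, list(beta = c(1, 2)), c(1, 1, 2)), "beta")
})
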