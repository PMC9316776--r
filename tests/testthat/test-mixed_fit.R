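# Marginal likelihood and estimation: degenerate limits, quadrature accuracy
# against brute-force integration, agreement with independent mixed-model
# implementations, and parameter recovery on seeded simulations.

test_that("zero random-effect variance reduces to the fixed-effects likelihood", {
  sim <- simulate_counts(small_truth("zinb", m = 4, nj = 30), seed = 12)
  spec <- small_spec("zinb")
  dm <- build_design(sim$data, spec)
  theta <- c(0.2, 0.4, -0.8, 0.3, log(0.6), -Inf)
  got <- marginal_loglik(sim$data, spec, theta)
  lp <- linear_predictors(dm, list(beta = c(0.2, 0.4), gamma = c(-0.8, 0.3)),
                          dm$group_index)
  ref <- sum(zinb_logpmf(dm$y, exp(lp$eta_count), 0.6,
                         plogis(lp$eta_zero)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("1-D adaptive quadrature matches a single-integral closed case", {
  # one group, one observation y = 0, Poisson, beta0 = 0, delta^2 = 1:
  # loglik = log Int exp(-e^b) N(b; 0, 1) db
  df <- data.frame(deaths = 0L, region = "g1")
  data <- load_dataset(df, list(outcome = "deaths", group = "region",
                                covariates = list()), quiet = TRUE)
  spec <- model_spec("poisson")
  got <- marginal_loglik(data, spec, c(0, 0), fit_control(n_quad = 25))
  b <- seq(-10, 10, length.out = 200001)
  h <- b[2] - b[1]
  ref <- log(sum(exp(-exp(b)) * dnorm(b) * h))
  expect_equal(got, ref, tolerance = 1e-6)
})

test_that("quadrature agrees with grid integration on random small instances", {
  set.seed(77)
  fams <- c("poisson", "nb", "zip", "zinb", "hp", "hnb")
  for (i in 1:24) {
    fam <- fams[(i - 1) %% 6 + 1]
    cfg <- small_truth(fam, m = 3, nj = 8,
                       beta0 = runif(1, -0.5, 0.7), beta1 = runif(1, -0.5, 0.5),
                       alpha = runif(1, 0.3, 1), re_var = runif(1, 0.1, 1))
    sim <- simulate_counts(cfg, seed = 7000 + i)
    spec <- small_spec(fam)
    dm <- build_design(sim$data, spec)
    has_zero <- fam %in% c("zip", "zinb", "hp", "hnb")
    has_alpha <- fam %in% c("nb", "zinb", "hnb")
    delta <- runif(1, 0.3, 1.2)
    beta <- c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3))
    gamma <- if (has_zero) c(runif(1, -1, 0), runif(1, -0.5, 0.5)) else NULL
    alpha <- if (has_alpha) runif(1, 0.2, 0.9) else 0
    theta <- c(beta, gamma, if (has_alpha) log(alpha), log(delta))
    got <- marginal_loglik(sim$data, spec, theta, fit_control(n_quad = 25))
    eta_fix <- drop(dm$X %*% beta)
    eta_zero <- if (has_zero) drop(dm$Z %*% gamma) else NULL
    ref <- grid_marginal_loglik(dm$y, eta_fix, eta_zero, fam, alpha, delta,
                                dm$group_index)
    expect_equal(got, ref, tolerance = 1e-6, label = paste(fam, i))
  }
})

test_that("duplicating every group doubles the marginal log-likelihood", {
  cfg <- small_truth("nb", m = 4, nj = 25)
  sim <- simulate_counts(cfg, seed = 3)
  rec <- sim$data$records
  rec2 <- rbind(rec, transform(rec, region = paste0(region, "_copy")))
  sch <- list(outcome = "deaths", group = "region", covariates = list(
    list(name = "x", type = "continuous")))
  d1 <- load_dataset(rec, sch, quiet = TRUE)
  d2 <- load_dataset(rec2, sch, quiet = TRUE)
  spec <- small_spec("nb")
  theta <- c(0.3, 0.5, log(0.7), log(0.5))
  expect_equal(marginal_loglik(d2, spec, theta),
               2 * marginal_loglik(d1, spec, theta), tolerance = 1e-9)
})

test_that("theta is validated", {
  sim <- simulate_counts(small_truth("poisson", m = 3, nj = 10), seed = 1)
  spec <- small_spec("poisson")
  expect_error(marginal_loglik(sim$data, spec, c(0, 0)), "length")
  expect_error(marginal_loglik(sim$data, spec, c(NaN, 0, 0)), "non-finite")
  expect_error(marginal_loglik(sim$data, spec, c(0, 0, Inf)), "non-finite")
})

test_that("Poisson random-intercept fit recovers the truth and matches glmer", {
  cfg <- small_truth("poisson", m = 60, nj = 50, beta0 = 0.3, beta1 = 0.4,
                     re_var = 0.5)
  sim <- simulate_counts(cfg, seed = 101)
  fit <- fit_count_model(sim$data, small_spec("poisson"))
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$beta[["(Intercept)"]] - 0.3),
            3 * fit$std_errors$beta[1])
  v <- fit$estimates$re_variances[["(Intercept)"]]
  expect_true(v > 0.25 && v < 0.9)

  gm <- lme4::glmer(deaths ~ x + (1 | region), sim$data$records,
                    family = poisson, nAGQ = 15)
  expect_equal(unname(fit$estimates$beta), unname(lme4::fixef(gm)),
               tolerance = 1e-3)
  expect_equal(v, as.numeric(lme4::VarCorr(gm)$region), tolerance = 1e-2)
})

test_that("ZINB fit agrees with glmmTMB on the same data", {
  sim <- simulate_counts(small_truth("zinb", m = 15, nj = 100), seed = 7)
  fit <- fit_count_model(sim$data, small_spec("zinb"))
  tm <- glmmTMB::glmmTMB(deaths ~ x + (1 | region), ziformula = ~x,
                         data = sim$data$records, family = glmmTMB::nbinom2)
  expect_equal(unname(fit$estimates$beta),
               unname(glmmTMB::fixef(tm)$cond), tolerance = 0.02)
  expect_equal(unname(fit$estimates$gamma),
               unname(glmmTMB::fixef(tm)$zi), tolerance = 0.02)
  expect_equal(fit$estimates$alpha, 1 / glmmTMB::sigma(tm), tolerance = 0.02)
  # AGHQ vs Laplace: log-likelihoods close, ours never materially worse
  expect_lt(abs(fit$loglik - as.numeric(logLik(tm))), 0.5)
  # SEs agree with the TMB information matrix to a few percent
  se_tmb <- summary(tm)$coefficients$cond[, "Std. Error"]
  expect_equal(unname(fit$std_errors$beta), unname(se_tmb), tolerance = 0.05)
})

test_that("data without group heterogeneity pushes the variance to zero", {
  cfg <- small_truth("poisson", m = 25, nj = 60, re_var = 0)
  sim <- simulate_counts(cfg, seed = 55)
  fit <- fit_count_model(sim$data, small_spec("poisson"))
  expect_lt(fit$estimates$re_variances[[1]], 0.05)
  # fixed estimates match the fixed-effects-only GLM
  gl <- glm(deaths ~ x, poisson, sim$data$records)
  expect_equal(unname(fit$estimates$beta), unname(coef(gl)),
               tolerance = 1e-3)
})

test_that("ZINB fitted to ZIP data collapses the dispersion", {
  sim <- simulate_counts(small_truth("zip", m = 30, nj = 60, alpha = 0),
                         seed = 42)
  fit <- fit_count_model(sim$data, small_spec("zinb"))
  expect_lt(fit$estimates$alpha, 0.2)
  expect_lt(abs(fit$estimates$beta[["x"]] - 0.5), 3 * fit$std_errors$beta[2])
  expect_lt(abs(fit$estimates$gamma[["(Intercept)"]] - (-1)),
            3 * fit$std_errors$gamma[1])
})

test_that("the optimum is a local maximum and scale-invariant", {
  sim <- simulate_counts(small_truth("nb", m = 10, nj = 40), seed = 9)
  spec <- small_spec("nb")
  fit <- fit_count_model(sim$data, spec)
  ll0 <- fit$loglik
  for (k in seq_along(fit$theta)) {
    for (s in c(-0.1, 0.1)) {
      th <- fit$theta; th[k] <- th[k] + s
      expect_lte(marginal_loglik(sim$data, spec, th, fit$control),
                 ll0 + 1e-6)
    }
  }
  # rescaling x by c and the coefficient by 1/c leaves the likelihood alone
  rec <- sim$data$records
  rec$x <- rec$x * 10
  sch <- list(outcome = "deaths", group = "region", covariates = list(
    list(name = "x", type = "continuous")))
  data10 <- load_dataset(rec, sch, quiet = TRUE)
  th10 <- fit$theta
  th10[2] <- th10[2] / 10
  expect_equal(marginal_loglik(data10, spec, th10, fit$control), ll0,
               tolerance = 1e-6)
})

test_that("Laplace handles random intercept plus slope and matches glmmTMB", {
  cfg <- truth_config("poisson", group_sizes = rep(80, 15),
                      covariates = list(x = list(type = "continuous",
                                                 mean = 0, sd = 1)),
                      beta = c(`(Intercept)` = 0.3, x = 0.4),
                      re_variances = c(`(Intercept)` = 0.3, x = 0.1),
                      seed = 11)
  sim <- simulate_counts(cfg)
  fit <- fit_count_model(sim$data,
                         model_spec("poisson", "x", random_slopes = "x"))
  expect_true(fit$converged)
  expect_equal(names(fit$estimates$re_variances), c("(Intercept)", "x"))
  tm <- glmmTMB::glmmTMB(deaths ~ x + (1 | region) + (0 + x | region),
                         data = sim$data$records, family = poisson)
  expect_lt(abs(fit$loglik - as.numeric(logLik(tm))), 0.05)
  expect_equal(unname(fit$estimates$re_variances),
               unname(c(glmmTMB::VarCorr(tm)$cond[[1]][1],
                        glmmTMB::VarCorr(tm)$cond[[2]][1])),
               tolerance = 0.05)
})

test_that("Wald arithmetic and the coefficient table are consistent", {
  wt <- wald_test(0.36, 0.04715)
  expect_equal(wt$z, 0.36 / 0.04715)
  expect_lt(wt$p, 1e-4)
  expect_equal(wt$stars, "***")
  expect_equal(wald_test(0, 0.1)$z, 0)
  expect_equal(wald_test(0, 0.1)$p, 1)
  expect_equal(wald_test(1.96 * 0.1, 0.1)$p, 0.05, tolerance = 1e-3)

  sim <- simulate_counts(small_truth("zip", m = 8, nj = 40), seed = 2)
  fit <- fit_count_model(sim$data, small_spec("zip"))
  tab <- wald_table(fit)
  fx <- tab[tab$part %in% c("count", "zero"), ]
  expect_equal(fx$z, fx$estimate / fx$std_error)
  expect_true(all(tab$part %in% c("count", "zero", "dispersion", "random")))
  expect_equal(sum(tab$part == "random"), 1)
})

test_that("group-effect predictions rank elevated groups first", {
  cfg <- small_truth("poisson", m = 8, nj = 60, re_var = 0.2)
  sim <- simulate_counts(cfg, seed = 14)
  # lift group 3's counts systematically
  rec <- sim$data$records
  boost <- rec$region == "g03"
  set.seed(1)
  rec$deaths <- rec$deaths + ifelse(boost, rpois(nrow(rec), 2), 0L)
  sch <- list(outcome = "deaths", group = "region", covariates = list(
    list(name = "x", type = "continuous")))
  data <- load_dataset(rec, sch, quiet = TRUE)
  fit <- fit_count_model(data, small_spec("poisson"))
  pg <- predict_group_effects(fit)
  expect_equal(rownames(pg$effects)[which.max(pg$effects[, 1])], "g03")
  expect_equal(nrow(pg$variances), 1)
  expect_equal(pg$variances$term, "(Intercept)")
})
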