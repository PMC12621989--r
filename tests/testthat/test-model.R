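test_that("design matrices have the documented columns and coding", {
  tab <- simulate_li_table(linear_truth(n = 50))
  d <- build_design(tab, model_spec(fp_spec(1)))
  expect_equal(ncol(d$X_mu), 3)                       # 1 + FP + sex
  expect_equal(colnames(d$X_mu), c("(Intercept)", "t^1", "sexmale"))
  expect_equal(d$X_mu[, "sexmale"], as.numeric(tab$sex == "male"))
  d2 <- build_design(tab, model_spec(fp_spec(c(1, 2))))
  expect_equal(ncol(d2$X_mu), 4)
  # single cohort: no offset block
  expect_null(d$cohort)
  expect_equal(n_free_params(d), 6)
  # constant age is rank deficient
  tabc <- tab; tabc$age <- 50
  expect_error(build_design(tabc, model_spec(fp_spec(1))),
               class = "wmasym_rank_error")
  expect_error(build_design(tab[1:5, ], model_spec()),
               class = "wmasym_validation_error")
})

test_that("negative log-likelihood matches the closed-form normal density", {
  d <- list(X_mu = cbind(1), X_sigma = cbind(1), y = 0, cohort = NULL,
            n_cohorts = 1)
  pr <- list(beta_mu = 0, beta_sigma = 0, u_mu = numeric(0), u_sigma = numeric(0))
  expect_equal(neg_log_likelihood(pr, d), 0.5 * log(2 * pi))
  # additivity: two identical observations double the value
  d2 <- d; d2$y <- c(0, 0); d2$X_mu <- cbind(c(1, 1)); d2$X_sigma <- cbind(c(1, 1))
  expect_equal(neg_log_likelihood(pr, d2), 2 * neg_log_likelihood(pr, d))
  # y = mu everywhere, sigma = 1: n/2 log(2 pi)
  d3 <- d2; d3$y <- c(0.3, -0.1); d3$X_mu <- cbind(c(0.3, -0.1))
  pr3 <- list(beta_mu = 1, beta_sigma = 0, u_mu = numeric(0), u_sigma = numeric(0))
  expect_equal(neg_log_likelihood(pr3, d3), log(2 * pi))
  # cross-check against dnorm on arbitrary values
  set.seed(3); y <- rnorm(20); mu <- 0.2; sg <- 0.7
  d4 <- list(X_mu = cbind(rep(1, 20)), X_sigma = cbind(rep(1, 20)), y = y,
             cohort = NULL, n_cohorts = 1)
  pr4 <- list(beta_mu = mu, beta_sigma = log(sg), u_mu = numeric(0), u_sigma = numeric(0))
  expect_equal(neg_log_likelihood(pr4, d4), -sum(dnorm(y, mu, sg, log = TRUE)))
})

test_that("packed analytic gradient matches numerical differentiation", {
  tab <- simulate_li_table(linear_truth(n = 120, n_cohorts = 3))
  spec <- model_spec(fp_spec(c(0, 1)), fp_spec(1))
  d <- build_design(tab, spec)
  theta <- c(0.01, 0.02, -0.01, 0.003, -3, 0.1, 0.005, 0.002, -0.003, 0.01, -0.02)
  stopifnot(length(theta) == n_free_params(d))
  g <- unname(wmasym:::grad_packed(theta, d))
  gn <- numDeriv_grad(function(th) wmasym:::nll_packed(th, d), theta)
  expect_equal(g, gn, tolerance = 1e-6)
  # and with ridge penalty
  g2 <- unname(wmasym:::grad_packed(theta, d, ridge_lambda = 2))
  gn2 <- numDeriv_grad(function(th) wmasym:::nll_packed(th, d, ridge_lambda = 2), theta)
  expect_equal(g2, gn2, tolerance = 1e-6)
})

test_that("ML estimates equal OLS for homoscedastic, cohort-free designs", {
  truth <- linear_truth(n = 500, seed = 9001)
  tab <- simulate_li_table(truth)
  fit <- fit_model(tab, model_spec(fp_spec(1), sigma_fp = NULL, include_sex = FALSE))
  X <- cbind(1, age_to_t(tab$age))
  ols <- qr.solve(X, tab$li)
  expect_lt(max(abs(fit$beta_mu - ols)), 1e-6)
  # ML sigma is the 1/n residual SD
  sig_ml <- sqrt(mean((tab$li - X %*% ols)^2))
  expect_equal(exp(fit$beta_sigma[["(Intercept)"]]), sig_ml, tolerance = 1e-6)
})

test_that("fit recovers known coefficients within sampling error", {
  truth <- linear_truth(n = 5000, seed = 9002, sex_mu = 0.004)
  tab <- simulate_li_table(truth)
  fit <- fit_model(tab, model_spec(fp_spec(1), fp_spec(1)))
  expect_true(fit$converged)
  # rough standard errors: sigma / sqrt(n) scale; allow 3x
  se_slope <- 0.04 / (sd(age_to_t(tab$age)) * sqrt(nrow(tab)))
  expect_lt(abs(fit$beta_mu[["t^1"]] - 0.006), 3 * se_slope)
  expect_lt(abs(fit$beta_mu[["sexmale"]] - 0.004), 3 * 2 * 0.04 / sqrt(nrow(tab)))
})

test_that("fits are invariant to row permutation and deterministic", {
  truth <- linear_truth(n = 400, seed = 9003, n_cohorts = 2)
  tab <- simulate_li_table(truth)
  spec <- model_spec(fp_spec(1), fp_spec(1))
  f1 <- fit_model(tab, spec)
  set.seed(42)
  f2 <- fit_model(tab[sample(nrow(tab)), ], spec)
  expect_equal(f1$beta_mu, f2$beta_mu, tolerance = 1e-8)
  expect_equal(f1$beta_sigma, f2$beta_sigma, tolerance = 1e-8)
  expect_equal(f1$u_mu, f2$u_mu, tolerance = 1e-8)
  f3 <- fit_model(tab, spec)
  expect_identical(f1$beta_mu, f3$beta_mu)
})

test_that("cohort offsets sum to zero and shift predictions additively", {
  truth <- linear_truth(n = 900, seed = 9004, n_cohorts = 3)
  tab <- simulate_li_table(truth)
  fit <- fit_model(tab, model_spec(fp_spec(1), fp_spec(1)))
  expect_lt(abs(sum(fit$u_mu)), 1e-8)
  expect_lt(abs(sum(fit$u_sigma)), 1e-8)
  p0 <- predict_mu_sigma(fit, 40, "female")
  p1 <- predict_mu_sigma(fit, 40, "female", cohort = names(fit$u_mu)[1])
  expect_equal(p1$mu - p0$mu, unname(fit$u_mu[1]))
  expect_error(predict_mu_sigma(fit, 40, "female", cohort = "nope"),
               class = "wmasym_lookup_error")
  # ridge shrinks offsets toward zero
  rfit <- fit_model(tab, model_spec(fp_spec(1), fp_spec(1),
                                    cohort_effect = "ridge", ridge_lambda = 50))
  expect_lt(sum(rfit$u_mu^2), sum(fit$u_mu^2))
  expect_lt(abs(sum(rfit$u_mu)), 1e-8)
})

test_that("predictions decompose into sex difference and exp link", {
  truth <- linear_truth(n = 800, seed = 9005, sex_mu = 0.01)
  tab <- simulate_li_table(truth)
  fit <- fit_model(tab, model_spec(fp_spec(1), fp_spec(1)))
  pf <- predict_mu_sigma(fit, c(10, 60), "female")
  pm <- predict_mu_sigma(fit, c(10, 60), "male")
  expect_equal(pm$mu - pf$mu, rep(fit$beta_mu[["sexmale"]], 2))
  expect_true(all(pf$sigma > 0))
})

test_that("BIC follows its definition and penalizes extra terms", {
  truth <- linear_truth(n = 1000, seed = 9006)
  tab <- simulate_li_table(truth)
  f1 <- fit_model(tab, model_spec(fp_spec(1), fp_spec(1)))
  expect_equal(f1$bic, -2 * f1$loglik + f1$n_params * log(f1$n_obs))
  expect_equal(bic_of(f1), f1$bic)
  # an irrelevant extra mu term cannot beat the penalty difference
  f2 <- fit_model(tab, model_spec(fp_spec(c(1, 1)), fp_spec(1)))
  expect_gt(f2$bic, f1$bic - 2e-8)
  expect_lte(-2 * f2$loglik, -2 * f1$loglik + 1e-6)  # larger model fits at least as well
})

test_that("mu estimates agree with an independent gaulss oracle", {
  skip_if_not_installed("mgcv")
  truth <- linear_truth(n = 600, seed = 9007, sex_mu = 0.005)
  tab <- simulate_li_table(truth)
  fit <- fit_model(tab, model_spec(fp_spec(1), fp_spec(1)))
  dat <- data.frame(li = tab$li, t = age_to_t(tab$age),
                    male = as.numeric(tab$sex == "male"))
  g <- mgcv::gam(list(li ~ t + male, ~ t + male),
                 family = mgcv::gaulss(b = 0), data = dat, method = "ML")
  mu_pkg <- predict_mu_sigma(fit, tab$age, tab$sex)$mu
  mu_gam <- predict(g)[, 1]
  expect_lt(max(abs(mu_pkg - mu_gam)), 1e-4)
})

test_that("staged selection prefers the generating smooth on nonlinear truth", {
  tab <- simulate_li_table(scenario("heteroscedastic_u_shape",
                                    n_subjects = 5000, seed = 555))
  sel <- select_model(tab, strategy = "staged")
  expect_s3_class(sel, "wmasym_fit")
  expect_true(sel$converged)
  expect_equal(as.numeric(sel$spec$mu_fp), c(0, 1))
  expect_true(!is.null(sel$selection) && nrow(sel$selection) == 88)
})

test_that("staged and exhaustive agree at order 1 on linear truth", {
  truth <- linear_truth(n = 2000, seed = 9008)
  tab <- simulate_li_table(truth)
  st <- select_model(tab, strategy = "staged", max_order = 1)
  ex <- select_model(tab, strategy = "exhaustive", max_order = 1)
  expect_equal(as.numeric(st$spec$mu_fp), as.numeric(ex$spec$mu_fp))
  expect_equal(st$bic, ex$bic, tolerance = 1e-6)
  expect_equal(nrow(ex$selection), 64)
  # linear truth: order-1 winner is the identity power
  expect_equal(as.numeric(st$spec$mu_fp), 1)
})
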