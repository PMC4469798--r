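test_that("CAR(1) correlation matrix has the stated entries", {
  expect_equal(car1_matrix(c(3, 7, 11), 0), diag(3))
  expect_equal(car1_matrix(c(1, 2), 0.5)[1, 2], 0.5)
  S <- car1_matrix(c(1, 2, 4), 0.5)
  expect_equal(S[1, 3], 0.125)
  expect_equal(diag(S), rep(1, 3))
  expect_error(car1_matrix(c(1, 2), 1), "phi")
  expect_error(car1_matrix(c(1, 2), -0.1), "phi")
})

test_that("with no random effects and no serial correlation the REML fit is OLS", {
  cfg <- cohort_config(200, seed = 21L, car1_phi = 0,
                       random_effect_cov = matrix(0, 2, 2),
                       questionnaire_prob = 0)
  sim <- simulate_cohort(cfg, list(snp_effect_spec(0.3, beta_level = 0.02)))
  d <- build_design(sim$phenotypes, sim$panel$dosages[, 1])
  # GLS at the zero-variance-component limit collapses to OLS
  fit <- reml_fit(d, init = list(G = matrix(0, 2, 2), sigma2 = 1, phi = 0),
                  optimize = FALSE, robust = FALSE)
  ols <- qr.coef(qr(d$X), d$y)
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-6)
  # and the freely-estimated fit reproduces the OLS *fitted values*
  fit2 <- reml_fit(d, robust = FALSE)
  expect_lt(max(abs(d$X %*% fit2$beta - d$X %*% ols)), 5e-3)
})

test_that("balanced random-intercept data reproduce the closed-form ANOVA/REML estimators", {
  set.seed(22)
  n <- 80; m <- 5
  tau2 <- 0.01; s2 <- 0.004
  a <- rnorm(n, 0, sqrt(tau2))
  y <- 2.8 + rep(a, each = m) + rnorm(n * m, 0, sqrt(s2))
  ages <- rep(c(4, 6, 8, 10, 12), n)
  design <- structure(list(
    X = matrix(1, n * m, 1, dimnames = list(NULL, "(Intercept)")),
    y = y, cluster = rep(sprintf("i%03d", 1:n), each = m), times = ages,
    source = numeric(n * m), snp_cols = integer(), basis = spline_basis(),
    n_individuals = n, n_obs = n * m,
    skipped = data.frame()), class = "gwas_design")
  fit <- reml_fit(design, robust = FALSE, random_slope = FALSE,
                  estimate_phi = FALSE, init = list(phi = 0))
  # balanced one-way ANOVA estimators (equal to REML in the balanced case)
  ybar_i <- tapply(y, design$cluster, mean)
  msw <- sum((y - rep(ybar_i, each = m))^2) / (n * (m - 1))
  msb <- m * sum((ybar_i - mean(y))^2) / (n - 1)
  expect_equal(unname(fit$beta[1]), mean(y), tolerance = 1e-8)
  expect_equal(fit$varcomps$sigma2, msw, tolerance = 1e-4)
  expect_equal(fit$varcomps$G[1, 1], (msb - msw) / m, tolerance = 1e-3)
})

test_that("the fit agrees with nlme::lme on the same model", {
  skip_if_not_installed("nlme")
  x <- fitted_small_cohort()
  ph <- x$sim$phenotypes
  ph$dose <- x$sim$panel$dosages[as.character(ph$iid), 1]
  B <- spline_basis_eval(spline_basis(), ph$age_years)
  colnames(B) <- paste0("s", 1:6)
  dat <- data.frame(y = log(ph$bmi), iid = ph$iid, age = ph$age_years,
                    sex = ph$sex, source = ph$source, dose = ph$dose, B)
  m <- nlme::lme(
    y ~ (s1 + s2 + s3 + s4 + s5 + s6) * sex + source +
      (s1 + s2 + s3 + s4 + s5 + s6) * dose,
    random = ~ 1 + I(age - 8) | iid,
    correlation = nlme::corCAR1(form = ~ age | iid),
    data = dat, method = "REML",
    control = nlme::lmeControl(opt = "optim", maxIter = 200, msMaxIter = 200))
  fit <- x$fit
  expect_equal(fit$reml_loglik, as.numeric(logLik(m)), tolerance = 1e-6)
  expect_equal(unname(fit$beta["dose"]), unname(nlme::fixef(m)["dose"]),
               tolerance = 1e-4)
  expect_equal(fit$varcomps$phi,
               unname(coef(m$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(sqrt(fit$varcomps$sigma2), m$sigma, tolerance = 1e-4)
})

test_that("adding a constant to the response changes only the intercept", {
  x <- fitted_small_cohort()
  fit2 <- reml_fit(x$design, response = x$design$y + 0.5,
                   init = x$fit$varcomps, optimize = FALSE, robust = FALSE)
  delta <- fit2$beta - x$fit$beta
  expect_equal(unname(delta["(Intercept)"]), 0.5, tolerance = 1e-6)
  expect_equal(max(abs(delta[-1])), 0, tolerance = 1e-6)
})

test_that("zero residuals give a zero sandwich covariance", {
  x <- fitted_small_cohort()
  yhat <- drop(x$design$X %*% x$fit$beta)
  V <- sandwich_covariance(x$fit, x$design, response = yhat,
                           cr_adjust = "cr0")
  expect_equal(max(abs(V)), 0, tolerance = 1e-20)
})

test_that("model covariances are symmetric PSD and the fit is reproducible", {
  x <- fitted_small_cohort()
  for (C in list(x$fit$cov_model, x$fit$cov_robust)) {
    expect_equal(C, t(C))
    expect_true(all(eigen(C, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-12))
  }
  expect_true(x$fit$converged)
  expect_true(is.finite(x$fit$reml_loglik))
})

test_that("robust and model-based SEs of the SNP effect agree under a correct model", {
  # large correctly-specified cohort: the sandwich should reproduce the
  # model-based SE to within ~10%
  cfg <- cohort_config(2000, seed = 23L, questionnaire_prob = 0)
  sim <- simulate_cohort(cfg, list(snp_effect_spec(0.3, beta_level = 0.012)))
  d <- build_design(sim$phenotypes, sim$panel$dosages[, 1])
  fit <- reml_fit(d)
  se_model <- sqrt(diag(fit$cov_model))["dose"]
  se_rob <- sqrt(diag(fit$cov_robust))["dose"]
  expect_equal(unname(se_rob / se_model), 1, tolerance = 0.1)
})

test_that("a singular design names the offending columns", {
  x <- fitted_small_cohort()
  zero_dose <- setNames(rep(0, x$cfg$n_individuals),
                        rownames(x$sim$panel$dosages))
  d <- build_design(x$sim$phenotypes, zero_dose)
  expect_error(reml_fit(d), "dose")
})

test_that("the questionnaire-source residual multiplier is recoverable", {
  cfg <- cohort_config(600, seed = 24L, source_error_multiplier = 1.5,
                       questionnaire_prob = 0.3)
  sim <- simulate_cohort(cfg, list(snp_effect_spec(0.3)))
  d <- build_design(sim$phenotypes, sim$panel$dosages[, 1])
  fit <- reml_fit(d, estimate_source_multiplier = TRUE, robust = FALSE)
  expect_equal(fit$varcomps$source_multiplier, 1.5, tolerance = 0.15)
})
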