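test_that("QC drops SNPs below the MAF and imputation-quality thresholds", {
  pan <- toy_panel(eaf = c(0.01, 0.05, 0.10, 0.30, 0.49))
  filt <- qc_filter(pan)
  expect_equal(ncol(filt$dosages), 4)  # MAF exactly 0.05 is retained
  excl <- attr(filt, "exclusions")
  expect_equal(excl$snp, "snp0001")
  expect_equal(excl$reason, "low_maf")

  pan2 <- toy_panel(eaf = c(0.2, 0.3), rsq = c(0.29, 0.30))
  filt2 <- qc_filter(pan2)
  expect_equal(ncol(filt2$dosages), 1)
  expect_equal(attr(filt2, "exclusions")$reason, "low_imputation_quality")

  pan3 <- toy_panel(eaf = c(0.2, 0.3), rsq = c(NA, 1))
  expect_equal(attr(qc_filter(pan3), "exclusions")$reason, "missing_metadata")

  # high-frequency effect alleles are judged by MAF, not EAF
  pan4 <- toy_panel(eaf = c(0.97, 0.6))
  expect_equal(ncol(qc_filter(pan4)$dosages), 1)
})

test_that("the Wald quadratic form matches a brute-force solve oracle", {
  expect_equal(wald_quadratic(rep(0, 4), diag(4)),
               list(statistic = 0, df = 4L, p = 1))
  w <- wald_quadratic(c(1, 1), diag(2))
  expect_equal(w$statistic, 2)
  expect_equal(w$p, exp(-1), tolerance = 1e-12)
  for (s in 1:20) {
    set.seed(s)
    b <- rnorm(7)
    R <- matrix(rnorm(49), 7)
    C <- crossprod(R) + diag(7) * 0.1
    w <- wald_quadratic(b, C)
    oracle <- drop(t(b) %*% solve(C) %*% b)
    expect_equal(w$statistic, oracle, tolerance = 1e-10)
    expect_equal(w$p, pchisq(oracle, 7, lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_error(wald_quadratic(c(1, 2), diag(3)), "matrix")
})

# A hand-built fit/design pair with chosen SNP-block coefficients.
fake_fit <- function(beta_snp, C_snp) {
  p <- 22
  sc <- 16:22
  beta <- setNames(numeric(p), c(
    "(Intercept)", paste0("s", 1:6), "sex", paste0("sex:s", 1:6), "source",
    "dose", paste0("dose:s", 1:6)))
  beta[sc] <- beta_snp
  C <- diag(1e-4, p)
  C[sc, sc] <- C_snp
  fit <- structure(list(beta = beta, cov_model = C, cov_robust = C,
                        varcomps = NULL, reml_loglik = 0,
                        n_individuals = 1000L, n_obs = 8000L,
                        converged = TRUE),
                   class = "traj_fit")
  design <- structure(list(X = matrix(0, 1, p, dimnames = list(NULL, names(beta))),
                           snp_cols = sc, basis = spline_basis()),
                      class = "gwas_design")
  list(fit = fit, design = design)
}

test_that("test_snp computes the level test from the robust SE and the stated z", {
  se <- 0.012 / 5.66
  f <- fake_fit(c(0.012, rep(0, 6)), diag(c(se^2, rep(1e-6, 6))))
  res <- test_snp(f$fit, f$design, snp_id = "rs1")
  expect_equal(res$beta8, 0.012)
  expect_equal(res$se8, se)
  expect_equal(res$p_snp, 2 * pnorm(5.66, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$p_snp, 1.5e-8, tolerance = 0.02)
  # zero interaction coefficients: no trajectory-change signal
  expect_equal(res$W_change, 0)
  expect_equal(res$p_change, 1)
})

test_that("recoding the effect allele negates beta8 and preserves all P-values", {
  x <- fitted_small_cohort()
  d1 <- x$design
  fit1 <- x$fit
  dose_flip <- 2 - x$sim$panel$dosages[, 1]
  d2 <- build_design(x$sim$phenotypes, dose_flip)
  fit2 <- reml_fit(d2, init = fit1$varcomps, optimize = FALSE)
  r1 <- test_snp(fit1, d1)
  r2 <- test_snp(fit2, d2)
  expect_equal(r2$beta8, -r1$beta8, tolerance = 1e-6)
  expect_equal(r2$p_snp, r1$p_snp, tolerance = 1e-6)
  # the multi-df P-values are near- but not exactly invariant: the
  # Satterthwaite effective df is computed in the reported allele's
  # parameterisation (see the methods vignette)
  expect_equal(r2$p_global, r1$p_global, tolerance = 0.01)
  expect_equal(r2$p_change, r1$p_change, tolerance = 0.01)
})

test_that("the age-effect curve equals beta8 at the centre age and matches a sampling oracle", {
  x <- fitted_small_cohort()
  curve <- snp_effect_at_ages(x$fit, x$design, ages = c(2, 8, 10))
  r <- test_snp(x$fit, x$design)
  expect_equal(curve$effect[curve$age == 8], r$beta8, tolerance = 1e-12)
  expect_equal(curve$ci_high, curve$effect + 1.96 * curve$se)
  # Monte-Carlo oracle: sample SNP-block coefficient vectors from the
  # fitted robust covariance and compare the empirical variance at age 10
  sc <- x$design$snp_cols
  set.seed(99)
  draws <- MASS::mvrnorm(1e6, x$fit$beta[sc], x$fit$cov_robust[sc, sc])
  a <- c(1, drop(spline_basis_eval(x$design$basis, 10)))
  v_mc <- var(drop(draws %*% a))
  expect_equal(curve$se[curve$age == 10]^2, v_mc,
               tolerance = 0.02)
  # zero shape coefficients give a flat curve
  f <- fake_fit(c(0.012, rep(0, 6)), diag(7) * 1e-5)
  flat <- snp_effect_at_ages(f$fit, f$design, ages = 1:16)
  expect_equal(flat$effect, rep(0.012, 16))
})

test_that("the GWAS scan reports per-SNP results, skips failures, and is deterministic", {
  cfg <- cohort_config(120, seed = 31L)
  specs <- lapply(runif(6, 0.2, 0.5), function(m) snp_effect_spec(maf = m))
  sim <- simulate_cohort(cfg, specs)
  # make one SNP monomorphic but QC-passable (constant heterozygote dosage)
  sim$panel$dosages[, 3] <- 1
  sim$panel$info$eaf[3] <- 0.5
  res <- run_gwas(sim$phenotypes, sim$panel)
  expect_s3_class(res, "gwas_results")
  expect_equal(nrow(res), 5)
  expect_true(all(res$converged))
  skipped <- attr(res, "skipped")
  expect_equal(skipped$snp, sim$panel$info$snp[3])
  expect_match(skipped$reason, "singular")
  res2 <- run_gwas(sim$phenotypes, sim$panel)
  expect_equal(res, res2, ignore_attr = TRUE)
})

test_that("a strong level effect is detected far more often than under the null", {
  # directional power check at the study's effect size
  hits <- c(effect = 0L, null = 0L)
  for (r in 1:6) {
    cfg <- cohort_config(5000, seed = 4000L + r, questionnaire_prob = 0)
    specs <- list(snp_effect_spec(0.4, beta_level = 0.012),
                  snp_effect_spec(0.4))
    sim <- simulate_cohort(cfg, specs)
    init <- NULL
    for (k in 1:2) {
      d <- build_design(sim$phenotypes, sim$panel$dosages[, k])
      fit <- reml_fit(d, init = init)
      init <- fit$varcomps
      p <- test_snp(fit, d)$p_snp
      if (p < 5e-8) hits[k] <- hits[k] + 1L
    }
  }
  expect_gt(hits["effect"], hits["null"])
})
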