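test_that("the genomic-control factor is the median ratio against the null chi-square median", {
  q <- qchisq(seq(0.1, 0.9, by = 0.1), df = 7)
  expect_equal(gc_lambda(q, 7), 1.0, tolerance = 1e-12)
  expect_equal(gc_lambda(2 * q, 7), 2.0, tolerance = 1e-12)
  set.seed(41)
  draws <- rchisq(1e4, df = 6)
  expect_equal(gc_lambda(draws, 6), 1.00, tolerance = 0.03)
  expect_error(gc_lambda(numeric(0), 7), "empty")
})

test_that("genomic-control adjustment of P-values matches the chi-square tail oracle", {
  p <- c(0.9, 0.5, 0.05, 1e-6)
  expect_equal(gc_adjust(p, 1, 7), p, tolerance = 1e-12)
  expect_equal(gc_adjust(0.05, 2, 1),
               pchisq(qchisq(0.05, 1, lower.tail = FALSE) / 2, 1,
                      lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(gc_adjust(0.05, 2, 1), 0.1658, tolerance = 1e-3)
  # monotone: inflating lambda never shrinks a P-value
  expect_true(all(gc_adjust(p, 1.5, 6) >= p))
  # idempotence of the correction: adjusted statistics have lambda 1
  set.seed(42)
  stats <- 1.4 * rchisq(2001, 7)
  lam <- gc_lambda(stats, 7)
  p_adj <- gc_adjust(pchisq(stats, 7, lower.tail = FALSE), lam, 7)
  stats_adj <- qchisq(p_adj, 7, lower.tail = FALSE)
  expect_equal(gc_lambda(stats_adj, 7), 1, tolerance = 1e-10)
  expect_error(gc_adjust(0, 1.2, 7), "\\(0, 1\\]")
})

test_that("inverse-variance weighting matches the closed-form oracle", {
  r <- ivw_meta(c(0.012, 0.012), c(0.002, 0.002))
  expect_equal(r$beta_meta, 0.012)
  expect_equal(r$se_meta, 0.002 / sqrt(2))
  r2 <- ivw_meta(c(0.4, 0.1), c(0.1, 0.1))
  expect_equal(r2$beta_meta, 0.25, tolerance = 1e-12)
  expect_equal(r2$Q, 4.5, tolerance = 1e-12)
  expect_equal(r2$I2, 100 * (4.5 - 1) / 4.5, tolerance = 1e-10)
  # Q below its df clamps I2 at zero
  r3 <- ivw_meta(c(0.10, 0.101), c(0.1, 0.1))
  expect_equal(r3$I2, 0)
  # k identical studies shrink the SE by exactly sqrt(k)
  for (k in c(3, 7)) {
    rk <- ivw_meta(rep(0.02, k), rep(0.005, k))
    expect_equal(rk$se_meta, 0.005 / sqrt(k), tolerance = 1e-12)
  }
  expect_error(ivw_meta(0.1, 0.1), "2 studies")
  expect_error(ivw_meta(c(0.1, 0.2), c(0.1, 0)), "ses")
})

test_that("weighted Stouffer combination behaves as the normal-quantile formula", {
  # neutral evidence stays neutral under any weighting
  expect_equal(stouffer_meta(c(0.5, 0.5, 0.5), c(10, 100, 1000))$p, 0.5,
               tolerance = 1e-12)
  # closed form for two studies
  p <- c(1e-4, 0.03); N <- c(5000, 2000)
  z <- qnorm(p, lower.tail = FALSE)
  zc <- sum(sqrt(N) * z) / sqrt(sum(N))
  expect_equal(stouffer_meta(p, N)$p, pnorm(zc, lower.tail = FALSE),
               tolerance = 1e-14)
  # invariant to study order and to rescaling all sample sizes
  expect_equal(stouffer_meta(rev(p), rev(N))$p, stouffer_meta(p, N)$p,
               tolerance = 1e-14)
  expect_equal(stouffer_meta(p, 7 * N)$p, stouffer_meta(p, N)$p,
               tolerance = 1e-14)
  expect_error(stouffer_meta(c(0, 0.5), c(1, 1)), "\\(0, 1\\)")
})

make_cohort_results <- function(name, n, beta8, se8, p_global, p_change,
                                snp = "rs1", ea = "C", oa = "T", eaf = 0.7) {
  res <- data.frame(
    snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
    beta8 = beta8, se8 = se8,
    p_snp = 2 * pnorm(abs(beta8 / se8), lower.tail = FALSE),
    W_global = qchisq(p_global, 7, lower.tail = FALSE), p_global = p_global,
    W_change = qchisq(p_change, 6, lower.tail = FALSE), p_change = p_change,
    n_individuals = n, n_obs = 8 * n, converged = TRUE,
    stringsAsFactors = FALSE)
  cohort_results(name, n, res, lambda_1df = 1, lambda_7df = 1,
                 lambda_6df = 1)
}

test_that("combining concordant cohorts strengthens the multi-df evidence", {
  c1 <- make_cohort_results("A", 8000, 0.012, 0.003, 1e-4, 0.01)
  c2 <- make_cohort_results("B", 1500, 0.012, 0.003, 1e-4, 0.01)
  meta <- combine_cohorts(list(c1, c2))
  expect_lt(meta$p_global_meta, 1e-4)
  expect_lt(meta$p_change_meta, 0.01)
  expect_equal(meta$beta_meta, 0.012, tolerance = 1e-12)
  expect_error(combine_cohorts(list(c1)), "at least 2")
})

test_that("effect-allele flips in one cohort are realigned before combination", {
  c1 <- make_cohort_results("A", 8000, 0.012, 0.003, 1e-4, 0.01)
  c2 <- make_cohort_results("B", 1500, 0.010, 0.004, 1e-3, 0.05)
  c2flip <- make_cohort_results("B", 1500, -0.010, 0.004, 1e-3, 0.05,
                                ea = "T", oa = "C", eaf = 0.3)
  m1 <- combine_cohorts(list(c1, c2))
  m2 <- combine_cohorts(list(c1, c2flip))
  expect_equal(m2$beta_meta, m1$beta_meta, tolerance = 1e-12)
  expect_equal(m2$p_global_meta, m1$p_global_meta, tolerance = 1e-12)
  expect_equal(m2$eaf, m1$eaf, tolerance = 1e-12)
})

test_that("unresolvable strand-ambiguous SNPs are dropped with a reason", {
  two_snp <- function(name, eaf_amb) {
    r1 <- make_cohort_results(name, 4000, 0.012, 0.003, 1e-4, 0.01)$results
    r2 <- make_cohort_results(name, 4000, 0.010, 0.004, 1e-3, 0.05,
                              snp = "rs_amb", ea = "A", oa = "T",
                              eaf = eaf_amb)$results
    cohort_results(name, 4000, rbind(r1, r2), lambda_1df = 1,
                   lambda_7df = 1, lambda_6df = 1)
  }
  meta <- combine_cohorts(list(two_snp("A", 0.52), two_snp("B", 0.48)))
  expect_equal(meta$snp, "rs1")
  dropped <- attr(meta, "dropped")
  expect_true("rs_amb" %in% dropped$snp)
  expect_true("allele_mismatch" %in% dropped$reason)
})

test_that("genomic control inflates per-cohort evidence before combination", {
  res <- make_cohort_results("A", 8000, 0.012, 0.003, 1e-4, 0.01)$results
  cA <- cohort_results("A", 8000, res, lambda_1df = 1.2, lambda_7df = 1.1,
                       lambda_6df = 1.05)
  cB <- make_cohort_results("B", 1500, 0.012, 0.003, 1e-4, 0.01)
  m_gc <- combine_cohorts(list(cA, cB), apply_gc = TRUE)
  m_raw <- combine_cohorts(list(cA, cB), apply_gc = FALSE)
  expect_gt(m_gc$p_global_meta, m_raw$p_global_meta)
  expect_gt(m_gc$se_meta, m_raw$se_meta)
  # lambdas below 1 are clamped: never deflate
  expect_equal(cB$lambda_1df, 1)
})
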