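# Per-SNP QC, the three association tests (level at age 8, 7-df global Wald,
# 6-df trajectory-change Wald), and the GWAS scan.

#' SNP quality-control filter
#'
#' Excludes SNPs whose minor allele frequency is strictly below `maf_min`
#' (default 5%) or whose imputation quality is strictly below `rsq_min`
#' (default 0.3). MAF is `min(eaf, 1 - eaf)` from the panel metadata.
#'
#' @param panel a `dosage_panel`.
#' @param maf_min MAF threshold; SNPs with MAF < `maf_min` are dropped.
#' @param rsq_min imputation-quality threshold; SNPs with rsq < `rsq_min`
#'   are dropped.
#' @return the filtered panel, with an `exclusions` attribute: data frame of
#'   dropped SNPs and reasons (`low_maf`, `low_imputation_quality`,
#'   `missing_metadata`).
#' @export
qc_filter <- function(panel, maf_min = 0.05, rsq_min = 0.3) {
  stopifnot(inherits(panel, "dosage_panel"),
            maf_min >= 0, maf_min <= 0.5, rsq_min >= 0, rsq_min <= 1)
  info <- panel$info
  maf <- pmin(info$eaf, 1 - info$eaf)
  reason <- rep(NA_character_, nrow(info))
  reason[is.na(maf) | is.na(info$rsq)] <- "missing_metadata"
  reason[is.na(reason) & maf < maf_min] <- "low_maf"
  reason[is.na(reason) & info$rsq < rsq_min] <- "low_imputation_quality"
  drop <- !is.na(reason)
  excl <- data.frame(snp = info$snp[drop], reason = reason[drop],
                     stringsAsFactors = FALSE)
  out <- panel
  out$info <- info[!drop, , drop = FALSE]
  out$dosages <- panel$dosages[, !drop, drop = FALSE]
  if (!is.null(panel$genotypes))
    out$genotypes <- panel$genotypes[, !drop, drop = FALSE]
  attr(out, "exclusions") <- excl
  out
}

#' Wald quadratic-form test
#'
#' Computes `coeffs' cov^-1 coeffs` and refers it to a chi-square with
#' `length(coeffs)` degrees of freedom. A non-invertible covariance is
#' handled by clipping eigenvalues at 1e-12 and using the pseudo-inverse
#' with rank-adjusted degrees of freedom.
#'
#' @param coeffs coefficient vector.
#' @param cov matching covariance matrix.
#' @return list with `statistic`, `df`, `p`.
#' @export
wald_quadratic <- function(coeffs, cov) {
  coeffs <- as.numeric(coeffs)
  k <- length(coeffs)
  if (!is.matrix(cov) || any(dim(cov) != k))
    stop("cov must be a ", k, " x ", k, " matrix")
  cov <- (cov + t(cov)) / 2
  stat <- tryCatch(drop(crossprod(coeffs, solve(cov, coeffs))),
                   error = function(e) NA_real_)
  df <- k
  if (!is.finite(stat) || stat < 0) {
    e <- eigen(cov, symmetric = TRUE)
    pos <- e$values > 1e-12
    df <- sum(pos)
    if (df == 0) return(list(statistic = 0, df = 0L, p = 1))
    u <- crossprod(e$vectors[, pos, drop = FALSE], coeffs)
    stat <- sum(u^2 / e$values[pos])
  }
  list(statistic = stat, df = as.integer(df),
       p = pchisq(stat, df = df, lower.tail = FALSE))
}

#' The three per-SNP association tests
#'
#' From a fitted per-SNP model with robust covariance:
#' * level effect at age 8: the dosage main-effect coefficient with its
#'   robust SE and a two-sided normal P-value (the age basis vanishes at 8,
#'   so this is the per-allele shift of the whole trajectory);
#' * global test: 7-df Wald quadratic form over the dosage main effect and
#'   the six dosage-by-basis interactions;
#' * change test: 6-df Wald quadratic form over the interactions only
#'   (trajectory shape).
#' All quadratic forms use the cluster-robust covariance block.
#'
#' A k-df quadratic form in a covariance estimated from J cluster scores is
#' the Hotelling T-squared situation: referring it directly to chi-square(k)
#' over-rejects by a factor of order k/J. The multi-df P-values are
#' therefore computed from the scaled-F reference
#' `W (J-k) / (k (J-1)) ~ F(k, J-k)`, and the reported statistic is the
#' chi-square-equivalent `qchisq(p, k, lower.tail = FALSE)`, so that
#' statistic and P-value remain consistent. For cohort-scale J (thousands)
#' the calibration is numerically inert.
#'
#' @param fit a [reml_fit()] with `cov_robust`.
#' @param design the matching [build_design()] object.
#' @param snp_id,effect_allele,other_allele,eaf optional metadata echoed
#'   into the result.
#' @return a one-row data frame of class `"snp_result"`.
#' @export
test_snp <- function(fit, design, snp_id = NA_character_,
                     effect_allele = NA_character_,
                     other_allele = NA_character_, eaf = NA_real_) {
  stopifnot(inherits(fit, "traj_fit"), inherits(design, "gwas_design"))
  if (is.null(fit$cov_robust))
    stop("fit lacks a robust covariance; refit with robust = TRUE")
  sc <- design$snp_cols
  C <- fit$cov_robust[sc, sc, drop = FALSE]
  b <- fit$beta[sc]

  beta8 <- unname(b[1])
  se8 <- sqrt(C[1, 1])
  z <- beta8 / se8
  p_snp <- 2 * pnorm(abs(z), lower.tail = FALSE)

  # Hotelling-type scaled-F calibration of a robust quadratic form, with a
  # Satterthwaite effective df when per-cluster score information is
  # available (falls back to J-1 independent cluster scores otherwise)
  Q <- attr(fit$cov_robust, "cluster_blocks")
  calibrate <- function(raw, sub) {
    k <- raw$df
    nu <- if (!is.null(Q)) aht_effective_df(Q, sub) else
      fit$n_individuals - 1
    if (k == 0 || nu - k + 1 <= 0) return(raw)
    Fstat <- raw$statistic * (nu - k + 1) / (nu * k)
    p <- stats::pf(Fstat, k, nu - k + 1, lower.tail = FALSE)
    list(statistic = qchisq(p, k, lower.tail = FALSE), df = k, p = p)
  }
  glob <- calibrate(wald_quadratic(b, C), 1:7)
  chg <- calibrate(wald_quadratic(b[-1], C[-1, -1, drop = FALSE]), 2:7)

  out <- data.frame(
    snp = snp_id, effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta8 = beta8, se8 = se8, p_snp = p_snp,
    W_global = glob$statistic, p_global = glob$p,
    W_change = chg$statistic, p_change = chg$p,
    n_individuals = fit$n_individuals, n_obs = fit$n_obs,
    converged = fit$converged, stringsAsFactors = FALSE)
  class(out) <- c("snp_result", "data.frame")
  out
}

#' Age-specific SNP effect with robust confidence band
#'
#' The per-allele effect at age t is `beta8 + gamma' B(t)`; its variance is
#' the quadratic form `a' C a` with `a = (1, B(t))` over the 7 SNP columns
#' of the robust covariance.
#'
#' @param fit a [reml_fit()] with `cov_robust`.
#' @param design the matching [build_design()] object.
#' @param ages age grid (years), inside the basis window.
#' @return data frame of class `"age_effect_curve"`: `age`, `effect`, `se`,
#'   `ci_low`, `ci_high` (pointwise 95%).
#' @export
snp_effect_at_ages <- function(fit, design,
                               ages = seq(design$basis$age_window[1],
                                          design$basis$age_window[2] - 1)) {
  stopifnot(inherits(fit, "traj_fit"))
  if (is.null(fit$cov_robust))
    stop("fit lacks a robust covariance; refit with robust = TRUE")
  basis <- design$basis
  if (any(ages < basis$age_window[1] | ages > basis$age_window[2]))
    stop("ages must lie inside the basis window")
  sc <- design$snp_cols
  C <- fit$cov_robust[sc, sc, drop = FALSE]
  b <- fit$beta[sc]
  B <- spline_basis_eval(basis, ages)
  A <- cbind(1, B)
  eff <- drop(A %*% b)
  se <- sqrt(rowSums((A %*% C) * A))
  out <- data.frame(age = ages, effect = eff, se = se,
                    ci_low = eff - 1.96 * se, ci_high = eff + 1.96 * se)
  class(out) <- c("age_effect_curve", "data.frame")
  out
}

#' Run the per-SNP trajectory GWAS
#'
#' Applies QC, then for each surviving SNP builds the per-SNP design, fits
#' the REML mixed model (warm-started at the previous SNP's variance
#' components), computes the sandwich covariance and the three tests.
#' Failures (e.g. a monomorphic SNP making the design singular) are logged
#' and skipped, never aborting the scan.
#'
#' @param phenotypes a phenotype table.
#' @param panel a `dosage_panel`.
#' @param basis the [spline_basis()].
#' @param covariates passed to [build_design()].
#' @param qc apply [qc_filter()] first (default `TRUE`).
#' @param maf_min,rsq_min QC thresholds.
#' @param sig_threshold genome-wide significance threshold applied to each
#'   of the three P-values for the `gw_significant` flag.
#' @param estimate_source_multiplier model a separate residual SD for
#'   questionnaire-source rows (`NULL`, the default, enables it exactly when
#'   the phenotype table has a varying `source` column).
#' @param value_col,log_transform passed to [build_design()].
#' @param verbose print a progress line every 50 SNPs.
#' @return a data frame of class `"gwas_results"` with one row per tested
#'   SNP; attributes `skipped` (data frame of SNP failures) and `exclusions`
#'   (QC report).
#' @export
run_gwas <- function(phenotypes, panel, basis = spline_basis(),
                     covariates = NULL, qc = TRUE, maf_min = 0.05,
                     rsq_min = 0.3, sig_threshold = 5e-8,
                     estimate_source_multiplier = NULL,
                     value_col = "bmi", log_transform = TRUE,
                     verbose = FALSE) {
  stopifnot(inherits(panel, "dosage_panel"))
  if (is.null(estimate_source_multiplier))
    estimate_source_multiplier <- "source" %in% names(phenotypes) &&
      length(unique(phenotypes$source)) > 1
  excl <- NULL
  if (qc) {
    panel <- qc_filter(panel, maf_min = maf_min, rsq_min = rsq_min)
    excl <- attr(panel, "exclusions")
  }
  m <- ncol(panel$dosages)
  if (m == 0) stop("no SNPs left after QC")

  res <- vector("list", m)
  skipped <- data.frame(snp = character(), reason = character(),
                        stringsAsFactors = FALSE)
  init <- NULL
  for (j in seq_len(m)) {
    info <- panel$info[j, ]
    out <- tryCatch({
      dose <- panel$dosages[, j]
      design <- build_design(phenotypes, dose, basis = basis,
                             covariates = covariates, value_col = value_col,
                             log_transform = log_transform)
      fit <- reml_fit(design, init = init, robust = TRUE,
                      estimate_source_multiplier = estimate_source_multiplier)
      init <- fit$varcomps
      test_snp(fit, design, snp_id = info$snp,
               effect_allele = info$effect_allele,
               other_allele = info$other_allele, eaf = info$eaf)
    }, error = function(e) conditionMessage(e))
    if (is.character(out)) {
      skipped <- rbind(skipped, data.frame(snp = info$snp, reason = out,
                                           stringsAsFactors = FALSE))
    } else {
      res[[j]] <- out
    }
    if (verbose && j %% 50 == 0)
      message("  ... ", j, "/", m, " SNPs")
  }
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) stop("all SNPs failed; nothing to report")
  res$gw_significant <- res$p_snp < sig_threshold |
    res$p_global < sig_threshold | res$p_change < sig_threshold
  rownames(res) <- NULL
  class(res) <- c("gwas_results", "data.frame")
  attr(res, "skipped") <- skipped
  attr(res, "exclusions") <- excl
  res
}
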