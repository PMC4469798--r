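# Two-stage meta-analysis across cohorts: genomic control of the per-cohort
# statistics, inverse-variance combination of the age-8 level effect, and
# sqrt(N)-weighted Stouffer combination of the multi-df Wald P-values.

#' Genomic-control inflation factor
#'
#' `lambda = median(statistics) / median of the central chi-square(df)`.
#' A well-calibrated scan gives lambda close to 1; lambda > 1 indicates
#' systematic inflation (e.g. population stratification).
#'
#' @param statistics observed chi-square statistics across SNPs.
#' @param df degrees of freedom of their null distribution (1 for the level
#'   test, 7 for the global Wald, 6 for the change Wald).
#' @return the inflation factor (scalar).
#' @export
gc_lambda <- function(statistics, df) {
  if (length(statistics) == 0) stop("empty statistics vector")
  stopifnot(all(is.finite(statistics)), all(statistics >= 0), df >= 1)
  median(statistics) / qchisq(0.5, df = df)
}

#' Genomic-control adjustment of P-values
#'
#' Each P-value is mapped to its chi-square(df) statistic, the statistic is
#' divided by `lambda`, and the result mapped back to an upper-tail P-value.
#' `lambda = 1` is the identity; `lambda > 1` makes every P-value larger.
#'
#' @param pvalues P-values in (0, 1\].
#' @param lambda inflation factor, >= 1.
#' @param df degrees of freedom of the underlying statistic.
#' @return adjusted P-values.
#' @export
gc_adjust <- function(pvalues, lambda, df) {
  stopifnot(lambda >= 1, df >= 1)
  if (any(pvalues <= 0 | pvalues > 1))
    stop("P-values must lie in (0, 1]")
  stat <- qchisq(pvalues, df = df, lower.tail = FALSE) / lambda
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Weights `1/se^2`; combined effect `sum(w b)/sum(w)`, combined SE
#' `1/sqrt(sum(w))`, two-sided normal P-value; Cochran's Q against
#' chi-square(k-1) and `I2 = max(0, (Q - (k-1))/Q) * 100`.
#'
#' @param betas per-study effect estimates.
#' @param ses per-study standard errors (> 0).
#' @return list with `beta_meta`, `se_meta`, `p_meta`, `Q`, `I2`, `p_het`.
#' @export
ivw_meta <- function(betas, ses) {
  k <- length(betas)
  if (k < 2) stop("need at least 2 studies")
  if (length(ses) != k) stop("betas and ses must have equal length")
  if (any(!is.finite(ses)) || any(ses <= 0)) stop("all ses must be finite and > 0")
  w <- 1 / ses^2
  beta_meta <- sum(w * betas) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  p_meta <- 2 * pnorm(abs(beta_meta / se_meta), lower.tail = FALSE)
  Q <- sum(w * (betas - beta_meta)^2)
  I2 <- max(0, (Q - (k - 1)) / Q) * 100
  if (!is.finite(I2)) I2 <- 0
  p_het <- pchisq(Q, df = k - 1, lower.tail = FALSE)
  list(beta_meta = beta_meta, se_meta = se_meta, p_meta = p_meta,
       Q = Q, I2 = I2, p_het = p_het)
}

#' Sample-size-weighted Stouffer combination of P-values
#'
#' Each P-value is converted to a one-sided standard normal quantile
#' `Z_i = qnorm(p_i, lower.tail = FALSE)` (multi-df chi-square P-values
#' carry no sign), combined as
#' `Z = sum(sqrt(N_i) Z_i) / sqrt(sum(N_i))`, and mapped back through the
#' upper normal tail.
#'
#' @param pvalues per-study P-values in (0, 1).
#' @param sample_sizes per-study sample sizes (> 0), used as squared
#'   weights.
#' @return list with `z` and `p` (combined).
#' @export
stouffer_meta <- function(pvalues, sample_sizes) {
  k <- length(pvalues)
  if (k < 1 || length(sample_sizes) != k)
    stop("pvalues and sample_sizes must have equal positive length")
  if (any(pvalues <= 0 | pvalues >= 1))
    stop("P-values must lie strictly in (0, 1)")
  if (any(sample_sizes <= 0)) stop("sample sizes must be > 0")
  z <- qnorm(pvalues, lower.tail = FALSE)
  zc <- sum(sqrt(sample_sizes) * z) / sqrt(sum(sample_sizes))
  list(z = zc, p = pnorm(zc, lower.tail = FALSE))
}

#' Bundle one cohort's GWAS results for meta-analysis
#'
#' @param name cohort label.
#' @param n sample size (individuals) used for the sqrt(N) Stouffer weight.
#' @param results a `gwas_results` table (or compatible data frame with the
#'   same columns).
#' @param lambda_1df,lambda_7df,lambda_6df optional pre-computed
#'   genomic-control factors; computed from the results when `NULL`.
#' @return an object of class `"cohort_results"`.
#' @export
cohort_results <- function(name, n, results, lambda_1df = NULL,
                           lambda_7df = NULL, lambda_6df = NULL) {
  need <- c("snp", "effect_allele", "other_allele", "eaf", "beta8", "se8",
            "p_snp", "W_global", "p_global", "W_change", "p_change")
  miss <- setdiff(need, names(results))
  if (length(miss))
    stop("results table lacks column(s): ", paste(miss, collapse = ", "))
  if (n <= 0) stop("n must be positive")
  if (is.null(lambda_1df))
    lambda_1df <- gc_lambda((results$beta8 / results$se8)^2, df = 1)
  if (is.null(lambda_7df)) lambda_7df <- gc_lambda(results$W_global, df = 7)
  if (is.null(lambda_6df)) lambda_6df <- gc_lambda(results$W_change, df = 6)
  structure(
    list(name = name, n = n, results = as.data.frame(results),
         lambda_1df = max(1, lambda_1df), lambda_7df = max(1, lambda_7df),
         lambda_6df = max(1, lambda_6df)),
    class = "cohort_results")
}

#' @export
print.cohort_results <- function(x, ...) {
  cat("Cohort", x$name, ": N =", x$n, ",", nrow(x$results), "SNPs; lambda =",
      format(c(x$lambda_1df, x$lambda_7df, x$lambda_6df), digits = 3), "\n")
  invisible(x)
}

# Align one cohort row to the reference alleles; returns the row with
# beta8/eaf flipped if needed, or NULL if unresolvable. Strand-ambiguous
# (A/T, C/G) SNPs are oriented by allele frequency when both frequencies are
# clearly away from 0.5, otherwise given up on.
align_alleles <- function(row, ea, oa, ref_eaf) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  r_ea <- toupper(row$effect_allele); r_oa <- toupper(row$other_allele)
  if (!all(c(r_ea, r_oa, ea, oa) %in% names(comp))) return(NULL)
  flip_row <- function(r) {
    r$beta8 <- -r$beta8
    r$eaf <- 1 - r$eaf
    r$effect_allele <- ea; r$other_allele <- oa
    r
  }
  keep_row <- function(r) {
    r$effect_allele <- ea; r$other_allele <- oa
    r
  }
  ambiguous <- unname(r_ea == comp[r_oa])
  if (ambiguous) {
    if (!setequal(c(r_ea, r_oa), c(ea, oa)) &&
        !setequal(c(comp[r_ea], comp[r_oa]), c(ea, oa))) return(NULL)
    if (abs(row$eaf - 0.5) <= 0.1 || abs(ref_eaf - 0.5) <= 0.1) return(NULL)
    same_side <- (row$eaf > 0.5) == (ref_eaf > 0.5)
    return(if (same_side) keep_row(row) else flip_row(row))
  }
  if (r_ea == ea && r_oa == oa) return(row)
  if (r_ea == oa && r_oa == ea) return(flip_row(row))
  if (comp[r_ea] == ea && comp[r_oa] == oa) return(keep_row(row))
  if (comp[r_ea] == oa && comp[r_oa] == ea) return(flip_row(row))
  NULL
}

#' Combine cohort results into the two-stage meta-analysis
#'
#' Per SNP (matched on id, alleles aligned by flipping and strand
#' complementing; unresolvable mismatches are dropped with a reason):
#' * the age-8 level effect is combined by inverse-variance weighting, with
#'   per-cohort SEs inflated by `sqrt(lambda_1df)` when `apply_gc`;
#' * the 7-df global and 6-df change P-values are genomic-control adjusted
#'   with the per-cohort `lambda_7df`/`lambda_6df` and combined by
#'   sqrt(N)-weighted Stouffer;
#' * Cochran's Q, I2 and the heterogeneity P come from the IVW inputs.
#'
#' @param cohorts list of [cohort_results()] objects (>= 2).
#' @param apply_gc apply genomic control (default `TRUE`).
#' @return a data frame of class `"meta_results"`, one row per SNP present
#'   in all cohorts; attribute `dropped` lists unmatched/unalignable SNPs.
#' @export
combine_cohorts <- function(cohorts, apply_gc = TRUE) {
  if (length(cohorts) < 2)
    stop("meta-analysis requires at least 2 cohorts")
  lapply(cohorts, function(ch) {
    if (!inherits(ch, "cohort_results"))
      stop("all elements must be cohort_results objects")
  })
  ref <- cohorts[[1]]$results
  snps <- ref$snp
  for (ch in cohorts[-1]) snps <- intersect(snps, ch$results$snp)
  dropped <- data.frame(snp = character(), reason = character(),
                        stringsAsFactors = FALSE)
  for (ch in cohorts) {
    un <- setdiff(ch$results$snp, snps)
    if (length(un))
      dropped <- rbind(dropped, data.frame(snp = un, reason = "unmatched_id",
                                           stringsAsFactors = FALSE))
  }
  Ns <- vapply(cohorts, function(ch) ch$n, numeric(1))
  out <- vector("list", length(snps))
  for (i in seq_along(snps)) {
    s <- snps[i]
    ref_row <- ref[ref$snp == s, ][1, ]
    ea <- toupper(ref_row$effect_allele); oa <- toupper(ref_row$other_allele)
    rows <- vector("list", length(cohorts))
    ok <- TRUE
    for (j in seq_along(cohorts)) {
      r <- cohorts[[j]]$results
      r <- r[r$snp == s, ][1, ]
      a <- if (j == 1) r else align_alleles(r, ea, oa, ref_row$eaf)
      if (is.null(a)) { ok <- FALSE; break }
      rows[[j]] <- a
    }
    if (!ok) {
      dropped <- rbind(dropped, data.frame(snp = s, reason = "allele_mismatch",
                                           stringsAsFactors = FALSE))
      next
    }
    betas <- vapply(rows, function(r) r$beta8, numeric(1))
    ses <- vapply(rows, function(r) r$se8, numeric(1))
    pg <- vapply(rows, function(r) r$p_global, numeric(1))
    pc <- vapply(rows, function(r) r$p_change, numeric(1))
    if (apply_gc) {
      l1 <- vapply(cohorts, function(ch) ch$lambda_1df, numeric(1))
      l7 <- vapply(cohorts, function(ch) ch$lambda_7df, numeric(1))
      l6 <- vapply(cohorts, function(ch) ch$lambda_6df, numeric(1))
      ses <- ses * sqrt(l1)
      pg <- vapply(seq_along(pg), function(j) gc_adjust(pg[j], l7[j], 7),
                   numeric(1))
      pc <- vapply(seq_along(pc), function(j) gc_adjust(pc[j], l6[j], 6),
                   numeric(1))
    }
    ivw <- ivw_meta(betas, ses)
    sg <- stouffer_meta(pg, Ns)
    sc <- stouffer_meta(pc, Ns)
    eafs <- vapply(rows, function(r) r$eaf, numeric(1))
    out[[i]] <- data.frame(
      snp = s, effect_allele = ea, other_allele = oa,
      eaf = sum(Ns * eafs) / sum(Ns),
      beta_meta = ivw$beta_meta, se_meta = ivw$se_meta, p_meta = ivw$p_meta,
      p_global_meta = sg$p, p_change_meta = sc$p,
      Q = ivw$Q, I2 = ivw$I2, p_het = ivw$p_het,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) stop("no SNPs could be meta-analysed")
  for (j in seq_along(cohorts)) {
    nm <- cohorts[[j]]$name
    out[[paste0("lambda_1df_", nm)]] <- cohorts[[j]]$lambda_1df
    out[[paste0("lambda_7df_", nm)]] <- cohorts[[j]]$lambda_7df
    out[[paste0("lambda_6df_", nm)]] <- cohorts[[j]]$lambda_6df
  }
  rownames(out) <- NULL
  class(out) <- c("meta_results", "data.frame")
  attr(out, "dropped") <- dropped
  out
}
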