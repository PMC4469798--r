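# Post-GWAS characterisation of a locus: genotype-specific BMI trajectories,
# the earliest age at which the effect is detectable, and conversion of
# log-scale effects to kg/m^2.

#' Predicted BMI trajectory by genotype
#'
#' Evaluates the fitted population-average log-BMI curve at a fixed sex and
#' allele count (0, 1 or 2), with source and any principal components held
#' at zero (clinic measurement, cohort-average ancestry), and exponentiates
#' back to kg/m^2.
#'
#' @param fit a [reml_fit()] object.
#' @param design the matching [build_design()] object (supplies the basis
#'   and column layout).
#' @param genotype allele count: 0, 1 or 2.
#' @param sex 0 = female, 1 = male.
#' @param ages age grid in years, inside the basis window.
#' @return data frame with columns `age`, `bmi` (kg/m^2).
#' @export
genotype_trajectory <- function(fit, design, genotype, sex = 0,
                                ages = seq(design$basis$age_window[1],
                                           design$basis$age_window[2],
                                           by = 0.25)) {
  stopifnot(inherits(fit, "traj_fit"), inherits(design, "gwas_design"))
  if (!genotype %in% c(0, 1, 2)) stop("genotype must be 0, 1 or 2")
  if (!sex %in% c(0, 1)) stop("sex must be 0 (female) or 1 (male)")
  basis <- design$basis
  if (any(ages < basis$age_window[1] | ages > basis$age_window[2]))
    stop("ages must lie inside the basis window")
  B <- spline_basis_eval(basis, ages)
  Xp <- matrix(0, length(ages), ncol(design$X),
               dimnames = list(NULL, colnames(design$X)))
  Xp[, "(Intercept)"] <- 1
  Xp[, paste0("s", seq_len(basis$dim))] <- B
  Xp[, "sex"] <- sex
  Xp[, paste0("sex:s", seq_len(basis$dim))] <- B * sex
  Xp[, "dose"] <- genotype
  Xp[, paste0("dose:s", seq_len(basis$dim))] <- B * genotype
  data.frame(age = ages, bmi = exp(drop(Xp %*% fit$beta)))
}

#' Earliest age at which a SNP effect is detectable
#'
#' Scans an age-effect curve on an integer grid for the smallest age at
#' which the pointwise 95% confidence interval excludes zero *and* every
#' later grid age also excludes zero on the same side. Requiring persistence
#' to the end of the grid avoids isolated-age false positives.
#'
#' @param curve an [snp_effect_at_ages()] data frame (`age`, `effect`,
#'   `ci_low`, `ci_high`).
#' @return the earliest detectable age (years), or `NA` if none qualifies.
#' @export
earliest_detectable_age <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("age", "ci_low", "ci_high") %in% names(curve)))
  curve <- curve[order(curve$age), ]
  side <- ifelse(curve$ci_low > 0, 1L, ifelse(curve$ci_high < 0, -1L, 0L))
  n <- length(side)
  for (i in seq_len(n)) {
    if (side[i] != 0L && all(side[i:n] == side[i]))
      return(curve$age[i])
  }
  NA_real_
}

#' Convert a log-scale BMI effect to kg/m^2
#'
#' A per-allele effect `beta_log` on log-BMI corresponds, at a population
#' mean log-BMI of `mu`, to a difference of
#' `exp(mu + beta_log) - exp(mu)` kg/m^2 per allele.
#'
#' @param beta_log per-allele effect on the natural-log scale.
#' @param mu population mean log-BMI at the reference age (default 2.80,
#'   i.e. about 16.4 kg/m^2 at age 8).
#' @return effect in kg/m^2 per allele.
#' @export
effect_to_bmi_units <- function(beta_log, mu = 2.80) {
  stopifnot(is.finite(mu))
  exp(mu + beta_log) - exp(mu)
}
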