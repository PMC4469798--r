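# Synthetic cohorts with the exact statistical structure the per-SNP model
# assumes: HWE dosages with imputation noise, sex-specific mean curves on the
# log-BMI scale, additive SNP effects on level and shape, individual random
# intercept/slope, and CAR(1) measurement noise.

#' Reference visit schedule and mean BMI by age bin
#'
#' Age-bin structure used by default for simulated visit schedules and for
#' the default population mean curve: bin centres (years), per-bin inclusion
#' probabilities, and mean BMI (kg/m^2) per bin. The values emulate the
#' unbalanced repeated-measures structure of a large UK birth cohort with
#' roughly 1--17 year follow-up and ~8.8 visits per child on average.
#'
#' @return data frame with columns `centre`, `prob`, `mean_bmi`.
#' @export
reference_visit_schedule <- function() {
  data.frame(
    centre   = c(1.25, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17),
    prob     = c(2372, 5490, 1679, 5949, 1602, 3322, 2728, 3588, 4376, 5516,
                 4710, 5116, 5268, 4603, 2342, 1659, 91) / 7916,
    mean_bmi = c(17.42, 16.82, 16.48, 16.25, 16.02, 15.71, 16.10, 16.30,
                 17.15, 17.67, 18.25, 19.04, 19.64, 20.30, 21.28, 21.39, 22.46))
}

# Least-squares fit of (intercept + 6-dim basis) through the log bin means,
# with the intercept (value at age 8) overridden by `intercept_mu`.
default_mean_curve <- function(basis, intercept_mu) {
  sched <- reference_visit_schedule()
  B <- spline_basis_eval(basis, sched$centre)
  cf <- unname(coef(lm(log(sched$mean_bmi) ~ B)))
  cf[1] <- intercept_mu
  cf
}

#' Configuration for a synthetic longitudinal cohort
#'
#' @param n_individuals number of children.
#' @param age_window modelling window in years.
#' @param visits visit schedule: `NULL` for the default unbalanced schedule
#'   (per-bin inclusion from [reference_visit_schedule()], ages jittered by
#'   +/- `jitter` years); a single *integer* (e.g. `6L`) for that many
#'   uniform random ages per child; or a numeric (double) vector of ages
#'   visited by every child, e.g. `c(8)` or `4:12 + 0.5`.
#' @param jitter half-width (years) of the uniform age jitter around bin
#'   centres under the default schedule.
#' @param sex_ratio proportion male (sex coded 0 = female, 1 = male).
#' @param intercept_mu population mean log-BMI at age 8 (log kg/m^2).
#' @param resid_sd within-person residual SD on the log scale.
#' @param car1_phi residual autocorrelation at a 1-year lag, in \[0, 1).
#' @param random_effect_cov 2x2 covariance of the individual random
#'   intercept and linear age slope (log^2 scale).
#' @param sex_effects length-7 vector: male-female difference at age 8
#'   followed by six sex-by-basis coefficients. The default encodes a small
#'   linear-in-age difference (+0.012 log units at age 1 falling to -0.004
#'   at age 17, +0.005 at age 8).
#' @param source_error_multiplier residual SD multiplier for
#'   questionnaire-source measurements.
#' @param questionnaire_prob probability that a measurement is
#'   questionnaire-sourced rather than clinic-measured.
#' @param random_curve_sd 6-vector of SDs for individual-level random
#'   coefficients on the age basis functions (default all zero). Nonzero
#'   values generate individual trajectory shapes richer than the random
#'   intercept + slope the analysis model assumes — the working-model
#'   misspecification scenario the cluster-robust covariance protects
#'   against.
#' @param mean_curve_params optional list with elements `female` and `male`,
#'   each a 7-vector (value at age 8 + six basis coefficients) of the
#'   population mean log-BMI curve; by default the female curve is fitted
#'   through the reference bin means and the male curve adds `sex_effects`.
#' @param basis the [spline_basis()] used both to generate and to analyse.
#' @param seed integer seed; all randomness in the generators flows from it.
#' @return an object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_individuals,
                          age_window = c(1, 17),
                          visits = NULL,
                          jitter = 0.4,
                          sex_ratio = 0.512,
                          intercept_mu = 2.80,
                          resid_sd = 0.057,
                          car1_phi = 0.5,
                          random_effect_cov = matrix(c(1.16e-2, 3.5e-4,
                                                       3.5e-4, 1.0e-4), 2),
                          sex_effects = c(5e-3, -1e-3, 0, 0, 0, 0, 0),
                          source_error_multiplier = 1.5,
                          questionnaire_prob = 0.25,
                          random_curve_sd = rep(0, 6),
                          mean_curve_params = NULL,
                          basis = spline_basis(age_window = age_window),
                          seed = 1L) {
  stopifnot(n_individuals >= 1, resid_sd >= 0,
            car1_phi >= 0, car1_phi < 1,
            sex_ratio >= 0, sex_ratio <= 1,
            is.matrix(random_effect_cov),
            all(dim(random_effect_cov) == 2),
            length(sex_effects) == basis$dim + 1L,
            length(random_curve_sd) == basis$dim,
            all(random_curve_sd >= 0),
            source_error_multiplier > 0)
  if (max(abs(random_effect_cov - t(random_effect_cov))) > 1e-12)
    stop("random_effect_cov must be symmetric")
  if (any(eigen(random_effect_cov, symmetric = TRUE,
                only.values = TRUE)$values < -1e-10))
    stop("random_effect_cov must be positive semidefinite")
  if (is.null(mean_curve_params)) {
    female <- default_mean_curve(basis, intercept_mu)
    mean_curve_params <- list(female = female, male = female + sex_effects)
  }
  stopifnot(length(mean_curve_params$female) == basis$dim + 1L,
            length(mean_curve_params$male) == basis$dim + 1L)
  structure(
    list(n_individuals = as.integer(n_individuals), age_window = age_window,
         visits = visits, jitter = jitter, sex_ratio = sex_ratio,
         intercept_mu = intercept_mu, resid_sd = resid_sd,
         car1_phi = car1_phi, random_effect_cov = random_effect_cov,
         sex_effects = sex_effects,
         source_error_multiplier = source_error_multiplier,
         questionnaire_prob = questionnaire_prob,
         random_curve_sd = random_curve_sd,
         mean_curve_params = mean_curve_params, basis = basis,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Per-SNP effect specification for the simulator
#'
#' @param maf minor (= effect) allele frequency, in (0, 0.5\].
#' @param beta_level additive per-allele effect on log-BMI at age 8.
#' @param beta_shape 6-vector of additive per-allele effects on the
#'   basis-interaction coefficients (trajectory shape).
#' @param imputation_rsq target imputation quality: squared correlation
#'   between observed dosage and true genotype, in (0, 1\].
#' @return an object of class `"snp_effect_spec"`.
#' @export
snp_effect_spec <- function(maf, beta_level = 0, beta_shape = rep(0, 6),
                            imputation_rsq = 1) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  if (!is.numeric(imputation_rsq) || imputation_rsq <= 0 || imputation_rsq > 1)
    stop("imputation_rsq must lie in (0, 1]")
  stopifnot(length(beta_level) == 1, length(beta_shape) == 6)
  structure(list(maf = maf, beta_level = beta_level,
                 beta_shape = beta_shape, imputation_rsq = imputation_rsq),
            class = "snp_effect_spec")
}

#' Simulate an imputed dosage panel under Hardy-Weinberg equilibrium
#'
#' True genotypes are drawn as Binomial(2, maf) counts of the effect allele.
#' Imputation noise follows the posterior-mean moment match
#' \eqn{d = (1-a)\,2p + a\,g + \epsilon} with \eqn{a = r^2} and
#' \eqn{Var(\epsilon) = r^2 (1 - r^2)\, 2p(1-p)}, which gives
#' \eqn{E(d) = 2p}, \eqn{Var(d) = r^2\,Var(g)} and
#' \eqn{cor^2(d, g) = r^2}; dosages are then clipped to \[0, 2\].
#'
#' @param config a [cohort_config()] (supplies `n_individuals` and `seed`).
#' @param specs list of [snp_effect_spec()]s, optionally named by SNP id.
#' @return an object of class `"dosage_panel"`: list with `dosages`
#'   (individuals x SNPs matrix), `info` (SNP metadata: alleles, effect
#'   allele frequency computed as `mean(dosage)/2`, imputation quality) and
#'   `genotypes` (the latent true genotypes, kept for validation).
#' @export
simulate_dosages <- function(config, specs) {
  stopifnot(inherits(config, "cohort_config"), length(specs) >= 1)
  lapply(specs, function(s) {
    if (!inherits(s, "snp_effect_spec")) stop("specs must be snp_effect_spec objects")
  })
  set.seed(config$seed)
  n <- config$n_individuals
  m <- length(specs)
  ids <- sprintf("I%05d", seq_len(n))
  snp_ids <- names(specs)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%04d", seq_len(m))

  G <- matrix(0L, n, m, dimnames = list(ids, snp_ids))
  D <- matrix(0, n, m, dimnames = list(ids, snp_ids))
  al <- t(vapply(seq_len(m), function(j) sample(c("A", "C", "G", "T"), 2),
                 character(2)))
  for (j in seq_len(m)) {
    p <- specs[[j]]$maf
    r2 <- specs[[j]]$imputation_rsq
    g <- rbinom(n, 2L, p)
    if (r2 >= 1) {
      d <- as.numeric(g)
    } else {
      # clipping to [0,2] truncates the noise and would push the realised
      # r^2 above target; a short fixed-point on the noise SD compensates
      eps <- rnorm(n)
      s <- sqrt(r2 * (1 - r2) * 2 * p * (1 - p))
      for (it in 1:4) {
        d <- pmin(pmax((1 - r2) * 2 * p + r2 * g + s * eps, 0), 2)
        r2_hat <- suppressWarnings(cor(d, g)^2)
        if (!is.finite(r2_hat) || abs(r2_hat - r2) < 1e-4) break
        s <- s * sqrt((r2_hat / (1 - r2_hat)) / (r2 / (1 - r2)))
      }
    }
    G[, j] <- g
    D[, j] <- d
  }
  info <- data.frame(
    snp = snp_ids, effect_allele = al[, 1], other_allele = al[, 2],
    eaf = colMeans(D) / 2,
    rsq = vapply(specs, function(s) s$imputation_rsq, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(dosages = D, info = info, genotypes = G),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat("Dosage panel:", nrow(x$dosages), "individuals x",
      ncol(x$dosages), "SNPs\n")
  invisible(x)
}

# CAR(1)-correlated residual vector for one individual's visit ages.
car1_noise <- function(times, phi, sd_vec) {
  m <- length(times)
  z <- rnorm(m)
  if (phi == 0 || m == 1) return(sd_vec * z)
  S <- car1_matrix(times, phi)
  diag(S) <- diag(S) + 1e-10
  sd_vec * drop(t(chol(S)) %*% z)
}

#' Simulate longitudinal log-BMI phenotypes
#'
#' For individual i at age t the simulated log-BMI is
#' \deqn{\mu_{sex}(t) + \sum_s d_{is}(\beta_s + \gamma_s^T B(t)) + b_{i0} +
#'   b_{i1}(t - 8) + e_i(t)}
#' where B(t) is the centred spline basis, \eqn{(b_{i0}, b_{i1})} is
#' bivariate normal with the configured covariance, and \eqn{e_i} has SD
#' `resid_sd` (times the source multiplier on questionnaire rows) and CAR(1)
#' correlation `car1_phi^|t - s|`. BMI is returned on the original kg/m^2
#' scale (exponentiated).
#'
#' @param config a [cohort_config()].
#' @param panel a [simulate_dosages()] panel aligned with `config`.
#' @param causal named list mapping SNP ids in the panel to
#'   [snp_effect_spec()]s whose `beta_level`/`beta_shape` act on the
#'   phenotype; empty for a null cohort.
#' @return a data frame of class `"phenotype_table"` with columns `iid`,
#'   `sex`, `age_years`, `bmi`, `source`.
#' @export
simulate_phenotypes <- function(config, panel, causal = list()) {
  stopifnot(inherits(config, "cohort_config"), inherits(panel, "dosage_panel"))
  if (nrow(panel$dosages) != config$n_individuals)
    stop("panel size does not match config n_individuals")
  unknown <- setdiff(names(causal), colnames(panel$dosages))
  if (length(unknown))
    stop("causal SNP id(s) not in panel: ", paste(unknown, collapse = ", "))

  set.seed((config$seed %% 1000000L) * 2017L + 77L)
  n <- config$n_individuals
  ids <- rownames(panel$dosages)
  sex <- rbinom(n, 1L, config$sex_ratio)
  b <- MASS::mvrnorm(n, c(0, 0), config$random_effect_cov)
  if (!is.matrix(b)) b <- matrix(b, nrow = n)
  curve_sd <- config$random_curve_sd
  bs <- if (any(curve_sd > 0)) {
    matrix(rnorm(n * length(curve_sd)), n) %*% diag(curve_sd)
  } else NULL

  sched <- reference_visit_schedule()
  age_l <- src_l <- lbmi_l <- vector("list", n)
  nvis <- integer(n)
  for (i in seq_len(n)) {
    if (is.null(config$visits)) {
      repeat {
        inc <- runif(nrow(sched)) < sched$prob
        if (any(inc)) break
      }
      ages <- sched$centre[inc] +
        runif(sum(inc), -config$jitter, config$jitter)
    } else if (length(config$visits) == 1L && is.integer(config$visits)) {
      ages <- runif(config$visits, config$age_window[1], config$age_window[2])
    } else {
      ages <- config$visits
    }
    ages <- sort(pmin(pmax(ages, config$age_window[1]), config$age_window[2]))
    m <- length(ages)
    src <- as.integer(runif(m) < config$questionnaire_prob)
    cf <- if (sex[i] == 1) config$mean_curve_params$male else
      config$mean_curve_params$female
    B <- spline_basis_eval(config$basis, ages)
    mu <- cf[1] + drop(B %*% cf[-1])
    for (s in names(causal)) {
      sp <- causal[[s]]
      mu <- mu + panel$dosages[i, s] *
        (sp$beta_level + drop(B %*% sp$beta_shape))
    }
    sd_vec <- config$resid_sd *
      ifelse(src == 1, config$source_error_multiplier, 1)
    e <- if (config$resid_sd > 0) car1_noise(ages, config$car1_phi, sd_vec)
         else numeric(m)
    lbmi <- mu + b[i, 1] + b[i, 2] * (ages - config$basis$centre_age) + e
    if (!is.null(bs)) lbmi <- lbmi + drop(B %*% bs[i, ])
    age_l[[i]] <- ages
    src_l[[i]] <- src
    lbmi_l[[i]] <- lbmi
    nvis[i] <- m
  }
  out <- data.frame(
    iid = rep(ids, nvis), sex = rep(sex, nvis),
    age_years = unlist(age_l), bmi = exp(unlist(lbmi_l)),
    source = unlist(src_l), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Simulate a complete cohort (dosages + phenotypes)
#'
#' @inheritParams simulate_phenotypes
#' @param specs list of [snp_effect_spec()]s; SNPs whose `beta_level` or
#'   `beta_shape` is nonzero act causally on the phenotype.
#' @return list with elements `panel` and `phenotypes`.
#' @export
simulate_cohort <- function(config, specs) {
  panel <- simulate_dosages(config, specs)
  snp_ids <- colnames(panel$dosages)
  causal <- Filter(function(s) s$beta_level != 0 || any(s$beta_shape != 0),
                   setNames(specs, snp_ids))
  list(panel = panel,
       phenotypes = simulate_phenotypes(config, panel, causal = causal))
}
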