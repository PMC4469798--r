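# Shared fixtures, memoised so expensive simulations run once per session.

.ggw_cache <- new.env(parent = emptyenv())

ggw_cached <- function(key, expr) {
  if (!exists(key, envir = .ggw_cache))
    assign(key, expr, envir = .ggw_cache)
  get(key, envir = .ggw_cache)
}

# Hand-built dosage panel for QC and IO tests.
toy_panel <- function(eaf = c(0.01, 0.05, 0.10, 0.30, 0.49),
                      rsq = rep(1, length(eaf)), n = 6) {
  m <- length(eaf)
  D <- matrix(rep(2 * eaf, each = n), n, m)
  rownames(D) <- sprintf("I%05d", seq_len(n))
  colnames(D) <- sprintf("snp%04d", seq_len(m))
  info <- data.frame(snp = colnames(D),
                     effect_allele = rep_len(c("A", "C"), m),
                     other_allele = rep_len(c("G", "T"), m),
                     eaf = eaf, rsq = rsq, stringsAsFactors = FALSE)
  structure(list(dosages = D, info = info, genotypes = NULL),
            class = "dosage_panel")
}

# A small cohort with one causal SNP, fitted once and reused.
fitted_small_cohort <- function() {
  ggw_cached("small_fit", {
    cfg <- cohort_config(250, seed = 901L)
    specs <- list(snp_effect_spec(0.3, beta_level = 0.03,
                                  beta_shape = c(2e-3, 0, 0, -1e-4, 0, 0)),
                  snp_effect_spec(0.4))
    sim <- simulate_cohort(cfg, specs)
    design <- build_design(sim$phenotypes, sim$panel$dosages[, 1])
    fit <- reml_fit(design)
    list(cfg = cfg, sim = sim, design = design, fit = fit)
  })
}

# Null GWAS scan at the generator defaults: 500 SNPs x 400 individuals.
# Used for the calibration (lambda) and P-value uniformity checks.
null_scan <- function() {
  ggw_cached("null_scan", {
    seed <- 424242L
    set.seed(seed)
    cfg <- cohort_config(400, seed = seed)
    specs <- lapply(runif(500, 0.1, 0.5),
                    function(m) snp_effect_spec(maf = m))
    sim <- simulate_cohort(cfg, specs)
    run_gwas(sim$phenotypes, sim$panel)
  })
}
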