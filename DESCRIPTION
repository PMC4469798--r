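Package: growthgwas
Title: Longitudinal GWAS of Growth Trajectories with Spline Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide association analysis of repeated anthropometric
    measurements across childhood. Fits, per SNP, a semi-parametric linear
    mixed model for log-scale body mass index with a truncated-power cubic
    spline in age (knots at 2, 8 and 12 years, centred at age 8), individual
    random intercepts and age slopes, and continuous-time AR(1) residual
    correlation, estimated by REML. Cluster-robust (sandwich) covariances
    give three association tests: the SNP level effect at age 8, a 7-df
    global Wald test, and a 6-df trajectory-change Wald test. Cohort results
    are combined by inverse-variance meta-analysis of the level effect and
    genomic-control-adjusted, sqrt(N)-weighted Stouffer combination of the
    multi-df Wald P-values, with Cochran heterogeneity statistics. A
    synthetic-cohort generator emulates the repeated-measures structure of
    childhood BMI studies (irregular visit schedules, sex-specific mean
    curves, Hardy-Weinberg dosages with imputation noise) so the whole
    pipeline is testable without access-controlled cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
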