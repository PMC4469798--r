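# REML fitting of the trajectory mixed model: individual random intercept +
# age slope, CAR(1) residual correlation, optional questionnaire-source
# residual SD multiplier, and cluster-robust sandwich covariance.

#' Continuous-time AR(1) correlation matrix
#'
#' Entry (j, k) is `phi^|t_j - t_k|`: the residual correlation between two
#' measurements on the same individual decays geometrically with the time
#' gap in years, with `phi` the correlation at a 1-year lag.
#'
#' @param times visit ages (years) of one individual.
#' @param phi correlation at a 1-year gap, in \[0, 1).
#' @return a `length(times)` square correlation matrix.
#' @export
car1_matrix <- function(times, phi) {
  stopifnot(is.numeric(times), all(is.finite(times)))
  if (!is.numeric(phi) || length(phi) != 1 || phi < 0 || phi >= 1)
    stop("phi must lie in [0, 1)")
  dt <- abs(outer(times, times, "-"))
  if (phi == 0) {
    S <- ifelse(dt == 0, 1, 0)
  } else {
    S <- phi^dt
  }
  matrix(S, length(times), length(times))
}

# Unconstrained parameter vector <-> variance structure.
# A = G/sigma2 via its Cholesky factor (log-diagonal), phi via logistic,
# source multiplier via log.
theta_to_struct <- function(theta, est_mult) {
  L <- matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
  list(A = L %*% t(L),
       phi = stats::plogis(theta[4]),
       mult = if (est_mult) exp(theta[5]) else attr(theta, "mult"))
}

struct_to_theta <- function(A, phi, mult, est_mult) {
  L <- tryCatch(t(chol(A + diag(1e-30, 2))), error = function(e) {
    diag(sqrt(pmax(diag(A), 1e-30)))
  })
  th <- c(log(max(L[1, 1], 1e-15)), L[2, 1], log(max(L[2, 2], 1e-15)),
          stats::qlogis(min(max(phi, 1e-300), 1 - 1e-6)))
  if (est_mult) th <- c(th, log(mult)) else attr(th, "mult") <- mult
  th
}

design_clusters <- function(design) {
  cl <- design$cluster
  idx <- which(c(TRUE, cl[-1] != cl[-length(cl)]))
  list(starts = as.integer(idx - 1L),
       ends = as.integer(c(idx[-1] - 1L, length(cl)) - 1L))
}

#' Fit the trajectory mixed model by REML
#'
#' Maximises the restricted likelihood of the linear mixed model with fixed
#' effects given by the design matrix, an individual-level random intercept
#' and linear age slope with unstructured 2x2 covariance G, CAR(1) residual
#' correlation, and (optionally) a separate residual SD multiplier for
#' questionnaire-source rows. The fixed effects and residual variance are
#' profiled out, so the optimiser works on (G/sigma2, phi\[, multiplier\])
#' through an unconstrained parameterisation (log-Cholesky for G/sigma2,
#' logistic for phi, log for the multiplier). Spline age terms are
#' deliberately fixed-only: this is the working-model misspecification that
#' the cluster-robust covariance guards against.
#'
#' @param design a [build_design()] object.
#' @param response response vector; defaults to the log-scale response
#'   stored in the design.
#' @param init optional starting values: list with any of `G` (2x2), `sigma2`,
#'   `phi`, `source_multiplier`.
#' @param estimate_source_multiplier estimate the questionnaire residual SD
#'   multiplier (default `FALSE`: multiplier fixed at its `init` value, 1
#'   unless supplied).
#' @param robust also compute the cluster-robust sandwich covariance
#'   (default `TRUE`).
#' @param cr_adjust small-sample adjustment for the sandwich meat: `"cr2"`
#'   (default, Bell-McCaffrey leverage adjustment), `"cr0"` (none) or
#'   `"cr1"` (J/(J-1) inflation). See [sandwich_covariance()].
#' @param optimize if `FALSE`, skip REML optimisation and evaluate the GLS
#'   fit at the `init` variance components as given (useful for refits at
#'   known components).
#' @param random_slope include the individual random age slope (default
#'   `TRUE`); with `FALSE` only the random intercept is fitted.
#' @param estimate_phi estimate the CAR(1) parameter (default `TRUE`); with
#'   `FALSE` phi is held at its `init` value (0 unless supplied).
#' @param reltol relative convergence tolerance on the REML objective.
#' @param max_iter iteration cap for the optimiser.
#' @return an object of class `"traj_fit"`: fixed effects `beta`, model-based
#'   covariance `cov_model`, sandwich covariance `cov_robust` (if requested),
#'   variance components `varcomps` (G, sigma2, phi, source_multiplier),
#'   `reml_loglik`, convergence information and bookkeeping counts.
#' @export
reml_fit <- function(design, response = NULL, init = NULL,
                     estimate_source_multiplier = FALSE, robust = TRUE,
                     cr_adjust = c("cr2", "cr0", "cr1"), optimize = TRUE,
                     random_slope = TRUE, estimate_phi = TRUE,
                     reltol = 1e-8, max_iter = 200L) {
  cr_adjust <- match.arg(cr_adjust)
  stopifnot(inherits(design, "gwas_design"))
  y <- if (is.null(response)) design$y else response
  if (!all(is.finite(y))) stop("non-finite response values")
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  if (design$n_individuals < 2) stop("need at least 2 individuals")

  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("singular fixed-effect design; offending column(s): ",
         paste(bad, collapse = ", "))
  }

  Z <- cbind(1, design$times - design$basis$centre_age)
  cl <- design_clusters(design)
  starts <- cl$starts; ends <- cl$ends
  src <- design$source
  est_mult <- isTRUE(estimate_source_multiplier) && any(src > 0)
  nugget <- 1e-8

  A0 <- diag(c(2, 0.02))
  phi0 <- if (estimate_phi) 0.3 else 0
  mult0 <- 1
  if (!is.null(init)) {
    s2 <- if (!is.null(init$sigma2)) init$sigma2 else 1
    if (!is.null(init$G)) A0 <- init$G / s2
    if (!is.null(init$phi)) phi0 <- init$phi
    if (!is.null(init$source_multiplier)) mult0 <- init$source_multiplier
  }
  th0 <- struct_to_theta(A0, phi0, mult0, est_mult)
  template <- as.numeric(th0)
  active <- c(TRUE, random_slope, random_slope, estimate_phi,
              if (est_mult) TRUE)
  if (!random_slope) {
    template[2] <- 0
    template[3] <- log(1e-8)
  }
  expand <- function(par) {
    th <- template
    th[active] <- par
    attr(th, "mult") <- attr(th0, "mult")
    th
  }

  evals <- 0L
  objective <- function(par) {
    st <- theta_to_struct(expand(par), est_mult)
    evals <<- evals + 1L
    if (!all(is.finite(c(st$A, st$phi, st$mult)))) return(1e10)
    core <- tryCatch(
      reml_core(X, y, Z, design$times, src, starts, ends,
                st$A, st$phi, st$mult, nugget),
      error = function(e) list(ok = FALSE))
    if (!isTRUE(core$ok) || core$rWr <= 0) return(1e10)
    dev <- (n - p) * log(core$rWr) + core$logdetW + core$logdetXtWiX
    if (!is.finite(dev)) return(1e10)
    dev
  }

  if (optimize && any(active)) {
    opt <- optim(template[active], objective, method = "BFGS",
                 control = list(maxit = max_iter, reltol = reltol))
  } else {
    opt <- list(par = template[active], convergence = 0L)
  }
  th <- expand(opt$par)
  st <- theta_to_struct(th, est_mult)
  core <- reml_core(X, y, Z, design$times, src, starts, ends,
                    st$A, st$phi, st$mult, nugget)
  if (!isTRUE(core$ok)) stop("variance structure not positive definite at optimum")

  sigma2 <- core$rWr / (n - p)
  beta <- drop(core$beta)
  names(beta) <- colnames(X)
  XtWiX <- core$XtWiX
  cov_model <- sigma2 * solve(XtWiX)
  cov_model <- (cov_model + t(cov_model)) / 2
  dimnames(cov_model) <- list(colnames(X), colnames(X))
  loglik <- -0.5 * ((n - p) * log(sigma2) + core$logdetW +
                      core$logdetXtWiX + (n - p) * (1 + log(2 * pi)))

  varcomps <- structure(
    list(G = st$A * sigma2, sigma2 = sigma2, phi = st$phi,
         source_multiplier = st$mult),
    class = "variance_components")

  fit <- structure(
    list(beta = beta, cov_model = cov_model, cov_robust = NULL,
         varcomps = varcomps, reml_loglik = loglik,
         n_individuals = design$n_individuals, n_obs = n,
         converged = opt$convergence == 0L,
         iterations = evals,
         theta = as.numeric(th), est_mult = est_mult),
    class = "traj_fit")
  if (robust)
    fit$cov_robust <- sandwich_covariance(fit, design, y,
                                          cr_adjust = cr_adjust)
  fit
}

#' Cluster-robust (sandwich) covariance of the fixed effects
#'
#' The individual-level sandwich estimator
#' \eqn{A^{-1} B A^{-1}} with \eqn{A = X^T V^{-1} X} and
#' \eqn{B = \sum_i X_i^T V_i^{-1} r_i r_i^T V_i^{-1} X_i}, where the
#' residuals r come from the fitted fixed effects and V is the fitted
#' marginal covariance. This protects the Wald tests when the age structure
#' of the random effects is misspecified (fixed spline terms, random
#' intercept + slope only).
#'
#' Because the residuals are computed from estimated fixed effects, the
#' plain (CR0) estimator is biased downward by the leverage of each cluster,
#' which inflates multi-df Wald statistics when the number of clusters is
#' only a few hundred. The default `"cr2"` applies the Bell-McCaffrey
#' working-model leverage adjustment, replacing each cluster residual by
#' `A_i r_i` with `A_i (W_i - X_i M X_i') A_i' = W_i`, which makes the meat
#' unbiased when the working covariance is correct and nearly so otherwise.
#'
#' @param fit a [reml_fit()] object.
#' @param design the [build_design()] object the model was fitted to.
#' @param response response vector (defaults to the design's).
#' @param cr_adjust `"cr2"` (default), `"cr0"` (no adjustment) or `"cr1"`
#'   (J/(J-1) inflation).
#' @return a symmetric positive semidefinite p x p covariance matrix.
#' @export
sandwich_covariance <- function(fit, design, response = NULL,
                                cr_adjust = c("cr2", "cr0", "cr1")) {
  cr_adjust <- match.arg(cr_adjust)
  stopifnot(inherits(fit, "traj_fit"), inherits(design, "gwas_design"))
  y <- if (is.null(response)) design$y else response
  cl <- design_clusters(design)
  if (length(cl$starts) < 2)
    stop("robust covariance undefined with fewer than 2 clusters")
  th <- fit$theta
  attr(th, "mult") <- fit$varcomps$source_multiplier
  st <- theta_to_struct(th, fit$est_mult)
  Z <- cbind(1, design$times - design$basis$centre_age)
  core <- reml_core(design$X, y, Z, design$times, design$source,
                    cl$starts, cl$ends, st$A, st$phi, st$mult, 1e-8)
  bread <- solve(core$XtWiX)
  adj <- match(cr_adjust, c("cr0", "cr1", "cr2")) - 1L
  meat <- cluster_meat(design$X, y, Z, design$times, design$source,
                       cl$starts, cl$ends, st$A, st$phi, st$mult, 1e-8,
                       fit$beta, adj, bread)
  V <- bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(design$X), colnames(design$X))
  if (length(design$snp_cols)) {
    Q <- cluster_score_blocks(design$X, Z, design$times, design$source,
                              cl$starts, cl$ends, st$A, st$phi, st$mult,
                              1e-8, bread, as.integer(design$snp_cols - 1L))
    attr(V, "cluster_blocks") <- Q
  }
  V
}

# Satterthwaite effective degrees of freedom for a multi-df robust Wald
# test: second moments of the block sandwich estimator are matched to a
# Wishart(nu, Omega/nu), giving nu = k(k+1) / sum_i [tr(S_i)^2 + tr(S_i^2)]
# with S_i = Q_i Omega^-1 and Omega = sum_i Q_i. For J equal independent
# clusters nu = J; heterogeneous cluster sizes push nu below J.
aht_effective_df <- function(Q, sub = seq_len(dim(Q)[1])) {
  k <- length(sub)
  Omega <- apply(Q[sub, sub, , drop = FALSE], c(1, 2), sum)
  Oinv <- solve(Omega)
  denom <- 0
  for (i in seq_len(dim(Q)[3])) {
    S <- Q[sub, sub, i] %*% Oinv
    denom <- denom + sum(diag(S))^2 + sum(S * t(S))
  }
  k * (k + 1) / denom
}

#' @export
print.traj_fit <- function(x, ...) {
  cat("Trajectory mixed model (REML",
      if (x$converged) "converged" else "NOT converged", ")\n")
  cat("  ", x$n_obs, "observations,", x$n_individuals, "individuals;",
      "log-restricted-likelihood", format(x$reml_loglik, digits = 8), "\n")
  vc <- x$varcomps
  cat("  sigma =", format(sqrt(vc$sigma2), digits = 4),
      " phi(1y) =", format(vc$phi, digits = 4),
      " sd(b0) =", format(sqrt(vc$G[1, 1]), digits = 4),
      " sd(b1) =", format(sqrt(vc$G[2, 2]), digits = 4), "\n")
  invisible(x)
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (log scale):\n")
  cat("  G (intercept, slope):\n")
  print(x$G)
  cat("  sigma2 =", x$sigma2, " phi =", x$phi,
      " source multiplier =", x$source_multiplier, "\n")
  invisible(x)
}
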