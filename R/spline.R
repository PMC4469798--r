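#' Age spline basis for growth-trajectory models
#'
#' A truncated-power piecewise-cubic basis in age, centred so that every
#' basis function vanishes at `centre_age`. With the default knots
#' \{2, 8, 12\} and centre 8 the basis has dimension 6:
#' \deqn{B(t) = (c,\; c^2,\; c^3,\; (t-2)_+^3 - 216,\; (t-8)_+^3,\; (t-12)_+^3)}
#' with \eqn{c = t - 8} and \eqn{216 = (8-2)^3}. Each truncated term is
#' recentred by its own value at `centre_age`, so the model intercept and any
#' main effect (sex, SNP dosage) are interpreted *at* the centre age: the
#' dosage main effect is the per-allele effect on log-BMI at age 8.
#'
#' @param knots strictly increasing knot ages in years.
#' @param centre_age age (years) at which all basis functions vanish; must be
#'   one of the interior ages of the modelling window.
#' @param age_window ages outside this window are excluded from designs.
#' @return an object of class `"spline_basis"`.
#' @examples
#' b <- spline_basis()
#' spline_basis_eval(b, 8)   # all zero
#' spline_basis_eval(b, 12)
#' @export
spline_basis <- function(knots = c(2, 8, 12), centre_age = 8,
                         age_window = c(1, 17)) {
  stopifnot(is.numeric(knots), length(knots) >= 1, !is.unsorted(knots),
            all(diff(knots) > 0), is.numeric(centre_age),
            length(age_window) == 2, age_window[1] < age_window[2])
  if (any(knots <= age_window[1]) || any(knots >= age_window[2]))
    stop("knots must lie strictly inside the age window")
  structure(
    list(knots = knots, degree = 3L, centre_age = centre_age,
         age_window = age_window, dim = 3L + length(knots)),
    class = "spline_basis")
}

#' Evaluate the age spline basis
#'
#' @param basis a [spline_basis()].
#' @param age numeric vector of ages in years.
#' @return a `length(age)` x `dim` matrix; one row per age.
#' @export
spline_basis_eval <- function(basis, age) {
  stopifnot(inherits(basis, "spline_basis"), is.numeric(age), all(is.finite(age)))
  c0 <- age - basis$centre_age
  poly <- cbind(c0, c0^2, c0^3)
  trunc <- vapply(basis$knots, function(k) {
    pmax(age - k, 0)^3 - max(basis$centre_age - k, 0)^3
  }, numeric(length(age)))
  out <- cbind(poly, matrix(trunc, nrow = length(age)))
  colnames(out) <- c("c", "c2", "c3", paste0("k", seq_along(basis$knots)))
  rownames(out) <- NULL
  out
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("Age spline basis (truncated-power cubic)\n")
  cat("  knots:", paste(x$knots, collapse = ", "), "years\n")
  cat("  centred at age", x$centre_age, "; dimension", x$dim, "\n")
  invisible(x)
}

#' Build fixed-effect design matrices for the per-SNP trajectory model
#'
#' Assembles the fixed-effect design for one SNP: intercept, the age spline
#' basis, sex main effect, sex-by-basis interactions, optional measurement
#' source indicator and principal components, then the SNP dosage main effect
#' and dosage-by-basis interactions (7 SNP columns in total). The response is
#' the natural log of the measurement. Rows are restricted to ages inside the
#' basis window and sorted by individual then age, so clusters are
#' contiguous.
#'
#' @param phenotypes a phenotype table as returned by [simulate_phenotypes()]
#'   or [read_phenotypes()]: columns `iid`, `sex` (0 = female, 1 = male),
#'   `age_years`, the measurement column, optionally `source`
#'   (0 = clinic, 1 = questionnaire) and `pc1..pcK`.
#' @param dosage named numeric vector: per-individual allele dosage in
#'   \[0, 2\], names matching `iid`.
#' @param basis a [spline_basis()].
#' @param covariates character vector of additional fixed-effect columns to
#'   include, from `"source"` and `"pc1"`, `"pc2"`, ... Default: `"source"`
#'   if present in the table.
#' @param value_col name of the measurement column (default `"bmi"`).
#' @param log_transform take the natural log of the measurement
#'   (default `TRUE`; disable for traits analysed on the raw scale).
#' @return an object of class `"gwas_design"`: list with the design matrix
#'   `X`, response `y`, `cluster` ids, `times`, `source` flags (all zero when
#'   no source column), `snp_cols` (indices of the 7 SNP columns), and a
#'   `skipped` data frame of dropped rows with reasons.
#' @export
build_design <- function(phenotypes, dosage, basis = spline_basis(),
                         covariates = NULL, value_col = "bmi",
                         log_transform = TRUE) {
  stopifnot(inherits(basis, "spline_basis"))
  ph <- as.data.frame(phenotypes)
  need <- c("iid", "sex", "age_years", value_col)
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(covariates)) {
    covariates <- intersect("source", names(ph))
    # a constant source column (single-source cohort) carries no information
    covariates <- covariates[vapply(covariates, function(cv)
      length(unique(ph[[cv]])) > 1, logical(1))]
  }
  bad_cov <- setdiff(covariates, names(ph))
  if (length(bad_cov))
    stop("covariate column(s) not in phenotype table: ",
         paste(bad_cov, collapse = ", "))
  if (is.null(names(dosage))) stop("dosage vector must be named by iid")

  skipped <- data.frame(iid = character(), age_years = numeric(),
                        reason = character(), stringsAsFactors = FALSE)
  note <- function(rows, why) {
    if (!any(rows)) return()
    skipped <<- rbind(skipped, data.frame(
      iid = as.character(ph$iid[rows]), age_years = ph$age_years[rows],
      reason = why, stringsAsFactors = FALSE))
  }

  out_win <- ph$age_years < basis$age_window[1] |
    ph$age_years > basis$age_window[2] | !is.finite(ph$age_years)
  note(out_win, "age_outside_window")
  nonpos <- !out_win & (!is.finite(ph[[value_col]]) | ph[[value_col]] <= 0)
  if (log_transform) note(nonpos, "nonpositive_value")
  no_dose <- !(as.character(ph$iid) %in% names(dosage))
  note(no_dose & !out_win & !(log_transform & nonpos), "missing_dosage")
  keep <- !out_win & !no_dose & !(log_transform & nonpos)
  ph <- ph[keep, , drop = FALSE]
  if (!nrow(ph)) stop("no usable rows after filtering")

  ph <- ph[order(ph$iid, ph$age_years), , drop = FALSE]
  B <- spline_basis_eval(basis, ph$age_years)
  d <- as.numeric(dosage[as.character(ph$iid)])
  sex <- as.numeric(ph$sex)

  X <- cbind(1, B, sex, B * sex)
  nm <- c("(Intercept)", paste0("s", seq_len(basis$dim)), "sex",
          paste0("sex:s", seq_len(basis$dim)))
  for (cv in covariates) {
    X <- cbind(X, as.numeric(ph[[cv]]))
    nm <- c(nm, cv)
  }
  snp_cols <- ncol(X) + seq_len(1L + basis$dim)
  X <- cbind(X, d, B * d)
  nm <- c(nm, "dose", paste0("dose:s", seq_len(basis$dim)))
  colnames(X) <- nm

  y <- if (log_transform) log(ph[[value_col]]) else ph[[value_col]]
  src <- if ("source" %in% names(ph)) as.numeric(ph$source) else numeric(nrow(ph))

  structure(
    list(X = X, y = y, cluster = as.character(ph$iid), times = ph$age_years,
         source = src, snp_cols = snp_cols, basis = basis,
         n_individuals = length(unique(ph$iid)), n_obs = nrow(ph),
         skipped = skipped),
    class = "gwas_design")
}

#' @export
print.gwas_design <- function(x, ...) {
  cat("Trajectory-model design:", x$n_obs, "observations on",
      x$n_individuals, "individuals;", ncol(x$X), "fixed-effect columns\n")
  if (nrow(x$skipped))
    cat("  ", nrow(x$skipped), "rows skipped (see $skipped)\n")
  invisible(x)
}
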