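# Delimited-text I/O: long-format phenotype tables, dosage panels (generic
# TSV and MACH mldose/mlinfo dialect), and METAL-style results tables.

#' Read a long-format phenotype table
#'
#' Tab-separated text with header columns `iid`, `sex`, `age_years`, the
#' measurement column (default `bmi`), optionally `source` and `pc1..pcK`.
#' Rows with a non-positive measurement or an age outside \[0, 25\] years
#' are rejected; the rejects (with reasons) are returned in the `rejects`
#' attribute.
#'
#' @param path file path.
#' @param value_col name of the measurement column.
#' @return a data frame of class `"phenotype_table"`.
#' @export
read_phenotypes <- function(path, value_col = "bmi") {
  ph <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("iid", "sex", "age_years", value_col)
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype file lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  reason <- rep(NA_character_, nrow(ph))
  reason[!is.finite(ph$age_years) | ph$age_years < 0 | ph$age_years > 25] <-
    "age_out_of_range"
  reason[is.na(reason) &
           (!is.finite(ph[[value_col]]) | ph[[value_col]] <= 0)] <-
    "nonpositive_value"
  bad <- !is.na(reason)
  rejects <- cbind(ph[bad, , drop = FALSE],
                   data.frame(reason = reason[bad]))
  ph <- ph[!bad, , drop = FALSE]
  rownames(ph) <- NULL
  class(ph) <- c("phenotype_table", "data.frame")
  attr(ph, "rejects") <- rejects
  ph
}

#' Write a phenotype table as tab-separated text
#'
#' @param phenotypes a phenotype table.
#' @param path output path.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(as.data.frame(phenotypes), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a dosage panel
#'
#' Two dialects:
#' * `"tsv"`: header row `iid` + SNP ids, one row per individual; SNP
#'   metadata from a companion info file (columns `snp`, `effect_allele`,
#'   `other_allele`, `eaf`, `rsq`) when given, else effect allele
#'   frequencies are computed from the dosages and quality is left missing.
#' * `"mach"`: mldose lines `ID ML_DOSE d1 d2 ...` with a companion
#'   whitespace-delimited mlinfo file (columns `SNP`, `Al1`, `Al2`, `Freq1`,
#'   `Rsq`); the effect allele is `Al1`.
#'
#' Dosages outside \[0, 2\] raise an error naming the offending line.
#'
#' @param path dosage file path.
#' @param dialect `"tsv"` or `"mach"`.
#' @param info_path companion metadata file (required for `"mach"`).
#' @return a `dosage_panel`.
#' @export
read_dosages <- function(path, dialect = c("tsv", "mach"), info_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(tab)[1] != "iid") stop("tsv dosage file must start with 'iid'")
    D <- as.matrix(tab[, -1, drop = FALSE])
    rownames(D) <- as.character(tab$iid)
    snp_ids <- colnames(D)
    if (!is.null(info_path)) {
      info <- read.delim(info_path, stringsAsFactors = FALSE)
      need <- c("snp", "effect_allele", "other_allele", "eaf", "rsq")
      miss <- setdiff(need, names(info))
      if (length(miss))
        stop("dosage info file lacks column(s): ", paste(miss, collapse = ", "))
      if (!setequal(info$snp, snp_ids) || nrow(info) != length(snp_ids))
        stop("info/dosage SNP sets disagree")
      info <- info[match(snp_ids, info$snp), ]
    } else {
      info <- data.frame(snp = snp_ids, effect_allele = NA_character_,
                         other_allele = NA_character_, eaf = colMeans(D) / 2,
                         rsq = NA_real_, stringsAsFactors = FALSE)
    }
  } else {
    if (is.null(info_path)) stop("mach dialect requires info_path (mlinfo)")
    ml <- read.table(info_path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("SNP", "Al1", "Al2", "Freq1", "Rsq")
    miss <- setdiff(need, names(ml))
    if (length(miss))
      stop("mlinfo lacks column(s): ", paste(miss, collapse = ", "))
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t]+")
    ids <- vapply(parts, function(x) sub(".*->", "", x[1]), character(1))
    D <- t(vapply(parts, function(x) as.numeric(x[-(1:2)]),
                  numeric(length(parts[[1]]) - 2)))
    if (ncol(D) != nrow(ml))
      stop("mldose has ", ncol(D), " dosage columns but mlinfo lists ",
           nrow(ml), " SNPs")
    rownames(D) <- ids
    colnames(D) <- ml$SNP
    info <- data.frame(snp = ml$SNP, effect_allele = ml$Al1,
                       other_allele = ml$Al2, eaf = ml$Freq1, rsq = ml$Rsq,
                       stringsAsFactors = FALSE)
  }
  bad_row <- which(apply(D, 1, function(x) any(!is.finite(x) | x < 0 | x > 2)))
  if (length(bad_row))
    stop("dosage outside [0, 2] at data line ", bad_row[1], " of ", path)
  rownames(info) <- NULL
  structure(list(dosages = D, info = info, genotypes = NULL),
            class = "dosage_panel")
}

#' Write a dosage panel
#'
#' @param panel a `dosage_panel`.
#' @param path output path for the dosage matrix (tsv) or mldose (mach).
#' @param dialect `"tsv"` or `"mach"`.
#' @param info_path output path for the metadata (tsv companion info or
#'   mlinfo); required for `"mach"`, optional for `"tsv"`.
#' @export
write_dosages <- function(panel, path, dialect = c("tsv", "mach"),
                          info_path = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(panel, "dosage_panel"))
  if (dialect == "tsv") {
    tab <- data.frame(iid = rownames(panel$dosages), panel$dosages,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(info_path))
      write.table(panel$info, info_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
  } else {
    if (is.null(info_path)) stop("mach dialect requires info_path (mlinfo)")
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(panel$dosages)))
      writeLines(paste(c(paste0(rownames(panel$dosages)[i], "->",
                                rownames(panel$dosages)[i]),
                         "ML_DOSE",
                         format(panel$dosages[i, ], digits = 6, trim = TRUE)),
                       collapse = " "), con)
    ml <- data.frame(SNP = panel$info$snp, Al1 = panel$info$effect_allele,
                     Al2 = panel$info$other_allele, Freq1 = panel$info$eaf,
                     MAF = pmin(panel$info$eaf, 1 - panel$info$eaf),
                     Quality = panel$info$rsq, Rsq = panel$info$rsq,
                     stringsAsFactors = FALSE)
    write.table(ml, info_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write GWAS results in a METAL-compatible layout
#'
#' Columns `SNP, EA, OA, EAF, BETA, SE, P, W_GLOBAL, P_GLOBAL, W_CHANGE,
#' P_CHANGE, N_IND, N_OBS`; P-values in scientific notation with 4
#' significant digits.
#'
#' @param results a `gwas_results` table.
#' @param path output path.
#' @export
write_results <- function(results, path) {
  fmtp <- function(p) sprintf("%.3e", p)
  tab <- data.frame(
    SNP = results$snp, EA = results$effect_allele,
    OA = results$other_allele, EAF = results$eaf,
    BETA = results$beta8, SE = results$se8, P = fmtp(results$p_snp),
    W_GLOBAL = results$W_global, P_GLOBAL = fmtp(results$p_global),
    W_CHANGE = results$W_change, P_CHANGE = fmtp(results$p_change),
    N_IND = results$n_individuals, N_OBS = results$n_obs,
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a METAL-style results table written by [write_results()]
#'
#' @param path file path.
#' @return a data frame with the `gwas_results` column layout.
#' @export
read_results <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(
    snp = tab$SNP, effect_allele = tab$EA, other_allele = tab$OA,
    eaf = tab$EAF, beta8 = tab$BETA, se8 = tab$SE, p_snp = tab$P,
    W_global = tab$W_GLOBAL, p_global = tab$P_GLOBAL,
    W_change = tab$W_CHANGE, p_change = tab$P_CHANGE,
    n_individuals = tab$N_IND, n_obs = tab$N_OBS,
    stringsAsFactors = FALSE)
  class(out) <- c("gwas_results", "data.frame")
  out
}
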