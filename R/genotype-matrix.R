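#' Construct a genotype matrix object
#'
#' The central container of the package: an `m x N` matrix of minor-allele
#' counts for `m` subjects at `N` biallelic SNPs, with per-SNP metadata and a
#' binary case/control phenotype. Genotype entries count copies of the
#' reference (counted, typically minor) allele, so each non-missing entry is
#' 0, 1 or 2; `NA` marks a missing call and must be resolved (see
#' [clean_missing()]) before distances or ReliefF scores are computed.
#'
#' @param genotypes integer matrix, subjects in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param snps data frame with one row per SNP and columns `snp_id`, `chrom`,
#'   `pos`, `allele_ref` (the counted allele), `allele_alt`; optional
#'   `freq_ref`. A `mutation_class` column (`"transition"`/`"transversion"`)
#'   is derived from the allele pair if absent.
#' @param phenotype vector of length `m` coercible to the labels `"control"`
#'   and `"case"` (accepts PLINK 1/2 coding, logicals, or the labels
#'   themselves).
#' @param subject_ids character vector of length `m`; defaults to
#'   `rownames(genotypes)` or `S1..Sm`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `genotypes`, `snps`, `phenotype` (factor with levels `control`, `case`),
#'   and `subject_ids`.
#' @seealso [load_plink()], [load_tsv_genotypes()], [simulate_gwas()]
#' @export
genotype_matrix <- function(genotypes, snps, phenotype, subject_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  m <- nrow(genotypes)
  if (is.null(subject_ids)) {
    subject_ids <- rownames(genotypes)
    if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(m))
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (any(!is.na(snps$allele_ref) & !is.na(snps$allele_alt) &
            snps$allele_ref == snps$allele_alt))
    stop("allele_ref must differ from allele_alt")
  if (is.null(snps$mutation_class)) {
    snps$mutation_class <- classify_titv(snps$allele_ref, snps$allele_alt)
  }
  if (is.null(snps$freq_ref)) snps$freq_ref <- NA_real_
  phenotype <- as_phenotype(phenotype)
  obj <- structure(
    list(genotypes = genotypes, snps = snps,
         phenotype = phenotype, subject_ids = as.character(subject_ids)),
    class = "genotype_matrix")
  validate_genotype_matrix(obj)
  dimnames(obj$genotypes) <- list(obj$subject_ids, obj$snps$snp_id)
  obj
}

#' Coerce a phenotype vector to the control/case factor
#'
#' Accepts the package's own labels, PLINK's 1 = control / 2 = case integer
#' coding (0 and -9 become `NA`), or logicals (`TRUE` = case).
#'
#' @param x vector of phenotype codes or labels.
#' @return factor with levels `control`, `case`; unknown codes are `NA`.
#' @export
as_phenotype <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.logical(x)) x <- ifelse(x, "case", "control")
  if (is.numeric(x)) {
    x <- ifelse(x == 2, "case", ifelse(x == 1, "control", NA_character_))
  }
  x <- as.character(x)
  bad <- !is.na(x) & !x %in% c("case", "control")
  if (any(bad)) stop("unrecognized phenotype labels: ",
                     paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = c("control", "case"))
}

validate_genotype_matrix <- function(G) {
  g <- G$genotypes
  if (!all(is.na(g) | (g >= 0L & g <= 2L)))
    stop("genotype entries must be 0, 1, 2 or NA")
  if (nrow(G$snps) != ncol(g))
    stop("snps table has ", nrow(G$snps), " rows but genotypes has ",
         ncol(g), " columns")
  if (length(G$phenotype) != nrow(g) || length(G$subject_ids) != nrow(g))
    stop("phenotype/subject_ids length must equal the number of subjects")
  same <- !is.na(G$snps$allele_ref) & !is.na(G$snps$allele_alt) &
    G$snps$allele_ref == G$snps$allele_alt
  if (any(same)) stop("allele_ref must differ from allele_alt")
  invisible(G)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$phenotype, useNA = "ifany")
  cat("genotype_matrix: ", nrow(x$genotypes), " subjects x ",
      ncol(x$genotypes), " SNPs\n", sep = "")
  cat("  phenotype: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  n_ti <- sum(x$snps$mutation_class == "transition", na.rm = TRUE)
  cat("  transitions: ", n_ti, ", transversions: ",
      nrow(x$snps) - n_ti, "\n", sep = "")
  n_miss <- sum(is.na(x$genotypes))
  if (n_miss > 0) cat("  missing calls: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

# Subset a genotype_matrix by SNP column index, keeping metadata in step.
subset_snps <- function(G, keep) {
  G$genotypes <- G$genotypes[, keep, drop = FALSE]
  G$snps <- G$snps[keep, , drop = FALSE]
  rownames(G$snps) <- NULL
  G
}
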