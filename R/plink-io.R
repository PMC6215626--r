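#' Read a PLINK bed/bim/fam file set
#'
#' Reads binary PLINK v1 genotype data (SNP-major bed with magic bytes
#' `0x6c 0x1b 0x01`, 2 bits per call) into a [genotype_matrix()]. Genotype
#' counts are of the bim A1 allele (conventionally the minor allele): bed
#' code `00` is two copies of A1, `10` one copy, `11` zero copies, `01`
#' missing. The phenotype comes from fam column 6 (1 = control, 2 = case,
#' 0/-9 missing) or, if given, from `pheno_path`, a whitespace-delimited
#' `FID IID PHENO` file in the same coding. Subjects with missing phenotype
#' are dropped; SNPs whose alleles are not both in `{A, C, G, T}` are
#' excluded with a warning (the mutation class would be undefined).
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` are read unless the
#'   individual paths are supplied.
#' @param bed_path,bim_path,fam_path optional explicit file paths.
#' @param pheno_path optional alternate phenotype file.
#' @return a [genotype_matrix()].
#' @seealso [save_plink()]
#' @export
load_plink <- function(prefix = NULL, bed_path = NULL, bim_path = NULL,
                       fam_path = NULL, pheno_path = NULL) {
  if (!is.null(prefix)) {
    if (is.null(bed_path)) bed_path <- paste0(prefix, ".bed")
    if (is.null(bim_path)) bim_path <- paste0(prefix, ".bim")
    if (is.null(fam_path)) fam_path <- paste0(prefix, ".fam")
  }
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("file not found: ", f)

  fam <- utils::read.table(fam_path, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  bim <- utils::read.table(bim_path, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  m <- nrow(fam)
  N <- nrow(bim)

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes): ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major bed files (mode byte 0x01) are supported")
  bytes_per_snp <- ceiling(m / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * N)
    stop("bed payload size does not match fam/bim dimensions")

  # 256 x 4 lookup: genotype count of A1 for each 2-bit field of a byte
  codes <- c(2L, NA_integer_, 1L, 0L)  # 00, 01, 10, 11
  b <- 0:255
  lut <- cbind(codes[bitwAnd(b, 3L) + 1L],
               codes[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
               codes[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
               codes[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
  decoded <- lut[as.integer(body) + 1L, , drop = FALSE]  # (bytes_per_snp*N) x 4
  g <- matrix(t(decoded), nrow = 4 * bytes_per_snp, ncol = N)[seq_len(m), , drop = FALSE]

  pheno <- fam$pheno
  if (!is.null(pheno_path)) {
    ph <- utils::read.table(pheno_path, stringsAsFactors = FALSE,
                            col.names = c("fid", "iid", "pheno"))
    pheno <- ph$pheno[match(fam$iid, ph$iid)]
  }
  labels <- as_phenotype(pheno)
  if (all(is.na(labels))) stop("all phenotypes are missing")
  keep_subj <- !is.na(labels)
  if (any(!keep_subj))
    message(sum(!keep_subj), " subjects dropped for missing phenotype")

  valid_alleles <- bim$a1 %in% c("A", "C", "G", "T") &
    bim$a2 %in% c("A", "C", "G", "T")
  if (any(!valid_alleles))
    warning(sum(!valid_alleles),
            " SNPs excluded: allele codes outside {A, C, G, T}")

  snps <- data.frame(snp_id = bim$snp_id, chrom = bim$chrom, pos = bim$pos,
                     allele_ref = bim$a1, allele_alt = bim$a2,
                     stringsAsFactors = FALSE)[valid_alleles, , drop = FALSE]
  genotype_matrix(g[keep_subj, valid_alleles, drop = FALSE], snps,
                  labels[keep_subj], subject_ids = fam$iid[keep_subj])
}

#' Write a genotype matrix as PLINK bed/bim/fam
#'
#' Inverse of [load_plink()] on cleaned matrices: writes a SNP-major v1 bed
#' (with the usual magic bytes), a 6-column bim (A1 = the counted allele,
#' A2 = the other), and a 6-column fam with phenotype coded 1 = control,
#' 2 = case. `load_plink(save_plink(G, prefix))` reproduces `G`.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix (directories must exist).
#' @return `prefix`, invisibly.
#' @export
save_plink <- function(G, prefix) {
  g <- G$genotypes
  m <- nrow(g)
  N <- ncol(g)
  fam <- data.frame(fid = G$subject_ids, iid = G$subject_ids,
                    pat = 0L, mat = 0L, sex = 0L,
                    pheno = ifelse(G$phenotype == "case", 2L, 1L))
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chrom = G$snps$chrom, snp_id = G$snps$snp_id, cm = 0L,
                    pos = G$snps$pos, a1 = G$snps$allele_ref,
                    a2 = G$snps$allele_alt)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # 2-bit codes per A1 count: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code_of <- function(x) {
    out <- integer(length(x))
    out[is.na(x)] <- 1L
    out[!is.na(x) & x == 1L] <- 2L
    out[!is.na(x) & x == 0L] <- 3L
    out
  }
  bytes_per_snp <- ceiling(m / 4)
  pad <- 4L * bytes_per_snp - m
  body <- raw(bytes_per_snp * N)
  pos <- 1L
  for (v in seq_len(N)) {
    codes <- c(code_of(g[, v]), rep(0L, pad))
    quads <- matrix(codes, nrow = 4L)
    byte_vals <- quads[1, ] + bitwShiftL(quads[2, ], 2L) +
      bitwShiftL(quads[3, ], 4L) + bitwShiftL(quads[4, ], 6L)
    body[pos:(pos + bytes_per_snp - 1L)] <- as.raw(byte_vals)
    pos <- pos + bytes_per_snp
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(body, con)
  invisible(prefix)
}

#' Read the plain-TSV genotype dialect
#'
#' A text alternative to the binary PLINK trio: a genotype TSV whose header
#' row is `subject_id`, `phenotype`, then one column per SNP id, with one row
#' per subject carrying the label (`case`/`control` or 1/2) and 0/1/2 calls
#' (`NA` allowed); plus a companion SNP-info TSV with columns `snp_id`,
#' `chrom`, `pos`, `ref`, `alt` in matrix column order.
#'
#' @param genotype_path,snpinfo_path paths to the two TSV files.
#' @return a [genotype_matrix()].
#' @seealso [save_tsv_genotypes()]
#' @export
load_tsv_genotypes <- function(genotype_path, snpinfo_path) {
  tab <- utils::read.delim(genotype_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  info <- utils::read.delim(snpinfo_path, stringsAsFactors = FALSE)
  snp_cols <- setdiff(names(tab), c("subject_id", "phenotype"))
  if (!setequal(snp_cols, info$snp_id))
    stop("SNP ids in genotype and SNP-info files do not match")
  info <- info[match(snp_cols, info$snp_id), , drop = FALSE]
  snps <- data.frame(snp_id = info$snp_id, chrom = info$chrom, pos = info$pos,
                     allele_ref = info$ref, allele_alt = info$alt,
                     stringsAsFactors = FALSE)
  genotype_matrix(as.matrix(tab[, snp_cols, drop = FALSE]), snps,
                  tab$phenotype, subject_ids = tab$subject_id)
}

#' Write the plain-TSV genotype dialect
#'
#' @param G a [genotype_matrix()].
#' @param genotype_path,snpinfo_path output paths.
#' @return `genotype_path`, invisibly.
#' @export
save_tsv_genotypes <- function(G, genotype_path, snpinfo_path) {
  tab <- data.frame(subject_id = G$subject_ids,
                    phenotype = as.character(G$phenotype),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(G$genotypes))
  utils::write.table(tab, genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  info <- data.frame(snp_id = G$snps$snp_id, chrom = G$snps$chrom,
                     pos = G$snps$pos, ref = G$snps$allele_ref,
                     alt = G$snps$allele_alt, stringsAsFactors = FALSE)
  utils::write.table(info, snpinfo_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(genotype_path)
}
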