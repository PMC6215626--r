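test_that("transition/transversion classification follows the purine/pyrimidine families", {
  expect_equal(unname(classify_titv("A", "G")), "transition")
  expect_equal(unname(classify_titv("C", "T")), "transition")
  expect_equal(unname(classify_titv("A", "C")), "transversion")
  expect_equal(unname(classify_titv("G", "T")), "transversion")
  # symmetric, and exactly 4 of the 12 ordered distinct pairs are transitions
  pairs <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  cls <- classify_titv(pairs$a, pairs$b)
  expect_equal(unname(cls), unname(classify_titv(pairs$b, pairs$a)))
  expect_equal(sum(cls == "transition"), 4L)
  expect_error(classify_titv("A", "A"), "distinct")
  expect_error(classify_titv("A", "N"), "A, C, G, T")
})

test_that("allele frequencies are allele counts over 2m, with monomorphic flags", {
  G <- toy_geno(cbind(c(0, 1, 1, 2), c(0, 0, 0, 0), c(2, 2, 2, 2)))
  p <- allele_freq(G)
  expect_equal(as.vector(p), c(0.5, 0, 1))
  expect_equal(unname(attr(p, "monomorphic")), c(FALSE, TRUE, TRUE))
})

test_that("flipping allele orientation maps p to 1 - p exactly", {
  G <- random_geno(m = 40, N = 25, seed = 11)
  p <- allele_freq(G)
  Gf <- G
  Gf$genotypes <- 2L - Gf$genotypes
  expect_identical(as.vector(allele_freq(Gf)), as.vector(1 - p))
})

test_that("MAF filter keeps SNPs at or above the threshold and is idempotent", {
  # m = 100 columns engineered to p = 0.005, 0.01, 0.2, 0.5, 0.995
  col <- function(n_ones, n_twos = 0) c(rep(1L, n_ones), rep(2L, n_twos),
                                        rep(0L, 100 - n_ones - n_twos))
  g <- cbind(col(1), col(2), col(40), col(100), 2L - col(1))
  G <- toy_geno(g)
  expect_equal(as.vector(allele_freq(G)), c(0.005, 0.01, 0.2, 0.5, 0.995))
  kept <- maf_filter(G, maf_min = 0.01)
  expect_equal(kept$snps$snp_id, c("s002", "s003", "s004"))  # boundary retained
  expect_equal(kept$snps$freq_ref, c(0.01, 0.2, 0.5))
  expect_identical(maf_filter(kept, maf_min = 0.01)$genotypes, kept$genotypes)
  expect_warning(maf_filter(toy_geno(cbind(col(1))), 0.01), "no SNPs")
})

test_that("LD pruning removes the lower-MAF member of correlated pairs", {
  set.seed(42)
  x <- rbinom(60, 2, 0.4)
  # identical columns: r^2 = 1, equal MAF, tie removes the higher index
  G <- toy_geno(cbind(x, x))
  pruned <- ld_prune(G)
  expect_equal(pruned$snps$snp_id, "s001")
  # independent low-correlation columns both survive
  y <- rbinom(60, 2, 0.4)
  G2 <- toy_geno(cbind(x, y))
  expect_lt(cor(x, y)^2, 0.5)  # fixture sanity
  expect_equal(ncol(ld_prune(G2)$genotypes), 2L)
})

test_that("greedy rule drops SNP 1 when r2(1,2) is high and MAF(1) < MAF(2)", {
  set.seed(7)
  s2 <- rbinom(80, 2, 0.45)
  s1 <- s2
  flip <- sample(80, 6)
  s1[flip] <- pmax(0L, s1[flip] - 1L)  # lowers MAF of column 1, keeps r2 high
  s3 <- sample(s2)                     # same margin, shuffled: low r2
  maf <- function(v) min(mean(v) / 2, 1 - mean(v) / 2)
  expect_lt(maf(s1), maf(s2))
  r2 <- cor(cbind(s1, s2, s3))^2
  expect_gt(r2[1, 2], 0.5)
  expect_lt(r2[1, 3], 0.5)
  expect_lt(r2[2, 3], 0.5)
  pruned <- ld_prune(toy_geno(cbind(s1, s2, s3)))
  expect_equal(pruned$snps$snp_id, c("s002", "s003"))
  expect_identical(ld_prune(pruned)$snps$snp_id, pruned$snps$snp_id)
})

test_that("LD pruning requires sorted positions", {
  G <- toy_geno(cbind(c(0, 1, 2, 1), c(1, 1, 0, 2)))
  G$snps$pos <- c(200L, 100L)
  expect_error(ld_prune(G), "sorted")
})

test_that("missing-call policies behave as documented", {
  g <- cbind(c(0L, 1L, NA, 1L), c(2L, 0L, 1L, 1L))
  G <- toy_geno(g)
  imp <- clean_missing(G, "impute_major")
  expect_equal(unname(imp$genotypes[, 1]), c(0L, 1L, 1L, 1L))  # mode of {0,1,1}
  # no missing entries: identity
  expect_identical(clean_missing(imp)$genotypes, imp$genotypes)
  # drop_snp removes the column with missingness
  expect_equal(clean_missing(G, "drop_snp")$snps$snp_id, "s002")
  # all-missing column has no mode
  G2 <- toy_geno(cbind(c(NA, NA, NA, NA), c(0L, 1L, 2L, 1L)))
  expect_error(clean_missing(G2, "impute_major"), "entirely missing")
  expect_error(clean_missing(G, "nonsense"))
})

test_that("PLINK bed/bim/fam round-trips a cleaned matrix", {
  d <- withr::local_tempdir()
  G <- toy_geno(matrix(c(0L, 1L, 2L, 1L,
                         2L, 2L, 0L, 1L,
                         1L, 0L, 1L, 2L), nrow = 4),
                classes = c("transition", "transversion", "transversion"))
  save_plink(G, file.path(d, "toy"))
  G2 <- load_plink(file.path(d, "toy"))
  expect_identical(G2$genotypes, G$genotypes)
  expect_identical(G2$phenotype, G$phenotype)
  expect_identical(G2$snps$mutation_class, G$snps$mutation_class)
  expect_identical(G2$subject_ids, G$subject_ids)
  # larger random matrix, including an odd subject count (byte padding path)
  Gr <- random_geno(m = 37, N = 60, seed = 5)
  save_plink(Gr, file.path(d, "rand"))
  expect_identical(load_plink(file.path(d, "rand"))$genotypes, Gr$genotypes)
})

test_that("PLINK loader honors phenotype coding, pheno files, and bad input", {
  d <- withr::local_tempdir()
  G <- random_geno(m = 12, N = 8, seed = 9)
  save_plink(G, file.path(d, "x"))
  # fam value 2 -> case (by construction of save_plink)
  fam <- read.table(file.path(d, "x.fam"))
  expect_identical(as.character(load_plink(file.path(d, "x"))$phenotype),
                   ifelse(fam$V6 == 2, "case", "control"))
  # alternate pheno file overrides fam, missing phenotype drops the subject
  ph <- data.frame(fid = G$subject_ids, iid = G$subject_ids,
                   pheno = c(rep(1L, 6), rep(2L, 5), -9L))
  write.table(ph, file.path(d, "alt.pheno"), row.names = FALSE, col.names = FALSE)
  suppressMessages(
    G2 <- load_plink(file.path(d, "x"), pheno_path = file.path(d, "alt.pheno")))
  expect_equal(nrow(G2$genotypes), 11L)
  expect_equal(sum(G2$phenotype == "case"), 5L)
  # corrupt magic bytes
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), file.path(d, "x.bed"))
  expect_error(load_plink(file.path(d, "x")), "magic")
})

test_that("non-ACGT alleles are excluded with a warning", {
  d <- withr::local_tempdir()
  G <- random_geno(m = 10, N = 4, seed = 2)
  save_plink(G, file.path(d, "y"))
  bim <- read.table(file.path(d, "y.bim"), stringsAsFactors = FALSE)
  bim$V5[2] <- "I"  # indel-style code
  write.table(bim, file.path(d, "y.bim"), row.names = FALSE, col.names = FALSE,
              quote = FALSE, sep = "\t")
  expect_warning(G2 <- load_plink(file.path(d, "y")), "allele codes")
  expect_equal(ncol(G2$genotypes), 3L)
})

test_that("the TSV dialect round-trips, including missing calls", {
  d <- withr::local_tempdir()
  G <- random_geno(m = 15, N = 10, seed = 21)
  G$genotypes[3, 4] <- NA
  save_tsv_genotypes(G, file.path(d, "g.tsv"), file.path(d, "s.tsv"))
  G2 <- load_tsv_genotypes(file.path(d, "g.tsv"), file.path(d, "s.tsv"))
  expect_identical(G2$genotypes, G$genotypes)
  expect_identical(G2$phenotype, G$phenotype)
  expect_identical(G2$snps$allele_ref, G$snps$allele_ref)
})

test_that("genotype_matrix validates its invariants", {
  expect_error(toy_geno(cbind(c(0, 3, 1, 2))), "0, 1, 2")
  snps <- data.frame(snp_id = "a", chrom = 1, pos = 1,
                     allele_ref = "A", allele_alt = "A")
  expect_error(genotype_matrix(cbind(c(0L, 1L)), snps, c("case", "control")),
               "allele_ref")
  expect_error(as_phenotype(c("case", "banana")), "unrecognized")
  expect_equal(as.character(as_phenotype(c(2, 1, 0))), c("case", "control", NA))
})
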