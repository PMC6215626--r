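# Small in-code fixtures shared across test files.

# Build a genotype_matrix from a plain matrix; alleles default to one
# transversion pair per SNP unless mutation classes are given.
toy_geno <- function(g, phenotype = NULL, classes = NULL) {
  g <- as.matrix(g)
  N <- ncol(g)
  if (is.null(classes)) classes <- rep("transversion", N)
  ref <- ifelse(classes == "transition", "A", "A")
  alt <- ifelse(classes == "transition", "G", "C")
  snps <- data.frame(snp_id = sprintf("s%03d", seq_len(N)), chrom = 1L,
                     pos = seq_len(N) * 100L, allele_ref = ref, allele_alt = alt,
                     stringsAsFactors = FALSE)
  if (is.null(phenotype))
    phenotype <- rep(c("case", "control"), length.out = nrow(g))
  genotype_matrix(g, snps, phenotype)
}

# Random genotype_matrix with a mix of transitions and transversions and a
# balanced random phenotype; deterministic under the given seed.
random_geno <- function(m, N, seed, ti_fraction = 0.5, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(N, maf[1], maf[2])
  g <- matrix(rbinom(m * N, 2L, rep(p, each = m)), m, N)
  classes <- rep("transversion", N)
  n_ti <- round(ti_fraction * N)
  if (n_ti > 0) classes[sample(N, n_ti)] <- "transition"
  pheno <- sample(rep(c("case", "control"), length.out = m))
  toy_geno(g, phenotype = pheno, classes = classes)
}

# All six canonical nn-metric x diff combinations
six_combos <- data.frame(
  nn = c("gm", "am", "titv", "grm", "grm", "grm"),
  diff = c("gm", "am", "titv", "gm", "am", "titv"),
  stringsAsFactors = FALSE)
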