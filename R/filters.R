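#' Classify an allele substitution as transition or transversion
#'
#' A transition exchanges a purine for the other purine (A <-> G) or a
#' pyrimidine for the other pyrimidine (C <-> T); every purine <-> pyrimidine
#' exchange is a transversion. The classification is symmetric in its
#' arguments; of the 12 ordered distinct nucleotide pairs exactly 4 are
#' transitions.
#'
#' @param allele1,allele2 character vectors of nucleotides in `{A, C, G, T}`;
#'   recycled to a common length.
#' @return character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_titv("A", "G")  # transition
#' classify_titv("A", "C")  # transversion
#' @export
classify_titv <- function(allele1, allele2) {
  a1 <- toupper(as.character(allele1))
  a2 <- toupper(as.character(allele2))
  nuc <- c("A", "C", "G", "T")
  if (!all(a1 %in% nuc) || !all(a2 %in% nuc))
    stop("alleles must be one of A, C, G, T")
  if (any(a1 == a2))
    stop("alleles of a biallelic SNP must be distinct")
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  ifelse(purine[a1] == purine[a2], "transition", "transversion")
}

#' Reference-allele frequencies
#'
#' Computes `p_nu = sum_i(g_i_nu) / (2m)`, the sample frequency of the counted
#' (reference) allele at each SNP. Monomorphic SNPs (`p` equal to 0 or 1) are
#' flagged in the `"monomorphic"` attribute; they are invalid for GRM
#' standardization and should be removed by [maf_filter()] first.
#'
#' @param G a [genotype_matrix()] with no missing genotypes.
#' @return named numeric vector of `p_nu` with attribute `monomorphic`
#'   (logical vector).
#' @export
allele_freq <- function(G) {
  g <- G$genotypes
  if (anyNA(g)) stop("resolve missing genotypes (clean_missing) before computing allele frequencies")
  p <- colSums(g) / (2 * nrow(g))
  names(p) <- G$snps$snp_id
  attr(p, "monomorphic") <- p == 0 | p == 1
  p
}

#' Filter SNPs by minor allele frequency
#'
#' Retains SNPs whose minor allele frequency `min(p, 1 - p)` is at least
#' `maf_min` (inclusive threshold). Frequencies are recomputed from the data
#' and stored on the returned object's SNP table.
#'
#' @param G a [genotype_matrix()] with no missing genotypes.
#' @param maf_min minimum minor allele frequency; default 0.01.
#' @return the filtered `genotype_matrix` with `snps$freq_ref` populated.
#' @export
maf_filter <- function(G, maf_min = 0.01) {
  p <- allele_freq(G)
  G$snps$freq_ref <- as.numeric(p)
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min
  if (!any(keep)) warning("no SNPs pass the MAF filter")
  subset_snps(G, keep)
}

#' Greedy windowed LD pruning
#'
#' Removes one member of each highly correlated SNP pair, in the style of
#' PLINK's indep-pairwise pruning. SNPs must be ordered by position within
#' chromosome. Within each sliding window of `window_snps` surviving SNPs the
#' squared Pearson correlation of genotype counts is computed for every pair;
#' while any pair exceeds `r2_max`, the member with the lower minor allele
#' frequency is removed (on a tie, the higher column index). The window then
#' advances by `step_snps`. Pairs involving a monomorphic column (undefined
#' correlation) are ignored. The operation is idempotent for fixed
#' parameters.
#'
#' @param G a [genotype_matrix()] with no missing genotypes.
#' @param r2_max squared-correlation threshold above which a pair is pruned;
#'   default 0.5.
#' @param window_snps,step_snps window size and step, in SNP counts;
#'   defaults 50 and 5.
#' @return the pruned `genotype_matrix`.
#' @export
ld_prune <- function(G, r2_max = 0.5, window_snps = 50, step_snps = 5) {
  if (anyNA(G$genotypes)) stop("resolve missing genotypes before LD pruning")
  snps <- G$snps
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    if (is.unsorted(snps$pos[idx])) stop("SNP positions must be sorted within chromosome ", ch)
  }
  g <- G$genotypes
  p <- colSums(g) / (2 * nrow(g))
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, ncol(g))
  for (ch in unique(snps$chrom)) {
    chrom_idx <- which(snps$chrom == ch)
    start <- 1L
    repeat {
      alive <- chrom_idx[keep[chrom_idx]]
      if (start > length(alive)) break
      win <- alive[seq(start, min(start + window_snps - 1L, length(alive)))]
      if (length(win) >= 2) {
        repeat {
          r2 <- suppressWarnings(stats::cor(g[, win, drop = FALSE]))^2
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          hit <- which(r2 > r2_max, arr.ind = TRUE)
          hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
          if (nrow(hit) == 0) break
          # first offending pair in (row-major) index order; drop lower-MAF member
          hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
          a <- win[hit[1, 1]]; b <- win[hit[1, 2]]
          drop <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else max(a, b)
          keep[drop] <- FALSE
          win <- win[win != drop]
          if (length(win) < 2) break
        }
      }
      alive <- chrom_idx[keep[chrom_idx]]
      if (start + window_snps - 1L >= length(alive)) break
      start <- start + step_snps
    }
  }
  subset_snps(G, keep)
}

#' Resolve missing genotype calls
#'
#' The ReliefF pipeline needs a complete matrix so that the subject count `m`
#' (and hence the neighbor count `k = floor(m/6)`) stays fixed. Policy
#' `"impute_major"` replaces each missing call with that SNP's modal genotype
#' count (ties broken toward the smaller count); `"drop_snp"` removes any SNP
#' with missingness.
#'
#' @param G a [genotype_matrix()].
#' @param policy `"impute_major"` (default) or `"drop_snp"`.
#' @return a complete `genotype_matrix`.
#' @export
clean_missing <- function(G, policy = c("impute_major", "drop_snp")) {
  policy <- match.arg(policy)
  g <- G$genotypes
  n_miss <- colSums(is.na(g))
  if (policy == "drop_snp") return(subset_snps(G, n_miss == 0L))
  for (j in which(n_miss > 0L)) {
    obs <- g[!is.na(g[, j]), j]
    if (length(obs) == 0L)
      stop("SNP ", G$snps$snp_id[j], " is entirely missing; no modal genotype defined")
    counts <- tabulate(obs + 1L, nbins = 3L)
    g[is.na(g[, j]), j] <- which.max(counts) - 1L
  }
  G$genotypes <- g
  G
}
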