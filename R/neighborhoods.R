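#' Subject-subject distance matrix from per-locus diffs
#'
#' Accumulates a chosen single-locus diff over all SNPs into a pairwise
#' subject distance: the Manhattan (city-block) form sums `|diff|` over SNPs,
#' the Euclidean form takes the square root of the sum of squared diffs.
#' When `kind = "titv"` each SNP contributes according to its own mutation
#' class. The diagonal is zero; for `kind = "gm"` or `"am"` the result is a
#' metric, for `"titv"` a symmetric non-negative dissimilarity (the
#' transition diff violates the per-locus triangle inequality).
#'
#' Implementation note: for each mutation-class stratum the distance is
#' assembled from genotype-indicator cross-products, so the cost is a handful
#' of `m x N` by `N x m` matrix multiplications rather than an `m^2 N` loop.
#'
#' @param G a complete [genotype_matrix()].
#' @param kind diff function: `"gm"`, `"am"` or `"titv"`.
#' @param norm `"manhattan"` (default) or `"euclidean"`.
#' @return `m x m` symmetric numeric matrix with zero diagonal, with
#'   attributes `metric` (descriptor string) recording the configuration.
#' @export
distance_city <- function(G, kind = c("gm", "am", "titv"),
                          norm = c("manhattan", "euclidean")) {
  kind <- match.arg(kind)
  norm <- match.arg(norm)
  g <- G$genotypes
  if (anyNA(g)) stop("resolve missing genotypes before computing distances")
  m <- nrow(g)
  D <- matrix(0, m, m)
  strata <- if (kind == "titv") {
    split(seq_len(ncol(g)), G$snps$mutation_class)
  } else {
    list(all = seq_len(ncol(g)))
  }
  for (s in names(strata)) {
    cols <- strata[[s]]
    if (length(cols) == 0) next
    vals <- switch(kind,
      gm = c(1, 1),                     # diff for |delta| = 1, 2
      am = c(0.5, 1),
      titv = if (s == "transition") c(0.25, 0.75) else c(0.5, 1))
    if (norm == "euclidean") vals <- vals^2
    gs <- g[, cols, drop = FALSE]
    I0 <- (gs == 0L) * 1; I1 <- (gs == 1L) * 1; I2 <- (gs == 2L) * 1
    x01 <- I0 %*% t(I1); x02 <- I0 %*% t(I2); x12 <- I1 %*% t(I2)
    D <- D + vals[1] * (x01 + t(x01) + x12 + t(x12)) +
             vals[2] * (x02 + t(x02))
  }
  if (norm == "euclidean") D <- sqrt(D)
  diag(D) <- 0
  dimnames(D) <- list(G$subject_ids, G$subject_ids)
  attr(D, "metric") <- paste0(norm, "-", kind)
  D
}

#' Genetic relationship matrix
#'
#' Pairwise genetic relatedness of subjects from allele-frequency
#' standardized genotypes:
#' `A_ij = (1/N) * sum_nu (g_i_nu - 2 p_nu) (g_j_nu - 2 p_nu) / (2 p_nu (1 - p_nu))`,
#' with `p_nu` the counted-allele frequency estimated from the analyzed
#' sample (cases and controls pooled). The diagonal is the same formula at
#' `i = j`; it is computed but never used for neighbor search (self is
#' excluded). `A` is invariant under flipping the counted allele of any SNP
#' (`g -> 2 - g`) and under subject reordering.
#'
#' @param G a complete [genotype_matrix()]; every SNP must be polymorphic.
#' @return `m x m` symmetric matrix with attribute `n_snps` (the `N` used).
#' @export
grm_matrix <- function(G) {
  g <- G$genotypes
  if (anyNA(g)) stop("resolve missing genotypes before computing the GRM")
  p <- colSums(g) / (2 * nrow(g))
  if (any(p == 0 | p == 1))
    stop("monomorphic SNPs present; apply maf_filter() before grm_matrix()")
  N <- ncol(g)
  Z <- sweep(g, 2, 2 * p, "-")
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  A <- tcrossprod(Z) / N
  dimnames(A) <- list(G$subject_ids, G$subject_ids)
  attr(A, "n_snps") <- N
  A
}

#' Distance from the genetic relationship matrix
#'
#' Converts relatedness into a subject-subject distance,
#' `D_ij = sqrt(2 N (1 - A_ij))`: unrelated pairs (`A = 0`) sit at the
#' distance expected for standardized independent genotypes, identical
#' relatedness (`A = 1`) at zero. Relatedness can exceed 1 for near-duplicate
#' subjects; the radicand is clamped at zero and the number of clamped
#' off-diagonal entries is recorded in the `clamped` attribute.
#'
#' @param A relatedness matrix from [grm_matrix()].
#' @param n_snps number of SNPs behind `A`; defaults to its `n_snps`
#'   attribute.
#' @return distance matrix with zero diagonal and attributes `metric`,
#'   `clamped`.
#' @export
grm_distance <- function(A, n_snps = attr(A, "n_snps")) {
  if (is.null(n_snps)) stop("n_snps must be supplied")
  rad <- 1 - A
  clamped <- sum(rad < 0 & row(A) != col(A))
  if (clamped > 0)
    warning(clamped, " off-diagonal relatedness values exceeded 1; distance clamped to 0")
  D <- sqrt(2 * n_snps * pmax(rad, 0))
  diag(D) <- 0
  attr(D, "metric") <- "grm"
  attr(D, "clamped") <- clamped
  D
}

#' Default neighbor count
#'
#' The constant neighborhood size `k = floor(m/6)`, which approximates the
#' adaptive-radius MultiSURF neighborhood and balances power for main effects
#' and interactions.
#'
#' @param m number of subjects (at least 12, so that `k >= 2`).
#' @return integer `k`.
#' @export
default_k <- function(m) {
  if (m < 12) stop("need at least 12 subjects for the default k = floor(m/6)")
  as.integer(m %/% 6)
}

#' k nearest hits and misses per subject
#'
#' For every subject, the `k` nearest same-class subjects (hits) and `k`
#' nearest other-class subjects (misses) under a precomputed distance matrix.
#' Self is excluded; ties in distance are broken by ascending subject index,
#' so the result is deterministic and invariant under any strictly monotone
#' transform of the distances.
#'
#' @param D `m x m` symmetric distance matrix.
#' @param phenotype length-`m` phenotype (coerced via [as_phenotype()]).
#' @param k neighbors per list; both classes must have more than `k` members.
#' @return object of class `neighbor_sets`: list with `hits` and `misses`
#'   (`m x k` integer index matrices, row `i` ordered nearest first) and `k`.
#' @export
find_neighbors <- function(D, phenotype, k) {
  phenotype <- as_phenotype(phenotype)
  m <- nrow(D)
  if (length(phenotype) != m) stop("phenotype length must match the distance matrix")
  if (anyNA(phenotype)) stop("phenotype must be complete")
  k <- as.integer(k)
  if (k < 1) stop("k must be at least 1")
  cls <- table(phenotype)
  if (any(cls == 0)) stop("both phenotype classes must be present")
  if (min(cls) <= k)
    stop("k = ", k, " requires more than k subjects in each class (smallest class: ",
         min(cls), ")")
  hits <- matrix(NA_integer_, m, k)
  misses <- matrix(NA_integer_, m, k)
  idx <- seq_len(m)
  for (i in idx) {
    ord <- order(D[i, ], idx)        # stable: ties broken by subject index
    ord <- ord[ord != i]
    same <- phenotype[ord] == phenotype[i]
    hits[i, ] <- ord[same][seq_len(k)]
    misses[i, ] <- ord[!same][seq_len(k)]
  }
  structure(list(hits = hits, misses = misses, k = k), class = "neighbor_sets")
}
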