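#' Single-locus diff functions
#'
#' Per-locus dissimilarities between two subjects' genotypes at a biallelic
#' SNP, used both to accumulate subject-subject distances and to score
#' attribute importance in ReliefF. Genotypes are minor-allele counts in
#' `{0, 1, 2}`.
#'
#' * `diff_gm()` -- genotype mismatch, the categorical ReliefF standard:
#'   0 if the genotypes are identical, 1 otherwise.
#' * `diff_am()` -- allele mismatch: `|g1 - g2| / 2`, i.e. 0, 0.5 or 1 when
#'   the subjects share 2, 1 or 0 alleles.
#' * `diff_titv()` -- transition/transversion diff derived from the 2d
#'   unit-circle encoding (see [encode_titv()]): for transversion SNPs it
#'   coincides with `diff_am`; for transition SNPs adjacent genotypes are
#'   contracted, giving 1/4 (het vs hom) and 3/4 (opposite homozygotes).
#'
#' All three are symmetric, lie in `[0, 1]`, and vanish on identical
#' genotypes, with the pointwise ordering `diff_titv <= diff_am <= diff_gm`.
#' Note the transition diff violates the per-locus triangle inequality
#' (3/4 > 1/4 + 1/4), so Manhattan sums of it form a symmetric dissimilarity,
#' not a metric.
#'
#' @param g1,g2 integer vectors of genotype counts in `{0, 1, 2}`; recycled.
#' @param mutation_class `"transition"` or `"transversion"` (vectorized).
#' @return numeric vector of diff values in `[0, 1]`.
#' @examples
#' diff_gm(2, 1)                        # 1
#' diff_am(2, 1)                        # 0.5
#' diff_titv(2, 0, "transversion")      # 1
#' diff_titv(2, 0, "transition")        # 0.75
#' @name snp_diffs
NULL

check_geno <- function(...) {
  for (g in list(...)) {
    if (!all(g %in% c(0, 1, 2)))
      stop("genotype counts must be 0, 1 or 2")
  }
  invisible(NULL)
}

#' @rdname snp_diffs
#' @export
diff_gm <- function(g1, g2) {
  check_geno(g1, g2)
  as.numeric(g1 != g2)
}

#' @rdname snp_diffs
#' @export
diff_am <- function(g1, g2) {
  check_geno(g1, g2)
  abs(g1 - g2) / 2
}

# closed-form Ti/Tv diff values indexed by |g1 - g2| + 1
.titv_transition <- c(0, 0.25, 0.75)
.titv_transversion <- c(0, 0.5, 1)

#' @rdname snp_diffs
#' @export
diff_titv <- function(g1, g2, mutation_class) {
  check_geno(g1, g2)
  mutation_class <- check_class(mutation_class)
  n <- max(length(g1), length(g2), length(mutation_class))
  d <- abs(rep_len(g1, n) - rep_len(g2, n)) + 1L
  ifelse(rep_len(mutation_class, n) == "transition",
         .titv_transition[d], .titv_transversion[d])
}

check_class <- function(mutation_class) {
  mutation_class <- as.character(mutation_class)
  if (!all(mutation_class %in% c("transition", "transversion")))
    stop('mutation_class must be "transition" or "transversion"')
  mutation_class
}

#' Two-dimensional Ti/Tv genotype encoding
#'
#' Represents a genotype as a unit vector in the plane; the similarity of two
#' genotypes is the squared dot product (squared cosine of their angular
#' separation), and the diff is one minus that similarity. With the `aa`
#' homozygote fixed at angle 0, transversion genotypes sit at
#' `{aa: 0, Aa: pi/4, AA: pi/2}` -- opposite homozygotes orthogonal -- while
#' transition genotypes are contracted to `{aa: 0, Aa: pi/6, AA: pi/3}`,
#' making transition changes more similar than the corresponding transversion
#' changes. Only angle differences enter the similarity, so the absolute
#' rotation of the basis is immaterial.
#'
#' @param g genotype count in `{0, 1, 2}` (vectorized).
#' @param mutation_class `"transition"` or `"transversion"` (vectorized).
#' @return a matrix with columns `x`, `y`; each row a unit vector.
#' @seealso [titv_similarity()] for the squared-dot-product similarity.
#' @export
encode_titv <- function(g, mutation_class) {
  check_geno(g)
  mutation_class <- check_class(mutation_class)
  n <- max(length(g), length(mutation_class))
  g <- rep_len(g, n)
  step <- ifelse(rep_len(mutation_class, n) == "transition", pi / 6, pi / 4)
  theta <- g * step
  cbind(x = cos(theta), y = sin(theta))
}

#' Ti/Tv similarity from the 2d encoding
#'
#' Squared dot product of two encoded genotype vectors, `cos^2` of their
#' angular separation. `1 - titv_similarity(...)` reproduces [diff_titv()]
#' exactly (to floating point); the closed-form table is what the distance
#' and scoring code uses.
#'
#' @inheritParams snp_diffs
#' @return numeric vector of similarities in `[0, 1]`.
#' @export
titv_similarity <- function(g1, g2, mutation_class) {
  v1 <- encode_titv(g1, mutation_class)
  v2 <- encode_titv(g2, mutation_class)
  rowSums(v1 * v2)^2
}

#' Catalog of diff values over all genotype pairs
#'
#' Emits the full table of a diff function over the 9 ordered genotype pairs
#' for both mutation classes, for documentation and tests. GM and AM do not
#' depend on the mutation class; the Ti/Tv diff is smaller on transitions.
#'
#' @param kind one of `"gm"`, `"am"`, `"titv"`.
#' @return data frame with columns `g1`, `g2`, `mutation_class`, `diff`.
#' @export
diff_table <- function(kind = c("gm", "am", "titv")) {
  kind <- match.arg(kind)
  grid <- expand.grid(g1 = 0:2, g2 = 0:2,
                      mutation_class = c("transition", "transversion"),
                      stringsAsFactors = FALSE)
  grid$diff <- switch(kind,
    gm = diff_gm(grid$g1, grid$g2),
    am = diff_am(grid$g1, grid$g2),
    titv = diff_titv(grid$g1, grid$g2, grid$mutation_class))
  grid
}
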