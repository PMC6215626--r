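test_that("city-block distances sum per-locus diffs", {
  # identical subjects: zero under every kind
  g <- rbind(c(0L, 1L, 2L), c(0L, 1L, 2L))
  for (kind in c("gm", "am", "titv")) {
    D <- distance_city(toy_geno(g), kind)
    expect_equal(unname(D[1, 2]), 0)
  }
  # single-SNP matrix: distance equals the per-locus diff
  G1 <- toy_geno(cbind(c(2L, 1L)), classes = "transition")
  expect_equal(unname(distance_city(G1, "titv")[1, 2]), 0.25)
  # (0,1,2) vs (2,1,0) over three transversion SNPs, AM: 1 + 0 + 1 = 2
  G2 <- toy_geno(rbind(c(0L, 1L, 2L), c(2L, 1L, 0L)))
  expect_equal(unname(distance_city(G2, "am")[1, 2]), 2)
  expect_equal(attr(distance_city(G2, "am"), "metric"), "manhattan-am")
})

test_that("distances agree with a naive double-loop on random data", {
  G <- random_geno(m = 12, N = 30, seed = 31)
  g <- G$genotypes
  is_ti <- G$snps$mutation_class == "transition"
  per_locus <- function(a, b, kind) {
    switch(kind,
           gm = as.numeric(a != b),
           am = abs(a - b) / 2,
           titv = ifelse(is_ti, c(0, .25, .75)[abs(a - b) + 1],
                         abs(a - b) / 2))
  }
  for (kind in c("gm", "am", "titv")) {
    for (norm in c("manhattan", "euclidean")) {
      D <- distance_city(G, kind, norm)
      ref <- matrix(0, 12, 12)
      for (i in 1:12) for (j in 1:12) {
        dv <- per_locus(g[i, ], g[j, ], kind)
        ref[i, j] <- if (norm == "manhattan") sum(dv) else sqrt(sum(dv^2))
      }
      expect_equal(unname(unclass(D))[seq_len(12), ], ref, tolerance = 1e-12)
      expect_true(isSymmetric(unname(unclass(D)[seq_len(12), ])))
    }
  }
})

test_that("Ti/Tv distances reduce to AM on transversion-only data", {
  G <- random_geno(m = 20, N = 40, seed = 13, ti_fraction = 0)
  expect_equal(unclass(distance_city(G, "titv"))[],
               unclass(distance_city(G, "am"))[], ignore_attr = TRUE)
})

test_that("GM/AM city distances satisfy the triangle inequality on random data", {
  G <- random_geno(m = 15, N = 25, seed = 77)
  for (kind in c("gm", "am")) {
    D <- distance_city(G, kind)
    for (i in 1:15) for (j in 1:15) for (l in 1:15)
      expect_lte(D[i, j], D[i, l] + D[l, j] + 1e-12)
  }
})

test_that("GRM matches hand-computed relatedness on a 3x2 toy", {
  # subjects (0,1), (1,2), (2,0); p = (0.5, 0.5); denominators 2p(1-p) = 0.5
  G <- toy_geno(rbind(c(0L, 1L), c(1L, 2L), c(2L, 0L)),
                phenotype = c("case", "control", "case"))
  A <- grm_matrix(G)
  expect_equal(unname(A[1, 2]), 0)    # ((-1)(0) + (0)(1)) / 0.5 / 2
  expect_equal(unname(A[1, 3]), -1)   # ((-1)(1) + (0)(-1)) / 0.5 / 2
  expect_equal(unname(A[2, 3]), -1)
  expect_equal(unname(A[1, 1]), 1)    # plain formula at i = j
  expect_equal(attr(A, "n_snps"), 2L)
  # identical genotype rows: A_12 equals A_11
  Gd <- toy_geno(rbind(c(0L, 1L), c(0L, 1L), c(2L, 0L)),
                 phenotype = c("case", "control", "case"))
  Ad <- grm_matrix(Gd)
  expect_equal(Ad[1, 2], Ad[1, 1])
})

test_that("GRM hand example with m = 2: opposite homozygotes give A = -2", {
  G <- toy_geno(cbind(c(0L, 2L)), phenotype = c("case", "control"))
  A <- grm_matrix(G)  # p = 0.5: (0-1)(2-1)/(2*0.25) = -2
  expect_equal(unname(A[1, 2]), -2)
})

test_that("GRM is invariant under per-SNP allele flips and subject reorder", {
  G <- random_geno(m = 25, N = 40, seed = 19)
  A <- grm_matrix(G)
  Gf <- G
  flip <- c(1, 5, 7, 20)
  Gf$genotypes[, flip] <- 2L - Gf$genotypes[, flip]
  expect_equal(unclass(grm_matrix(Gf))[], unclass(A)[], tolerance = 1e-12)
  perm <- sample(25)
  Gp <- G
  Gp$genotypes <- Gp$genotypes[perm, ]
  Gp$phenotype <- Gp$phenotype[perm]
  Gp$subject_ids <- Gp$subject_ids[perm]
  expect_equal(unclass(grm_matrix(Gp))[, ], unclass(A)[perm, perm],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("monomorphic SNPs are rejected by the GRM", {
  G <- toy_geno(cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 2L, 1L)))
  expect_error(grm_matrix(G), "maf_filter")
})

test_that("GRM distance maps relatedness to sqrt(2N(1-A)) with clamping", {
  A <- matrix(c(1, 0, 1.2,
                0, 1, 0.5,
                1.2, 0.5, 1), 3, 3)
  attr(A, "n_snps") <- 50L
  expect_warning(D <- grm_distance(A), "clamped")
  expect_equal(unname(D[1, 2]), 10)      # sqrt(2 * 50 * 1)
  expect_equal(unname(D[1, 3]), 0)       # radicand clamped at 0
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(attr(D, "clamped"), 2L)   # symmetric entry counted twice
  expect_error(grm_distance(unclass(A)[, ]), "n_snps")
})

test_that("the default neighbor count is floor(m/6)", {
  expect_identical(default_k(12), 2L)
  expect_identical(default_k(13), 2L)
  expect_identical(default_k(600), 100L)
  expect_error(default_k(11), "at least 12")
})

test_that("neighbor search matches exhaustive search on hand-set distances", {
  D <- matrix(c(0, 1, 4, 3,
                1, 0, 2, 5,
                4, 2, 0, 6,
                3, 5, 6, 0), 4, 4)
  pheno <- c("case", "case", "control", "control")
  nb <- find_neighbors(D, pheno, k = 1)
  # brute force: nearest same-class / other-class subject, self excluded
  for (i in 1:4) {
    cand <- setdiff(1:4, i)
    same <- cand[pheno[cand] == pheno[i]]
    diff <- cand[pheno[cand] != pheno[i]]
    expect_identical(nb$hits[i, 1], same[which.min(D[i, same])])
    expect_identical(nb$misses[i, 1], diff[which.min(D[i, diff])])
  }
})

test_that("self is excluded but a zero-distance duplicate is an eligible hit", {
  D <- matrix(1, 4, 4) - diag(4)
  D[1, 2] <- D[2, 1] <- 0  # subject 2 duplicates subject 1
  nb <- find_neighbors(D, c("case", "case", "control", "control"), k = 1)
  expect_identical(nb$hits[1, 1], 2L)
  expect_identical(nb$hits[2, 1], 1L)
})

test_that("distance ties resolve to the lowest-index eligible subjects", {
  D <- matrix(1, 6, 6) - diag(6)
  nb <- find_neighbors(D, rep(c("case", "control"), 3), k = 2)
  expect_identical(nb$hits[1, ], c(3L, 5L))
  expect_identical(nb$misses[1, ], c(2L, 4L))
})

test_that("neighbors are invariant under strictly monotone distance transforms", {
  G <- random_geno(m = 24, N = 30, seed = 55)
  D <- distance_city(G, "am")
  nb1 <- find_neighbors(D, G$phenotype, 3)
  nb2 <- find_neighbors(sqrt(unclass(D)[, ] + 2), G$phenotype, 3)
  expect_identical(nb1$hits, nb2$hits)
  expect_identical(nb1$misses, nb2$misses)
})

test_that("neighbor search validates class sizes", {
  D <- matrix(1, 5, 5) - diag(5)
  expect_error(find_neighbors(D, c("case", "case", "case", "case", "control"), 1),
               "more than k subjects")
  expect_error(find_neighbors(D, rep("case", 5), 1), "both phenotype classes")
})
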