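#' Brute-force ReliefF oracle
#'
#' A deliberately naive reference implementation used to validate the fast
#' path: it recomputes the distance matrix with an explicit double loop over
#' subject pairs, selects neighbors by sorting full distance rows, and
#' accumulates the attribute weights SNP by SNP and subject by subject. It
#' shares no code with [distance_city()], [grm_matrix()],
#' [find_neighbors()] or [relieff_scores()] beyond the per-locus diff
#' definitions themselves, and is only intended for small problems
#' (roughly `m <= 200`, `N <= 500`).
#'
#' @param G a complete [genotype_matrix()].
#' @param k neighbors per class; default `floor(m/6)`.
#' @param nn_metric `"gm"`, `"am"`, `"titv"` or `"grm"`.
#' @param diff_metric `"gm"`, `"am"` or `"titv"`.
#' @param norm `"manhattan"` or `"euclidean"` for the diff-based metrics.
#' @return data frame with columns `snp_id`, `W`, `mean_miss_diff`,
#'   `mean_hit_diff`.
#' @export
relieff_oracle <- function(G, k = NULL,
                           nn_metric = c("gm", "am", "titv", "grm"),
                           diff_metric = c("gm", "am", "titv"),
                           norm = c("manhattan", "euclidean")) {
  nn_metric <- match.arg(nn_metric)
  diff_metric <- match.arg(diff_metric)
  norm <- match.arg(norm)
  g <- G$genotypes
  m <- nrow(g)
  N <- ncol(g)
  if (is.null(k)) k <- m %/% 6
  is_ti <- G$snps$mutation_class == "transition"
  pheno <- as.character(G$phenotype)

  # per-locus diff evaluated directly from the definitions; `ti` is the
  # transition flag aligned with `a` and `b`
  locus_diff <- function(a, b, kind, ti) {
    if (kind == "gm") return(as.numeric(a != b))
    if (kind == "am") return(abs(a - b) / 2)
    delta <- abs(a - b)
    out <- numeric(length(delta))
    out[delta == 1] <- ifelse(ti[delta == 1], 1 / 4, 1 / 2)
    out[delta == 2] <- ifelse(ti[delta == 2], 3 / 4, 1)
    out
  }

  D <- matrix(0, m, m)
  if (nn_metric == "grm") {
    p <- numeric(N)
    for (v in seq_len(N)) p[v] <- sum(g[, v]) / (2 * m)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      a <- sum((g[i, ] - 2 * p) * (g[j, ] - 2 * p) / (2 * p * (1 - p))) / N
      D[i, j] <- sqrt(2 * N * max(0, 1 - a))
    }
    diag(D) <- 0
  } else {
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      dv <- locus_diff(g[i, ], g[j, ], nn_metric, is_ti)
      D[i, j] <- if (norm == "manhattan") sum(abs(dv)) else sqrt(sum(dv^2))
    }
  }

  hits <- vector("list", m)
  misses <- vector("list", m)
  for (i in seq_len(m)) {
    ord <- order(D[i, ], seq_len(m))
    ord <- ord[ord != i]
    hits[[i]] <- ord[pheno[ord] == pheno[i]][seq_len(k)]
    misses[[i]] <- ord[pheno[ord] != pheno[i]][seq_len(k)]
  }

  mbar <- numeric(N)
  hbar <- numeric(N)
  for (i in seq_len(m)) {
    for (j in misses[[i]])
      mbar <- mbar + locus_diff(g[i, ], g[j, ], diff_metric, is_ti)
    for (j in hits[[i]])
      hbar <- hbar + locus_diff(g[i, ], g[j, ], diff_metric, is_ti)
  }
  mbar <- mbar / (m * k)
  hbar <- hbar / (m * k)
  data.frame(snp_id = G$snps$snp_id, W = mbar - hbar,
             mean_miss_diff = mbar, mean_hit_diff = hbar,
             stringsAsFactors = FALSE)
}
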