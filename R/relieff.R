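#' ReliefF attribute importance scores
#'
#' The reformulated ReliefF weight of each SNP as a difference of mean diffs:
#' with `M_j(R_i)` and `H_j(R_i)` the k nearest misses and hits of subject
#' `R_i`,
#' `Mbar = (1/(mk)) * sum_i sum_j diff(g_nu, R_i, M_j(R_i))`,
#' `Hbar` analogously over hits, and `W = Mbar - Hbar`. A SNP whose genotypes
#' separate subjects in different classes more than subjects in the same
#' class receives a positive weight. Every subject contributes exactly `k`
#' hit and `k` miss terms, so `Mbar, Hbar` lie in `[0, 1]` and `W` in
#' `[-1, 1]`. Evaluation order is deterministic, so results are reproducible
#' bit for bit.
#'
#' @param G a complete [genotype_matrix()].
#' @param neighbors a `neighbor_sets` object from [find_neighbors()] built on
#'   the same subjects.
#' @param kind attribute diff: `"gm"`, `"am"` or `"titv"`.
#' @return object of class `relieff_scores`: a data frame with columns
#'   `snp_id`, `W`, `mean_miss_diff`, `mean_hit_diff`, `rank` (1 = most
#'   important; ties by ascending SNP index), plus attributes `kind` and `k`.
#' @export
relieff_scores <- function(G, neighbors, kind = c("gm", "am", "titv")) {
  kind <- match.arg(kind)
  g <- G$genotypes
  if (anyNA(g)) stop("resolve missing genotypes before scoring")
  m <- nrow(g)
  if (nrow(neighbors$hits) != m)
    stop("neighbor sets were built for ", nrow(neighbors$hits),
         " subjects but the matrix has ", m)
  k <- neighbors$k
  is_ti <- G$snps$mutation_class == "transition"
  miss_sum <- pair_diff_sums(g, rep(seq_len(m), times = k),
                             as.vector(neighbors$misses), kind, is_ti)
  hit_sum <- pair_diff_sums(g, rep(seq_len(m), times = k),
                            as.vector(neighbors$hits), kind, is_ti)
  mbar <- unname(miss_sum / (m * k))
  hbar <- unname(hit_sum / (m * k))
  W <- mbar - hbar
  out <- data.frame(snp_id = G$snps$snp_id, W = W,
                    mean_miss_diff = mbar, mean_hit_diff = hbar,
                    stringsAsFactors = FALSE)
  out$rank <- rank_order_to_rank(order(-out$W, seq_len(nrow(out))))
  attr(out, "kind") <- kind
  attr(out, "k") <- k
  class(out) <- c("relieff_scores", "data.frame")
  out
}

# turn an ordering (best first) into per-element ranks
rank_order_to_rank <- function(ord) {
  r <- integer(length(ord))
  r[ord] <- seq_along(ord)
  r
}

# Sum of per-locus diffs over a list of subject pairs, per SNP.
# ia/ib are parallel index vectors; processed in row chunks to bound memory.
pair_diff_sums <- function(g, ia, ib, kind, is_ti, chunk = 4096L) {
  N <- ncol(g)
  total <- numeric(N)
  n_pairs <- length(ia)
  ti_vals <- c(0, 0.25, 0.75)
  for (from in seq(1L, n_pairs, by = chunk)) {
    to <- min(from + chunk - 1L, n_pairs)
    d <- abs(g[ia[from:to], , drop = FALSE] - g[ib[from:to], , drop = FALSE])
    dd <- switch(kind,
      gm = (d > 0) * 1,
      am = d / 2,
      titv = {
        x <- d / 2
        if (any(is_ti)) {
          sub <- d[, is_ti, drop = FALSE]
          x[, is_ti] <- ti_vals[sub + 1L]
        }
        x
      })
    total <- total + colSums(dd)
  }
  total
}

#' Rank SNPs by ReliefF weight
#'
#' Orders SNPs by descending weight `W`, ties broken by ascending SNP index
#' (original column order), optionally truncated.
#'
#' @param scores a `relieff_scores` object (or data frame with `snp_id`, `W`).
#' @param top_n optional number of top SNPs to keep.
#' @return data frame of the ranked SNPs (columns of `scores` plus `rank`).
#' @export
rank_snps <- function(scores, top_n = NULL) {
  ord <- order(-scores$W, seq_len(nrow(scores)))
  out <- as.data.frame(scores)[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

#' @export
print.relieff_scores <- function(x, ...) {
  cat("relieff_scores: ", nrow(x), " SNPs (diff = ", attr(x, "kind"),
      ", k = ", attr(x, "k"), ")\n", sep = "")
  print(utils::head(rank_snps(x), 5))
  invisible(x)
}

#' Run ReliefF end to end on a genotype matrix
#'
#' Convenience wrapper wiring the pieces together: builds the
#' nearest-neighbor distance matrix under `nn_metric` (one of the three
#' Manhattan-of-diffs metrics, or the GRM distance which ignores `norm`),
#' selects `k` nearest hits and misses per subject, and scores every SNP with
#' the `diff_metric` attribute diff. The six canonical combinations are
#' GM-GM, AM-AM, TiTv-TiTv (Manhattan) and GRM-GM, GRM-AM, GRM-TiTv, but any
#' combination is allowed.
#'
#' @param G a complete [genotype_matrix()].
#' @param nn_metric neighbor metric: `"gm"`, `"am"`, `"titv"` or `"grm"`.
#' @param diff_metric attribute diff: `"gm"`, `"am"` or `"titv"`.
#' @param norm `"manhattan"` or `"euclidean"` (diff-based metrics only).
#' @param k neighbors per class; default [default_k()] of the subject count.
#' @return a `relieff_scores` object (attribute `nn_metric` records the
#'   neighbor metric).
#' @examples
#' sim <- simulate_gwas(sim_config(m = 60, n_snps = 50, n_main = 2, seed = 7))
#' sc <- relieff(sim$genotypes, nn_metric = "titv", diff_metric = "titv")
#' head(rank_snps(sc))
#' @export
relieff <- function(G, nn_metric = c("gm", "am", "titv", "grm"),
                    diff_metric = c("gm", "am", "titv"),
                    norm = c("manhattan", "euclidean"), k = NULL) {
  nn_metric <- match.arg(nn_metric)
  diff_metric <- match.arg(diff_metric)
  norm <- match.arg(norm)
  if (is.null(k)) k <- default_k(nrow(G$genotypes))
  D <- if (nn_metric == "grm") {
    grm_distance(grm_matrix(G))
  } else {
    distance_city(G, kind = nn_metric, norm = norm)
  }
  nb <- find_neighbors(D, G$phenotype, k)
  sc <- relieff_scores(G, nb, kind = diff_metric)
  attr(sc, "nn_metric") <- if (nn_metric == "grm") "grm" else paste0(norm, "-", nn_metric)
  sc
}

#' Write ReliefF scores to a TSV results file
#'
#' Columns `snp_id`, `W`, `mean_miss_diff`, `mean_hit_diff`, `rank`, sorted
#' by rank.
#'
#' @param scores a `relieff_scores` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  out <- rank_snps(scores)
  utils::write.table(out[, c("snp_id", "W", "mean_miss_diff", "mean_hit_diff", "rank")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranking from a scores TSV
#'
#' Accepts the file written by [write_scores()] or any external two-plus
#' column TSV with `snp_id` and a numeric score column (first numeric column
#' is used), enabling comparison of rankings produced by other tools.
#'
#' @param path TSV file with a header.
#' @return data frame with `snp_id` and `W`, sorted best first.
#' @export
read_ranking <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"snp_id" %in% names(tab)) names(tab)[1] <- "snp_id"
  score_col <- if ("W" %in% names(tab)) "W" else
    names(tab)[which(vapply(tab, is.numeric, logical(1)))[1]]
  if (is.na(score_col)) stop("no numeric score column found in ", path)
  out <- data.frame(snp_id = as.character(tab$snp_id), W = tab[[score_col]],
                    stringsAsFactors = FALSE)
  out[order(-out$W, seq_len(nrow(out))), , drop = FALSE]
}
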