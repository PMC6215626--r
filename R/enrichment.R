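#' Read a SNP-to-gene map
#'
#' A two-column TSV (`snp_id`, `gene_symbol`) assigning each SNP to its
#' closest gene; one gene per SNP. Duplicate SNP ids keep the first entry.
#'
#' @param path TSV file with a header.
#' @return data frame with columns `snp_id`, `gene_symbol`.
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "gene_symbol") %in% names(tab)))
    stop("gene map must have columns snp_id and gene_symbol")
  tab <- tab[!duplicated(tab$snp_id), c("snp_id", "gene_symbol")]
  rownames(tab) <- NULL
  tab
}

#' Read pathway gene sets from a GMT file
#'
#' Tab-separated: set name, description, then member gene symbols. Parsed
#' with `fgsea::gmtPathways()`; duplicate genes within a set are dropped.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lapply(fgsea::gmtPathways(path), unique)
}

#' Top unique genes from a SNP ranking
#'
#' Walks a ranked SNP list best-first, maps each SNP to its gene, and
#' collects unique gene symbols in order of first occurrence until `n_genes`
#' are found. Because many top SNPs map to the same gene, the ranking should
#' contain comfortably more than `n_genes` SNPs. SNPs absent from the map
#' are skipped (their count is reported in the `n_unmapped` attribute); if
#' fewer than `n_genes` distinct genes are reachable, all of them are
#' returned with a warning.
#'
#' @param ranking data frame with a `snp_id` column ordered best first
#'   (e.g. from [rank_snps()]), or a character vector of SNP ids.
#' @param gene_map data frame from [read_gene_map()].
#' @param n_genes target number of unique genes; default 500.
#' @return character vector of gene symbols (attribute `n_unmapped`).
#' @export
top_genes <- function(ranking, gene_map, n_genes = 500) {
  ids <- if (is.character(ranking)) ranking else as.character(ranking$snp_id)
  genes <- gene_map$gene_symbol[match(ids, gene_map$snp_id)]
  n_unmapped <- sum(is.na(genes))
  genes <- genes[!is.na(genes)]
  genes <- genes[!duplicated(genes)]
  if (length(genes) < n_genes)
    warning("only ", length(genes), " unique genes reachable (requested ",
            n_genes, ")")
  out <- utils::head(genes, n_genes)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Pathway overlap counts for a gene list
#'
#' For each pathway, the number of genes of `genes` it contains
#' (`|genes intersect pathway|`). No significance is attached: the counts are
#' meant for side-by-side comparison of selection methods against the
#' random-gene null.
#'
#' @param genes character vector of gene symbols.
#' @param pathways named list of gene sets from [read_gmt()].
#' @return named integer vector of overlap counts.
#' @export
pathway_overlap <- function(genes, pathways) {
  genes <- unique(as.character(genes))
  vapply(pathways, function(p) length(intersect(genes, p)), integer(1))
}

#' Random-gene null for pathway overlap
#'
#' Estimates the overlap expected by chance from pathway size alone: draw
#' `size` genes from the universe without replacement, count the overlap with
#' each pathway, and average over `reps` replicates. The mean converges to
#' the hypergeometric expectation `size * |pathway ∩ universe| / |universe|`.
#'
#' @param universe character vector of candidate gene symbols.
#' @param pathways named list of gene sets.
#' @param size genes per replicate; default 500.
#' @param reps number of replicates; default 100.
#' @param seed optional integer seed for reproducibility.
#' @return named numeric vector of mean overlaps, with attribute `sd`
#'   (per-pathway standard deviation across replicates).
#' @export
random_gene_null <- function(universe, pathways, size = 500, reps = 100,
                             seed = NULL) {
  universe <- unique(as.character(universe))
  if (size > length(universe))
    stop("size (", size, ") exceeds the gene universe (", length(universe), ")")
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(0L, nrow = reps, ncol = length(pathways),
                   dimnames = list(NULL, names(pathways)))
  for (r in seq_len(reps)) {
    draw <- sample(universe, size)
    counts[r, ] <- pathway_overlap(draw, pathways)
  }
  out <- colMeans(counts)
  attr(out, "sd") <- apply(counts, 2, stats::sd)
  out
}

#' Pathway overlap report for one or more rankings
#'
#' Combines [top_genes()], [pathway_overlap()] and [random_gene_null()] into
#' the comparison table: one row per method per pathway with the overlap
#' count and the random-gene mean for that pathway.
#'
#' @param rankings named list of ranked SNP data frames (or id vectors),
#'   one per method.
#' @param gene_map data frame from [read_gene_map()].
#' @param pathways named list from [read_gmt()].
#' @param n_genes unique genes per method; default 500.
#' @param null_reps replicates for the random-gene null; default 100.
#' @param universe gene universe for the null; default all genes in the map.
#' @param seed optional seed for the null.
#' @return data frame with columns `method`, `pathway`, `count`, `null_mean`.
#' @export
overlap_report <- function(rankings, gene_map, pathways, n_genes = 500,
                           null_reps = 100, universe = NULL, seed = NULL) {
  if (is.null(universe)) universe <- unique(gene_map$gene_symbol)
  null_mean <- random_gene_null(universe, pathways,
                                size = min(n_genes, length(universe)),
                                reps = null_reps, seed = seed)
  rows <- lapply(names(rankings), function(meth) {
    genes <- top_genes(rankings[[meth]], gene_map, n_genes)
    counts <- pathway_overlap(genes, pathways)
    data.frame(method = meth, pathway = names(counts),
               count = as.integer(counts),
               null_mean = as.numeric(null_mean[names(counts)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
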