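#' Run the full ReliefF pipeline from files
#'
#' Command-line-style front end: loads genotypes (PLINK `bfile` prefix or the
#' TSV dialect), resolves missing calls, applies the MAF and LD filters,
#' runs [relieff()] with the requested nearest-neighbor metric and attribute
#' diff, and writes a scores TSV plus a run log recording the parameters,
#' the subject and SNP counts before and after each filter, `k`, and any
#' numerical warnings (GRM distance clamps). This is the function behind the
#' `relief-snp run` command (see `system.file("cli", "relief-snp.R",
#' package = "reliefsnp")`).
#'
#' @param bfile PLINK prefix (`.bed/.bim/.fam`), or `NULL` when `geno_tsv`
#'   is given.
#' @param geno_tsv,snp_tsv paths of the TSV genotype dialect.
#' @param pheno optional alternate phenotype file (PLINK input only).
#' @param nn_metric,diff_metric,norm,k passed to [relieff()].
#' @param maf_min MAF filter threshold; default 0.01.
#' @param ld_r2,ld_window,ld_step LD pruning parameters (see [ld_prune()]).
#' @param missing_policy passed to [clean_missing()].
#' @param out output prefix; writes `<out>.scores.tsv` and `<out>.log`.
#' @return the `relieff_scores` object, invisibly.
#' @export
run_relieff <- function(bfile = NULL, geno_tsv = NULL, snp_tsv = NULL,
                        pheno = NULL,
                        nn_metric = "gm", diff_metric = "gm",
                        norm = "manhattan", k = NULL,
                        maf_min = 0.01, ld_r2 = 0.5, ld_window = 50,
                        ld_step = 5, missing_policy = "impute_major",
                        out = "relieff") {
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  G <- if (!is.null(bfile)) {
    load_plink(bfile, pheno_path = pheno)
  } else if (!is.null(geno_tsv)) {
    if (is.null(snp_tsv)) stop("snp_tsv is required with geno_tsv")
    load_tsv_genotypes(geno_tsv, snp_tsv)
  } else stop("supply bfile or geno_tsv")
  say("loaded ", nrow(G$genotypes), " subjects x ", ncol(G$genotypes), " SNPs")
  G <- clean_missing(G, missing_policy)
  n0 <- ncol(G$genotypes)
  G <- maf_filter(G, maf_min)
  say("MAF filter (>= ", maf_min, "): ", n0, " -> ", ncol(G$genotypes), " SNPs")
  n1 <- ncol(G$genotypes)
  G <- ld_prune(G, r2_max = ld_r2, window_snps = ld_window, step_snps = ld_step)
  say("LD pruning (r2 > ", ld_r2, ", window ", ld_window, "/", ld_step, "): ",
      n1, " -> ", ncol(G$genotypes), " SNPs")
  if (is.null(k)) k <- default_k(nrow(G$genotypes))
  say("nn_metric = ", nn_metric, ", diff_metric = ", diff_metric,
      ", norm = ", norm, ", k = ", k)
  clamped <- 0L
  sc <- withCallingHandlers(
    relieff(G, nn_metric = nn_metric, diff_metric = diff_metric,
            norm = norm, k = k),
    warning = function(w) {
      if (grepl("clamped", conditionMessage(w))) {
        clamped <<- clamped + 1L
        log_lines <<- c(log_lines, paste0("warning: ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    })
  if (nn_metric == "grm") say("GRM distance clamp events: ", clamped)
  write_scores(sc, paste0(out, ".scores.tsv"))
  say("scores written to ", out, ".scores.tsv")
  writeLines(log_lines, paste0(out, ".log"))
  invisible(sc)
}

#' Run the gene-mapping and pathway-overlap step from files
#'
#' Reads one or more score/ranking TSVs (from [run_relieff()] or external
#' tools), maps the top SNPs of each to unique genes, counts pathway
#' overlaps against a GMT file, appends the random-gene null, and writes the
#' report TSV. Warns when the SNP-id namespaces of the rankings and the gene
#' map barely overlap.
#'
#' @param score_files named character vector of ranking TSV paths (names
#'   become method labels; unnamed vectors use file basenames).
#' @param genemap path to the SNP-to-gene TSV.
#' @param gmt path to the pathway GMT file.
#' @param n_genes unique genes per method; default 500.
#' @param null_reps random-gene replicates; default 100.
#' @param seed seed for the null sampler.
#' @param out output TSV path; `NULL` skips writing.
#' @return the report data frame (`method`, `pathway`, `count`, `null_mean`).
#' @export
run_enrichment <- function(score_files, genemap, gmt, n_genes = 500,
                           null_reps = 100, seed = NULL, out = NULL) {
  if (is.null(names(score_files)) || any(names(score_files) == ""))
    names(score_files) <- tools::file_path_sans_ext(basename(score_files))
  gene_map <- read_gene_map(genemap)
  pathways <- read_gmt(gmt)
  rankings <- lapply(score_files, read_ranking)
  for (meth in names(rankings)) {
    hit_rate <- mean(rankings[[meth]]$snp_id %in% gene_map$snp_id)
    if (hit_rate < 0.5)
      warning(sprintf("method %s: only %.0f%% of ranked SNPs found in the gene map",
                      meth, 100 * hit_rate))
  }
  report <- overlap_report(rankings, gene_map, pathways, n_genes = n_genes,
                           null_reps = null_reps, seed = seed)
  if (!is.null(out)) {
    utils::write.table(report, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  report
}
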