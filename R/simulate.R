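#' Configuration for the synthetic GWAS generator
#'
#' Bundles the knobs of [simulate_gwas()] with the package's chosen defaults:
#' a case/control cohort of 200 subjects and 1000 biallelic SNPs with minor
#' allele frequencies uniform on (0.05, 0.5), a transition fraction of 2/3
#' (the genome-wide Ti:Tv ratio of about 2:1), no background linkage
#' disequilibrium unless requested, and a logistic disease model over the
#' functional SNPs. Main-effect SNPs act additively with a per-allele
#' log-odds of `main_effect`; epistatic pairs act through a pure-interaction
#' XOR-style term (`+epi_effect` on the log-odds when the two minor-allele
#' counts have odd sum, `-epi_effect` otherwise) and are forced to allele
#' frequency 0.5 so that each member has exactly zero marginal effect.
#'
#' @param m number of subjects.
#' @param n_snps number of SNPs.
#' @param maf_range range of simulated reference-allele frequencies.
#' @param ti_fraction fraction of SNPs assigned a transition allele pair
#'   (held exactly, by assignment).
#' @param n_main number of additive main-effect SNPs.
#' @param main_effect per-minor-allele log-odds of the main-effect SNPs.
#' @param n_epistatic number of purely epistatic SNP pairs.
#' @param epi_effect log-odds half-range of the XOR interaction term.
#' @param ld_block_size SNPs per LD block among background SNPs; 1 disables
#'   LD.
#' @param ld_rho probability that a block member copies the block seed's
#'   genotype entry (higher = stronger within-block correlation).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(m = 200, n_snps = 1000, maf_range = c(0.05, 0.5),
                       ti_fraction = 2 / 3, n_main = 0, main_effect = 1.0,
                       n_epistatic = 0, epi_effect = 3.0,
                       ld_block_size = 1, ld_rho = 0.8, seed = NULL) {
  cfg <- list(m = m, n_snps = n_snps, maf_range = maf_range,
              ti_fraction = ti_fraction, n_main = n_main,
              main_effect = main_effect, n_epistatic = n_epistatic,
              epi_effect = epi_effect, ld_block_size = ld_block_size,
              ld_rho = ld_rho, seed = seed)
  if (cfg$n_main + 2 * cfg$n_epistatic > cfg$n_snps)
    stop("functional SNPs exceed n_snps")
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range >= 1))
    stop("maf_range must lie strictly inside (0, 1)")
  structure(cfg, class = "sim_config")
}

#' Simulate a case/control SNP dataset with known architecture
#'
#' Generates a seeded [genotype_matrix()] whose background SNPs are drawn
#' `Binomial(2, p_nu)` under Hardy-Weinberg with `p_nu` uniform over
#' `maf_range`, with optional LD blocks (each non-seed block member copies
#' the block seed's genotype with probability `ld_rho`, otherwise redraws
#' from its own binomial), an exactly held transition fraction, and a
#' phenotype drawn from a logistic model over the functional SNPs (see
#' [sim_config()]). Main-effect terms are centered at the SNP's expected
#' count so the intercept stays near a 50% prevalence; epistatic pairs have
#' no marginal effect by construction. Functional SNPs are kept free of LD
#' copying.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `genotypes` (a `genotype_matrix`), `truth`
#'   (data frame: `snp_id`, `role` in `main`/`epistatic`, `partner` id for
#'   pair members), and `config`.
#' @export
simulate_gwas <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- cfg$m
  N <- cfg$n_snps
  p <- stats::runif(N, cfg$maf_range[1], cfg$maf_range[2])

  n_func <- cfg$n_main + 2 * cfg$n_epistatic
  func_idx <- if (n_func > 0) sample(N, n_func) else integer(0)
  main_idx <- utils::head(func_idx, cfg$n_main)
  epi_idx <- utils::tail(func_idx, 2 * cfg$n_epistatic)
  p[epi_idx] <- 0.5  # zero marginal effect for XOR pairs requires p = 1/2

  g <- matrix(stats::rbinom(m * N, 2L, rep(p, each = m)), nrow = m, ncol = N)

  if (cfg$ld_block_size > 1) {
    background <- setdiff(seq_len(N), func_idx)
    blocks <- split(background, ceiling(seq_along(background) / cfg$ld_block_size))
    for (blk in blocks) {
      if (length(blk) < 2) next
      seed_col <- g[, blk[1]]
      for (j in blk[-1]) {
        copy <- stats::runif(m) < cfg$ld_rho
        g[copy, j] <- seed_col[copy]
      }
    }
  }

  # allele pairs: exact transition count by assignment
  n_ti <- round(cfg$ti_fraction * N)
  is_ti <- rep(FALSE, N)
  if (n_ti > 0) is_ti[sample(N, n_ti)] <- TRUE
  ti_pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  tv_pairs <- rbind(c("A", "C"), c("A", "T"), c("G", "C"), c("G", "T"),
                    c("C", "A"), c("T", "A"), c("C", "G"), c("T", "G"))
  alleles <- matrix("", N, 2)
  if (any(is_ti))
    alleles[is_ti, ] <- ti_pairs[sample(nrow(ti_pairs), sum(is_ti), replace = TRUE), ]
  if (any(!is_ti))
    alleles[!is_ti, ] <- tv_pairs[sample(nrow(tv_pairs), sum(!is_ti), replace = TRUE), ]

  eta <- rep(0, m)
  for (s in main_idx) eta <- eta + cfg$main_effect * (g[, s] - 2 * p[s])
  if (cfg$n_epistatic > 0) {
    for (q in seq_len(cfg$n_epistatic)) {
      a <- epi_idx[2 * q - 1]
      b <- epi_idx[2 * q]
      eta <- eta + cfg$epi_effect * ifelse((g[, a] + g[, b]) %% 2 == 1, 1, -1)
    }
  }
  case <- stats::runif(m) < stats::plogis(eta)
  if (length(unique(case)) < 2)
    stop("degenerate simulation: a single phenotype class; adjust effect sizes")

  snp_id <- sprintf("snp%04d", seq_len(N))
  snps <- data.frame(snp_id = snp_id, chrom = 1L,
                     pos = seq_len(N) * 1000L,
                     allele_ref = alleles[, 1], allele_alt = alleles[, 2],
                     stringsAsFactors = FALSE)
  G <- genotype_matrix(g, snps, ifelse(case, "case", "control"),
                       subject_ids = sprintf("subj%04d", seq_len(m)))

  truth <- data.frame(snp_id = character(0), role = character(0),
                      partner = character(0), stringsAsFactors = FALSE)
  if (cfg$n_main > 0)
    truth <- rbind(truth, data.frame(snp_id = snp_id[main_idx], role = "main",
                                     partner = NA_character_))
  if (cfg$n_epistatic > 0) {
    a <- epi_idx[seq(1, length(epi_idx), by = 2)]
    b <- epi_idx[seq(2, length(epi_idx), by = 2)]
    truth <- rbind(truth,
                   data.frame(snp_id = snp_id[c(a, b)], role = "epistatic",
                              partner = snp_id[c(b, a)]))
  }
  list(genotypes = G, truth = truth, config = cfg)
}

#' Write a simulated dataset as on-disk fixtures
#'
#' Emits every input format the pipeline consumes: the PLINK trio and
#' phenotype file, the TSV genotype dialect, a positional SNP-to-gene map
#' (consecutive runs of `snps_per_gene` SNPs share a synthetic gene symbol),
#' a GMT file with a `TARGET` pathway containing the functional SNPs' genes
#' padded with random genes plus size-matched `DECOY` pathways, and a JSON
#' manifest echoing the configuration and truth table. All gene symbols and
#' pathways are synthetic.
#'
#' @param sim result of [simulate_gwas()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; default `"sim"`.
#' @param snps_per_gene SNPs per synthetic gene; default 4.
#' @param pathway_size genes per pathway; default 50.
#' @param n_decoys number of decoy pathways; default 3.
#' @return named character vector of the paths written, invisibly.
#' @export
write_fixtures <- function(sim, dir, prefix = "sim", snps_per_gene = 4,
                           pathway_size = 50, n_decoys = 3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  G <- sim$genotypes
  base <- file.path(dir, prefix)
  save_plink(G, base)
  save_tsv_genotypes(G, paste0(base, ".geno.tsv"), paste0(base, ".snps.tsv"))
  pheno <- data.frame(fid = G$subject_ids, iid = G$subject_ids,
                      pheno = ifelse(G$phenotype == "case", 2L, 1L))
  utils::write.table(pheno, paste0(base, ".pheno"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  N <- ncol(G$genotypes)
  gene <- sprintf("GENE%04d", ceiling(seq_len(N) / snps_per_gene))
  gene_map <- data.frame(snp_id = G$snps$snp_id, gene_symbol = gene,
                         stringsAsFactors = FALSE)
  utils::write.table(gene_map, paste0(base, ".genemap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  universe <- unique(gene)
  truth_genes <- unique(gene_map$gene_symbol[match(sim$truth$snp_id,
                                                   gene_map$snp_id)])
  target_size <- min(pathway_size, length(universe))
  pad <- setdiff(universe, truth_genes)
  target <- c(truth_genes, sample(pad, max(0, target_size - length(truth_genes))))
  sets <- list(TARGET = target)
  for (d in seq_len(n_decoys))
    sets[[paste0("DECOY", d)]] <- sample(universe, target_size)
  gmt_path <- paste0(base, ".gmt")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, gmt_path)

  manifest_path <- paste0(base, ".manifest.json")
  jsonlite::write_json(
    list(config = unclass(sim$config), truth = sim$truth,
         n_subjects = nrow(G$genotypes), n_snps = N,
         files = basename(c(paste0(base, c(".bed", ".bim", ".fam", ".pheno",
                                           ".geno.tsv", ".snps.tsv",
                                           ".genemap.tsv", ".gmt"))))),
    manifest_path, auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(c(bed = paste0(base, ".bed"), bim = paste0(base, ".bim"),
              fam = paste0(base, ".fam"), pheno = paste0(base, ".pheno"),
              geno_tsv = paste0(base, ".geno.tsv"),
              snps_tsv = paste0(base, ".snps.tsv"),
              genemap = paste0(base, ".genemap.tsv"), gmt = gmt_path,
              manifest = manifest_path))
}
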