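Package: reliefsnp
Title: ReliefF Feature Selection for SNP Data with Genotype-Aware Diff Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Nearest-neighbor (ReliefF) feature selection for case/control
    genotype data. Implements three single-locus dissimilarity ("diff")
    functions -- binary genotype mismatch (GM), allele mismatch (AM), and a
    transition/transversion (Ti/Tv) diff built on a two-dimensional unit-circle
    genotype encoding -- together with two families of subject-subject
    nearest-neighbor metrics: Manhattan (or Euclidean) sums of per-locus diffs
    and a distance derived from the genetic relationship matrix (GRM).
    Includes PLINK bed/bim/fam and plain-TSV genotype input/output,
    minor-allele-frequency and linkage-disequilibrium filtering, SNP-to-gene
    mapping of top-ranked variants, pathway-overlap counting against GMT gene
    sets with a random-gene null, and a seeded synthetic GWAS generator with
    main-effect and purely epistatic functional SNPs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
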