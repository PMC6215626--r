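---
title: "Genotype-aware diff metrics for ReliefF feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-aware diff metrics for ReliefF feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reliefsnp)
```

## The model

ReliefF weights an attribute by contrasting how much it differs between a
subject and its nearest neighbors of the opposite phenotype class (misses)
versus the same class (hits). With `m` subjects, `k` neighbors per class and
a per-locus dissimilarity `diff`, the weight of SNP $g_\nu$ is

$$W[g_\nu] = \bar M_{g_\nu} - \bar H_{g_\nu},\qquad
\bar M_{g_\nu} = \frac{1}{mk}\sum_{i=1}^m\sum_{j=1}^k
  \mathrm{diff}(g_\nu, R_i, M_j(R_i)),$$

and analogously for $\bar H$. Every diff lies in $[0,1]$ and the double sum
has exactly $mk$ terms, so $\bar M,\bar H\in[0,1]$ and $W\in[-1,1]$ by
construction. A positive weight means the SNP's genotypes separate the
classes more than they separate subjects within a class — which is how the
algorithm picks up loci that act only through interactions: a SNP whose
effect depends on the genotype at another locus still shifts the local
hit/miss geometry even when its marginal association is nil.

### Per-locus diffs

Genotypes are minor-allele counts $g \in \{0,1,2\}$. Three diffs are
implemented (`diff_gm`, `diff_am`, `diff_titv`):

* **GM** (genotype mismatch): 0 if identical, 1 otherwise — the categorical
  ReliefF standard, blind to the *degree* of difference.
* **AM** (allele mismatch): $|g_1-g_2|/2$, i.e. 0, 1/2, 1 for 2, 1, 0 shared
  alleles.
* **Ti/Tv**: allele sharing refined by the physicochemical class of the
  substitution.

The Ti/Tv diff is defined through a two-dimensional encoding
(`encode_titv`): each genotype is a unit vector in the plane, similarity is
the squared dot product $\cos^2\theta$ of the angular separation, and the
diff is $1-\cos^2\theta$. For a transversion SNP the homozygotes are
orthogonal with the heterozygote midway (angles $0, \pi/4, \pi/2$), which
reproduces AM exactly. For a transition SNP the fan is contracted (angles
$0, \pi/6, \pi/3$), giving diffs 1/4 (het vs hom) and 3/4 (opposite
homozygotes): transitions stay within a nucleotide family, so their genotype
differences are treated as milder than transversions.

Two remarks on this encoding, both asserted in the test suite:

* Descriptions of the transition fan are sometimes given as a single
  "separation angle"; the only reading consistent with the published diff
  values 1/4 and 3/4 is adjacent separation $\pi/6$ with the homozygotes
  $\pi/3$ apart, symmetric in $aa \leftrightarrow AA$. That symmetric
  geometry is what this package implements, and `diff_titv` uses the exact
  closed-form table (with the trigonometric path retained in
  `titv_similarity` for verification) so hot loops carry no rounding.
  The heterozygote's absolute position (conventionally "centered at
  $\pi/4$") is immaterial: only angle differences enter the similarity, so
  the implementation fixes $aa$ at angle 0.
* The transition diff violates the per-locus triangle inequality
  ($3/4 > 1/4 + 1/4$), so Manhattan accumulations of it form a symmetric
  dissimilarity rather than a true metric. Neighbor search only needs
  ordering, so nothing downstream depends on metric axioms.

### Neighbor metrics

Neighbors are found in the space of **all** SNPs, either by accumulating a
diff with a Manhattan (optionally Euclidean) sum, or from the genetic
relationship matrix:

$$D^{GRM}_{ij} = \sqrt{2N(1-A_{ij})},\qquad
A_{ij} = \frac1N\sum_\nu
  \frac{(g_{i\nu}-2p_\nu)(g_{j\nu}-2p_\nu)}{2p_\nu(1-p_\nu)},$$

which standardizes each locus by its allele frequency and thereby keeps
common SNPs from dominating the neighborhood structure. $p_\nu$ is estimated
from the pooled analyzed sample (cases plus controls), matching common GRM
practice; no external reference panel is used. The six headline
combinations are the three diffs used for both neighbors and scoring
(GM-GM, AM-AM, TiTv-TiTv) and the three diffs scored in GRM neighborhoods
(GRM-GM, GRM-AM, GRM-TiTv); `relieff()` accepts any combination.

## Parameters that matter

* `k` — neighbors per class, default $\lfloor m/6\rfloor$ (`default_k`).
  This constant-$k$ choice approximates the adaptive-radius MultiSURF
  neighborhood and balances power for main effects against interactions.
  It requires both classes to exceed `k` subjects.
* `maf_min` — minor-allele-frequency floor, default 0.01, **inclusive**
  (a SNP at exactly the threshold is retained; the boundary is asserted in
  tests and configurable).
* `r2_max`, `window_snps`, `step_snps` — LD pruning, defaults 0.5 / 50 / 5.
  Only the correlation threshold is a scientific choice; the window and step
  follow the conventional PLINK indep-pairwise defaults and are exposed as
  arguments.
* `n_genes` — unique genes taken from the top of a ranking, default 500.
  Because adjacent top SNPs frequently map to the same gene, rankings should
  be much longer than `n_genes`; deduplication keeps the first (best-ranked)
  occurrence, which for a descending ranking is equivalent to keeping the
  best-scoring SNP per gene.

## Numerical and design choices

* **Fixed neighborhoods.** Neighbor sets are computed once, in the full SNP
  space, and reused for every attribute. A stricter leave-one-attribute-out
  reading (neighbors recomputed in the space of "all other" SNPs for each
  scored SNP) is quadratically more expensive and is not what
  constant-neighborhood ReliefF implementations do; the fixed-neighborhood
  reading is adopted deliberately and the brute-force oracle
  (`relieff_oracle`) implements the same convention, so the equivalence
  tests pin the semantics down.
* **Determinism.** Distance ties in neighbor search break by ascending
  subject index; ranking ties break by ascending SNP index. Reruns on
  identical inputs are byte-identical.
* **GRM diagonal.** The self-relatedness entries use the same formula as the
  off-diagonal ones (no specialized diagonal estimator); they are computed
  but never consulted, since self is excluded from neighbor search.
* **Clamping.** $A_{ij}>1$ can occur for near-duplicate subjects and would
  make the radicand of $D^{GRM}$ negative; it is clamped to zero and the
  event counted (`clamped` attribute, surfaced in the run log).
* **Missing calls.** The pipeline imputes a missing call to the SNP's modal
  genotype by default (`clean_missing`), keeping `m` — and hence `k` —
  fixed; dropping affected SNPs is available as a policy.
* **LD pruning detail.** Within each window the first offending pair in
  index order is resolved by removing the lower-MAF member (ties: the
  higher column index), then correlations are re-examined; the operation is
  idempotent. Pairs involving a monomorphic column are skipped (their
  correlation is undefined; such SNPs belong to the MAF filter anyway).

## The synthetic-data generator

`simulate_gwas()` emulates the features of a case/control GWAS that the
pipeline actually exercises: binomial Hardy-Weinberg genotypes with a
uniform allele-frequency spectrum on (0.05, 0.5); an exact 2/3 transition
fraction (the genome-wide Ti:Tv ratio of roughly 2:1); optional LD blocks
made by copy-with-noise (enough to exercise pruning, without a coalescent
simulator); and a logistic phenotype model. Main-effect SNPs contribute
`main_effect` (default 1.0, a strong GWAS effect of odds ratio ≈ 2.7) per
minor allele, centered so prevalence stays near 50%. Epistatic pairs
contribute a pure XOR-style interaction: $\pm$`epi_effect` (default 3.0,
a near-deterministic interaction penetrance) on the log-odds according to
the parity of the two minor-allele counts, with both loci forced to allele
frequency 1/2 so each member has *exactly* zero marginal effect — the
cleanest desk-scale surrogate for interaction-driven architecture, and one
a univariate test provably cannot see.

What the generator does **not** emulate: population structure and
relatedness, genotyping error and missingness patterns, realistic LD decay,
allele-frequency spectra skewed toward rare variants, and
transition/transversion differences that *affect the phenotype*. Passing
tests therefore demonstrate correctness of the algorithms and qualitative
power properties, not performance on real GWAS data.

Problem sizes used in the checked claims are chosen to keep every property
measurable at a desk scale: oracle-equivalence datasets up to 60×500;
null-calibration and main-effect recovery at 200×1000 over 20 replicates;
epistatic recovery at 600×1000 (interaction detection by nearest-neighbor
methods needs more subjects per attribute than main-effect detection — at
200 subjects even a near-deterministic XOR pair is invisible, which is
itself a documented property of the method, not a defect of the
implementation).

## Known limitations

* Biallelic autosomal SNPs only: no multi-allelic sites, CNVs, sex
  chromosomes, or dosage formats.
* No population-structure correction (principal components) and no
  significance machinery for either the weights or the pathway overlaps —
  overlap counts are compared against the random-gene null, not tested.
* The whole `m × m` distance matrix is held in memory; the intended scale is
  thousands of subjects, not biobanks.
* SNP-to-gene mapping is file-based by design; no annotation service is
  queried.
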