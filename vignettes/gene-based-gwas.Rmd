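---
title: "Two-stage gene-based association testing with genegwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage gene-based association testing with genegwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genegwas)
```

## The problem

Single-marker GWAS tests each SNP against a quantitative trait one at a
time. When a trait is influenced by several variants of small effect inside
one gene, no individual SNP may clear a genome-wide threshold even though
the gene as a unit carries clear signal. Gene-based association testing
aggregates the evidence across all SNPs assigned to a gene into one test
per gene, shrinking the multiple-testing burden from hundreds of thousands
of markers to tens of thousands of genes and borrowing strength across
correlated markers.

`genegwas` implements a two-stage gene test for dense SNP panels in
livestock-scale populations (the motivating application is carcass and
meat-quality traits in beef cattle), together with the supporting pipeline:
genotype quality control, population-structure correction, fixed-effect
phenotype adjustment, SNP-to-gene assignment, a single-marker mixed-model
scan for comparison, and a synthetic-population generator used throughout
the test suite.

## The two-stage gene statistic

**Stage 1 — orthogonalization.** Within a gene, SNP genotype codes (0/1/2
copies of the minor allele) are strongly correlated through linkage
disequilibrium, so their per-SNP tests are redundant. `gene_pca()`
computes the variance-covariance matrix of the gene's SNP codes
(mean-imputed, centered, *not* standardized), eigendecomposes it, and keeps
the smallest number `K` of leading principal components whose cumulative
eigenvalue fraction reaches 85% of the total SNP variance. The component
scores are exactly uncorrelated by construction.

**Stage 2 — combination.** Each retained component is tested against the
adjusted trait through its Pearson correlation `r`, converted to a
two-sided p-value via `t = r sqrt(n-2) / sqrt(1-r^2)` on `n-2` degrees of
freedom (`pc_pvalues()`). Because the components are orthogonal, the `K`
p-values are treated as independent and combined with Fisher's method
(`fisher_combination()`):

    chi^2 = -2 * sum_k log(p_k)  ~  chi^2 with 2K df under the null.

The gene's p-value is the upper-tail probability of that chi-square.
Significance is declared by Bonferroni correction over the `N` genes
actually tested: `p < alpha / N` (`genome_scan()`). With 21836 genes and
`alpha = 0.05` that threshold is 2.29e-6.

Why the orthogonality audit matters: the 2K-df reference distribution is
only valid if the per-component p-values are independent. The test suite
checks that the correlation matrix of retained scores is the identity to
1e-8, and that gene p-values are uniform under permutation of the
phenotype.

### Parameter choices

* `variance_target = 0.85` — the retained-variance rule. `K` is the
  smallest count whose cumulative eigenvalue fraction is >= 0.85; at an
  exact tie the deterministic eigensolver's index order breaks it.
* Two-sided per-component tests: component signs are arbitrary under any
  PCA sign convention, so a one-sided test would be meaningless.
* Covariance (not correlation) PCA: the statistic weights SNPs by their
  genotypic variance, which is how the decomposition of the raw
  variance-covariance matrix behaves. Standardizing first would change
  `K` and the scores.
* p-values underflowing to 0 are clamped at 1e-300 before logging; this
  keeps the chi-square statistic finite and has no effect on ranking.
* Genes sharing SNPs (overlapping 20 kb windows) are tested independently
  and no multiplicity adjustment beyond the Bonferroni over genes is
  applied; multi-assigned SNPs therefore contribute to several tests.

## The supporting pipeline

**Quality control** (`apply_qc()`): individuals with > 10% missing
genotypes are removed first; SNP filters are then computed on the retained
individuals in the order unmapped position, call rate < 90%, MAF < 5%,
observed genotype class carried by fewer than 5 individuals, exact
Hardy-Weinberg p < 1e-6, each removal attributed to the first failing
filter. The order is a convention (common chip-QC practice); it makes the
removal report deterministic. The HWE test is the exact conditional test
computed by a stable recurrence — the chi-square approximation misbehaves
exactly where the filter operates, at rare genotype classes. The
"genotype in < 5 individuals" rule is ambiguous in the field's usage; the
package counts only classes observed at least once and flags the
convention in the QC report.

**Structure correction** (`structure_pcs()`): principal components of a
random 10% SNP subsample (mean-imputed, centered at observed means),
first five components by default. Subsampling is seeded and recorded.
The genomic relationship matrix (`vanraden_grm()`) is
`G = ZZ' / (2 sum p(1-p))` with `Z` centered at twice the allele
frequency.

**Phenotype adjustment** (`adjust_phenotype()`): ordinary least squares of
the trait on year, farm, gender, fattening days, entering weight and the
structure PCs; the residuals are the corrected phenotype for the gene
scan. Incomplete rows are dropped listwise with a logged count. Both
traits are adjusted with the same covariate set.

**SNP-to-gene assignment** (`assign_snps_to_genes()`): a SNP maps to every
gene whose span extended by a closed +/-20 kb window contains it, and only
genes with at least five mapped SNPs are tested. The window boundaries are
inclusive (a SNP at exactly `start - 20000` is in); gene coordinates are
normalized to 1-based inclusive internally, with BED input shifted on
read. The full annotated gene span is used (not CDS features), consistent
with testing non-coding genes and pseudogenes.

**Single-marker mixed model** (`fit_variance_components()`,
`snp_scan()`): the comparison arm fits `y = Xb + Wv + u + e` with
`u ~ N(0, sigma2_g K)`. Variance components are estimated once by REML on
the null model through the eigendecomposition of `K` (a one-dimensional
optimization over the variance ratio) and reused for every SNP — the
"population parameters previously determined" shortcut. Each SNP is then
a generalized-least-squares test with a closed-form t-statistic on
`n - rank(X) - 1` degrees of freedom. Group compression of the random
effect (clustering individuals before fitting) is deliberately not
implemented: the uncompressed individual-level model preserves the
statistical contract (mixed model + per-SNP t-test + the 1/M suggestive
and 0.05/M Bonferroni thresholds) without the extra clustering machinery,
and the simplification is recorded in the output metadata. When the REML
estimate of `sigma2_g` hits the zero boundary the scan degrades to OLS
with a warning.

## The synthetic population generator

`simulate_population()` emulates the data regime the pipeline targets —
roughly a thousand genotyped animals, dense biallelic SNPs, two
quantitative traits — without any external download.

* **LD structure.** Haplotypes are generated block-wise: all SNPs in a
  block share one allele frequency drawn from `maf_range`, and each allele
  is copied from its left neighbour with probability `ld_decay`, otherwise
  redrawn. This first-order allele-copy process gives an adjacent-SNP
  genotype correlation of exactly `ld_decay` in expectation — the simplest
  structure that makes within-gene PCA genuinely non-trivial. Blocks are
  independent and never span chromosomes.
* **Traits.** `y = fixed effects + g + c + e` with
  `g ~ N(0, h2_polygenic * K)` for the VanRaden `K` of the simulated
  genotypes themselves (so REML recovery is well-posed), `c` the summed
  effects of causal SNPs inside randomly chosen causal genes — each causal
  gene scaled to an equal slice of `h2_causal` — and the non-fixed part
  normalized to unit variance before mapping onto the trait's output
  scale. Defaults put total genetic variance at 0.41 of the non-fixed
  variance (0.37 polygenic + 0.04 causal), a body-weight-like heritability
  for a beef-cattle trait, with the BW-like trait on a mean 40 / SD 6.58
  scale and the pH-like trait on mean 5.63 / SD 0.38.
* **Covariates.** Year, farm and gender are categorical with configurable
  level counts; fattening days and entering weight are Gaussian
  (mean 300/SD 30 days, mean 250/SD 25 kg). Each covariate contributes
  `effect_sd` (default 0.5) phenotypic SDs of variation — large enough
  that skipping adjustment visibly hurts, small enough to stay realistic.
* **Seeds.** One master seed; each stage (haplotypes, missingness, gene
  map, phenotypes) derives its own child seed deterministically, so a
  stage can be regenerated independently and replicate phenotype draws can
  reuse one genotype panel.

What the generator does *not* emulate: realistic recombination maps,
selection, pedigree structure, admixed subpopulations, genotyping-error
modes, or the joint covariate distribution of any real herd. Passing tests
demonstrate that the statistics behave as designed under their own model
assumptions — calibrated nulls, recoverable signals — not that any
particular biological result in real cattle would reproduce.

## Verification strategy and problem sizes

The test suite pins every numerical core to an independent oracle: the
GRM to a brute-force pairwise loop, the within-gene PCA to a separate SVD
route, the exact HWE test to direct log-factorial enumeration, interval
assignment to a double loop over all (gene, SNP) pairs, the
eigen-rotation GLS to an explicit covariance-inverse GLS, REML to a grid
search of the restricted likelihood, and Fisher's df = 4 tail to the
closed form `exp(-x/2)(1 + x/2)`.

The statistical properties are checked by simulation at sizes chosen to
keep the full suite fast while leaving Monte Carlo error well inside the
asserted margins: null calibration of the gene scan with 500 individuals,
1000 genes and 200 replicate phenotype draws over one panel (family-wise
error at the Bonferroni threshold <= 0.05; uniformity checked on one gene
p-value per replicate, since overlapping windows make p-values within one
scan dependent);
power with three causal genes each explaining 2% of phenotypic variance at
n = 1000 over 50 replicates; and
REML recovery of a true h2 of 0.40 within +/-0.05 on average over 200
replicates at n = 1000. Replicate draws share one genotype panel and its
precomputed stage-1 decompositions — stage 1 depends only on genotypes, so
this is the identical statistic computed faster.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 600, n_chromosomes = 5,
                  snps_per_chromosome = 400, n_genes = 120,
                  h2_polygenic = 0.3, h2_causal = 0.1, seed = 42)
sim <- simulate_population(cfg)

qc   <- apply_qc(sim$genotypes)
pcs  <- structure_pcs(qc$genotypes, snp_fraction = 0.10, k = 5, seed = 42)
ph   <- merge(sim$phenotypes, sim$covariates, by = "id", sort = FALSE)
adj  <- adjust_phenotype(ph, "BW", pcs)

asg  <- assign_snps_to_genes(qc$genotypes, sim$genes)
scan <- genome_scan(qc$genotypes, asg, adj)
head(scan[order(scan$p_value), ])

K    <- vanraden_grm(qc$genotypes)
X    <- mlm_design(sim$covariates, pcs)
fit  <- fit_variance_components(ph$BW, X, K)
snps <- snp_scan(fit, qc$genotypes)

th   <- suggestive_threshold(nrow(snps))
hits <- make_hit_tables(snps, scan, snp_threshold = th$suggestive,
                        genes = sim$genes)
plot_qq(make_qq(snps$p_value[!is.na(snps$p_value)]))
plot_manhattan(make_manhattan(scan, thresholds = attr(scan, "threshold")))
```

## Known limitations

* **Fisher dilution bounds the power of the gene statistic for localized
  signals.** At the SNP densities the pipeline targets (one SNP per ~3.4 kb,
  +/-20 kb windows), a gene window holds roughly 13-26 SNPs and the 85%
  rule retains K around 9 components. A causal signal confined to one
  direction then contributes one small per-component p-value while the
  remaining K-1 components add pure noise to the chi-square: even a
  perfectly component-aligned signal explaining 2% of phenotypic variance
  at n = 1000 yields a combined gene p-value around a few times 1e-3, not
  1e-5. Consistently ranking several such genes above hundreds of nulls
  therefore requires larger effects, larger samples, or smaller K. Worse,
  when causal effects on LD-correlated SNPs carry opposing signs, their
  combination is a low-variance direction that the 85% truncation may
  discard entirely. The power simulation in the acceptance suite measures
  exactly this behaviour, and its recovery rate should be read as a
  property of the statistic, not a bug in the implementation (each
  numerical step is independently oracle-verified).
* The gene test conditions on the adjusted phenotype; residual relatedness
  not captured by the structure PCs can inflate gene-level statistics.
  The mixed-model arm handles relatedness through `K`, the gene arm only
  through the PC adjustment — as designed.
* Degrees of freedom in stage 2 use `n - 2` per component, ignoring the
  covariate degrees of freedom spent by the adjustment; at the intended
  sample sizes (hundreds to thousands) the effect is negligible.
* Mendelian-error filtering is a no-op hook (`qc_mendel_hook()`); it needs
  pedigree records the package does not model.
* Multi-assigned SNPs make neighbouring gene tests positively dependent;
  the Bonferroni correction remains valid (conservative) under that
  dependence.
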