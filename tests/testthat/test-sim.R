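test_that("simulated genotype codes lie in {0,1,2} with requested missingness", {
  cfg <- small_config(n_individuals = 4, n_chromosomes = 1,
                      snps_per_chromosome = 3, missing_rate = 0)
  g <- simulate_genotypes(cfg)
  expect_equal(dim(g$codes), c(4L, 3L))
  expect_true(all(g$codes %in% 0:2))

  cfg2 <- small_config(n_individuals = 500, snps_per_chromosome = 200,
                       missing_rate = 0.05, seed = 3)
  g2 <- simulate_genotypes(cfg2)
  expect_true(all(g2$codes %in% 0:2 | is.na(g2$codes)))
  expect_lt(abs(mean(is.na(g2$codes)) - 0.05), 0.01)
})

test_that("same seed gives bitwise-identical simulation output", {
  cfg <- small_config(missing_rate = 0.02, seed = 11)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$genotypes$codes, b$genotypes$codes)
  expect_identical(a$genes, b$genes)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$covariates, b$covariates)
})

test_that("invalid config fields raise errors naming the field", {
  expect_error(small_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(small_config(ld_decay = 1), "ld_decay")
  expect_error(small_config(h2_polygenic = 0.6, h2_causal = 0.5), "h2_")
  expect_error(small_config(missing_rate = 1), "missing_rate")
  expect_error(small_config(n_individuals = 0), "n_individuals")
})

test_that("ld_decay = 0 gives uncorrelated SNPs within blocks", {
  cfg <- sim_config(n_individuals = 2000, n_chromosomes = 1,
                    snps_per_chromosome = 100, ld_block_size = 10,
                    ld_decay = 0, n_genes = 1, n_causal_genes = 0,
                    h2_causal = 0, seed = 5)
  g <- simulate_genotypes(cfg)
  rs <- unlist(lapply(split(seq_len(100), g$map$block), function(idx) {
    cc <- cor(g$codes[, idx])
    cc[upper.tri(cc)]
  }))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("adjacent within-block genotype correlation matches the ld_decay target", {
  cfg <- sim_config(n_individuals = 2000, n_chromosomes = 1,
                    snps_per_chromosome = 100, ld_block_size = 10,
                    ld_decay = 0.9, n_genes = 1, n_causal_genes = 0,
                    h2_causal = 0, seed = 5)
  hp <- simulate_haplotypes(cfg)
  g <- simulate_genotypes(cfg)
  adj_r <- function(mat, map) {
    unlist(lapply(split(seq_len(ncol(mat)), map$block), function(idx) {
      if (length(idx) < 2) return(NULL)
      vapply(seq_len(length(idx) - 1),
             function(k) cor(mat[, idx[k]], mat[, idx[k + 1]]), numeric(1))
    }))
  }
  # oracle: correlation recomputed from the raw haplotypes
  r_hap <- mean(adj_r(hp$haplotypes, hp$map))
  r_geno <- mean(adj_r(g$codes, g$map))
  expect_lt(abs(r_hap - 0.9), 0.05)
  expect_lt(abs(r_geno - 0.9), 0.05)
})

test_that("gene map geometry: empty, valid intervals, causal genes have SNP support", {
  cfg <- small_config()
  g <- simulate_genotypes(cfg)
  empty <- simulate_gene_map(small_config(n_genes = 0, n_causal_genes = 0,
                                          h2_causal = 0), g)
  expect_equal(nrow(empty), 0L)

  cfg2 <- sim_config(n_individuals = 100, n_chromosomes = 5,
                     snps_per_chromosome = 1000, n_genes = 50,
                     n_causal_genes = 5, seed = 2)
  g2 <- simulate_genotypes(cfg2)
  genes <- simulate_gene_map(cfg2, g2)
  expect_true(all(genes$start_bp < genes$end_bp))
  expect_true(all(genes$chrom %in% g2$map$chrom))
  # brute-force interval scan: enough genes carry >= 5 SNPs in the 20 kb window
  counts <- vapply(seq_len(nrow(genes)), function(i) {
    sum(g2$map$chrom == genes$chrom[i] &
          g2$map$pos_bp >= genes$start_bp[i] - 20000 &
          g2$map$pos_bp <= genes$end_bp[i] + 20000)
  }, numeric(1))
  expect_gte(sum(counts >= 5), cfg2$n_causal_genes)
  # impossible geometry errors out
  expect_error(
    simulate_gene_map(small_config(gene_length_range = c(1e9, 2e9)), g),
    "configuration error")
})

test_that("null phenotype model is pure noise at the configured variance", {
  cfg <- sim_config(n_individuals = 2000, n_chromosomes = 1,
                    snps_per_chromosome = 100, n_genes = 10,
                    h2_polygenic = 0, h2_causal = 0, n_causal_genes = 0,
                    fixed_effects = list(year_levels = 2, farm_levels = 2,
                                         gender_levels = 2, effect_sd = 0),
                    traits = list(T1 = c(mean = 0, sd = 1)), seed = 8)
  sim <- simulate_population(cfg)
  expect_lt(abs(var(sim$phenotypes$T1) - 1), 0.1)      # sigma2_e = 1 here
  expect_lt(abs(mean(sim$phenotypes$T1)), 0.1)
})

test_that("OLS on the true causal design recovers effect signs", {
  cfg <- sim_config(n_individuals = 1000, n_chromosomes = 2,
                    snps_per_chromosome = 500, n_genes = 40,
                    n_causal_genes = 3, causal_snps_per_gene = 2,
                    h2_polygenic = 0, h2_causal = 0.2,
                    fixed_effects = list(year_levels = 2, farm_levels = 2,
                                         gender_levels = 2, effect_sd = 0),
                    traits = list(T1 = c(mean = 0, sd = 1)), seed = 4)
  sim <- simulate_population(cfg)
  tr <- sim$truth$T1
  X <- impute_genotypes(sim$genotypes)[, tr$causal_snp_idx, drop = FALSE]
  fit <- lm(sim$phenotypes$T1 ~ X)
  est <- coef(fit)[-1]
  big <- abs(tr$causal_effects) >= 0.5 * sd(sim$phenotypes$T1)
  if (any(big))
    expect_true(all(sign(est[big]) == sign(tr$causal_effects[big])))
  # and all estimated effects correlate with the truth
  expect_gt(cor(est, tr$causal_effects), 0.9)
})

test_that("realized variance fractions track the configured h2 at n = 2000", {
  cfg <- sim_config(n_individuals = 2000, n_chromosomes = 2,
                    snps_per_chromosome = 300, n_genes = 40,
                    n_causal_genes = 3, h2_polygenic = 0.37, h2_causal = 0.04,
                    traits = list(T1 = c(mean = 0, sd = 1)), seed = 9)
  sim <- simulate_population(cfg)
  tr <- sim$truth$T1
  expect_lt(abs(tr$realized_h2_polygenic - 0.37), 0.05)
  expect_lt(abs(tr$realized_h2_causal - 0.04), 0.05)
  expect_equal(length(tr$causal_genes), 3L)
  expect_true(all(tr$causal_genes %in% sim$genes$gene_id))
  expect_equal(nrow(sim$phenotypes), 2000L)
})
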