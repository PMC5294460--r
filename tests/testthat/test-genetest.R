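test_that("a rank-1 gene yields K = 1 capturing all variance", {
  set.seed(31)
  col <- rbinom(60, 2, 0.4)
  g <- toy_genotypes(matrix(rep(col, 5), 60, 5))
  dec <- gene_pca(g, 1:5)
  expect_equal(dec$K, 1L)
  expect_equal(dec$variance_fraction_captured, 1, tolerance = 1e-12)
})

test_that("independent equal-variance SNPs give a flat spectrum with K near 0.85 * n_snps", {
  set.seed(32)
  n <- 4000; m <- 20
  g <- toy_genotypes(sapply(rep(0.5, m), function(p) rbinom(n, 2, p)))
  dec <- gene_pca(g, 1:m)
  expect_lte(abs(dec$K - ceiling(0.85 * m)), 1)
})

test_that("scores and K match an independent decomposition of a 6-SNP toy gene", {
  set.seed(33)
  n <- 40
  base <- rbinom(n, 2, 0.5)
  codes <- cbind(base,
                 ifelse(runif(n) < 0.8, base, rbinom(n, 2, 0.5)),
                 rbinom(n, 2, 0.3), rbinom(n, 2, 0.4),
                 rbinom(n, 2, 0.2), rbinom(n, 2, 0.5))
  g <- toy_genotypes(codes)
  dec <- gene_pca(g, 1:6)
  # independent route: SVD of the centered data, never eigen() of cov()
  Xc <- scale(matrix(as.numeric(codes), n, 6), center = TRUE, scale = FALSE)
  sv <- svd(Xc)
  ev_ind <- sv$d^2 / (n - 1)
  expect_equal(dec$eigenvalues, ev_ind, tolerance = 1e-10)
  K_ind <- which(cumsum(ev_ind) / sum(ev_ind) >= 0.85)[1]
  expect_equal(dec$K, K_ind)
  scores_ind <- sv$u[, 1:K_ind, drop = FALSE] %*% diag(sv$d[1:K_ind], K_ind)
  for (j in seq_len(K_ind))
    expect_lt(min(max(abs(dec$scores[, j] - scores_ind[, j])),
                  max(abs(dec$scores[, j] + scores_ind[, j]))), 1e-8)
  # variance bookkeeping: eigenvalue sum = trace of covariance
  expect_equal(sum(dec$eigenvalues), sum(diag(cov(Xc))), tolerance = 1e-8)
  # retained score columns are uncorrelated (identity correlation matrix)
  cm <- cor(dec$scores)
  expect_lt(max(abs(cm - diag(K_ind))), 1e-8)
})

test_that("zero-variance SNPs are dropped; fully degenerate genes error", {
  set.seed(34)
  codes <- cbind(rbinom(30, 2, 0.4), rep(1, 30), rbinom(30, 2, 0.3))
  dec <- gene_pca(toy_genotypes(codes), 1:3)
  expect_equal(dec$n_snps_dropped, 1L)
  expect_equal(dec$n_snps_used, 2L)
  expect_error(gene_pca(toy_genotypes(matrix(1, 10, 4)), 1:4), "degenerate")
})

test_that("per-PC p-values follow the correlation t-test exactly", {
  # r = 0 exactly -> p = 1
  s <- matrix(c(1, -1, 1, -1, 1, -1), 6, 1)
  y <- c(2, 2, 5, 5, -1, -1)
  expect_equal(unname(pc_pvalues(s, y)), 1)

  # n = 20, r = 0.5: oracle = numerical integration of the t density, 18 df
  set.seed(35)
  x <- rnorm(20)
  x <- (x - mean(x)) / sd(x)
  z <- rnorm(20); z <- residuals(lm(z ~ x)); z <- z / sd(z)
  r <- 0.5
  y2 <- r * x + sqrt(1 - r^2) * z          # sample correlation exactly 0.5
  expect_equal(cor(x, y2), 0.5, tolerance = 1e-12)
  p_impl <- pc_pvalues(matrix(x, 20, 1), y2)
  tstat <- r * sqrt(18) / sqrt(1 - r^2)
  dens <- function(u) (1 + u^2 / 18)^(-19 / 2)
  norm_c <- integrate(dens, -Inf, Inf)$value
  p_oracle <- 2 * integrate(dens, tstat, Inf)$value / norm_c
  expect_equal(unname(p_impl), p_oracle, tolerance = 1e-8)
})

test_that("per-PC p-values are uniform under the null", {
  set.seed(36)
  n <- 50
  s <- matrix(rnorm(n), n, 1)
  p <- replicate(10000, pc_pvalues(s, rnorm(n)))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("Fisher combination: identity at K = 1, closed-form df = 4 survival, boundaries", {
  for (p1 in c(1, 0.5, 0.05, 1e-12)) {
    fc <- fisher_combination(p1)
    expect_equal(fc$gene_p, p1, tolerance = 1e-12)
    expect_equal(fc$df, 2L)
  }
  fc1 <- fisher_combination(1)
  expect_equal(fc1$chi2_stat, 0)
  expect_equal(fc1$gene_p, 1)

  # K = 2: chi2 = -2 * sum(log p); survival of chi2_4 is exp(-x/2) (1 + x/2)
  for (pp in list(c(0.05, 0.05), c(0.3, 0.8), c(1e-4, 0.02), c(1, 1))) {
    fc <- fisher_combination(pp)
    x <- -2 * sum(log(pp))
    expect_equal(fc$chi2_stat, x, tolerance = 1e-12)
    expect_equal(fc$df, 4L)
    expect_equal(fc$gene_p, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  }

  expect_error(fisher_combination(c(0.5, 1.2)), "p-values")
  expect_error(fisher_combination(numeric(0)), "at least one")
  expect_warning(fc0 <- fisher_combination(c(0, 0.5)), "clamped")
  expect_true(is.finite(fc0$chi2_stat))
  # extreme p-values stay finite and positive
  fc_tiny <- fisher_combination(rep(1e-300, 3))
  expect_gt(fc_tiny$gene_p, 0)
})

test_that("Fisher combination is monotone in every component", {
  set.seed(37)
  for (i in 1:1000) {
    K <- sample(1:6, 1)
    p <- runif(K)
    j <- sample(K, 1)
    p2 <- p; p2[j] <- p[j] * runif(1)
    expect_lte(fisher_combination(p2)$gene_p, fisher_combination(p)$gene_p)
  }
})

test_that("genome scan applies the Bonferroni threshold over tested genes", {
  cfg <- small_config(n_individuals = 120, seed = 41)
  sim <- simulate_population(cfg)
  asg <- assign_snps_to_genes(sim$genotypes, sim$genes)
  ph <- merge(sim$phenotypes, sim$covariates, by = "id", sort = FALSE)
  adj <- adjust_phenotype(ph, "BW")
  res <- genome_scan(sim$genotypes, asg, adj)
  expect_equal(attr(res, "threshold"), 0.05 / attr(res, "n_genes_tested"))
  expect_true(all(res$df == 2L * res$K))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$chi2 >= 0))
  expect_identical(res$significant, res$p_value < attr(res, "threshold"))
  # rows ordered by chromosome then start
  expect_false(is.unsorted(order(as.numeric(res$chrom), res$start_bp)))
  empty <- asg; empty$snp_indices <- list()
  expect_error(genome_scan(sim$genotypes, empty, adj), "empty")
})

test_that("gene p-values are uniform under phenotype permutation", {
  cfg <- small_config(n_individuals = 150, seed = 42)
  sim <- simulate_population(cfg)
  asg <- assign_snps_to_genes(sim$genotypes, sim$genes)
  dec <- gene_pca(sim$genotypes, asg$snp_indices[[1]])
  ph <- merge(sim$phenotypes, sim$covariates, by = "id", sort = FALSE)
  adj <- adjust_phenotype(ph, "BW")
  y <- unname(adj$residuals)
  set.seed(43)
  gene_p <- replicate(2000, {
    fisher_combination(pc_pvalues(dec, sample(y)))$gene_p
  })
  # empirical CDF within the Kolmogorov band of the uniform at level 0.01
  expect_gt(ks.test(gene_p, "punif")$p.value, 0.01)
})
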