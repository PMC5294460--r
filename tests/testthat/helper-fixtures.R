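# small configs and hand-built fixtures shared across test files

small_config <- function(...) {
  args <- list(n_individuals = 200, n_chromosomes = 2,
               snps_per_chromosome = 100, n_genes = 30,
               gene_length_range = c(5000, 30000), seed = 1L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# deterministic toy genotype matrix with chosen codes
toy_genotypes <- function(codes, chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = m)
  genotype_matrix(codes,
                  data.frame(snp_id = paste0("s", seq_len(m)), chrom = chrom,
                             pos_bp = pos, a1 = "A", a2 = "B",
                             stringsAsFactors = FALSE))
}

# random 0/1/2 matrix (optionally with missing calls) as a GenotypeMatrix
random_genotypes <- function(n, m, maf = NULL, missing_rate = 0, seed = 1) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
  codes <- sapply(maf, function(p) rbinom(n, 2, p))
  if (missing_rate > 0)
    codes[runif(n * m) < missing_rate] <- NA
  toy_genotypes(codes)
}

# exact HWE p-value by direct enumeration with log-factorials;
# independent of the package's recurrence implementation
hwe_enum_oracle <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  if (2 * n_hom_minor + n_het > n) {
    tmp <- n_hom_minor; n_hom_minor <- n_hom_major; n_hom_major <- tmp
  }
  rare <- 2 * n_hom_minor + n_het
  if (rare == 0 || rare == 2 * n) return(1)
  hets <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2; hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(rare) + lfactorial(2 * n - rare) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs + 1e-12]))
}
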