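test_that("call rate matches an explicit per-column count", {
  g <- toy_genotypes(matrix(c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0), 10, 1))
  expect_equal(unname(snp_call_rate(g)), 1.0)
  codes <- matrix(c(0, 1, NA, 2, NA, 1, 0, NA, 2, 1), 10, 1)
  expect_equal(unname(snp_call_rate(toy_genotypes(codes))), 0.7)

  gr <- random_genotypes(50, 30, missing_rate = 0.2, seed = 2)
  oracle <- apply(gr$codes, 2, function(x) sum(!is.na(x)) / length(x))
  expect_equal(snp_call_rate(gr), oracle)
})

test_that("minor allele frequency is orientation-corrected and in [0, 0.5]", {
  expect_equal(unname(minor_allele_frequency(toy_genotypes(matrix(c(0, 0, 0, 0), 4, 1)))), 0)
  expect_equal(unname(minor_allele_frequency(toy_genotypes(matrix(c(0, 1, 1, 2), 4, 1)))), 0.5)
  # codes counting the MAJOR allele are flipped when reported
  expect_equal(unname(minor_allele_frequency(toy_genotypes(matrix(c(2, 2, 2, 1), 4, 1)))),
               1 / 8)
  gr <- random_genotypes(100, 50, missing_rate = 0.1, seed = 3)
  expect_true(all(minor_allele_frequency(gr) <= 0.5))
})

test_that("HWE exact test agrees with direct enumeration", {
  # perfect HWE at n = 100, allele count 100
  p_impl <- hwe_test(n_het = 50, n_hom_minor = 25, n_hom_major = 25)
  expect_equal(p_impl, hwe_enum_oracle(50, 25, 25), tolerance = 1e-10)
  expect_gt(p_impl, 0.9)
  # extreme heterozygote deficit
  p_def <- hwe_test(n_het = 0, n_hom_minor = 50, n_hom_major = 50)
  expect_equal(p_def, hwe_enum_oracle(0, 50, 50), tolerance = 1e-8)
  expect_lt(p_def, 1e-6)
  # monomorphic convention
  expect_equal(hwe_test(n_het = 0, n_hom_minor = 0, n_hom_major = 40), 1)
  # random configurations
  set.seed(1)
  for (i in 1:25) {
    n <- sample(10:200, 1)
    nm <- sample(0:(n %/% 2), 1)
    nh <- sample(0:(n - 2 * max(nm, 0)), 1)
    counts <- c(nh, nm, n - nh - nm)
    if (any(counts < 0)) next
    expect_equal(hwe_test(n_het = counts[1], n_hom_minor = counts[2],
                          n_hom_major = counts[3]),
                 hwe_enum_oracle(counts[1], counts[2], counts[3]),
                 tolerance = 1e-8)
  }
})

test_that("clean matrices pass QC unchanged", {
  g <- random_genotypes(300, 40, maf = runif(40, 0.3, 0.45), seed = 4)
  out <- apply_qc(g)
  expect_equal(dim(out$genotypes$codes), dim(g$codes))
  expect_equal(sum(out$report$snp_removals), 0L)
})

test_that("violations are attributed to the right filter and the survivor set matches an independent re-application", {
  set.seed(10)
  n <- 200
  codes <- sapply(runif(30, 0.25, 0.45), function(p) rbinom(n, 2, p))
  codes[, 1] <- rbinom(n, 2, 0.01)                        # MAF violation
  codes[sample(n, 50), 2] <- NA                           # call rate 0.75
  codes[, 3] <- sample(c(rep(2, 2), rep(1, 30), rep(0, n - 32)))  # minor-hom class of 2, MAF ok
  codes[, 4] <- sample(c(rep(1, 6), rep(0, 97), rep(2, 97)))      # het deficit, classes >= 5
  codes[50, ] <- NA                                       # individual fully missing
  g <- toy_genotypes(codes)
  g$map$pos_bp[5] <- 0                                    # unmapped

  th <- qc_thresholds()
  out <- apply_qc(g, th)
  rep <- out$report
  expect_equal(rep$n_individuals_removed, 1L)
  expect_true(rep$snp_removals[["maf"]] >= 1)
  expect_true(rep$snp_removals[["call_rate"]] >= 1)
  expect_true(rep$snp_removals[["genotype_count"]] >= 1)
  expect_true(rep$snp_removals[["hwe"]] >= 1)
  expect_true(rep$snp_removals[["unmapped"]] == 1)
  expect_equal(names(rep$removed_snp_ids)[rep$removed_snp_ids == "s1"], "maf")
  expect_equal(names(rep$removed_snp_ids)[rep$removed_snp_ids == "s3"], "genotype_count")
  expect_equal(names(rep$removed_snp_ids)[rep$removed_snp_ids == "s4"], "hwe")

  # oracle: apply each rule independently on the individual-filtered matrix
  keep_ind <- rowMeans(is.na(g$codes)) <= th$mind
  sub <- g$codes[keep_ind, , drop = FALSE]
  cr <- colMeans(!is.na(sub))
  f <- colMeans(sub, na.rm = TRUE) / 2; maf <- pmin(f, 1 - f)
  minc <- apply(sub, 2, function(x) {
    tb <- table(x[!is.na(x)]); if (length(tb)) min(tb) else 0 })
  hwe <- apply(sub, 2, function(x) {
    x <- x[!is.na(x)]
    hwe_enum_oracle(sum(x == 1), sum(x == 2), sum(x == 0)) })
  mapped <- g$map$pos_bp > 0
  survivors <- which(cr >= th$call_rate & maf >= th$maf &
                       minc >= th$min_genotype_count & hwe >= th$hwe_p & mapped)
  expect_setequal(out$genotypes$map$snp_id, g$map$snp_id[survivors])

  # every surviving SNP satisfies all thresholds when re-checked
  g2 <- out$genotypes
  expect_true(all(snp_call_rate(g2) >= th$call_rate))
  expect_true(all(minor_allele_frequency(g2) >= th$maf))
  expect_true(all(hwe_test(g2) >= th$hwe_p))

  # idempotence
  out2 <- apply_qc(out$genotypes, th)
  expect_identical(out2$genotypes$codes, out$genotypes$codes)
  expect_equal(sum(out2$report$snp_removals), 0L)
})

test_that("degenerate QC outcomes raise explicit errors", {
  g <- toy_genotypes(matrix(c(0, 0, 0, 0, 0, 0), 3, 2))   # all monomorphic
  expect_error(apply_qc(g), "all SNPs")
  g2 <- toy_genotypes(matrix(NA_integer_, 3, 2))
  expect_error(apply_qc(g2), "individuals")
})

test_that("the Mendel-error hook is a no-op", {
  g <- random_genotypes(10, 5)
  expect_identical(qc_mendel_hook(g), g)
})
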