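#' Per-SNP call rate
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector in `[0, 1]`, the fraction of non-missing calls
#'   per SNP.
#' @export
snp_call_rate <- function(g) {
  stopifnot(inherits(g, "GenotypeMatrix"), ncol(g$codes) > 0)
  colMeans(!is.na(g$codes))
}

#' Per-SNP minor allele frequency
#'
#' Computed over non-missing genotypes and orientation-corrected, so the
#' returned frequency is always that of the less common allele (in
#' `[0, 0.5]`). SNPs with no observed calls get `NA`.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector of MAFs.
#' @export
minor_allele_frequency <- function(g) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  f <- colMeans(g$codes, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  pmin(f, 1 - f)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' The standard biallelic exact test: conditional on the observed allele
#' counts, heterozygote counts are enumerated by a stable recurrence from
#' the modal configuration and the p-value sums the probabilities of all
#' configurations no more likely than the observed one. Monomorphic SNPs
#' return `p = 1` by convention.
#'
#' @param g a [genotype_matrix()], or `NULL` when using `n_het`/`n_hom_minor`.
#' @param n_het,n_hom_minor,n_hom_major optional explicit genotype counts
#'   for a single SNP (used instead of `g`).
#' @return numeric vector of p-values in `(0, 1]`, one per SNP.
#' @export
hwe_test <- function(g = NULL, n_het = NULL, n_hom_minor = NULL,
                     n_hom_major = NULL) {
  if (is.null(g)) {
    return(hwe_exact_one(n_het, n_hom_minor, n_hom_major))
  }
  stopifnot(inherits(g, "GenotypeMatrix"))
  apply(g$codes, 2L, function(x) {
    x <- x[!is.na(x)]
    hwe_exact_one(sum(x == 1L), sum(x == 2L), sum(x == 0L))
  })
}

hwe_exact_one <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  if (n == 0L) return(1)
  rare <- 2L * min(n_hom_minor, n_hom_major) + n_het
  # orient so "rare" counts the minor allele
  if (2L * n_hom_minor + n_het > n) {
    tmp <- n_hom_minor; n_hom_minor <- n_hom_major; n_hom_major <- tmp
  }
  rare <- 2L * n_hom_minor + n_het
  if (rare == 0L || rare == 2L * n) return(1)          # monomorphic
  hets <- seq.int(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  probs <- numeric(length(hets))
  # start the recurrence at the modal heterozygote count
  mid <- round(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  mid <- min(max(mid, min(hets)), max(hets))
  i0 <- match(mid, hets)
  probs[i0] <- 1
  if (i0 > 1L) for (i in (i0 - 1L):1L) {
    h <- hets[i + 1L]                                   # going down: h -> h-2
    hom_r <- (rare - h) / 2; hom_c <- n - h - hom_r
    probs[i] <- probs[i + 1L] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
  }
  if (i0 < length(hets)) for (i in (i0 + 1L):length(hets)) {
    h <- hets[i - 1L]                                   # going up: h -> h+2
    hom_r <- (rare - h) / 2; hom_c <- n - h - hom_r
    probs[i] <- probs[i - 1L] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

#' Default quality-control thresholds
#'
#' Chip-GWAS defaults: SNP call rate >= 0.90, MAF >= 0.05, every observed
#' genotype class carried by >= 5 individuals, HWE exact p >= 1e-6,
#' individual missingness <= 0.10, and removal of SNPs with missing or
#' non-positive map positions.
#'
#' @param call_rate,maf,min_genotype_count,hwe_p,mind threshold values.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(call_rate = 0.90, maf = 0.05,
                          min_genotype_count = 5L, hwe_p = 1e-6,
                          mind = 0.10) {
  list(call_rate = call_rate, maf = maf,
       min_genotype_count = as.integer(min_genotype_count),
       hwe_p = hwe_p, mind = mind)
}

#' Apply marker- and individual-level quality control
#'
#' Individuals exceeding the missingness threshold are removed first; SNP
#' filters are then computed on the retained individuals, applied in the
#' order unmapped position, call rate, MAF, minimum genotype-class count,
#' HWE, with each removed SNP attributed to the first filter that failed
#' it. Genotype codes are re-oriented where filtering changes which allele
#' is minor, so output codes always count the minor allele.
#'
#' The genotype-class rule counts only classes observed at least once: a
#' class absent from the data does not fail the filter, one carried by 1-4
#' individuals does. This reading of "a genotype occurring in fewer than 5
#' individuals" is recorded in the report (`genotype_count_rule`).
#'
#' @param g a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()] list.
#' @return list with elements `genotypes` (filtered [genotype_matrix()])
#'   and `report` (class `qc_report`).
#' @export
apply_qc <- function(g, thresholds = qc_thresholds()) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  th <- thresholds
  n_ind_in <- nrow(g$codes); n_snp_in <- ncol(g$codes)

  ind_miss <- rowMeans(is.na(g$codes))
  keep_ind <- ind_miss <= th$mind
  n_ind_removed <- sum(!keep_ind)
  if (!any(keep_ind))
    stop("quality control removed all individuals (mind = ", th$mind, ")")
  g2 <- subset_genotypes(g, i = which(keep_ind))

  removed_by <- rep(NA_character_, ncol(g2$codes))
  unmapped <- is.na(g2$map$pos_bp) | g2$map$pos_bp <= 0
  removed_by[unmapped] <- "unmapped"

  cr <- snp_call_rate(g2)
  sel <- is.na(removed_by) & cr < th$call_rate
  removed_by[sel] <- "call_rate"

  maf <- minor_allele_frequency(g2)
  sel <- is.na(removed_by) & (is.na(maf) | maf < th$maf)
  removed_by[sel] <- "maf"

  min_class <- apply(g2$codes, 2L, function(x) {
    tab <- tabulate(x[!is.na(x)] + 1L, nbins = 3L)
    tab <- tab[tab > 0L]
    if (length(tab)) min(tab) else 0L
  })
  sel <- is.na(removed_by) & min_class < th$min_genotype_count
  removed_by[sel] <- "genotype_count"

  check_hwe <- which(is.na(removed_by))
  if (length(check_hwe)) {
    hwe_p <- apply(g2$codes[, check_hwe, drop = FALSE], 2L, function(x) {
      x <- x[!is.na(x)]
      hwe_exact_one(sum(x == 1L), sum(x == 2L), sum(x == 0L))
    })
    removed_by[check_hwe[hwe_p < th$hwe_p]] <- "hwe"
  }

  keep_snp <- is.na(removed_by)
  if (!any(keep_snp))
    stop("quality control removed all SNPs")
  g3 <- subset_genotypes(g2, j = which(keep_snp))

  # re-orient codes so they count the minor allele among retained individuals
  f <- colMeans(g3$codes, na.rm = TRUE) / 2
  flip <- which(!is.na(f) & f > 0.5)
  if (length(flip)) {
    g3$codes[, flip] <- 2L - g3$codes[, flip, drop = FALSE]
    tmp <- g3$map$a1[flip]
    g3$map$a1[flip] <- g3$map$a2[flip]
    g3$map$a2[flip] <- tmp
  }

  filters <- c("unmapped", "call_rate", "maf", "genotype_count", "hwe")
  per_filter <- vapply(filters, function(f) sum(removed_by == f, na.rm = TRUE),
                       integer(1))
  report <- structure(list(
    n_individuals_in = n_ind_in, n_individuals_out = nrow(g3$codes),
    n_individuals_removed = n_ind_removed,
    n_snps_in = n_snp_in, n_snps_out = ncol(g3$codes),
    snp_removals = per_filter,
    thresholds = th,
    genotype_count_rule = "minimum count over genotype classes observed >= 1",
    removed_snp_ids = stats::setNames(g2$map$snp_id[!keep_snp],
                                      removed_by[!keep_snp])
  ), class = "qc_report")
  stopifnot(report$n_snps_out == report$n_snps_in - sum(per_filter))
  list(genotypes = g3, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  individuals: %d -> %d (%d removed, missingness > %g)\n",
              x$n_individuals_in, x$n_individuals_out,
              x$n_individuals_removed, x$thresholds$mind))
  cat(sprintf("  SNPs: %d -> %d\n", x$n_snps_in, x$n_snps_out))
  for (f in names(x$snp_removals))
    cat(sprintf("    removed by %s: %d\n", f, x$snp_removals[[f]]))
  invisible(x)
}

#' Mendelian-error filter hook
#'
#' Pedigree-based Mendelian-inconsistency filtering requires parent
#' records this package does not model; the hook exists so pipelines can
#' slot a pedigree-aware implementation in. The default is a no-op that
#' returns its input unchanged.
#'
#' @param g a [genotype_matrix()].
#' @param pedigree ignored by the default implementation.
#' @param max_error_rate ignored by the default implementation.
#' @return `g`, unchanged.
#' @export
qc_mendel_hook <- function(g, pedigree = NULL, max_error_rate = 0.02) {
  g
}
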