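#' VanRaden genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum_j p_j (1 - p_j))` where `Z` is the genotype matrix
#' centered per SNP at twice the allele frequency `p_j` of the counted
#' (minor) allele. Missing calls are mean-imputed per SNP before
#' centering; monomorphic SNPs contribute nothing and are excluded from
#' the denominator.
#'
#' @param g a [genotype_matrix()] or a plain 0/1/2 matrix (individuals in
#'   rows).
#' @return object of class `KinshipMatrix`: list with `values` (symmetric
#'   n x n matrix), `individual_ids`, `method = "vanraden"`.
#' @export
vanraden_grm <- function(g) {
  m <- impute_genotypes(g)
  ids <- if (inherits(g, "GenotypeMatrix")) g$individual_ids else rownames(m)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(m)))
  p <- colMeans(m) / 2
  poly <- p > 0 & p < 1
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  if (denom <= 0)
    stop("degenerate input: all SNPs are monomorphic, VanRaden denominator is 0")
  Z <- sweep(m[, poly, drop = FALSE], 2L, 2 * p[poly], "-")
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(ids, ids)
  structure(list(values = G, individual_ids = ids, method = "vanraden"),
            class = "KinshipMatrix")
}

#' @export
print.KinshipMatrix <- function(x, ...) {
  cat("KinshipMatrix (", x$method, "): ", nrow(x$values), " individuals; ",
      sprintf("mean diagonal %.3f\n", mean(diag(x$values))), sep = "")
  invisible(x)
}

#' Population-structure principal components from a SNP fraction
#'
#' Samples `snp_fraction` of the SNPs at random (seeded), mean-imputes and
#' centers them at their observed column means, and eigendecomposes the
#' individual-by-individual covariance. The defaults (10% of SNPs, first
#' five PCs) correct population structure ahead of association testing.
#' Each score column's sign is fixed so its largest-magnitude loading is
#' positive, for reproducible output.
#'
#' @param g a [genotype_matrix()].
#' @param snp_fraction fraction of SNPs to sample, in (0, 1].
#' @param k number of components to return (`k <= n - 1`).
#' @param seed integer seed controlling the SNP subsample.
#' @return object of class `StructurePCs`: `scores` (n x k), `explained`
#'   (variance fractions, non-increasing), `snp_index` (sampled SNPs),
#'   `snp_fraction`, `seed`, `centering = "observed_mean"`.
#' @export
structure_pcs <- function(g, snp_fraction = 0.10, k = 5, seed = 1L) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  if (snp_fraction <= 0 || snp_fraction > 1)
    stop("snp_fraction must be in (0, 1]")
  n <- nrow(g$codes)
  if (k > n - 1) stop("rank error: k = ", k, " exceeds n - 1 = ", n - 1)
  m_total <- ncol(g$codes)
  n_sample <- max(1L, round(snp_fraction * m_total))
  set.seed(as.integer(seed))
  snp_index <- sort(sample.int(m_total, n_sample))
  X <- impute_genotypes(subset_genotypes(g, j = snp_index))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = k, nv = k)
  if (sum(sv$d > 1e-10) < k)
    stop("rank error: requested ", k, " PCs but the sampled genotypes have rank ",
         sum(sv$d > 1e-10))
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  # sign convention: largest-|loading| positive
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) { scores[, j] <- -scores[, j] }
  }
  ev <- sv$d^2
  explained <- ev[seq_len(k)] / sum(ev)
  rownames(scores) <- g$individual_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, explained = explained,
                 snp_index = snp_index, snp_fraction = snp_fraction,
                 seed = as.integer(seed), centering = "observed_mean"),
            class = "StructurePCs")
}

#' @export
print.StructurePCs <- function(x, ...) {
  cat("StructurePCs:", nrow(x$scores), "individuals x", ncol(x$scores),
      "components from", length(x$snp_index), "sampled SNPs\n")
  cat("explained variance fractions:",
      paste(sprintf("%.3f", x$explained), collapse = " "), "\n")
  invisible(x)
}

#' Write kinship or PC scores as TSV
#' @param x a `KinshipMatrix` or `StructurePCs`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structure_tsv <- function(x, path) {
  if (inherits(x, "KinshipMatrix")) {
    utils::write.table(data.frame(id = x$individual_ids, x$values,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "StructurePCs")) {
    utils::write.table(data.frame(id = rownames(x$scores), x$scores),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
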