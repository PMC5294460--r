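#' Within-gene principal component decomposition
#'
#' Stage 1 of the two-stage gene test. The SNPs assigned to a gene are
#' mean-imputed, zero-variance columns are dropped, and the eigen
#' decomposition of their variance-covariance matrix (covariance of the
#' centered, unstandardized codes) is taken. The smallest number `K` of
#' leading components whose cumulative eigenvalue fraction reaches
#' `variance_target` is retained; scores are the centered genotypes
#' projected on those eigenvectors. Retained score columns are mutually
#' orthogonal, which is what licenses treating their per-component
#' association tests as independent in stage 2.
#'
#' @param g a [genotype_matrix()].
#' @param snp_indices SNP column indices of the gene's SNPs.
#' @param variance_target cumulative variance fraction to capture (default
#'   0.85).
#' @return object of class `GenePcDecomposition`: `scores` (n x K),
#'   `eigenvalues` (all, descending), `K`, `variance_fraction_captured`,
#'   `n_snps_used`, `n_snps_dropped` (zero-variance).
#' @export
gene_pca <- function(g, snp_indices, variance_target = 0.85) {
  X <- impute_genotypes(
    if (inherits(g, "GenotypeMatrix")) g$codes[, snp_indices, drop = FALSE]
    else g[, snp_indices, drop = FALSE])
  v <- apply(X, 2L, stats::var)
  dropped <- sum(v <= 1e-12)
  X <- X[, v > 1e-12, drop = FALSE]
  if (ncol(X) == 0)
    stop("degenerate gene: all SNP columns have zero variance")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  C <- stats::cov(Xc)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  frac <- cumsum(ev) / sum(ev)
  K <- which(frac >= variance_target)[1]
  scores <- Xc %*% e$vectors[, seq_len(K), drop = FALSE]
  rownames(scores) <- rownames(X)
  structure(list(scores = scores, eigenvalues = ev, K = K,
                 variance_fraction_captured = frac[K],
                 variance_target = variance_target,
                 n_snps_used = ncol(X), n_snps_dropped = dropped),
            class = "GenePcDecomposition")
}

#' Per-component association p-values
#'
#' Stage 2, first half: each retained within-gene PC is tested against the
#' adjusted trait through its Pearson correlation `r`, converted to
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and a two-sided p-value on
#' `n - 2` degrees of freedom. Zero-variance score columns are excluded
#' with a warning (reducing `K`).
#'
#' @param pcs a [gene_pca()] decomposition, or a numeric score matrix.
#' @param y an [adjust_phenotype()] result or a numeric vector aligned with
#'   the score rows.
#' @return numeric vector of `K` p-values in `(0, 1]`.
#' @export
pc_pvalues <- function(pcs, y) {
  scores <- if (inherits(pcs, "GenePcDecomposition")) pcs$scores else as.matrix(pcs)
  yv <- if (inherits(y, "AdjustedPhenotype")) y$residuals else y
  if (inherits(y, "AdjustedPhenotype") && !is.null(rownames(scores))) {
    idx <- match(rownames(scores), names(yv))
    if (anyNA(idx)) stop("phenotype missing for some individuals in the scores")
    yv <- yv[idx]
  }
  n <- length(yv)
  if (nrow(scores) != n) stop("scores and phenotype lengths differ")
  if (n <= ncol(scores) + 2) stop("need n > K + 2 individuals")
  sds <- apply(scores, 2L, stats::sd)
  if (any(sds <= 1e-12)) {
    warning("excluding ", sum(sds <= 1e-12), " zero-variance PC column(s)")
    scores <- scores[, sds > 1e-12, drop = FALSE]
  }
  r <- as.vector(stats::cor(scores, yv))
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Fisher's combination of independent p-values
#'
#' `chi2 = -2 * sum(log(p_k))`, referred to the upper tail of a chi-square
#' distribution with `2K` degrees of freedom. With a single component the
#' combined p-value equals the input p-value exactly. Zero p-values are
#' clamped to 1e-300 (with a warning) so the statistic stays finite; the
#' tail probability is computed in log space and is stable down to that
#' clamp.
#'
#' @param p_values numeric vector of K p-values in `(0, 1]`.
#' @return list with `chi2_stat`, `df` (= 2K) and `gene_p`.
#' @export
fisher_combination <- function(p_values) {
  if (length(p_values) < 1) stop("need at least one p-value")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  if (any(p_values == 0)) {
    warning("p-value of 0 clamped to 1e-300")
    p_values[p_values == 0] <- 1e-300
  }
  K <- length(p_values)
  chi2 <- -2 * sum(log(p_values))
  gene_p <- stats::pchisq(chi2, df = 2 * K, lower.tail = FALSE)
  if (gene_p == 0) gene_p <- 1e-300
  list(chi2_stat = chi2, df = 2L * K, gene_p = gene_p)
}

#' Precompute stage-1 decompositions for all genes
#'
#' The within-gene PCA depends only on the genotypes, so when several
#' traits (or replicate phenotypes) are scanned against one panel the
#' decompositions can be computed once and passed to [genome_scan()].
#' Degenerate genes (all SNPs zero-variance) are skipped with a message.
#'
#' @param g a [genotype_matrix()].
#' @param assignment a [assign_snps_to_genes()] result.
#' @param variance_target cumulative variance fraction for [gene_pca()].
#' @return named list of `GenePcDecomposition` objects.
#' @export
gene_pca_all <- function(g, assignment, variance_target = 0.85) {
  stopifnot(inherits(assignment, "GeneSnpAssignment"))
  out <- vector("list", length(assignment$snp_indices))
  names(out) <- names(assignment$snp_indices)
  for (gid in names(out)) {
    out[[gid]] <- tryCatch(
      gene_pca(g, assignment$snp_indices[[gid]], variance_target),
      error = function(e) {
        message("skipping gene ", gid, ": ", conditionMessage(e))
        NULL
      })
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Genome-wide two-stage gene-based scan
#'
#' Runs [gene_pca()] and [pc_pvalues()] + [fisher_combination()] for every
#' retained gene and Bonferroni-corrects over the number of genes actually
#' tested: a gene is flagged significant when its combined p-value is below
#' `alpha / N`.
#'
#' @param g a [genotype_matrix()].
#' @param assignment a [assign_snps_to_genes()] result.
#' @param y an [adjust_phenotype()] result or aligned numeric vector.
#' @param alpha family-wise error level (default 0.05).
#' @param variance_target stage-1 cumulative variance fraction.
#' @param decompositions optional [gene_pca_all()] output to reuse.
#' @return data.frame of class `gene_scan` with one row per tested gene:
#'   `gene_id`, `symbol`, `chrom`, `start_bp`, `end_bp`, `K`, `chi2`,
#'   `df`, `p_value`, `significant`; attributes `threshold`, `alpha`,
#'   `n_genes_tested`. Rows are ordered by chromosome and start position.
#' @export
genome_scan <- function(g, assignment, y, alpha = 0.05,
                        variance_target = 0.85, decompositions = NULL) {
  stopifnot(inherits(assignment, "GeneSnpAssignment"))
  if (length(assignment$snp_indices) == 0)
    stop("empty gene-SNP assignment: nothing to test")
  if (is.null(decompositions))
    decompositions <- gene_pca_all(g, assignment, variance_target)
  gids <- names(decompositions)
  genes <- assignment$genes[match(gids, assignment$genes$gene_id), , drop = FALSE]
  K <- integer(length(gids)); chi2 <- p <- numeric(length(gids))
  for (i in seq_along(gids)) {
    dec <- decompositions[[i]]
    pv <- pc_pvalues(dec, y)
    fc <- fisher_combination(pv)
    K[i] <- length(pv); chi2[i] <- fc$chi2_stat; p[i] <- fc$gene_p
  }
  n_tested <- length(gids)
  threshold <- alpha / n_tested
  res <- data.frame(
    gene_id = gids,
    symbol = if (!is.null(genes$symbol)) genes$symbol else gids,
    chrom = genes$chrom, start_bp = genes$start_bp, end_bp = genes$end_bp,
    K = K, chi2 = chi2, df = 2L * K, p_value = p,
    significant = p < threshold,
    stringsAsFactors = FALSE
  )
  res <- res[order(suppressWarnings(as.numeric(res$chrom)), res$chrom,
                   res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "threshold") <- threshold
  attr(res, "alpha") <- alpha
  attr(res, "n_genes_tested") <- n_tested
  class(res) <- c("gene_scan", "data.frame")
  res
}

#' Write gene-scan results as TSV
#' @param x a [genome_scan()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_scan <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
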