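#' Assign SNPs to genes by a flanking-window rule
#'
#' A SNP is assigned to every gene whose span, extended by `window_bp` on
#' each side, contains the SNP position; the window is closed, so a SNP at
#' exactly `start - window_bp` or `end + window_bp` is included. Genes with
#' fewer than `min_snps` assigned SNPs are dropped (their count is
#' reported). A SNP may belong to several overlapping genes.
#'
#' @param g a [genotype_matrix()].
#' @param genes gene-model data.frame (`gene_id`, `chrom`, `start_bp`,
#'   `end_bp`, optionally `symbol`, `biotype`).
#' @param window_bp flank added to each side of the gene span (default
#'   20 kb).
#' @param min_snps minimum mapped SNPs for a gene to be retained (default 5).
#' @param strict_chrom_check error (rather than silently assign nothing)
#'   when annotation chromosomes never occur in the SNP map.
#' @return object of class `GeneSnpAssignment`: `genes` (retained gene
#'   models with `n_snps`), `snp_indices` (named list, gene_id -> ordered
#'   SNP column indices), `window_bp`, `min_snps`, `n_genes_dropped`.
#' @export
assign_snps_to_genes <- function(g, genes, window_bp = 20000, min_snps = 5,
                                 strict_chrom_check = TRUE) {
  stopifnot(inherits(g, "GenotypeMatrix"), is.data.frame(genes))
  if (nrow(genes) == 0)
    stop("empty gene annotation")
  map_chroms <- unique(g$map$chrom)
  bad <- setdiff(unique(genes$chrom), map_chroms)
  if (strict_chrom_check && length(bad) == length(unique(genes$chrom)))
    stop("chromosome naming mismatch: annotation chromosome(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         " never occur in the genotype map (map has: ",
         paste(utils::head(map_chroms, 10), collapse = ", "), ")")
  snp_gr <- GenomicRanges::GRanges(
    seqnames = g$map$chrom,
    ranges = IRanges::IRanges(start = g$map$pos_bp, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1, genes$start_bp - window_bp),
                              end = genes$end_bp + window_bp))
  hits <- GenomicRanges::findOverlaps(gene_gr, snp_gr)
  by_gene <- split(S4Vectors::subjectHits(hits),
                   factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(genes))))
  n_snps <- lengths(by_gene)
  keep <- n_snps >= min_snps
  retained <- genes[keep, , drop = FALSE]
  retained$n_snps <- n_snps[keep]
  snp_indices <- lapply(by_gene[keep], function(i) sort(unname(i)))
  names(snp_indices) <- retained$gene_id
  structure(list(genes = retained, snp_indices = snp_indices,
                 window_bp = window_bp, min_snps = min_snps,
                 n_genes_in = nrow(genes),
                 n_genes_dropped = sum(!keep)),
            class = "GeneSnpAssignment")
}

#' @export
print.GeneSnpAssignment <- function(x, ...) {
  cat("GeneSnpAssignment:", nrow(x$genes), "genes retained (",
      x$n_genes_dropped, "dropped, < ", x$min_snps, "SNPs );",
      "window", x$window_bp, "bp\n")
  invisible(x)
}

#' Nearest gene to a SNP
#'
#' Distance is 0 — reported as the string `"in"` — when the SNP lies inside
#' the gene body, otherwise `min(|pos - start|, |pos - end|)`. Only genes
#' on the SNP's chromosome compete; if there are none the sentinel
#' `"none"` is returned.
#'
#' @param chrom,pos_bp SNP coordinates.
#' @param genes gene-model data.frame.
#' @return list with `gene_id`, `symbol`, and `distance` (`"in"`, a number
#'   of bp, or `"none"`).
#' @export
nearest_gene <- function(chrom, pos_bp, genes) {
  cand <- genes[genes$chrom == as.character(chrom), , drop = FALSE]
  if (nrow(cand) == 0)
    return(list(gene_id = "none", symbol = "none", distance = "none"))
  inside <- pos_bp >= cand$start_bp & pos_bp <= cand$end_bp
  d <- pmin(abs(pos_bp - cand$start_bp), abs(pos_bp - cand$end_bp))
  d[inside] <- 0
  i <- which.min(d)
  list(gene_id = cand$gene_id[i],
       symbol = if (!is.null(cand$symbol)) cand$symbol[i] else cand$gene_id[i],
       distance = if (inside[i]) "in" else d[i])
}

#' Annotate a SNP table with nearest genes
#'
#' @param snp_table data.frame with `chrom` and `pos_bp` columns.
#' @param genes gene-model data.frame.
#' @return `snp_table` with `nearest_gene`, `gene_symbol` and `distance`
#'   columns appended.
#' @export
annotate_nearest_gene <- function(snp_table, genes) {
  res <- lapply(seq_len(nrow(snp_table)), function(i)
    nearest_gene(snp_table$chrom[i], snp_table$pos_bp[i], genes))
  snp_table$nearest_gene <- vapply(res, `[[`, character(1), "gene_id")
  snp_table$gene_symbol <- vapply(res, `[[`, character(1), "symbol")
  snp_table$distance <- vapply(res, function(r) as.character(r$distance),
                               character(1))
  snp_table
}

#' Write a SNP-to-gene assignment as TSV
#' @param x a `GeneSnpAssignment`.
#' @param g the [genotype_matrix()] it was computed from (for SNP ids).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_assignment <- function(x, g, path) {
  df <- data.frame(
    gene_id = x$genes$gene_id,
    n_snps = x$genes$n_snps,
    snp_ids = vapply(x$snp_indices, function(i)
      paste(g$map$snp_id[i], collapse = ","), character(1))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
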