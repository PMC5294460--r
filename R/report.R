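#' Q-Q data and genomic inflation factor
#'
#' Sorted observed `-log10(p)` against the expected uniform quantiles
#' `-log10((i - 0.5) / m)`, plus the genomic inflation factor
#' `lambda = median(chi2_1(p)) / 0.4549364` (the null median of a 1-df
#' chi-square).
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return object of class `QqData`: data.frame `expected`/`observed`
#'   (both ascending) and attribute `lambda`.
#' @export
make_qq <- function(p_values) {
  if (length(p_values) == 0) stop("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p_values)
  observed <- -log10(sort(p_values, decreasing = TRUE))
  expected <- -log10((m:1 - 0.5) / m)
  lambda <- stats::median(stats::qchisq(p_values, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
  out <- data.frame(expected = expected, observed = observed)
  attr(out, "lambda") <- lambda
  class(out) <- c("QqData", "data.frame")
  out
}

#' Manhattan-plot coordinates
#'
#' Cumulative genome coordinates for SNP- or gene-level results: positions
#' are offset by the running chromosome lengths (chromosomes in
#' numeric-aware order), genes plotted at their midpoint
#' `(start + end) / 2`.
#'
#' @param results a [snp_scan()] or [genome_scan()] data.frame.
#' @param thresholds optional named numeric vector of significance levels
#'   to carry as horizontal-line attributes.
#' @return data.frame of class `ManhattanData`: `unit_id`, `chrom`,
#'   `pos_bp`, `cum_pos`, `neglog10_p`; attribute `thresholds`.
#' @export
make_manhattan <- function(results, thresholds = NULL) {
  df <- as.data.frame(results)
  if ("snp_id" %in% names(df)) {
    unit_id <- df$snp_id; pos <- df$pos_bp
  } else if ("gene_id" %in% names(df)) {
    unit_id <- df$gene_id; pos <- (df$start_bp + df$end_bp) / 2
  } else stop("results must come from a SNP or gene scan")
  keep <- !is.na(df$p_value)
  df <- df[keep, , drop = FALSE]; unit_id <- unit_id[keep]; pos <- pos[keep]
  chroms <- unique(df$chrom)
  num <- suppressWarnings(as.numeric(chroms))
  chroms <- chroms[order(num, chroms)]
  offsets <- stats::setNames(numeric(length(chroms)), chroms)
  running <- 0
  for (ch in chroms) {
    offsets[ch] <- running
    running <- running + max(pos[df$chrom == ch])
  }
  out <- data.frame(unit_id = unit_id, chrom = df$chrom, pos_bp = pos,
                    cum_pos = pos + offsets[df$chrom],
                    neglog10_p = -log10(df$p_value),
                    stringsAsFactors = FALSE)
  ord <- order(match(out$chrom, chroms), out$pos_bp)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  class(out) <- c("ManhattanData", "data.frame")
  out
}

format_p <- function(p) toupper(formatC(p, format = "e", digits = 2))

#' Significant-hit tables
#'
#' Filters the two scans at their thresholds (strict `<`) and formats the
#' columns the way GWAS reports print them: p-values in scientific
#' notation with two decimals (`2.36E-07`), MAF to four decimals. The SNP
#' table carries nearest-gene annotation (`"in"` for SNPs inside a gene
#' body) when a gene annotation is supplied.
#'
#' @param snp_results a [snp_scan()] data.frame (or NULL).
#' @param gene_results a [genome_scan()] data.frame (or NULL).
#' @param snp_threshold significance level for SNPs (e.g.
#'   [suggestive_threshold()]`$suggestive`).
#' @param gene_threshold significance level for genes (e.g. the scan's
#'   `threshold` attribute).
#' @param genes optional gene-model data.frame for nearest-gene annotation
#'   of the SNP table.
#' @return list with `snp_table` and `gene_table` data.frames (possibly
#'   zero rows, headers always present).
#' @export
make_hit_tables <- function(snp_results = NULL, gene_results = NULL,
                            snp_threshold = NULL, gene_threshold = NULL,
                            genes = NULL) {
  snp_table <- data.frame(SNP = character(), BTA = character(),
                          Position = numeric(), P_value = character(),
                          MAF = character(), Nearest_Gene = character(),
                          Distance = character(), stringsAsFactors = FALSE)
  gene_table <- data.frame(Gene_ID = character(), BTA = character(),
                           Start_bp = numeric(), End_bp = numeric(),
                           P_value = character(), Gene_symbol = character(),
                           stringsAsFactors = FALSE)
  if (!is.null(snp_results)) {
    if (is.null(snp_threshold)) stop("snp_threshold required")
    hit <- !is.na(snp_results$p_value) & snp_results$p_value < snp_threshold
    h <- as.data.frame(snp_results)[hit, , drop = FALSE]
    if (nrow(h)) {
      ann <- if (!is.null(genes)) annotate_nearest_gene(h, genes) else
        cbind(h, gene_symbol = NA_character_, distance = NA_character_)
      snp_table <- data.frame(SNP = h$snp_id, BTA = h$chrom,
                              Position = h$pos_bp,
                              P_value = format_p(h$p_value),
                              MAF = sprintf("%.4f", h$maf),
                              Nearest_Gene = ann$gene_symbol,
                              Distance = ann$distance,
                              stringsAsFactors = FALSE)
    }
  }
  if (!is.null(gene_results)) {
    if (is.null(gene_threshold))
      gene_threshold <- attr(gene_results, "threshold")
    if (is.null(gene_threshold)) stop("gene_threshold required")
    hit <- !is.na(gene_results$p_value) & gene_results$p_value < gene_threshold
    h <- as.data.frame(gene_results)[hit, , drop = FALSE]
    if (nrow(h))
      gene_table <- data.frame(Gene_ID = h$gene_id, BTA = h$chrom,
                               Start_bp = h$start_bp, End_bp = h$end_bp,
                               P_value = format_p(h$p_value),
                               Gene_symbol = h$symbol,
                               stringsAsFactors = FALSE)
  }
  list(snp_table = snp_table, gene_table = gene_table)
}

#' Write hit tables as TSV
#' @param tables output of [make_hit_tables()].
#' @param out_dir directory; `snp_hits.tsv` and `gene_hits.tsv` are written.
#' @return invisibly, the file paths.
#' @export
write_hit_tables <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(snp = file.path(out_dir, "snp_hits.tsv"),
             gene = file.path(out_dir, "gene_hits.tsv"))
  utils::write.table(tables$snp_table, paths["snp"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tables$gene_table, paths["gene"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Base-graphics Manhattan plot
#'
#' Rendering is best-effort: any device failure is caught and reported as
#' a message, never an error, since the data tables are the contract.
#'
#' @param md a [make_manhattan()] data.frame.
#' @param main plot title.
#' @return invisibly, TRUE if the plot rendered.
#' @export
plot_manhattan <- function(md, main = "Manhattan plot") {
  ok <- tryCatch({
    chroms <- unique(md$chrom)
    col <- c("grey25", "steelblue")[(match(md$chrom, chroms) %% 2) + 1]
    plot(md$cum_pos, md$neglog10_p, pch = 20, cex = 0.5, col = col,
         xlab = "genome position", ylab = expression(-log[10](p)),
         main = main, xaxt = "n")
    th <- attr(md, "thresholds")
    if (!is.null(th))
      graphics::abline(h = -log10(th), col = "red", lty = 2)
    TRUE
  }, error = function(e) {
    message("manhattan plot skipped: ", conditionMessage(e)); FALSE
  })
  invisible(ok)
}

#' Base-graphics Q-Q plot
#' @param qq a [make_qq()] data.frame.
#' @param main plot title.
#' @return invisibly, TRUE if the plot rendered.
#' @export
plot_qq <- function(qq, main = "Q-Q plot") {
  ok <- tryCatch({
    plot(qq$expected, qq$observed, pch = 20, cex = 0.5,
         xlab = expression(Expected ~ -log[10](p)),
         ylab = expression(Observed ~ -log[10](p)), main = main)
    graphics::abline(0, 1, col = "red")
    graphics::legend("topleft", bty = "n",
                     legend = sprintf("lambda = %.3f", attr(qq, "lambda")))
    TRUE
  }, error = function(e) {
    message("qq plot skipped: ", conditionMessage(e)); FALSE
  })
  invisible(ok)
}
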