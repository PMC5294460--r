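#' Construct a genotype matrix
#'
#' The central container of the package: an individuals-by-SNPs matrix of
#' additive genotype codes together with the marker map. Codes count copies
#' of the minor allele, so 0/1/2 correspond to major-homozygote,
#' heterozygote and minor-homozygote; `NA` marks a missing call.
#'
#' @param codes integer or numeric matrix, individuals in rows, SNPs in
#'   columns; entries must be 0, 1, 2 or `NA`.
#' @param map data.frame with one row per SNP and columns `snp_id`,
#'   `chrom`, `pos_bp` (1-based), and optionally `a1` (minor) and `a2`
#'   (major) allele labels. Positions must be non-decreasing within each
#'   chromosome.
#' @param individual_ids character vector, one id per row of `codes`.
#'   Defaults to rownames of `codes` or `ind1..indN`.
#' @return an object of class `GenotypeMatrix`: a list with elements
#'   `codes`, `map`, `individual_ids`.
#' @export
genotype_matrix <- function(codes, map, individual_ids = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (!all(codes %in% c(0L, 1L, 2L) | is.na(codes)))
    stop("genotype codes must be 0, 1, 2 or NA")
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos_bp")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols))
    stop("map is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(map) != ncol(codes))
    stop("map has ", nrow(map), " rows but codes has ", ncol(codes), " columns")
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  map$chrom <- as.character(map$chrom)
  map$pos_bp <- as.numeric(map$pos_bp)
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    p <- p[!is.na(p) & p > 0]          # unmapped SNPs (NA or 0) are exempt
    if (is.unsorted(p))
      stop("pos_bp must be non-decreasing within chromosome ", ch)
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(codes)
    if (is.null(individual_ids))
      individual_ids <- paste0("ind", seq_len(nrow(codes)))
  }
  if (length(individual_ids) != nrow(codes))
    stop("individual_ids length does not match number of rows")
  dimnames(codes) <- list(individual_ids, map$snp_id)
  structure(
    list(codes = codes, map = map, individual_ids = as.character(individual_ids)),
    class = "GenotypeMatrix"
  )
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$codes), "individuals x", ncol(x$codes), "SNPs\n")
  cat("chromosomes:", paste(unique(x$map$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$codes))
  cat(sprintf("missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$codes)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i individual (row) index.
#' @param j SNP (column) index.
#' @param ... ignored.
#' @return a `GenotypeMatrix` restricted to the selected rows/columns.
#' @export
subset_genotypes <- function(x, i = NULL, j = NULL, ...) {
  stopifnot(inherits(x, "GenotypeMatrix"))
  if (is.null(i)) i <- seq_len(nrow(x$codes))
  if (is.null(j)) j <- seq_len(ncol(x$codes))
  genotype_matrix(x$codes[i, j, drop = FALSE], x$map[j, , drop = FALSE],
                  x$individual_ids[i])
}

#' Mean-imputed, numeric genotype matrix
#'
#' Replaces each missing call with the per-SNP mean of the observed codes
#' (the standard chip-GWAS convention before centering). SNPs with no
#' observed calls are imputed to 0 and flagged.
#'
#' @param x a [genotype_matrix()] or a numeric matrix with `NA`s.
#' @return numeric matrix with no missing values.
#' @export
impute_genotypes <- function(x) {
  m <- if (inherits(x, "GenotypeMatrix")) x$codes else as.matrix(x)
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  if (!anyNA(m)) return(m)
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- mu[idx[, 2L]]
  m
}

# ---- PLINK text -------------------------------------------------------------

#' Write genotypes as PLINK text (.ped/.map)
#'
#' Alleles are written as the map's `a1` (minor) / `a2` (major) labels and
#' missing calls as `0 0`. The .map file has the usual four columns
#' (chromosome, SNP id, genetic distance 0, bp position).
#'
#' @param g a [genotype_matrix()].
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` are written.
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  map <- data.frame(g$map$chrom, g$map$snp_id, 0L, as.integer(g$map$pos_bp))
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(g$codes); m <- ncol(g$codes)
  a1 <- g$map$a1; a2 <- g$map$a2
  lines <- character(n)
  for (i in seq_len(n)) {
    x <- g$codes[i, ]
    first <- ifelse(is.na(x), "0", ifelse(x >= 1, a1, a2))
    second <- ifelse(is.na(x), "0", ifelse(x == 2, a1, a2))
    al <- character(2L * m)
    al[c(TRUE, FALSE)] <- first
    al[c(FALSE, TRUE)] <- second
    lines[i] <- paste(c("FAM1", g$individual_ids[i], "0", "0", "0", "-9", al),
                      collapse = " ")
  }
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read PLINK text (.ped/.map) genotypes
#'
#' Minor/major allele orientation is determined from the data (the less
#' frequent allele becomes `a1` and is the counted allele); ties keep the
#' lexicographically smaller allele as minor.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  mapfile <- paste0(prefix, ".map"); pedfile <- paste0(prefix, ".ped")
  if (!file.exists(mapfile) || !file.exists(pedfile))
    stop("missing .ped/.map pair at prefix ", prefix)
  map_in <- utils::read.table(mapfile, header = FALSE,
                              col.names = c("chrom", "snp_id", "cm", "pos_bp"),
                              colClasses = c("character", "character", "numeric", "numeric"))
  ped <- utils::read.table(pedfile, header = FALSE, colClasses = "character")
  m <- nrow(map_in)
  if (ncol(ped) != 6L + 2L * m)
    stop(".ped has ", ncol(ped), " columns; expected ", 6L + 2L * m)
  ids <- ped[[2L]]
  allele_mat <- as.matrix(ped[, -(1:6), drop = FALSE])
  n <- nrow(allele_mat)
  codes <- matrix(NA_integer_, n, m)
  a1 <- a2 <- character(m)
  for (j in seq_len(m)) {
    x1 <- allele_mat[, 2L * j - 1L]; x2 <- allele_mat[, 2L * j]
    ok <- x1 != "0" & x2 != "0"
    als <- sort(unique(c(x1[ok], x2[ok])))
    if (length(als) == 0L) { a1[j] <- "A"; a2[j] <- "B"; next }
    if (length(als) > 2L) stop("SNP ", map_in$snp_id[j], " has >2 alleles")
    counts <- table(factor(c(x1[ok], x2[ok]), levels = als))
    minor <- names(counts)[which.min(counts)]
    major <- if (length(als) == 2L) setdiff(als, minor) else minor
    a1[j] <- minor; a2[j] <- major
    codes[ok, j] <- (x1[ok] == minor) + (x2[ok] == minor)
  }
  map <- data.frame(snp_id = map_in$snp_id, chrom = map_in$chrom,
                    pos_bp = map_in$pos_bp, a1 = a1, a2 = a2,
                    stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos_bp)
  genotype_matrix(codes[, ord, drop = FALSE], map[ord, , drop = FALSE], ids)
}

# ---- VCF --------------------------------------------------------------------

#' Write a minimal VCF 4.2 (GT field only)
#'
#' REF is the major allele, ALT the minor allele; genotype codes count ALT
#' copies, written unphased (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "GenotypeMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$individual_ids), collapse = "\t")),
             con)
  gt_str <- c("0/0", "0/1", "1/1")
  m <- ncol(g$codes)
  rows <- character(m)
  for (j in seq_len(m)) {
    x <- g$codes[, j]
    gt <- ifelse(is.na(x), "./.", gt_str[x + 1L])
    rows[j] <- paste(c(g$map$chrom[j], as.integer(g$map$pos_bp[j]),
                       g$map$snp_id[j], g$map$a2[j], g$map$a1[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t")
  }
  writeLines(rows, con)
  invisible(path)
}

#' Read genotypes from a VCF (GT field)
#'
#' Parses with `vcfR` and converts to additive ALT-allele dosage. If ALT is
#' not the minor allele in the sample, codes are flipped so that, as
#' throughout the package, code 2 means two copies of the minor allele.
#'
#' @param path a VCF file (plain or gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- function(s) {
    out <- rep(NA_integer_, length(s))
    ok <- !is.na(s) & !grepl("\\.", s)
    parts <- strsplit(gsub("\\|", "/", s[ok]), "/", fixed = TRUE)
    out[ok] <- vapply(parts, function(p) sum(as.integer(p)), integer(1))
    out
  }
  codes <- t(apply(gt, 1L, dose))                     # SNP x ind
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  a_ref <- fix$REF; a_alt <- fix$ALT
  # orient so the counted allele is the minor one
  freq <- rowMeans(codes, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  codes[flip, ] <- 2L - codes[flip, , drop = FALSE]
  a1 <- ifelse(flip, a_ref, a_alt)
  a2 <- ifelse(flip, a_alt, a_ref)
  map <- data.frame(snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                    paste0(fix$CHROM, ":", fix$POS), fix$ID),
                    chrom = fix$CHROM, pos_bp = as.numeric(fix$POS),
                    a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  ord <- order(map$chrom, map$pos_bp)
  genotype_matrix(t(codes)[, ord, drop = FALSE], map[ord, , drop = FALSE],
                  colnames(gt))
}
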