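#' Simulation configuration for a synthetic genotyped population
#'
#' Parameterizes a diploid population genotyped at dense biallelic SNPs with
#' block linkage disequilibrium, a gene map of multi-SNP genes, and
#' quantitative traits built from categorical/continuous fixed effects, a
#' polygenic term driven by the genomic relationship matrix of the simulated
#' genotypes themselves, and a small number of causal genes.
#'
#' Defaults emulate a beef-cattle carcass study: ~1,100 animals on 29
#' autosomes, SNP spacing a few kb, a body-weight-like trait with total
#' genetic variance around 0.41 of the non-fixed-effect variance (0.37
#' polygenic + 0.04 concentrated in three causal genes), and a second
#' pH-like trait on its own scale.
#'
#' Within an LD block all SNPs share one allele frequency and haplotype
#' alleles follow a first-order allele-copy process: each allele is copied
#' from its left neighbour with probability `ld_decay`, otherwise drawn
#' fresh. Adjacent within-block genotype correlation is therefore exactly
#' `ld_decay` in expectation; blocks are independent and never span
#' chromosome boundaries.
#'
#' @param n_individuals number of diploid individuals.
#' @param n_chromosomes number of autosomes.
#' @param snps_per_chromosome SNPs simulated per chromosome.
#' @param maf_range length-2 numeric in (0, 0.5]; one allele frequency per
#'   LD block is drawn uniformly from this interval.
#' @param ld_block_size SNPs per haplotype block.
#' @param ld_decay allele-copy probability in `[0, 1)`; the target
#'   adjacent-SNP correlation within a block.
#' @param snp_spacing_bp mean distance between consecutive SNPs (bp).
#' @param n_genes genes to place on the simulated chromosomes.
#' @param gene_length_range length-2 numeric, gene span in bp.
#' @param n_causal_genes number of genes harbouring causal SNPs (per trait).
#' @param causal_snps_per_gene causal SNPs drawn inside each causal gene's
#'   20 kb window.
#' @param h2_polygenic fraction of the non-fixed phenotypic variance from
#'   the polygenic term `g ~ N(0, sigma2_g * K)`.
#' @param h2_causal fraction from the causal-gene SNP effects.
#' @param fixed_effects list with elements `year_levels`, `farm_levels`,
#'   `gender_levels` (level counts for the categorical covariates) and
#'   `effect_sd` (standard deviation, in phenotypic-SD units, contributed
#'   by each covariate; set 0 to switch fixed effects off).
#' @param traits named list of trait scales, each `c(mean =, sd =)`.
#' @param missing_rate fraction of genotype calls masked as missing.
#' @param seed master seed; all stages derive child seeds from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 1141,
                       n_chromosomes = 29,
                       snps_per_chromosome = 200,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_decay = 0.7,
                       snp_spacing_bp = 3430,
                       n_genes = 300,
                       gene_length_range = c(5000, 50000),
                       n_causal_genes = 3,
                       causal_snps_per_gene = 2,
                       h2_polygenic = 0.37,
                       h2_causal = 0.04,
                       fixed_effects = list(year_levels = 6, farm_levels = 3,
                                            gender_levels = 2, effect_sd = 0.5),
                       traits = list(BW = c(mean = 40, sd = 6.58),
                                     pH = c(mean = 5.63, sd = 0.38)),
                       missing_rate = 0.0,
                       seed = 1L) {
  cfg <- list(n_individuals = n_individuals, n_chromosomes = n_chromosomes,
              snps_per_chromosome = snps_per_chromosome, maf_range = maf_range,
              ld_block_size = ld_block_size, ld_decay = ld_decay,
              snp_spacing_bp = snp_spacing_bp, n_genes = n_genes,
              gene_length_range = gene_length_range,
              n_causal_genes = n_causal_genes,
              causal_snps_per_gene = causal_snps_per_gene,
              h2_polygenic = h2_polygenic, h2_causal = h2_causal,
              fixed_effects = fixed_effects, traits = traits,
              missing_rate = missing_rate, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, nm, zero_ok = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
        x < if (zero_ok) 0 else 1)
      stop("invalid sim_config field '", nm, "': must be a ",
           if (zero_ok) "non-negative" else "positive", " count", call. = FALSE)
  }
  chk_count(cfg$n_individuals, "n_individuals")
  chk_count(cfg$n_chromosomes, "n_chromosomes")
  chk_count(cfg$snps_per_chromosome, "snps_per_chromosome")
  chk_count(cfg$ld_block_size, "ld_block_size")
  chk_count(cfg$n_genes, "n_genes", zero_ok = TRUE)
  chk_count(cfg$n_causal_genes, "n_causal_genes", zero_ok = TRUE)
  chk_count(cfg$causal_snps_per_gene, "causal_snps_per_gene")
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("invalid sim_config field 'maf_range': must lie in (0, 0.5]",
         call. = FALSE)
  if (cfg$ld_decay < 0 || cfg$ld_decay >= 1)
    stop("invalid sim_config field 'ld_decay': must be in [0, 1)", call. = FALSE)
  if (cfg$h2_polygenic < 0 || cfg$h2_causal < 0 ||
      cfg$h2_polygenic + cfg$h2_causal >= 1)
    stop("invalid sim_config field 'h2_polygenic'/'h2_causal': ",
         "fractions must be non-negative with sum < 1", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid sim_config field 'missing_rate': must be in [0, 1)",
         call. = FALSE)
  if (length(cfg$gene_length_range) != 2L || any(cfg$gene_length_range < 1) ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2])
    stop("invalid sim_config field 'gene_length_range'", call. = FALSE)
  invisible(cfg)
}

# one master seed; deterministic child seeds so stages regenerate independently
child_seed <- function(seed, stage) {
  stages <- c(haplotypes = 1L, missing = 2L, genes = 3L, phenotypes = 4L)
  off <- stages[[stage]]
  as.integer((as.double(seed) * 48271 + off * 100003) %% 2147483647)
}

sim_chrom_length <- function(cfg) cfg$snps_per_chromosome * cfg$snp_spacing_bp

sim_map <- function(cfg) {
  set.seed(child_seed(cfg$seed, "haplotypes"))
  len <- sim_chrom_length(cfg)
  m <- cfg$snps_per_chromosome
  pos <- lapply(seq_len(cfg$n_chromosomes),
                function(ch) sort(sample.int(len, m, replace = FALSE)))
  blocks_per_chr <- ceiling(m / cfg$ld_block_size)
  block <- rep(seq_len(blocks_per_chr), each = cfg$ld_block_size)[seq_len(m)]
  data.frame(
    snp_id = sprintf("snp_%d_%06d", rep(seq_len(cfg$n_chromosomes), each = m),
                     unlist(pos)),
    chrom = as.character(rep(seq_len(cfg$n_chromosomes), each = m)),
    pos_bp = as.numeric(unlist(pos)),
    a1 = "A", a2 = "B",
    block = paste0(rep(seq_len(cfg$n_chromosomes), each = m), "_",
                   rep(block, cfg$n_chromosomes)),
    stringsAsFactors = FALSE
  )
}

#' Simulate haplotypes under the block allele-copy LD model
#'
#' Returns the raw `2n x m` haplotype allele matrix (0/1 counting the minor
#' "A" allele) underlying [simulate_genotypes()]; rows `1..n` and
#' `n+1..2n` are the two haplotypes of each individual. Exposed so the
#' generator's LD target can be audited directly from the haplotypes.
#'
#' @param config a [sim_config()].
#' @return list with `haplotypes` (matrix), `map` (SNP map with block ids)
#'   and `block_freq` (named per-block allele frequency).
#' @export
simulate_haplotypes <- function(config) {
  validate_sim_config(config)
  map <- sim_map(config)
  set.seed(child_seed(config$seed, "haplotypes") + 1L)
  n2 <- 2L * config$n_individuals
  m <- nrow(map)
  h <- matrix(0L, n2, m)
  blocks <- split(seq_len(m), map$block)
  block_freq <- numeric(length(blocks))
  names(block_freq) <- names(blocks)
  # iterate in genomic order for reproducibility
  for (b in unique(map$block)) {
    idx <- blocks[[b]]
    p <- stats::runif(1, config$maf_range[1], config$maf_range[2])
    block_freq[b] <- p
    h[, idx[1]] <- stats::rbinom(n2, 1L, p)
    if (length(idx) > 1L) for (k in 2:length(idx)) {
      copy <- stats::runif(n2) < config$ld_decay
      fresh <- stats::rbinom(n2, 1L, p)
      h[, idx[k]] <- ifelse(copy, h[, idx[k - 1L]], fresh)
    }
  }
  list(haplotypes = h, map = map, block_freq = block_freq)
}

#' Simulate a genotype matrix
#'
#' Sums the two haplotypes of [simulate_haplotypes()] into additive codes
#' and masks calls at `missing_rate`. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] of codes in 0/1/2 with `NA` missing calls.
#' @export
simulate_genotypes <- function(config) {
  hp <- simulate_haplotypes(config)
  n <- config$n_individuals
  codes <- hp$haplotypes[seq_len(n), , drop = FALSE] +
    hp$haplotypes[n + seq_len(n), , drop = FALSE]
  if (config$missing_rate > 0) {
    set.seed(child_seed(config$seed, "missing"))
    mask <- stats::runif(length(codes)) < config$missing_rate
    codes[mask] <- NA_integer_
  }
  genotype_matrix(codes, hp$map)
}

#' Simulate a gene map over the simulated chromosomes
#'
#' Places `n_genes` non-degenerate intervals, each anchored at a randomly
#' chosen SNP so genes land in genotyped territory. Coordinates are 1-based
#' inclusive. At least `n_causal_genes` genes must contain
#' `max(causal_snps_per_gene, 5)` SNPs within their +/-20 kb window,
#' otherwise the geometry is declared infeasible.
#'
#' @param config a [sim_config()].
#' @param genotypes the matching [simulate_genotypes()] output (for SNP
#'   positions).
#' @return data.frame of gene models: `gene_id`, `symbol`, `chrom`,
#'   `start_bp`, `end_bp`, `biotype`.
#' @export
simulate_gene_map <- function(config, genotypes) {
  validate_sim_config(config)
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  if (config$n_genes == 0L)
    return(data.frame(gene_id = character(), symbol = character(),
                      chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), biotype = character(),
                      stringsAsFactors = FALSE))
  chr_len <- sim_chrom_length(config)
  if (config$gene_length_range[1] >= chr_len)
    stop("configuration error: genes of length ", config$gene_length_range[1],
         " bp cannot fit on chromosomes of ", chr_len, " bp")
  set.seed(child_seed(config$seed, "genes"))
  map <- genotypes$map
  anchors <- sample.int(nrow(map), config$n_genes, replace = TRUE)
  len <- round(stats::runif(config$n_genes, config$gene_length_range[1],
                            config$gene_length_range[2]))
  start <- pmax(1, round(map$pos_bp[anchors] - len / 2))
  end <- pmin(chr_len, start + len - 1)
  start <- pmax(1, pmin(start, end - 1))           # keep non-degenerate
  genes <- data.frame(
    gene_id = sprintf("ENSSYNG%011d", seq_len(config$n_genes)),
    symbol = sprintf("GENE%d", seq_len(config$n_genes)),
    chrom = map$chrom[anchors],
    start_bp = as.numeric(start), end_bp = as.numeric(end),
    biotype = sample(c("protein_coding", "lincRNA", "pseudogene"),
                     config$n_genes, replace = TRUE, prob = c(0.85, 0.1, 0.05)),
    stringsAsFactors = FALSE
  )
  need <- max(config$causal_snps_per_gene, 5L)
  counts <- count_snps_in_windows(map, genes, window_bp = 20000)
  if (sum(counts >= need) < config$n_causal_genes)
    stop("configuration error: only ", sum(counts >= need), " genes carry >= ",
         need, " SNPs within their 20 kb window; ", config$n_causal_genes,
         " causal genes requested")
  genes
}

count_snps_in_windows <- function(map, genes, window_bp) {
  vapply(seq_len(nrow(genes)), function(i) {
    sum(map$chrom == genes$chrom[i] &
          map$pos_bp >= genes$start_bp[i] - window_bp &
          map$pos_bp <= genes$end_bp[i] + window_bp)
  }, numeric(1))
}

#' Simulate phenotypes, covariates and ground truth
#'
#' Builds, per trait, `y = fixed effects + g + c + e` with
#' `g ~ N(0, sigma2_g K)` for the VanRaden kinship `K` of the simulated
#' genotypes, `c` the summed effects of causal SNPs inside randomly chosen
#' causal genes, and independent Gaussian noise `e`. The non-fixed part
#' `g + c + e` has unit variance in expectation, split as
#' `h2_polygenic : h2_causal : remainder`; everything is then placed on the
#' trait's output scale (`mean`, `sd` from `config$traits`).
#'
#' @param config a [sim_config()].
#' @param genotypes output of [simulate_genotypes()].
#' @param genes output of [simulate_gene_map()].
#' @param kinship_eigen optional precomputed `eigen()` of the VanRaden
#'   kinship of `genotypes` (symmetric), reused across replicate phenotype
#'   draws on one panel so the factorization is not repeated.
#' @return a `sim_output` list: `genotypes`, `genes`, `phenotypes`
#'   (data.frame id + one column per trait), `covariates` (year, farm,
#'   gender, fattening_days, entering_weight), and `truth` — per trait the
#'   causal gene ids, causal SNP ids/indices and effects, the variance
#'   components used, realized variance fractions, and the raw components
#'   (`fixed`, `g`, `causal`, `e`) on the output scale.
#' @export
simulate_phenotypes <- function(config, genotypes, genes, kinship_eigen = NULL) {
  validate_sim_config(config)
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  n <- config$n_individuals
  if (nrow(genotypes$codes) != n)
    stop("genotypes have ", nrow(genotypes$codes),
         " individuals but config expects ", n)
  set.seed(child_seed(config$seed, "phenotypes"))

  fe <- config$fixed_effects
  covariates <- data.frame(
    id = genotypes$individual_ids,
    year = factor(sample(2009:(2009 + fe$year_levels - 1), n, replace = TRUE)),
    farm = factor(sample(paste0("farm", seq_len(fe$farm_levels)), n, replace = TRUE)),
    gender = factor(sample(c("M", "F")[seq_len(fe$gender_levels)], n, replace = TRUE)),
    fattening_days = round(stats::rnorm(n, 300, 30)),
    entering_weight = round(stats::rnorm(n, 250, 25), 1),
    stringsAsFactors = FALSE
  )

  h2g <- config$h2_polygenic; h2c <- config$h2_causal
  sigma2_e <- 1 - h2g - h2c

  # kinship of the simulated genotypes themselves makes REML recovery well-posed
  L <- NULL
  if (h2g > 0) {
    eK <- if (is.null(kinship_eigen))
      eigen(vanraden_grm(genotypes)$values, symmetric = TRUE) else kinship_eigen
    L <- eK$vectors %*% diag(sqrt(pmax(eK$values, 0)), n)
  }

  window <- 20000
  need <- max(config$causal_snps_per_gene, 5L)
  eligible <- which(count_snps_in_windows(genotypes$map, genes, window) >= need)

  phen <- data.frame(id = genotypes$individual_ids, stringsAsFactors = FALSE)
  truth <- list()
  Ximp <- if (h2c > 0 && config$n_causal_genes > 0)
    impute_genotypes(genotypes) else NULL

  for (tr in names(config$traits)) {
    scale <- config$traits[[tr]]
    # fixed effects
    fixed <- numeric(n)
    fx <- list()
    if (fe$effect_sd > 0) {
      for (v in c("year", "farm", "gender")) {
        lev <- levels(covariates[[v]])
        eff <- stats::rnorm(length(lev), 0, fe$effect_sd)
        fx[[v]] <- stats::setNames(eff, lev)
        fixed <- fixed + eff[as.integer(covariates[[v]])]
      }
      for (v in c("fattening_days", "entering_weight")) {
        slope <- fe$effect_sd / stats::sd(covariates[[v]])
        fx[[v]] <- slope
        fixed <- fixed + slope * (covariates[[v]] - mean(covariates[[v]]))
      }
    }
    # polygenic
    g <- if (h2g > 0) sqrt(h2g) * as.vector(L %*% stats::rnorm(n)) else numeric(n)
    # causal genes
    causal <- numeric(n)
    causal_genes <- character(0); causal_snps <- integer(0); effects <- numeric(0)
    if (h2c > 0 && config$n_causal_genes > 0) {
      pick <- sample(eligible, config$n_causal_genes)
      causal_genes <- genes$gene_id[pick]
      h2_per_gene <- h2c / config$n_causal_genes
      for (gi in pick) {
        in_win <- which(genotypes$map$chrom == genes$chrom[gi] &
                          genotypes$map$pos_bp >= genes$start_bp[gi] - window &
                          genotypes$map$pos_bp <= genes$end_bp[gi] + window)
        snps <- sample(in_win, config$causal_snps_per_gene)
        beta <- stats::rnorm(length(snps))
        raw <- as.vector(scale(Ximp[, snps, drop = FALSE], scale = FALSE) %*% beta)
        sd_raw <- stats::sd(raw)
        if (sd_raw > 0) {
          # each causal gene contributes an equal slice of h2_causal
          beta <- beta * sqrt(h2_per_gene) / sd_raw
          causal <- causal + raw * sqrt(h2_per_gene) / sd_raw
        }
        causal_snps <- c(causal_snps, snps)
        effects <- c(effects, beta)
      }
    }
    e <- stats::rnorm(n, 0, sqrt(sigma2_e))
    y_std <- fixed + g + causal + e
    phen[[tr]] <- scale[["mean"]] + scale[["sd"]] * y_std
    nonfixed_var <- stats::var(g + causal + e)
    truth[[tr]] <- list(
      causal_genes = causal_genes,
      causal_snp_idx = causal_snps,
      causal_snp_ids = genotypes$map$snp_id[causal_snps],
      causal_effects = effects * scale[["sd"]],
      fixed_effects = fx,
      sigma2_g = h2g * scale[["sd"]]^2,
      sigma2_e = sigma2_e * scale[["sd"]]^2,
      realized_h2_polygenic = stats::var(g) / nonfixed_var,
      realized_h2_causal = stats::var(causal) / nonfixed_var,
      components = data.frame(fixed = fixed * scale[["sd"]],
                              g = g * scale[["sd"]],
                              causal = causal * scale[["sd"]],
                              e = e * scale[["sd"]])
    )
  }
  structure(list(genotypes = genotypes, genes = genes, phenotypes = phen,
                 covariates = covariates, truth = truth, config = config),
            class = "sim_output")
}

#' Simulate a full synthetic population
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulate_gene_map()] and [simulate_phenotypes()].
#'
#' @param config a [sim_config()].
#' @return a `sim_output` list; see [simulate_phenotypes()].
#' @export
simulate_population <- function(config) {
  g <- simulate_genotypes(config)
  genes <- simulate_gene_map(config, g)
  simulate_phenotypes(config, g, genes)
}

# ---- annotation and table writers -------------------------------------------

#' Write gene models as BED6 (0-based half-open)
#' @param genes gene model data.frame (see [simulate_gene_map()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(genes$chrom, as.integer(genes$start_bp) - 1L,
                    as.integer(genes$end_bp), genes$gene_id, 0L, "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3 (1-based closed)
#' @inheritParams write_gene_bed
#' @return invisibly, `path`.
#' @export
write_gene_gff3 <- function(genes, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  attr_col <- sprintf("ID=%s;Name=%s;biotype=%s",
                      genes$gene_id, genes$symbol, genes$biotype)
  rows <- paste(genes$chrom, "genegwas", "gene",
                as.integer(genes$start_bp), as.integer(genes$end_bp),
                ".", "+", ".", attr_col, sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Read gene models from GFF3 or BED
#'
#' Uses `rtracklayer` and normalizes to the package's 1-based inclusive
#' gene-model data.frame (BED's 0-based half-open starts are shifted on
#' read). For GFF3, only `gene`-type features are kept when a type column
#' is present.
#'
#' @param path annotation file (`.gff3`/`.gff` or `.bed`).
#' @return gene model data.frame as from [simulate_gene_map()].
#' @export
read_gene_annotation <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  df <- as.data.frame(gr)
  if (fmt == "gff3") {
    if (!is.null(df$type)) df <- df[df$type == "gene", , drop = FALSE]
    gene_id <- if (!is.null(df$ID)) as.character(df$ID) else
      sprintf("gene%d", seq_len(nrow(df)))
    symbol <- if (!is.null(df$Name)) as.character(df$Name) else gene_id
    biotype <- if (!is.null(df$biotype)) as.character(df$biotype) else NA_character_
  } else {
    gene_id <- if (!is.null(df$name)) as.character(df$name) else
      sprintf("gene%d", seq_len(nrow(df)))
    symbol <- gene_id
    biotype <- NA_character_
  }
  # rtracklayer already returns 1-based inclusive starts for both formats
  data.frame(gene_id = gene_id, symbol = symbol,
             chrom = as.character(df$seqnames),
             start_bp = as.numeric(df$start), end_bp = as.numeric(df$end),
             biotype = biotype, stringsAsFactors = FALSE)
}

#' Write the phenotype + covariate table as TSV
#' @param sim a `sim_output` from [simulate_population()], or a data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_phenotypes <- function(sim, path) {
  df <- if (inherits(sim, "sim_output"))
    merge(sim$phenotypes, sim$covariates, by = "id", sort = FALSE) else sim
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype + covariate TSV
#' @param path TSV with header, one row per individual, `id` column first.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
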