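#' Fixed-effect design matrix for the single-marker model
#'
#' Builds the incidence matrix `X` of the mixed model from the covariate
#' table (year, farm, gender, fattening days, entering weight) and,
#' optionally, structure PC scores, with an intercept and treatment-coded
#' factors.
#'
#' @param covariates data.frame with an `id` column and covariate columns.
#' @param pcs optional [structure_pcs()] object or score matrix with id
#'   rownames.
#' @return numeric design matrix with rownames = individual ids.
#' @export
mlm_design <- function(covariates, pcs = NULL) {
  stopifnot(is.data.frame(covariates), "id" %in% names(covariates))
  df <- covariates
  for (v in setdiff(names(df), "id"))
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  rhs <- setdiff(names(df), "id")
  X <- stats::model.matrix(stats::reformulate(if (length(rhs)) rhs else "1"),
                           data = df)
  rownames(X) <- df$id
  if (!is.null(pcs)) {
    scores <- if (inherits(pcs, "StructurePCs")) pcs$scores else as.matrix(pcs)
    idx <- match(df$id, rownames(scores))
    if (anyNA(idx)) stop("PC scores missing for some individuals")
    X <- cbind(X, scores[idx, , drop = FALSE])
  }
  X
}

#' REML variance components for the null mixed model
#'
#' Fits `y = X b + u + e`, `u ~ N(0, sigma2_g K)`, `e ~ N(0, sigma2_e I)`
#' by restricted maximum likelihood, using the eigendecomposition of `K` to
#' reduce the problem to a one-dimensional optimization over the variance
#' ratio `delta = sigma2_g / sigma2_e`. The components are estimated once
#' on the null (no-SNP) model and reused for every marker test
#' ("population parameters previously determined").
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (full rank, includes intercept).
#' @param K a [vanraden_grm()] `KinshipMatrix` or a symmetric PSD matrix.
#' @param K_eigen optional precomputed `eigen(K, symmetric = TRUE)`, reused
#'   when many traits or replicate phenotypes are fitted against one
#'   kinship matrix.
#' @return object of class `MlmFit`: `sigma2_g`, `sigma2_e`, `h2`
#'   (= sigma2_g / (sigma2_g + sigma2_e)), `delta`, `loglik` (restricted),
#'   `beta`, plus the rotation (`U`, `d`) and rotated data reused by
#'   [snp_scan()].
#' @export
fit_variance_components <- function(y, X, K, K_eigen = NULL) {
  Km <- if (inherits(K, "KinshipMatrix")) K$values else as.matrix(K)
  n <- length(y)
  stopifnot(nrow(Km) == n, nrow(X) == n)
  if (max(abs(Km - t(Km))) > 1e-8) stop("K must be symmetric")
  eK <- if (is.null(K_eigen)) eigen(Km, symmetric = TRUE) else K_eigen
  if (min(eK$values) < -1e-6 * max(abs(eK$values)))
    stop("K is not positive semi-definite (eigenvalue ",
         signif(min(eK$values), 3), ")")
  d <- pmax(eK$values, 0)
  U <- eK$vectors
  ys <- crossprod(U, y)
  Xs <- crossprod(U, X)
  q <- qr(X)$rank
  if (q < ncol(X)) stop("X is rank-deficient")

  reml <- function(log_delta) {
    delta <- exp(log_delta)
    D <- delta * d + 1
    w <- 1 / D
    A <- Xs * sqrt(w)
    b <- ys * sqrt(w)
    qa <- qr(A)
    r <- stats::residuals(stats::lm.fit(A, b))
    rss <- sum(r^2)
    s2e <- rss / (n - q)
    R <- qr.R(qa)
    logdet_xvx <- 2 * sum(log(abs(diag(R))))
    -0.5 * ((n - q) * (log(2 * pi * s2e) + 1) + sum(log(D)) + logdet_xvx)
  }
  lo <- -12; hi <- 12
  opt <- stats::optimize(reml, c(lo, hi), maximum = TRUE, tol = 1e-8)
  # prefer the OLS boundary (delta -> 0) when the surface is flat there,
  # e.g. K = I where only sigma2_g + sigma2_e is identifiable
  if (reml(lo) >= opt$objective - 1e-8)
    opt <- list(maximum = lo, objective = reml(lo))
  delta <- exp(opt$maximum)
  boundary <- opt$maximum <= lo + 1e-6
  if (boundary) {
    warning("sigma2_g estimate at zero boundary; scan proceeds as OLS")
    delta <- 0
  }
  D <- delta * d + 1
  w <- 1 / D
  A <- Xs * sqrt(w); b <- ys * sqrt(w)
  fit0 <- stats::lm.fit(A, b)
  s2e <- sum(stats::residuals(fit0)^2) / (n - q)
  structure(list(
    sigma2_g = delta * s2e, sigma2_e = s2e,
    h2 = delta / (delta + 1), delta = delta,
    loglik = opt$objective, beta = stats::coef(fit0),
    U = U, d = d, ys = as.vector(ys), Xs = Xs, q = q,
    n = n, boundary = boundary
  ), class = "MlmFit")
}

#' @export
print.MlmFit <- function(x, ...) {
  cat(sprintf("MlmFit: sigma2_g = %.4g, sigma2_e = %.4g (h2 = %.3f)%s\n",
              x$sigma2_g, x$sigma2_e, x$h2,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Single-marker mixed-model scan
#'
#' Tests each SNP with generalized least squares under the covariance
#' `sigma2_g K + sigma2_e I` fixed at the null-model REML estimates. The
#' eigen-rotation of [fit_variance_components()] turns every marker test
#' into a weighted regression: the SNP vector (mean-imputed) is rotated,
#' residualized against the fixed effects, and its effect, standard error
#' and two-sided t-test on `n - rank(X) - 1` degrees of freedom computed in
#' closed form. Monomorphic SNPs are skipped (NA row) with a warning.
#'
#' @param model an `MlmFit` from [fit_variance_components()].
#' @param g a [genotype_matrix()] with the same individuals, same order.
#' @return data.frame of class `snp_scan` with columns `snp_id`, `chrom`,
#'   `pos_bp`, `effect`, `se`, `t`, `p_value`, `maf`; attribute `df`.
#' @export
snp_scan <- function(model, g) {
  stopifnot(inherits(model, "MlmFit"), inherits(g, "GenotypeMatrix"))
  n <- model$n
  if (nrow(g$codes) != n) stop("genotypes and model dimension disagree")
  W <- impute_genotypes(g)
  maf <- minor_allele_frequency(g)
  w <- 1 / (model$delta * model$d + 1)
  sw <- sqrt(w)
  b <- model$ys * sw
  A <- model$Xs * sw
  Ws <- crossprod(model$U, W) * sw
  qa <- qr(A)
  e_y <- stats::residuals(stats::lm.fit(A, b))
  E_w <- Ws - qr.fitted(qa, Ws)
  s_w <- colSums(E_w^2)
  mono <- s_w <= 1e-10
  if (any(mono))
    warning(sum(mono), " monomorphic/degenerate SNP(s) skipped")
  cross <- as.vector(crossprod(E_w, e_y))
  df <- n - model$q - 1L
  effect <- ifelse(mono, NA_real_, cross / s_w)
  rss <- sum(e_y^2) - ifelse(mono, 0, cross^2 / s_w)
  s2 <- rss / df
  se <- ifelse(mono, NA_real_, sqrt(s2 / s_w))
  tt <- effect / se
  p <- 2 * stats::pt(-abs(tt), df = df)
  res <- data.frame(snp_id = g$map$snp_id, chrom = g$map$chrom,
                    pos_bp = g$map$pos_bp, effect = effect, se = se,
                    t = tt, p_value = p, maf = maf,
                    stringsAsFactors = FALSE)
  attr(res, "df") <- df
  attr(res, "sigma2_g") <- model$sigma2_g
  attr(res, "sigma2_e") <- model$sigma2_e
  class(res) <- c("snp_scan", "data.frame")
  res
}

#' Genome-wide significance thresholds for a SNP scan
#'
#' The suggestive threshold `1 / n_snps` (one false positive expected per
#' genome scan) and the strict Bonferroni threshold `0.05 / n_snps`.
#'
#' @param n_snps number of markers tested.
#' @param alpha family-wise level for the Bonferroni companion.
#' @return list with `suggestive` and `bonferroni`.
#' @export
suggestive_threshold <- function(n_snps, alpha = 0.05) {
  stopifnot(n_snps >= 1)
  list(suggestive = 1 / n_snps, bonferroni = alpha / n_snps)
}

#' Write SNP-scan results as TSV
#' @param x a [snp_scan()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_snp_scan <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
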